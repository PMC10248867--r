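# Distances, dihedrals (including round-trips through the toy builder) and
# Kabsch superposition, each checked against an independent oracle.

test_that("Euclidean distance matches hand values and rejects bad input", {
  expect_equal(vec_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(vec_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(vec_distance(c(1, 1, 1), c(2, 2, 2)), sqrt(3))
  expect_error(vec_distance(c(Inf, 0, 0), c(0, 0, 0)), "finite")
})

test_that("dihedral angle follows the IUPAC convention (cis 0, trans 180)", {
  p1 <- c(-1, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(2, -1, 0)), 180)
  expect_equal(dihedral_angle(p1, p2, p3, c(2, 1, 0)), 0)
  # p4 rotated +90 degrees about the p2-p3 axis from the cis position
  p4cis <- c(2, 1, 0)
  R <- rotation_matrix(c(1, 0, 0), pi / 2)
  expect_equal(dihedral_angle(p1, p2, p3, as.numeric(R %*% p4cis)), 90,
               tolerance = 1e-9)
  expect_error(dihedral_angle(p1, p2, p2, c(2, 1, 0)), "degenerate")
})

test_that("dihedrals agree with an independent implementation on random points", {
  set.seed(42)
  for (i in 1:100) {
    pts <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    mine <- tryCatch(dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                     error = function(e) NA_real_)
    if (is.na(mine)) next
    ref <- bio3d::torsion.xyz(as.numeric(t(pts)), atm.inc = 4)
    expect_equal(kinconform:::normalize_angle(mine - ref), 0, tolerance = 1e-6)
  }
})

test_that("dihedral is invariant under rigid motion and reverses with order", {
  set.seed(7)
  for (i in 1:25) {
    pts <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    d0 <- tryCatch(dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                   error = function(e) NA_real_)
    if (is.na(d0)) next
    rt <- random_rigid()
    moved <- sweep(pts %*% rt$R, 2, -rt$t)
    expect_equal(dihedral_angle(moved[1, ], moved[2, ], moved[3, ], moved[4, ]),
                 d0, tolerance = 1e-8)
    expect_equal(dihedral_angle(pts[4, ], pts[3, ], pts[2, ], pts[1, ]), d0,
                 tolerance = 1e-8)
  }
})

test_that("backbone dihedrals round-trip through the toy builder", {
  # helical target at DFG-Phe, extended at X-DFG (builder defaults)
  m <- build_toy_kinase(toy_kinase_spec())
  bd <- backbone_dihedrals(m, "A", 238)
  expect_equal(bd$phi, -57, tolerance = 0.5)
  expect_equal(bd$psi, -47, tolerance = 0.5)
  bd2 <- backbone_dihedrals(m, "A", 236)
  expect_equal(bd2$phi, -120, tolerance = 0.5)
  expect_equal(bd2$psi, 130, tolerance = 0.5)
  # explicit phi/psi request
  m3 <- build_toy_kinase(toy_kinase_spec(
    phi_psi = list(xdfg = c(-120, 130), dfg_asp = c(-120, 130),
                   dfg_phe = c(-120, 130))))
  bd3 <- backbone_dihedrals(m3, "A", 237)
  expect_equal(bd3$phi, -120, tolerance = 0.5)
  expect_equal(bd3$psi, 130, tolerance = 0.5)
})

test_that("chain-terminal residues flag the undefined angle as incomplete", {
  m <- build_toy_kinase(toy_kinase_spec())
  first <- backbone_dihedrals(m, "A", 95)
  expect_false(first$phi_complete); expect_true(first$psi_complete)
  last <- backbone_dihedrals(m, "A", 295)
  expect_true(last$phi_complete); expect_false(last$psi_complete)
  expect_error(backbone_dihedrals(m, "A", 999), "not found")
})

test_that("chi1 round-trips through the builder; Gly has no chi1", {
  for (target in c(-60, 180, 65)) {
    m <- build_toy_kinase(toy_kinase_spec(chi1 = target))
    expect_equal(kinconform:::normalize_angle(chi1_angle(m, "A", 238) - target),
                 0, tolerance = 0.5)
  }
  m <- build_toy_kinase(toy_kinase_spec())
  expect_error(chi1_angle(m, "A", 239), "incomplete side chain")  # DFG Gly
})

test_that("superposing a rigidly moved copy gives zero RMSD and keeps all pairs", {
  m <- build_toy_kinase(toy_kinase_spec())
  set.seed(11)
  rt <- random_rigid()
  m2 <- transform_model(m, rt$R, rt$t)
  s <- superpose(m2, m, trim = TRUE)
  expect_lt(s$rmsd_all, 1e-6)
  expect_equal(s$n_pairs_final, s$n_pairs_initial)
  expect_equal(det(s$rotation), 1, tolerance = 1e-6)
})

test_that("iterative trimming rejects a planted outlier", {
  m <- build_toy_kinase(toy_kinase_spec())
  m2 <- m
  i <- which(m2$atoms$resno == 150 & m2$atoms$atom == "CA")
  m2$atoms$x[i] <- m2$atoms$x[i] + 10
  s <- superpose(m2, m, trim = list(cycles = 5, factor = 2.0))
  expect_equal(s$rejected, "A:150")
  expect_lt(s$rmsd_trimmed, 1e-6)
  expect_gt(s$rmsd_all, 0.5)
  expect_lte(s$rmsd_trimmed, s$rmsd_all)
})

test_that("Kabsch RMSD matches a brute-force rotation search on small sets", {
  # independent oracle: minimise RMSD directly over Euler angles
  brute_rmsd <- function(X, Y) {
    Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
    obj <- function(ang) {
      R <- rotation_matrix(c(1, 0, 0), ang[1]) %*%
        rotation_matrix(c(0, 1, 0), ang[2]) %*%
        rotation_matrix(c(0, 0, 1), ang[3])
      sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
    }
    grid <- as.matrix(expand.grid(a = seq(0, 2 * pi, length.out = 13)[-13],
                                  b = seq(0, pi, length.out = 7),
                                  c = seq(0, 2 * pi, length.out = 13)[-13]))
    vals <- apply(grid, 1, obj)
    best <- grid[which.min(vals), ]
    stats::optim(best, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))$value
  }
  set.seed(5)
  for (i in 1:3) {
    X <- matrix(stats::rnorm(12, sd = 4), 4, 3)
    Y <- matrix(stats::rnorm(12, sd = 4), 4, 3)
    expect_equal(kinconform:::kabsch_fit(X, Y)$rmsd, brute_rmsd(X, Y),
                 tolerance = 1e-3)
  }
})

test_that("superposition RMSD is symmetric and rigid-motion invariant", {
  m <- build_toy_kinase(toy_kinase_spec())
  m2 <- build_toy_kinase(toy_kinase_spec(regions = "ALA", seed = 2))
  s12 <- superpose(m, m2, trim = FALSE)
  s21 <- superpose(m2, m, trim = FALSE)
  expect_equal(s12$rmsd_all, s21$rmsd_all, tolerance = 1e-6)
  set.seed(3)
  rt <- random_rigid()
  s12b <- superpose(transform_model(m, rt$R, rt$t), m2, trim = FALSE)
  expect_equal(s12b$rmsd_all, s12$rmsd_all, tolerance = 1e-6)
})

test_that("Kabsch agrees with the bio3d fitting routine", {
  m <- build_toy_kinase(toy_kinase_spec())
  m2 <- build_toy_kinase(toy_kinase_spec(regions = "ALA", seed = 9))
  s <- superpose(m, m2, trim = FALSE)
  ca1 <- as.matrix(kinconform:::ca_table(m)[, c("x", "y", "z")])
  ca2 <- as.matrix(kinconform:::ca_table(m2)[, c("x", "y", "z")])
  ref_rmsd <- bio3d::rmsd(as.numeric(t(ca2)), as.numeric(t(ca1)), fit = TRUE)
  expect_equal(s$rmsd_all, ref_rmsd, tolerance = 1e-3)
})

test_that("fewer than three pairs is an error", {
  p <- write_mini_pdb(tempfile(fileext = ".pdb"))
  m <- read_structure(p)
  m2 <- m
  m2$atoms <- m2$atoms[!(m2$atoms$resno %in% c(2, 3) & !m2$atoms$is_het), ]
  expect_error(superpose(m2, m), "insufficient pairs")
})
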