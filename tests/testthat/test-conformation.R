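# The classification pipeline: spatial DFG label, Ramachandran regions and
# rotamer bins, dihedral clusters, salt bridge, spines, contacts,
# phospho-sites and the composed verdict.

toy_report <- function(...) {
  m <- build_toy_kinase(toy_kinase_spec(...))
  classify_state(m, find_anchors(extract_sequence(m, "A")))
}

test_that("spatial DFG groups follow the D1/D2 threshold rules", {
  m <- build_toy_kinase(toy_kinase_spec(d1 = 8, d2 = 14))
  a <- find_anchors(extract_sequence(m, "A"))
  s <- spatial_dfg_label(m, a)
  expect_equal(s$group, "DFGin")
  expect_equal(s$d1, 8, tolerance = 0.05)
  expect_equal(s$d2, 14, tolerance = 0.05)
  m2 <- build_toy_kinase(toy_kinase_spec(d1 = 14, d2 = 8))
  expect_equal(spatial_dfg_label(m2, a)$group, "DFGout")
  m3 <- build_toy_kinase(toy_kinase_spec(d1 = 8, d2 = 8))
  expect_equal(spatial_dfg_label(m3, a)$group, "DFGinter")
})

test_that("boundary D1/D2 values follow the <=/>= conventions exactly", {
  a <- find_anchors(extract_sequence(build_toy_kinase(toy_kinase_spec()), "A"))
  # direct evaluation of the rule on exact boundary distances (the builder's
  # 0.05 A construction band is too coarse for boundary equality), then the
  # full pipeline on distances nudged clear of the band
  cases <- list(
    list(d1 = 11, d2 = 11, group = "DFGin", p1 = 10.8, p2 = 11.2),
    list(d1 = 11, d2 = 10.5, group = "DFGinter", p1 = 10.8, p2 = 10.3),
    list(d1 = 11.2, d2 = 11, group = "DFGout", p1 = 11.4, p2 = 10.8),
    list(d1 = 11.2, d2 = 11.2, group = "DFGinter", p1 = 11.4, p2 = 11.4))
  t1 <- kin_config()$d1_threshold; t2 <- kin_config()$d2_threshold
  for (cs in cases) {
    got <- if (cs$d1 <= t1 && cs$d2 >= t2) "DFGin"
           else if (cs$d1 > t1 && cs$d2 <= t2) "DFGout" else "DFGinter"
    expect_equal(got, cs$group)
    m <- build_toy_kinase(toy_kinase_spec(d1 = cs$p1, d2 = cs$p2))
    expect_equal(spatial_dfg_label(m, a)$group, cs$group)
  }
})

test_that("a missing defining atom yields an incomplete spatial label", {
  m <- build_toy_kinase(toy_kinase_spec())
  a <- find_anchors(extract_sequence(m, "A"))
  m$atoms <- m$atoms[!(m$atoms$resno == 238 & m$atoms$atom == "CZ"), ]
  s <- spatial_dfg_label(m, a)
  expect_equal(s$group, "incomplete")
  expect_true(is.na(s$d1))
})

test_that("Ramachandran regions and rotamer bins match their definitions", {
  expect_equal(ramachandran_region(-57, -47), "A")
  expect_equal(ramachandran_region(-120, 130), "B")
  expect_equal(ramachandran_region(60, 40), "L")
  expect_equal(ramachandran_region(60, 170), "E")
  expect_equal(ramachandran_region(-180, -100), "A")  # psi interval closed at -100
  expect_equal(ramachandran_region(-180, -101), "B")
  expect_equal(rotamer_bin(-60), "minus")
  expect_equal(rotamer_bin(65), "plus")
  expect_equal(rotamer_bin(175), "trans")
  expect_equal(rotamer_bin(-120), "minus")
  expect_equal(rotamer_bin(0), "plus")
  expect_equal(rotamer_bin(120), "trans")
})

test_that("dihedral clusters round-trip through the builder", {
  for (case in list(c("BLA", "minus"), c("BLA", "plus"), c("ABL", "trans"),
                    c("EBA", "minus"))) {
    r <- toy_report(regions = case[1], rotamer = case[2])
    expect_equal(r$cluster$name, paste0(case[1], case[2]))
  }
})

test_that("salt-bridge presence follows the N-O cutoff", {
  m <- build_toy_kinase(toy_kinase_spec(bridge = 3.0))
  a <- find_anchors(extract_sequence(m, "A"))
  sb <- salt_bridge(m, a$beta3_lys, a$alphaC_glu, cutoff = 4.0)
  expect_true(sb$present)
  expect_equal(sb$min_no_distance, 3.0, tolerance = 0.05)
  expect_equal(sb$atom_pair, c("NZ", "OE1"))
  m2 <- build_toy_kinase(toy_kinase_spec(bridge = 5.0))
  expect_false(salt_bridge(m2, a$beta3_lys, a$alphaC_glu, cutoff = 4.0)$present)
  # all side-chain atoms missing -> incomplete, not an error
  m3 <- m
  m3$atoms <- m3$atoms[!(m3$atoms$resno == 124 & m3$atoms$atom == "NZ"), ]
  expect_false(salt_bridge(m3, a$beta3_lys, a$alphaC_glu)$complete)
})

test_that("spines assemble at stacking distance and break when displaced", {
  m <- build_toy_kinase(toy_kinase_spec())
  a <- find_anchors(extract_sequence(m, "A"))
  r <- spine_assembly(m, a, "R")
  expect_true(r$assembled)
  expect_true(all(r$adjacent_gaps <= 4.5))
  expect_equal(r$anchor_hbond, 3.0, tolerance = 0.05)
  cs <- spine_assembly(m, a, "C")
  expect_true(cs$assembled)
  expect_equal(length(cs$members), 9L)   # adenine joins the stack
  m2 <- build_toy_kinase(toy_kinase_spec(r_spine_gap = 8.0))
  expect_false(spine_assembly(m2, a, "R")$assembled)
  m3 <- build_toy_kinase(toy_kinase_spec(c_spine_gap = 8.0))
  expect_false(spine_assembly(m3, a, "C")$assembled)
})

test_that("a missing spine member leaves the spine unassembled with a note", {
  m <- build_toy_kinase(toy_kinase_spec())
  a <- find_anchors(extract_sequence(m, "A"))
  m$atoms <- m$atoms[!(m$atoms$resno == 155 & !m$atoms$is_het), ]
  r <- spine_assembly(m, a, "R")
  expect_false(r$assembled)
  expect_false(r$complete)
  expect_match(r$note, "no resolved heavy atoms")
})

test_that("nucleotide contacts report the Gly-loop hydrogen bond", {
  m <- build_toy_kinase(toy_kinase_spec(contact_distance = 2.9))
  a <- find_anchors(extract_sequence(m, "A"))
  ct <- nucleotide_contacts(m, a)
  expect_true(101 %in% ct$resno)
  expect_equal(ct$distance[ct$resno == 101], 2.9, tolerance = 0.05)
  apo <- build_toy_kinase(toy_kinase_spec(ligand = "none"))
  expect_equal(nrow(nucleotide_contacts(apo, a)), 0L)
})

test_that("phospho-sites are the modified residues inside the activation segment", {
  m <- build_toy_kinase(toy_kinase_spec(phospho = c(250L, 253L, 254L)))
  a <- find_anchors(extract_sequence(m, "A"))
  ps <- phospho_sites(m, a)
  expect_equal(ps$resno, c(250L, 253L, 254L))
  expect_equal(ps$resname, c("TPO", "SEP", "TPO"))
  none <- build_toy_kinase(toy_kinase_spec(phospho = integer(0)))
  expect_equal(nrow(phospho_sites(none, a)), 0L)
  one <- build_toy_kinase(toy_kinase_spec(phospho = 250L))
  expect_equal(phospho_sites(one, a)$resno, 250L)
})

test_that("the verdict is the conjunction of bridge, DFGin, BLAminus and R-spine", {
  expect_equal(toy_report()$verdict, "active")
  expect_equal(toy_report(bridge = 6.0)$verdict, "inactive")
  expect_equal(toy_report(d1 = 14, d2 = 8)$verdict, "inactive")
  expect_equal(toy_report(rotamer = "plus")$verdict, "inactive")
  expect_equal(toy_report(regions = "ABL")$verdict, "inactive")
  expect_equal(toy_report(r_spine_gap = 8.0)$verdict, "inactive")
  expect_equal(toy_report(anchor_hbond = 6.0)$verdict, "inactive")
  # restoring the failing conjunct restores the active verdict
  expect_equal(toy_report(bridge = 3.0)$verdict, "active")
})

test_that("incomplete components propagate to an indeterminate verdict", {
  m <- build_toy_kinase(toy_kinase_spec())
  a <- find_anchors(extract_sequence(m, "A"))
  m$atoms <- m$atoms[!(m$atoms$resno == 238 & m$atoms$atom %in%
                         c("CB", "CG", "CD1", "CD2", "CE1", "CZ")), ]
  r <- classify_state(m, a)
  expect_equal(r$spatial$group, "incomplete")
  expect_false(r$cluster$complete)
  expect_equal(r$verdict, "indeterminate")
})

test_that("classification is invariant under global rigid motion", {
  m <- build_toy_kinase(toy_kinase_spec())
  a <- find_anchors(extract_sequence(m, "A"))
  r0 <- classify_state(m, a)
  set.seed(21)
  for (i in 1:3) {
    rt <- random_rigid()
    r1 <- classify_state(transform_model(m, rt$R, rt$t), a)
    expect_equal(r1$verdict, r0$verdict)
    expect_equal(r1$cluster$name, r0$cluster$name)
    expect_equal(r1$spatial$d1, r0$spatial$d1, tolerance = 1e-6)
    expect_equal(r1$spatial$d2, r0$spatial$d2, tolerance = 1e-6)
    expect_equal(r1$salt_bridge$min_no_distance, r0$salt_bridge$min_no_distance,
                 tolerance = 1e-6)
    expect_equal(r1$r_spine$assembled, r0$r_spine$assembled)
  }
})

test_that("the alphaC status mirrors the salt bridge", {
  expect_equal(toy_report()$alphaC_status, "in")
  expect_equal(toy_report(bridge = 6.0)$alphaC_status, "out")
})
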