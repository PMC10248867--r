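# Synthetic inputs with known ground truth for every pipeline stage: toy
# kinase coordinate models with controllable dihedrals, D1/D2 placement,
# salt-bridge geometry, spine stacking and bound nucleotide; alignments
# evolved on a known tree; and qPCR Ct tables with known fold changes.

REGION_PHIPSI <- list(A = c(-57, -47), B = c(-120, 130),
                      L = c(60, 40),  E = c(60, 170))
ROTAMER_CHI1 <- c(minus = -60, plus = 60, trans = 180)

#' Specification for a toy kinase coordinate model
#'
#' The defaults plant the full conserved-motif architecture at kinase-domain
#' style author numbering (Gly loop at 99/101/104, beta3 Ala-x-Lys at
#' 122-124, alphaC Glu at 140, catalytic-loop YRD at 217, DFG at 237, APE at
#' 260, alphaF Asp at 278) and a fully active geometry: BLA dihedrals with a
#' gauche-minus DFG-Phe, D1/D2 of 8/14 A (DFGin under the default 11/11
#' thresholds), a 3.0 A beta3-Lys/alphaC-Glu salt bridge, both spines stacked
#' at 4.0 A with a 3.0 A alphaF anchor bond, phosphothreonine/-serine at
#' 250/253/254, and bound ATP plus Mg.
#'
#' @param regions 3-char string over A/B/L/E for the X-DFG, DFG-Asp and
#'   DFG-Phe backbone (realised through representative phi/psi pairs), or
#'   NULL to use `phi_psi`.
#' @param phi_psi Optional explicit list with `xdfg`, `dfg_asp`, `dfg_phe`
#'   numeric (phi, psi) pairs; overrides `regions`.
#' @param rotamer DFG-Phe chi1 bin ("minus", "plus", "trans") or use `chi1`.
#' @param chi1 Explicit DFG-Phe chi1 in degrees; overrides `rotamer`.
#' @param d1,d2 Target distances (A) from the alphaC-Glu+4 and beta3-Lys
#'   C-alpha to the DFG-Phe C-zeta.
#' @param bridge Target beta3-Lys NZ to alphaC-Glu OE1 distance (A).
#' @param r_spine_gap,c_spine_gap Spacing (A) of consecutive spine contact
#'   atoms (4.0 stacks the spine; 8.0 breaks it).
#' @param anchor_hbond Catalytic-loop backbone to alphaF-Asp side-chain O
#'   distance (A).
#' @param phospho Residue numbers written as phospho residues (TPO/SEP).
#' @param ligand "ATP", "ADP" or "none".
#' @param mg Include a magnesium ion next to the DFG-Asp carboxylate.
#' @param contact_distance Gly-loop backbone N to phosphate O distance (A).
#' @param start_resno,len Chain numbering and length.
#' @param chain Chain id.
#' @param jitter Gaussian coordinate noise sd (A), seeded; 0 keeps the model
#'   exactly on target.
#' @param seed RNG seed; the builder is a pure function of (spec, seed).
#' @return A `toy_kinase_spec` list.
#' @export
toy_kinase_spec <- function(regions = "BLA", phi_psi = NULL,
                            rotamer = "minus", chi1 = NULL,
                            d1 = 8, d2 = 14, bridge = 3.0,
                            r_spine_gap = 4.0, c_spine_gap = 4.0,
                            anchor_hbond = 3.0,
                            phospho = c(250L, 253L, 254L),
                            ligand = c("ATP", "ADP", "none"), mg = TRUE,
                            contact_distance = 2.9,
                            start_resno = 95L, len = 201L, chain = "A",
                            jitter = 0, seed = 1L) {
  ligand <- match.arg(ligand)
  if (is.null(phi_psi)) {
    stopifnot(nchar(regions) == 3L,
              all(strsplit(regions, "")[[1]] %in% names(REGION_PHIPSI)))
    r <- strsplit(regions, "")[[1]]
    phi_psi <- list(xdfg = REGION_PHIPSI[[r[1]]], dfg_asp = REGION_PHIPSI[[r[2]]],
                    dfg_phe = REGION_PHIPSI[[r[3]]])
  }
  if (is.null(chi1)) chi1 <- ROTAMER_CHI1[[match.arg(rotamer, names(ROTAMER_CHI1))]]
  if (any(c(d1, d2, bridge, r_spine_gap, c_spine_gap, anchor_hbond) <= 0))
    stop("toy_kinase_spec: all target distances must be positive")
  spec <- list(phi_psi = phi_psi, chi1 = chi1, d1 = d1, d2 = d2,
               bridge = bridge, r_spine_gap = r_spine_gap,
               c_spine_gap = c_spine_gap, anchor_hbond = anchor_hbond,
               phospho = as.integer(phospho), ligand = ligand, mg = mg,
               contact_distance = contact_distance,
               start_resno = as.integer(start_resno), len = as.integer(len),
               chain = chain, jitter = jitter, seed = as.integer(seed))
  class(spec) <- "toy_kinase_spec"
  spec
}

# motif layout of the toy (author residue numbers)
TOY_MOTIFS <- list(gly = c(99L, 101L, 104L), beta2 = 103L,
                   beta3_ala = 122L, beta3_lys = 124L,
                   alphaC_glu = 140L, alphaC_plus4 = 144L, beta4 = 155L,
                   hinge = 169L:172L, alphaD = 177L,
                   cat_loop = 217L, catloop_c = 225L:227L,
                   dfg = 237L, act_thr = c(250L, 253L, 254L),
                   ape = 260L, alphaF_asp = 278L, alphaF_c = c(285L, 289L))

toy_sequence <- function(spec) {
  n <- spec$len; s0 <- spec$start_resno
  letters <- rep("A", n)
  set <- function(resno, aa) {
    i <- resno - s0 + 1L
    stopifnot(all(i >= 1L & i <= n))
    letters[i] <<- strsplit(aa, "")[[1]]
  }
  M <- TOY_MOTIFS
  set(M$gly, "GGG"); set(M$beta2, "V")
  set(M$beta3_lys, "K")                  # beta3 is A-x-K on the Ala background
  set(M$alphaC_glu, "E"); set(M$alphaC_plus4, "L"); set(M$beta4, "L")
  set(M$hinge, "YEQM"); set(M$alphaD, "L")
  set(M$cat_loop, "Y"); set(M$cat_loop + 1L, "R"); set(M$cat_loop + 2L, "D")
  set(M$catloop_c, "ILL")
  set(M$dfg, "D"); set(M$dfg + 1L, "F"); set(M$dfg + 2L, "G")
  set(M$act_thr, "TST")
  set(M$ape, "A"); set(M$ape + 1L, "P"); set(M$ape + 2L, "E")
  set(M$alphaF_asp, "D"); set(M$alphaF_c, "VL")
  letters
}

AA1TO3 <- stats::setNames(names(AA3)[1:20], unname(AA3)[1:20])

# phi/psi schedule: helix everywhere, a beta-hairpin between beta3 and
# alphaC (strands out and back with a tight two-residue turn) so that the
# beta3-Lys and alphaC-Glu+4 C-alphas end up ~12.5 A apart, making the
# default and example D1/D2 constraints realizable; the requested angles are
# applied at X-DFG/Asp/Phe
toy_dihedral_schedule <- function(spec) {
  n <- spec$len; s0 <- spec$start_resno
  phi <- rep(-57, n); psi <- rep(-47, n)
  strand <- (125:143) - s0 + 1L
  phi[strand] <- -120; psi[strand] <- 130
  turn <- (133:134) - s0 + 1L
  phi[turn] <- -30; psi[turn] <- -90
  idx <- function(resno) resno - s0 + 1L
  trio <- c(TOY_MOTIFS$dfg - 1L, TOY_MOTIFS$dfg, TOY_MOTIFS$dfg + 1L)
  tg <- spec$phi_psi
  phi[idx(trio)] <- c(tg$xdfg[1], tg$dfg_asp[1], tg$dfg_phe[1])
  psi[idx(trio)] <- c(tg$xdfg[2], tg$dfg_asp[2], tg$dfg_phe[2])
  list(phi = phi, psi = psi)
}

# grow an ideal-geometry backbone (N, CA, C, O) realising the schedule
toy_backbone <- function(spec) {
  sch <- toy_dihedral_schedule(spec)
  n <- spec$len
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, sch$psi[i])
    CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ], 1.458, 121.7, 180)
    C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ], 1.525, 111.2,
                              sch$phi[i + 1L])
    O[i, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ], 1.231, 120.5, 180)
  }
  O[n, ] <- place_atom(N[n, ], CA[n, ], C[n, ], 1.231, 120.5, 135)
  list(N = N, CA = CA, C = C, O = O)
}

unit3 <- function(v) v / sqrt(sum(v^2))

# point at distance d1 from a and d2 from b, on their intersection circle,
# closest to the steering point `toward`
sphere_sphere_point <- function(a, b, d1, d2, toward) {
  D <- vec_distance(a, b)
  if (D > d1 + d2 - 1e-9 || D < abs(d1 - d2) + 1e-9)
    stop(sprintf(paste0("unrealizable geometry: reference C-alphas are %.2f A apart ",
                        "but target distances d1 = %.2f, d2 = %.2f require ",
                        "separation in (%.2f, %.2f)"),
                 D, d1, d2, abs(d1 - d2), d1 + d2))
  nhat <- unit3(b - a)
  x <- (D^2 + d1^2 - d2^2) / (2 * D)
  r <- sqrt(max(d1^2 - x^2, 0))
  m <- a + x * nhat
  w <- toward - m
  w_perp <- w - sum(w * nhat) * nhat
  if (sqrt(sum(w_perp^2)) < 1e-9) {
    w_perp <- cross3(nhat, c(1, 0, 0))
    if (sqrt(sum(w_perp^2)) < 1e-9) w_perp <- cross3(nhat, c(0, 1, 0))
  }
  m + r * unit3(w_perp)
}

#' Build a toy kinase coordinate model from a specification
#'
#' The backbone is grown by internal-coordinate chain extension (ideal bond
#' lengths N-CA 1.458, CA-C 1.525, C-N 1.329 A, ideal angles, omega 180)
#' realising the requested phi/psi; CB and gamma atoms realise the requested
#' chi1; the DFG-Phe C-zeta, the beta3-Lys NZ, the alphaF-Asp carboxylate and
#' the spine contact atoms are positioned by direct construction so that the
#' target D1/D2, salt-bridge, anchor-bond and spine-gap distances are met
#' within 0.05 A.  Phospho positions are written as modified residues
#' (TPO/SEP); the nucleotide is schematic (adenine ring stacked into the
#' C-spine, phosphate oxygens at the Gly loop) but fully consumable by the
#' classifier.  Deterministic under the spec seed.
#'
#' @param spec A [toy_kinase_spec()].
#' @param path Optional PDB output path.
#' @return A `structure_model` (invisibly written to `path` when given).
#' @export
build_toy_kinase <- function(spec = toy_kinase_spec(), path = NULL) {
  stopifnot(inherits(spec, "toy_kinase_spec"))
  set.seed(spec$seed)
  n <- spec$len; s0 <- spec$start_resno; ch <- spec$chain
  letters <- toy_sequence(spec)
  bb <- toy_backbone(spec)
  idx <- function(resno) resno - s0 + 1L
  M <- TOY_MOTIFS

  resno <- s0 + seq_len(n) - 1L
  resname <- unname(AA1TO3[letters])
  ph <- intersect(spec$phospho, resno)
  resname[idx(ph)] <- ifelse(letters[idx(ph)] == "S", "SEP", "TPO")

  # backbone + CB assembled vectorized; special atoms appended via add()
  cb <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (letters[i] == "G") next
    cb[i, ] <- place_atom(bb$C[i, ], bb$N[i, ], bb$CA[i, ], 1.53, 110.4, 122.7)
  }
  hascb <- !is.na(cb[, 1])
  bb_names <- c("N", "CA", "C", "O")
  bb_el <- c("N", "C", "C", "O")
  xyz0 <- rbind(bb$N, bb$CA, bb$C, bb$O, cb[hascb, , drop = FALSE])
  base <- data.frame(
    chain = ch,
    resno = c(rep(resno, 4), resno[hascb]),
    icode = "",
    resname = c(rep(resname, 4), resname[hascb]),
    atom = c(rep(bb_names, each = n), rep("CB", sum(hascb))),
    element = c(rep(bb_el, each = n), rep("C", sum(hascb))),
    x = xyz0[, 1], y = xyz0[, 2], z = xyz0[, 3], occ = 1, b = 0,
    stringsAsFactors = FALSE)
  atoms <- list(base)
  add <- function(resno_i, rn, atom, el, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      chain = ch, resno = resno_i, icode = "", resname = rn, atom = atom,
      element = el, x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, b = 0,
      stringsAsFactors = FALSE)
  }
  gamma_of <- function(i, chi1, name, el = "C") {
    g <- place_atom(bb$N[i, ], bb$CA[i, ], cb[i, ], 1.52, 114, chi1)
    add(resno[i], resname[i], name, el, g)
    g
  }

  # alphaC-Glu carboxylate (schematic, extended from CB)
  ie <- idx(M$alphaC_glu)
  cg_e <- gamma_of(ie, -60, "CG")
  cd_e <- cg_e + 1.52 * unit3(cg_e - cb[ie, ])
  oe1 <- cd_e + 1.25 * unit3(cd_e - cg_e)
  add(M$alphaC_glu, "GLU", "CD", "C", cd_e)
  add(M$alphaC_glu, "GLU", "OE1", "O", oe1)
  add(M$alphaC_glu, "GLU", "OE2", "O", oe1 + c(0, 0, 1.2))

  # beta3-Lys NZ placed directly on the OE1 -> Lys-CB line at the target
  # bridge distance
  ik <- idx(M$beta3_lys)
  nz <- oe1 + spec$bridge * unit3(cb[ik, ] - oe1)
  add(M$beta3_lys, "LYS", "NZ", "N", nz)

  # DFG-Phe: chi1-exact CG, then C-zeta directly on the D1/D2 spheres
  ifp <- idx(M$dfg + 1L)
  cg_f <- gamma_of(ifp, spec$chi1, "CG")
  cz <- sphere_sphere_point(bb$CA[idx(M$alphaC_plus4), ], bb$CA[ik, ],
                            spec$d1, spec$d2, cg_f)
  add(M$dfg + 1L, "PHE", "CD1", "C", cg_f + (cz - cg_f) / 3)
  add(M$dfg + 1L, "PHE", "CE1", "C", cg_f + 2 * (cz - cg_f) / 3)
  add(M$dfg + 1L, "PHE", "CZ", "C", cz)

  # DFG-Asp carboxylate and the Mg site
  ida <- idx(M$dfg)
  cg_d <- gamma_of(ida, -60, "CG")
  od1_d <- cg_d + 1.25 * unit3(cg_d - cb[ida, ])
  add(M$dfg, "ASP", "OD1", "O", od1_d)
  add(M$dfg, "ASP", "OD2", "O", od1_d + c(1.2, 0, 0))

  # catalytic-loop aromatic gamma (tyrosine)
  iy <- idx(M$cat_loop)
  gamma_of(iy, -60, "CG")

  # alphaF-Asp: side-chain O at the target anchor-bond distance from the
  # catalytic-loop backbone N, pointing away from its backbone O
  iaf <- idx(M$alphaF_asp)
  gamma_of(iaf, -60, "CG")
  u <- unit3(bb$N[iy, ] - bb$O[iy, ])
  od1_af <- bb$N[iy, ] + spec$anchor_hbond * u
  add(M$alphaF_asp, "ASP", "OD1", "O", od1_af)
  add(M$alphaF_asp, "ASP", "OD2", "O", od1_af + 1.0 * u)

  # R-spine contact atoms on a line with the requested spacing
  dirR <- unit3(c(1, 1, 1))
  baseR <- bb$CA[idx(M$beta4), ] + 4 * dirR
  pR <- lapply(0:3, function(k) baseR + k * spec$r_spine_gap * dirR)
  add(M$beta4, "LEU", "CD1", "C", pR[[1]])
  add(M$alphaC_plus4, "LEU", "CD1", "C", pR[[2]])
  add(M$dfg + 1L, "PHE", "CD2", "C", pR[[3]])
  add(M$cat_loop, "TYR", "CD1", "C", pR[[4]])

  # C-spine contact atoms; slot 3 is reserved for the adenine ring
  dirC <- unit3(c(1, -1, 1))
  baseC <- bb$CA[idx(M$alphaD), ] + 4 * dirC
  qC <- lapply(0:8, function(k) baseC + k * spec$c_spine_gap * dirC)
  add(M$beta2, "VAL", "CG1", "C", qC[[1]])
  add(M$beta3_ala, "ALA", "CB2", "C", qC[[2]])
  add(M$alphaD, "LEU", "CD1", "C", qC[[4]])
  add(M$catloop_c[1], "ILE", "CD1", "C", qC[[5]])
  add(M$catloop_c[2], "LEU", "CD1", "C", qC[[6]])
  add(M$catloop_c[3], "LEU", "CD1", "C", qC[[7]])
  add(M$alphaF_c[1], "VAL", "CG1", "C", qC[[8]])
  add(M$alphaF_c[2], "LEU", "CD1", "C", qC[[9]])

  # schematic nucleotide: adenine ring stacked into the C-spine slot,
  # phosphate oxygens hydrogen-bonding the Gly loop
  if (spec$ligand != "none") {
    lig_resno <- max(resno) + 10L
    center <- qC[[3]]
    e1 <- unit3(cross3(dirC, c(0, 0, 1)))
    e2 <- unit3(cross3(dirC, e1))
    ring_el <- ifelse(substr(ADENINE_ATOMS, 1, 1) == "N", "N", "C")
    add(lig_resno, spec$ligand, "N9", "N", center)
    for (j in seq_along(ADENINE_ATOMS)[-10]) {
      th <- 2 * pi * j / 9
      add(lig_resno, spec$ligand, ADENINE_ATOMS[j], ring_el[j],
          center + 1.2 * (cos(th) * e1 + sin(th) * e2))
    }
    ig <- idx(M$gly[2])
    up <- unit3(bb$N[ig, ] - bb$CA[ig, ])
    o_contact <- bb$N[ig, ] + spec$contact_distance * up
    pname <- if (spec$ligand == "ATP") "PG" else "PB"
    oname <- if (spec$ligand == "ATP") c("O1G", "O2G", "O3G") else c("O1B", "O2B", "O3B")
    add(lig_resno, spec$ligand, oname[1], "O", o_contact)
    p_at <- o_contact + 1.5 * up
    add(lig_resno, spec$ligand, pname, "P", p_at)
    add(lig_resno, spec$ligand, oname[2], "O", p_at + 1.48 * unit3(c(1, 0, 0)))
    add(lig_resno, spec$ligand, oname[3], "O", p_at + 1.48 * unit3(c(0, 1, 0)))
    if (spec$mg)
      add(lig_resno + 1L, "MG", "MG", "MG", od1_d + 2.1 * unit3(cg_d - cb[ida, ]))
  }

  at <- do.call(rbind, atoms)
  at$one_letter <- ifelse(at$resname %in% names(AA3), AA3[at$resname],
                   ifelse(at$resname %in% names(default_phospho_map()),
                          default_phospho_map()[at$resname], "X"))
  at$is_phospho <- at$resname %in% names(default_phospho_map())
  is_poly <- at$resname %in% c(names(AA3), names(default_phospho_map()))
  at$category <- ifelse(is_poly, "polymer",
                 ifelse(at$resname %in% NUCLEOTIDE_NAMES, "nucleotide",
                 ifelse(at$resname %in% METAL_NAMES, "metal", "other")))
  at$is_het <- at$category != "polymer"
  if (spec$jitter > 0) {
    at$x <- at$x + stats::rnorm(nrow(at), 0, spec$jitter)
    at$y <- at$y + stats::rnorm(nrow(at), 0, spec$jitter)
    at$z <- at$z + stats::rnorm(nrow(at), 0, spec$jitter)
  }
  at <- at[order(at$is_het, at$chain, at$resno, at$icode), , drop = FALSE]
  rownames(at) <- NULL
  model <- structure(list(model_id = sprintf("toy_kinase_seed%d", spec$seed),
                          source_format = "TOY", atoms = at),
                     class = "structure_model")
  if (spec$jitter == 0) {
    m_d1 <- vec_distance(bb$CA[idx(M$alphaC_plus4), ], cz)
    m_d2 <- vec_distance(bb$CA[ik, ], cz)
    m_br <- vec_distance(nz, oe1)
    stopifnot(abs(m_d1 - spec$d1) < 0.05, abs(m_d2 - spec$d2) < 0.05,
              abs(m_br - spec$bridge) < 0.05)
  }
  if (!is.null(path)) write_structure(model, path)
  model
}

#' Evolve an amino-acid alignment on a known tree
#'
#' The root sequence is uniform over the 20 amino acids; along each branch a
#' Poisson(branch length x rate x length) number of substitutions hits
#' uniformly chosen sites, each replaced by a uniformly chosen different
#' residue.  Gap-free by construction.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param length Number of alignment columns.
#' @param subs_rate Per-site substitution rate multiplier.
#' @param seed RNG seed.
#' @return An `aa_alignment` (see [read_alignment()]).
#' @export
simulate_alignment <- function(tree, length, subs_rate = 1, seed = 1L) {
  ncol <- as.integer(length)
  stopifnot(inherits(tree, "phylo"), subs_rate >= 0, ncol >= 1)
  set.seed(seed)
  aas <- unique(unname(AA3)[1:20])
  ntip <- base::length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample(aas, ncol, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    bl <- ord$edge.length[k]
    s <- seqs[[par]]
    nsub <- stats::rpois(1, bl * subs_rate * ncol)
    if (nsub > 0) {
      sites <- sample.int(ncol, nsub, replace = TRUE)
      for (site in sites) s[site] <- sample(setdiff(aas, s[site]), 1)
    }
    seqs[[child]] <- s
  }
  rows <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), "")
  new_alignment(tree$tip.label, rows)
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Target Ct is `ct_target_base - log2(fold)` plus Gaussian noise; reference
#' Ct is `ct_ref_base` plus Gaussian noise.  With zero noise the 2^-ddCt
#' computation recovers each group's fold exactly (relative to the group
#' whose fold is 1).
#'
#' @param groups Named numeric vector of true fold changes (> 0); include the
#'   calibrator at fold 1.
#' @param n_reps Replicates per group.
#' @param ct_ref_base Reference-gene Ct baseline (cycles).
#' @param noise_sd Gaussian Ct noise sd (cycles).
#' @param seed RNG seed.
#' @param ct_target_base Target-gene Ct baseline at fold 1.
#' @return A `ct_table` data frame (sample, group, ct_target, ct_reference).
#' @export
simulate_ct_table <- function(groups, n_reps = 3L, ct_ref_base = 20,
                              noise_sd = 0, seed = 1L,
                              ct_target_base = ct_ref_base + 2) {
  stopifnot(all(groups > 0), !is.null(names(groups)))
  set.seed(seed)
  rows <- lapply(names(groups), function(g) {
    data.frame(
      sample = sprintf("%s_%d", g, seq_len(n_reps)), group = g,
      ct_target = ct_target_base - log2(groups[[g]]) +
        stats::rnorm(n_reps, 0, noise_sd),
      ct_reference = ct_ref_base + stats::rnorm(n_reps, 0, noise_sd),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ct_table", "data.frame")
  out
}
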