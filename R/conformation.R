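# The conformational-state classification pipeline for kinase domain
# structures: spatial DFG label from the D1/D2 distances, the
# Ramachandran-region/chi1-rotamer dihedral cluster (e.g. BLAminus), the
# beta3-Lys/alphaC-Glu salt bridge, catalytic- and regulatory-spine assembly,
# nucleotide contacts, activation-segment phospho-sites, and the composed
# active/inactive verdict.

#' Classification configuration with defaults
#'
#' All geometric cutoffs used by the classification, echoed verbatim into
#' every report.  Defaults: D1/D2 spatial thresholds 11.0 A each (the D1/D2
#' construction defines the spatial groups; the thresholds are the
#' literature-conventional values and are configurable); salt bridge 4.0 A
#' (min side-chain N-O); spine contact 4.5 A (min heavy-atom); hydrogen bond
#' 3.5 A; Ramachandran region boundaries as rectangular approximations (see
#' [ramachandran_region()]).
#'
#' @param d1_threshold,d2_threshold Spatial DFG thresholds t1, t2 (Angstrom).
#' @param salt_bridge_cutoff Salt-bridge N-O cutoff (Angstrom).
#' @param contact_cutoff Spine adjacent-member heavy-atom cutoff (Angstrom).
#' @param hbond_cutoff Hydrogen-bond cutoff (Angstrom), used for the R-spine
#'   alphaF anchor and for nucleotide contacts.
#' @param rama_boundaries List with `A_psi` and `L_psi` half-open psi ranges.
#' @param trim Superposition trimming defaults (cycles, factor).
#' @return A `kin_config` list.
#' @export
kin_config <- function(d1_threshold = 11.0, d2_threshold = 11.0,
                       salt_bridge_cutoff = 4.0, contact_cutoff = 4.5,
                       hbond_cutoff = 3.5,
                       rama_boundaries = list(A_psi = c(-100, 50),
                                              L_psi = c(-50, 100)),
                       trim = list(cycles = 5L, factor = 2.0)) {
  cfg <- list(d1_threshold = d1_threshold, d2_threshold = d2_threshold,
              salt_bridge_cutoff = salt_bridge_cutoff,
              contact_cutoff = contact_cutoff, hbond_cutoff = hbond_cutoff,
              rama_boundaries = rama_boundaries, trim = trim)
  num <- unlist(cfg[1:5])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("kin_config: every cutoff must be positive and finite")
  structure(cfg, class = "kin_config")
}

#' Spatial DFG label from the D1/D2 distances
#'
#' D1 is the distance from the alphaC-Glu(+4) C-alpha to the DFG-Phe C-zeta;
#' D2 from the beta3-Lys C-alpha to the DFG-Phe C-zeta.  The Phe ring packed
#' under the alphaC helix (small D1, large D2) is DFGin; the reverse is
#' DFGout; anything else DFGinter.  A missing defining atom gives group
#' "incomplete" rather than an error.
#'
#' @param model A `structure_model`.
#' @param anchors A `kinase_anchors`.
#' @param config A [kin_config()].
#' @return List: `d1`, `d2` (Angstrom or NA), `group` in
#'   DFGin/DFGout/DFGinter/incomplete.
#' @export
spatial_dfg_label <- function(model, anchors, config = kin_config()) {
  g4 <- anchors$alphaC_glu_plus4; fk <- anchors$dfg_phe; k <- anchors$beta3_lys
  a <- atom_xyz(model, g4$chain, g4$resno, "CA", g4$icode)
  b <- atom_xyz(model, k$chain, k$resno, "CA", k$icode)
  cz <- atom_xyz(model, fk$chain, fk$resno, "CZ", fk$icode)
  if (is.null(a) || is.null(b) || is.null(cz))
    return(list(d1 = NA_real_, d2 = NA_real_, group = "incomplete"))
  d1 <- vec_distance(a, cz); d2 <- vec_distance(b, cz)
  t1 <- config$d1_threshold; t2 <- config$d2_threshold
  group <- if (d1 <= t1 && d2 >= t2) "DFGin"
           else if (d1 > t1 && d2 <= t2) "DFGout"
           else "DFGinter"
  list(d1 = d1, d2 = d2, group = group)
}

#' Ramachandran region of a phi/psi pair
#'
#' Four-region (A/B/L/E) annotation with rectangular default boundaries:
#' for phi < 0, psi in [-100, 50) is A (alpha region) and the rest is B
#' (beta/extended); for phi >= 0, psi in [-50, 100) is L (left-handed alpha)
#' and the rest is E.  Boundaries are configurable approximations.
#'
#' @param phi,psi Angles in degrees.
#' @param boundaries List with `A_psi`, `L_psi` half-open psi intervals.
#' @return One of "A", "B", "L", "E".
#' @export
ramachandran_region <- function(phi, psi,
                                boundaries = kin_config()$rama_boundaries) {
  if (is.na(phi) || is.na(psi)) stop("ramachandran_region: undefined angle")
  if (phi < 0) {
    if (psi >= boundaries$A_psi[1] && psi < boundaries$A_psi[2]) "A" else "B"
  } else {
    if (psi >= boundaries$L_psi[1] && psi < boundaries$L_psi[2]) "L" else "E"
  }
}

#' chi1 rotamer bin
#'
#' gauche-minus for chi1 in [-120, 0), gauche-plus for [0, 120), trans
#' otherwise.
#'
#' @param chi1 Angle in degrees.
#' @return One of "minus", "plus", "trans".
#' @export
rotamer_bin <- function(chi1) {
  if (is.na(chi1)) stop("rotamer_bin: undefined chi1")
  if (chi1 >= -120 && chi1 < 0) "minus"
  else if (chi1 >= 0 && chi1 < 120) "plus"
  else "trans"
}

#' Dihedral-cluster label of the X-DFG motif
#'
#' Concatenates the Ramachandran regions of the X-DFG residue (the residue
#' immediately preceding the DFG Asp), the DFG Asp and the DFG Phe with the
#' DFG-Phe chi1 rotamer bin, e.g. "BLAminus".
#'
#' @inheritParams spatial_dfg_label
#' @return List: `regions` (3-char), `rotamer`, `name`, `complete`, plus the
#'   underlying angles.
#' @export
dihedral_cluster <- function(model, anchors, config = kin_config()) {
  res <- residue_table(model)
  res <- res[!res$is_het & res$chain == anchors$dfg_asp$chain, , drop = FALSE]
  di <- which(res$resno == anchors$dfg_asp$resno & res$icode == anchors$dfg_asp$icode)
  incomplete <- list(regions = NA_character_, rotamer = NA_character_,
                     name = NA_character_, complete = FALSE, angles = NULL)
  if (length(di) != 1L || di == 1L) return(incomplete)
  xres <- res[di - 1L, ]
  trio <- list(rid(xres$chain, xres$resno, xres$icode), anchors$dfg_asp, anchors$dfg_phe)
  angs <- lapply(trio, function(r)
    backbone_dihedrals(model, r$chain, r$resno, r$icode))
  if (!all(vapply(angs, function(a) a$phi_complete && a$psi_complete, TRUE)))
    return(incomplete)
  regions <- vapply(angs, function(a)
    ramachandran_region(a$phi, a$psi, config$rama_boundaries), "")
  chi1 <- tryCatch(chi1_angle(model, anchors$dfg_phe$chain, anchors$dfg_phe$resno,
                              anchors$dfg_phe$icode),
                   error = function(e) NA_real_)
  if (is.na(chi1)) return(incomplete)
  rotamer <- rotamer_bin(chi1)
  reg <- paste(regions, collapse = "")
  list(regions = reg, rotamer = rotamer, name = paste0(reg, rotamer),
       complete = TRUE,
       angles = list(xdfg = angs[[1]], dfg_asp = angs[[2]], dfg_phe = angs[[3]],
                     chi1_phe = chi1))
}

SIDECHAIN_N <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
SIDECHAIN_O <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))

#' Salt bridge between a basic and an acidic residue
#'
#' Minimum distance over basic side-chain nitrogens (Lys NZ; Arg NH1/NH2/NE)
#' by acidic side-chain oxygens (Glu OE1/OE2; Asp OD1/OD2); present when at
#' or below the cutoff.
#'
#' @param model A `structure_model`.
#' @param basic,acidic Residue ids (`list(chain=, resno=, icode=)` or
#'   "chain:resno" strings).
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @return List: `basic`, `acidic`, `min_no_distance`, `present`,
#'   `atom_pair`, `complete`.
#' @export
salt_bridge <- function(model, basic, acidic, cutoff = 4.0) {
  as_rid <- function(v) {
    if (is.list(v)) return(rid(v$chain, v$resno, if (is.null(v$icode)) "" else v$icode))
    p <- strsplit(v, ":", fixed = TRUE)[[1]]; rid(p[1], as.integer(p[2]))
  }
  basic <- as_rid(basic); acidic <- as_rid(acidic)
  res <- residue_table(model)
  bname <- res$resname[res$chain == basic$chain & res$resno == basic$resno &
                         res$icode == basic$icode & !res$is_het][1]
  aname <- res$resname[res$chain == acidic$chain & res$resno == acidic$resno &
                         res$icode == acidic$icode & !res$is_het][1]
  natoms <- SIDECHAIN_N[[bname]]; oatoms <- SIDECHAIN_O[[aname]]
  if (is.null(natoms) || is.null(oatoms))
    stop(sprintf("salt_bridge: %s/%s is not a Lys/Arg x Glu/Asp pair",
                 bname, aname))
  best <- Inf; pair <- c(NA_character_, NA_character_)
  for (na in natoms) for (oa in oatoms) {
    p <- atom_xyz(model, basic$chain, basic$resno, na, basic$icode)
    q <- atom_xyz(model, acidic$chain, acidic$resno, oa, acidic$icode)
    if (is.null(p) || is.null(q)) next
    d <- vec_distance(p, q)
    if (d < best) { best <- d; pair <- c(na, oa) }
  }
  if (!is.finite(best))
    return(list(basic = basic, acidic = acidic, min_no_distance = NA_real_,
                present = NA, atom_pair = pair, complete = FALSE))
  list(basic = basic, acidic = acidic, min_no_distance = best,
       present = best <= cutoff, atom_pair = pair, complete = TRUE)
}

min_heavy_distance <- function(A, B) {
  if (!nrow(A) || !nrow(B)) return(NA_real_)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Hydrophobic spine assembly
#'
#' Computes the minimum heavy-atom distance between consecutive members of
#' the catalytic (C) or regulatory (R) spine.  For the C-spine with a bound
#' nucleotide, the adenine ring joins the stack between the two N-lobe
#' members and the C-lobe members.  The R-spine is additionally anchored to
#' the alphaF-helix Asp through a hydrogen bond from the catalytic-loop
#' aromatic backbone.  Assembled when every adjacent gap is at or below the
#' contact cutoff (and, for R, the anchor bond at or below the H-bond
#' cutoff); a missing member leaves that gap undefined and the spine not
#' assembled, with a note.
#'
#' @inheritParams spatial_dfg_label
#' @param kind "C" or "R".
#' @return List: `kind`, `members` (ids), `adjacent_gaps`, `anchor_hbond`
#'   (R only), `assembled`, `note`.
#' @export
spine_assembly <- function(model, anchors, kind = c("R", "C"),
                           config = kin_config()) {
  kind <- match.arg(kind)
  members <- if (kind == "R") anchors$r_spine else anchors$c_spine
  labels <- vapply(members, rid_str, "")
  coords <- lapply(members, function(r) {
    if (is.null(r)) return(matrix(numeric(0), 0, 3))
    residue_heavy_xyz(model, r$chain, r$resno, r$icode, het = FALSE)
  })

  note <- NULL
  if (kind == "C") {
    lig <- list_ligands(model)$ligands
    nuc <- lig[lig$category == "nucleotide", , drop = FALSE]
    if (nrow(nuc)) {
      ring <- adenine_xyz(model, nuc[1, ])
      # adenine stacks between the N-lobe members (beta2/beta3-Ala) and the
      # C-lobe members
      coords <- append(coords, list(ring), after = 2L)
      labels <- append(labels, sprintf("%s(adenine)", nuc$resname[1]), after = 2L)
    }
  }
  gaps <- rep(NA_real_, length(coords) - 1L)
  for (i in seq_along(gaps))
    gaps[i] <- min_heavy_distance(coords[[i]], coords[[i + 1L]])
  incomplete <- any(is.na(gaps)) ||
    any(vapply(coords, nrow, 0L) == 0L)
  if (incomplete) note <- "one or more spine members have no resolved heavy atoms"

  anchor_hbond <- NA_real_
  if (kind == "R") {
    cl <- anchors$cat_loop_aromatic; af <- anchors$r_spine_anchor
    if (!is.null(cl) && !is.null(af)) {
      bb <- lapply(c("N", "O"), function(nm)
        atom_xyz(model, cl$chain, cl$resno, nm, cl$icode))
      sc <- lapply(SIDECHAIN_O$ASP, function(nm)
        atom_xyz(model, af$chain, af$resno, nm, af$icode))
      ds <- unlist(lapply(bb, function(p) lapply(sc, function(q)
        if (is.null(p) || is.null(q)) NA_real_ else vec_distance(p, q))))
      anchor_hbond <- if (all(is.na(ds))) NA_real_ else min(ds, na.rm = TRUE)
    }
    if (is.na(anchor_hbond)) {
      incomplete <- TRUE
      note <- c(note, "R-spine alphaF anchor atoms missing")
    }
  }
  assembled <- !incomplete && all(gaps <= config$contact_cutoff) &&
    (kind == "C" || anchor_hbond <= config$hbond_cutoff)
  list(kind = kind, members = labels, adjacent_gaps = gaps,
       anchor_hbond = anchor_hbond, assembled = assembled,
       complete = !incomplete,
       note = if (is.null(note)) NA_character_ else paste(note, collapse = "; "))
}

ADENINE_ATOMS <- c("N1", "C2", "N3", "C4", "C5", "C6", "N6", "N7", "C8", "N9")

adenine_xyz <- function(model, nuc_row) {
  a <- model$atoms
  sel <- a$is_het & a$chain == nuc_row$chain & a$resno == nuc_row$resno &
    a$icode == nuc_row$icode & a$element != "H"
  ring <- sel & a$atom %in% ADENINE_ATOMS
  if (any(ring)) sel <- ring   # fall back to all heavy atoms if unnamed
  as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
}

#' Protein-nucleotide polar contacts
#'
#' All protein N/O atoms within the H-bond cutoff of any nucleotide N/O/P
#' atom, deduplicated per residue (closest pair kept), waters excluded,
#' sorted by residue number.
#'
#' @inheritParams spatial_dfg_label
#' @return Data frame (chain, resno, resname, protein_atom, ligand_atom,
#'   distance); zero rows (with attribute `note`) when no nucleotide is bound.
#' @export
nucleotide_contacts <- function(model, anchors = NULL, config = kin_config()) {
  empty <- data.frame(chain = character(), resno = integer(),
                      resname = character(), protein_atom = character(),
                      ligand_atom = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  lig <- list_ligands(model)$ligands
  nuc <- lig[lig$category == "nucleotide", , drop = FALSE]
  if (!nrow(nuc)) { attr(empty, "note") <- "no nucleotide ligand"; return(empty) }
  a <- model$atoms
  lsel <- a$is_het & a$resname %in% nuc$resname & a$element %in% c("N", "O", "P")
  psel <- !a$is_het & a$element %in% c("N", "O")
  L <- as.matrix(a[lsel, c("x", "y", "z")]); P <- as.matrix(a[psel, c("x", "y", "z")])
  if (!nrow(L) || !nrow(P)) { attr(empty, "note") <- "no polar atoms"; return(empty) }
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  hit <- which(d <= config$hbond_cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  pi <- which(psel)[hit[, 1]]; li <- which(lsel)[hit[, 2]]
  out <- data.frame(chain = a$chain[pi], resno = a$resno[pi],
                    resname = a$resname[pi], protein_atom = a$atom[pi],
                    ligand_atom = a$atom[li],
                    distance = d[hit], stringsAsFactors = FALSE)
  out <- out[order(out$resno, out$distance), , drop = FALSE]
  out <- out[!duplicated(paste(out$chain, out$resno)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Phosphorylated residues in the activation segment
#'
#' Residues within the activation segment (DFG-Asp to APE) carried as
#' modified phospho residues (TPO/SEP/PTR), ordered by residue number.
#'
#' @inheritParams spatial_dfg_label
#' @return Data frame (chain, resno, resname).
#' @export
phospho_sites <- function(model, anchors) {
  res <- residue_table(model)
  seg <- anchors$activation_segment
  sel <- !res$is_het & res$is_phospho & res$chain == anchors$dfg_asp$chain &
    res$resno >= seg[1] & res$resno <= seg[2]
  out <- res[sel, c("chain", "resno", "resname"), drop = FALSE]
  out <- out[order(out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full conformational-state classification of one structure
#'
#' Runs the spatial DFG label, dihedral cluster, beta3-Lys/alphaC-Glu salt
#' bridge, both spines, nucleotide contacts and phospho-sites, and composes
#' the verdict: active when the salt bridge is present, the spatial group is
#' DFGin, the dihedral cluster is BLAminus and the R-spine is assembled;
#' inactive when all components are defined and any conjunct fails;
#' indeterminate when any component is incomplete (e.g. missing density).
#' The alphaC-helix status is reported as the salt-bridge proxy (in when
#' present).
#'
#' @inheritParams spatial_dfg_label
#' @return Object of class `conformation_report`.
#' @export
classify_state <- function(model, anchors, config = kin_config()) {
  spatial <- spatial_dfg_label(model, anchors, config)
  cluster <- dihedral_cluster(model, anchors, config)
  bridge <- salt_bridge(model, anchors$beta3_lys, anchors$alphaC_glu,
                        cutoff = config$salt_bridge_cutoff)
  r_spine <- spine_assembly(model, anchors, "R", config)
  c_spine <- spine_assembly(model, anchors, "C", config)
  contacts <- nucleotide_contacts(model, anchors, config)
  phospho <- phospho_sites(model, anchors)

  complete <- spatial$group != "incomplete" && cluster$complete &&
    bridge$complete && r_spine$complete
  verdict <- if (!complete) "indeterminate"
  else if (isTRUE(bridge$present) && spatial$group == "DFGin" &&
           identical(cluster$name, "BLAminus") && isTRUE(r_spine$assembled))
    "active" else "inactive"

  structure(list(
    structure_id = model$model_id,
    anchors = anchors,
    spatial = spatial, cluster = cluster, salt_bridge = bridge,
    r_spine = r_spine, c_spine = c_spine,
    nucleotide_contacts = contacts, phospho_sites = phospho,
    alphaC_status = if (!bridge$complete) NA_character_
                    else if (isTRUE(bridge$present)) "in" else "out",
    verdict = verdict,
    config = config
  ), class = "conformation_report")
}

#' @export
print.conformation_report <- function(x, ...) {
  cat(sprintf("Conformation report for %s\n", x$structure_id))
  cat(sprintf("  spatial DFG: %s (D1 = %.2f, D2 = %.2f A)\n", x$spatial$group,
              x$spatial$d1, x$spatial$d2))
  cat(sprintf("  dihedral cluster: %s\n",
              if (isTRUE(x$cluster$complete)) x$cluster$name else "incomplete"))
  cat(sprintf("  salt bridge %s-%s: %s (min N-O %.2f A)\n",
              rid_str(x$salt_bridge$basic), rid_str(x$salt_bridge$acidic),
              if (isTRUE(x$salt_bridge$present)) "present" else "absent",
              x$salt_bridge$min_no_distance))
  cat(sprintf("  R-spine: %s;  C-spine: %s\n",
              if (isTRUE(x$r_spine$assembled)) "assembled" else "not assembled",
              if (isTRUE(x$c_spine$assembled)) "assembled" else "not assembled"))
  cat(sprintf("  nucleotide contacts: %d residue(s); phospho-sites: %s\n",
              nrow(x$nucleotide_contacts),
              if (nrow(x$phospho_sites)) paste(x$phospho_sites$resno, collapse = ", ")
              else "none"))
  cat(sprintf("  alphaC: %s;  verdict: %s\n", x$alphaC_status, toupper(x$verdict)))
  invisible(x)
}
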