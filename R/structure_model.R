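# Coordinate-model input: parse PDB/mmCIF files (via bio3d) into a validated
# in-memory atom table, with the altloc, modified-residue and ligand policies
# the downstream classification relies on, plus resolution of the conserved
# kinase motif anchors from sequence.

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
         GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V", MSE = "M")

#' Default phospho-residue vocabulary
#'
#' Maps modified-residue three-letter codes to the parent one-letter code:
#' phosphothreonine (TPO) to T, phosphoserine (SEP) to S, phosphotyrosine
#' (PTR) to Y.  Extensible: pass a modified copy to [read_structure()].
#' @return Named character vector.
#' @export
default_phospho_map <- function() c(TPO = "T", SEP = "S", PTR = "Y")

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")
NUCLEOTIDE_NAMES <- c("ATP", "ADP", "AMP", "ANP", "ACP", "AGS",
                      "GTP", "GDP", "GNP", "GSP")
METAL_NAMES <- c("MG", "MN", "ZN", "CA", "NA", "K", "FE", "NI", "CO", "CU", "CD")

#' Read a PDB or mmCIF file into a structure model
#'
#' Parsing is delegated to bio3d (`read.pdb`/`read.cif`); the result is
#' normalised into a single atom table.  Only the first model of multi-model
#' files is kept.  For alternate locations the highest-occupancy conformer is
#' retained (ties broken toward altloc "A").  Hydrogens are retained in the
#' table but ignored by all downstream geometry.  Hetero residues are
#' categorised as nucleotide, metal, water or other; modified Ser/Thr/Tyr
#' residues (TPO/SEP/PTR by default) are kept in the polymer with their parent
#' one-letter code and flagged as phosphorylated.
#'
#' @param path File path.
#' @param format "auto" (by extension), "pdb" or "cif".
#' @param phospho_map Named vector mapping phospho residue names to one-letter
#'   codes; see [default_phospho_map()].
#' @return Object of class `structure_model`: `model_id`, `source_format` and
#'   an `atoms` data frame (chain, resno, icode, resname, one_letter,
#'   is_phospho, is_het, category, atom, element, x, y, z, occ, b).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           phospho_map = default_phospho_map()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("read_structure: file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
    error = function(e) stop(sprintf("read_structure: parse error in '%s' (%s): %s",
                                     path, format, conditionMessage(e))))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  at$chain[is.na(at$chain)] <- " "

  # altloc policy: highest occupancy wins, ties go to the lexicographically
  # first altloc (blank before "A"); deterministic by construction
  ord <- order(at$chain, at$resno, at$insert, at$elety, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  at <- at[!duplicated(key), , drop = FALSE]
  # restore file order within the deduplicated set
  at <- at[order(as.numeric(rownames(at))), , drop = FALSE]

  atoms <- data.frame(
    chain = at$chain, resno = as.integer(at$resno), icode = at$insert,
    resname = at$resid, atom = at$elety,
    element = guess_element(at$elesy, at$elety),
    x = at$x, y = at$y, z = at$z, occ = at$o, b = at$b,
    stringsAsFactors = FALSE)
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("read_structure: non-finite coordinates")

  atoms$one_letter <- ifelse(atoms$resname %in% names(AA3), AA3[atoms$resname],
                      ifelse(atoms$resname %in% names(phospho_map),
                             phospho_map[atoms$resname], "X"))
  atoms$is_phospho <- atoms$resname %in% names(phospho_map)
  is_polymer <- atoms$resname %in% c(names(AA3), names(phospho_map))
  atoms$category <- ifelse(is_polymer, "polymer",
                    ifelse(atoms$resname %in% WATER_NAMES, "water",
                    ifelse(atoms$resname %in% NUCLEOTIDE_NAMES, "nucleotide",
                    ifelse(atoms$resname %in% METAL_NAMES, "metal", "other"))))
  atoms$is_het <- atoms$category != "polymer"

  # polymer residues sorted by (chain, resno, icode); hetero kept after
  atoms <- atoms[order(atoms$is_het, atoms$chain, atoms$resno, atoms$icode), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  if (!any(!atoms$is_het))
    stop(sprintf("read_structure: no polymer residues in '%s'", path))
  structure(list(model_id = sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path),
                                ignore.case = TRUE),
                 source_format = toupper(format), atoms = atoms),
            class = "structure_model")
}

guess_element <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy) | elesy == "", "", elesy)))
  miss <- el == ""
  if (any(miss)) {
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", elety[miss]))
    el[miss] <- toupper(substr(nm, 1, ifelse(toupper(nm) %in% METAL_NAMES, 2, 1)))
  }
  el
}

# One row per residue, in model order.
residue_table <- function(model) {
  a <- model$atoms
  key <- paste(a$is_het, a$chain, a$resno, a$icode)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             icode = a$icode[first], resname = a$resname[first],
             one_letter = a$one_letter[first], is_phospho = a$is_phospho[first],
             is_het = a$is_het[first], category = a$category[first],
             stringsAsFactors = FALSE)
}

# Coordinates of one named atom, or NULL when absent.
atom_xyz <- function(model, chain, resno, atom, icode = "") {
  a <- model$atoms
  i <- which(a$chain == chain & a$resno == resno & a$icode == icode & a$atom == atom)
  if (!length(i)) return(NULL)
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

# All heavy (non-hydrogen) atom coordinates of one residue.
residue_heavy_xyz <- function(model, chain, resno, icode = "", het = NA) {
  a <- model$atoms
  sel <- a$chain == chain & a$resno == resno & a$icode == icode & a$element != "H"
  if (!is.na(het)) sel <- sel & a$is_het == het
  as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
}

ca_table <- function(model) {
  a <- model$atoms
  a[!a$is_het & a$atom == "CA", c("chain", "resno", "icode", "x", "y", "z"),
    drop = FALSE]
}

#' @export
print.structure_model <- function(x, ...) {
  res <- residue_table(x)
  cat(sprintf("structure_model '%s' (%s): %d polymer residues, %d ligand groups\n",
              x$model_id, x$source_format, sum(!res$is_het),
              sum(res$is_het & res$category != "water")))
  invisible(x)
}

#' Write a structure model to a PDB file
#'
#' Minimal fixed-width PDB writer (ATOM/HETATM/END) for models produced by
#' [read_structure()] or [build_toy_kinase()]; coordinates to 3 decimals.
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  rec <- ifelse(a$is_het, "HETATM", "ATOM")
  name <- ifelse(nchar(a$atom) >= 4, substr(a$atom, 1, 4),
                 paste0(" ", formatC(a$atom, width = -3)))
  lines <- sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)) %% 100000L, name, "",
                   substr(a$resname, 1, 3), substr(a$chain, 1, 1), a$resno %% 10000L,
                   substr(paste0(a$icode, " "), 1, 1),
                   a$x, a$y, a$z, a$occ, a$b, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Fetch deposited coordinates by PDB id
#'
#' Thin convenience downloader (RCSB) for validating against deposited
#' entries; requires network access.
#'
#' @param id 4-character PDB id, e.g. "8HO6".
#' @param dir Download directory.
#' @param format "pdb" or "cif".
#' @param timeout Seconds before giving up.
#' @return Path to the downloaded file.
#' @export
fetch_structure <- function(id, dir = tempdir(), format = c("pdb", "cif"),
                            timeout = 60) {
  format <- match.arg(format)
  id <- toupper(id)
  dest <- file.path(dir, sprintf("%s.%s", id, format))
  if (file.exists(dest)) return(dest)
  url <- sprintf("https://files.rcsb.org/download/%s.%s", id, format)
  old <- getOption("timeout"); on.exit(options(timeout = old))
  options(timeout = timeout)
  status <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop(sprintf("fetch_structure: could not retrieve %s from %s", id, url))
  }
  dest
}

#' Extract the one-letter sequence of a chain
#'
#' Follows polymer order; unknown residues are emitted as "X"; modified
#' phospho residues map to their parent letter.  The per-position mapping to
#' author residue ids is returned alongside.
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @return Object of class `chain_sequence`: `sequence` (string) and `map`
#'   (data frame pos, chain, resno, icode, resname, one_letter, is_phospho).
#' @export
extract_sequence <- function(model, chain) {
  res <- residue_table(model)
  res <- res[!res$is_het, , drop = FALSE]
  if (!chain %in% res$chain)
    stop(sprintf("extract_sequence: chain '%s' not found (available: %s)",
                 chain, paste(unique(res$chain), collapse = ", ")))
  res <- res[res$chain == chain, , drop = FALSE]
  map <- data.frame(pos = seq_len(nrow(res)), chain = res$chain,
                    resno = res$resno, icode = res$icode, resname = res$resname,
                    one_letter = res$one_letter, is_phospho = res$is_phospho,
                    stringsAsFactors = FALSE)
  structure(list(sequence = paste(res$one_letter, collapse = ""), map = map),
            class = "chain_sequence")
}

#' Default motif-scan windows and positional offsets for anchor resolution
#'
#' Windows are start-to-start residue offsets between motif matches, chosen
#' from canonical kinase domain architecture; offsets place the spine and
#' hinge members relative to the scanned anchors (with a small local scan for
#' the expected residue class).  All values are overridable.
#' @return List of windows and offsets.
#' @export
anchor_defaults <- function() list(
  windows = list(beta3 = c(10, 45), alphaC = c(8, 25), dfg = c(10, 35),
                 ape = c(20, 35)),
  offsets = list(beta2 = 4,        # from first Gly-loop G, scan [VILMFA] +-1
                 beta4 = 15,       # from alphaC-Glu, scan [LIVMF] +-2
                 hinge = 29,       # from alphaC-Glu; 4 consecutive residues
                 alphaD = 37,      # from alphaC-Glu, scan [LIVMFA] +-2
                 catloop_cspine = c(8, 9, 10),  # from catalytic-loop aromatic
                 alphaF_asp = 61,  # from catalytic-loop aromatic, scan D +-2
                 alphaF_cspine = c(7, 11))     # from the alphaF Asp, scan +-2
)

rid <- function(chain, resno, icode = "") {
  list(chain = chain, resno = as.integer(resno), icode = icode)
}
rid_str <- function(r) {
  if (is.null(r)) "-" else sprintf("%s:%d%s", r$chain, r$resno, r$icode)
}

#' Resolve conserved kinase motif anchors from a chain sequence
#'
#' Scans, in order: the glycine-rich loop (G.G..G), the beta3 Ala-x-Lys
#' (first `[AVILMFC].K` 10-45 residues downstream of the Gly loop; the Lys is
#' the beta3 Lys), the alphaC Glu (first E 8-25 residues after the beta3
#' Lys), the catalytic loop (first `[HY]RD` downstream), the DFG motif (first
#' literal DFG 10-35 residues after the catalytic loop) and APE (first APE,
#' fallback `.PE`, 20-35 residues after DFG; when absent the activation
#' segment is taken as DFG-Asp to DFG-Asp+30).  Spine, hinge and C-spine
#' members are derived positionally (see [anchor_defaults()]).  Any override
#' replaces the scanned value verbatim.
#'
#' @param seq A `chain_sequence` from [extract_sequence()].
#' @param overrides Named list of residue numbers (or "chain:resno" strings)
#'   keyed by anchor name (e.g. `list(beta3_lys = 124)`).
#' @param config Windows/offsets, see [anchor_defaults()].
#' @return Object of class `kinase_anchors`.
#' @export
find_anchors <- function(seq, overrides = list(), config = anchor_defaults()) {
  stopifnot(inherits(seq, "chain_sequence"))
  s <- seq$sequence; map <- seq$map
  chain <- map$chain[1]
  W <- config$windows; OFF <- config$offsets

  parse_override <- function(v) {
    if (is.list(v) && !is.null(v$resno)) return(rid(v$chain, v$resno, if (is.null(v$icode)) "" else v$icode))
    if (is.character(v) && grepl(":", v)) {
      p <- strsplit(v, ":", fixed = TRUE)[[1]]
      return(rid(p[1], as.integer(p[2])))
    }
    rid(chain, as.integer(v))
  }
  ov <- lapply(overrides, parse_override)
  pos_of <- function(r) {           # map a residue id back to sequence position
    i <- which(map$chain == r$chain & map$resno == r$resno & map$icode == r$icode)
    if (length(i)) i[1] else NA_integer_
  }
  at_pos <- function(p) {
    if (is.na(p) || p < 1L || p > nrow(map))
      stop("find_anchors: derived anchor position outside the chain")
    rid(map$chain[p], map$resno[p], map$icode[p])
  }
  if (nchar(s) < 50 && !all(c("beta3_lys", "alphaC_glu", "dfg_asp") %in% names(ov)))
    stop("find_anchors: sequence shorter than 50 residues and anchors not overridden")

  all_matches <- function(pattern) {
    m <- gregexpr(pattern, s, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  windowed <- function(pattern, from, window, motif) {
    hits <- all_matches(pattern)
    hits <- hits[hits - from >= window[1] & hits - from <= window[2]]
    if (!length(hits))
      stop(sprintf("find_anchors: %s motif ('%s') not found %d-%d residues downstream",
                   motif, pattern, window[1], window[2]))
    if (length(hits) > 1L)
      stop(sprintf("find_anchors: ambiguous %s motif (%d candidate matches at %s); resolve via overrides",
                   motif, length(hits), paste(hits, collapse = ", ")))
    hits[1]
  }
  scan_near <- function(center, classes, tol, motif) {
    # residue of the expected class nearest to `center` within +-tol
    if (is.na(center)) stop(sprintf("find_anchors: no reference position for %s", motif))
    offs <- seq(-tol, tol); offs <- offs[order(abs(offs), offs)]
    for (o in offs) {
      p <- center + o
      if (p >= 1L && p <= nchar(s) && grepl(classes, substr(s, p, p))) return(p)
    }
    stop(sprintf("find_anchors: no %s residue near position %d for %s",
                 classes, center, motif))
  }

  # --- glycine-rich loop -------------------------------------------------
  if (!is.null(ov$gly_loop)) {
    gly1_pos <- pos_of(ov$gly_loop)
    gly <- list(ov$gly_loop, NULL, NULL)
  } else {
    g <- all_matches("G.G..G")
    if (!length(g)) stop("find_anchors: glycine-rich loop motif (G.G..G) not found")
    gly1_pos <- g[1]
    gly <- lapply(gly1_pos + c(0L, 2L, 5L), at_pos)
  }

  # --- beta3 Ala-x-Lys ---------------------------------------------------
  if (!is.null(ov$beta3_lys)) {
    beta3_lys <- ov$beta3_lys
    beta3_ala <- if (!is.null(ov$beta3_ala)) ov$beta3_ala else
      rid(beta3_lys$chain, beta3_lys$resno - 2L)
    k_pos <- pos_of(beta3_lys)
  } else {
    b3 <- windowed("[AVILMFC].K", gly1_pos, W$beta3, "beta3 Ala-x-Lys")
    beta3_ala <- at_pos(b3); beta3_lys <- at_pos(b3 + 2L); k_pos <- b3 + 2L
  }

  # --- alphaC Glu --------------------------------------------------------
  if (!is.null(ov$alphaC_glu)) {
    alphaC_glu <- ov$alphaC_glu; e_pos <- pos_of(alphaC_glu)
  } else {
    if (is.na(k_pos)) stop("find_anchors: cannot window alphaC-Glu scan (beta3 Lys not on this chain)")
    hits <- all_matches("E")
    hits <- hits[hits - k_pos >= W$alphaC[1] & hits - k_pos <= W$alphaC[2]]
    if (!length(hits))
      stop("find_anchors: alphaC-Glu motif (E) not found 8-25 residues after the beta3 Lys")
    e_pos <- hits[1]
    alphaC_glu <- at_pos(e_pos)
  }
  alphaC_glu_plus4 <- if (!is.null(ov$alphaC_glu_plus4)) ov$alphaC_glu_plus4 else
    rid(alphaC_glu$chain, alphaC_glu$resno + 4L)

  # --- catalytic loop ----------------------------------------------------
  if (!is.null(ov$cat_loop_aromatic)) {
    cat_loop_aromatic <- ov$cat_loop_aromatic; cat_pos <- pos_of(cat_loop_aromatic)
  } else {
    if (is.na(e_pos)) stop("find_anchors: cannot place catalytic-loop scan (alphaC Glu not on this chain)")
    hits <- all_matches("[HY]RD"); hits <- hits[hits > e_pos]
    if (!length(hits))
      stop("find_anchors: catalytic-loop motif ([HY]RD) not found downstream of alphaC-Glu")
    cat_pos <- hits[1]
    cat_loop_aromatic <- at_pos(cat_pos)
  }

  # --- DFG ---------------------------------------------------------------
  if (!is.null(ov$dfg_asp)) {
    dfg_asp <- ov$dfg_asp; dfg_pos <- pos_of(dfg_asp)
    dfg_phe <- if (!is.null(ov$dfg_phe)) ov$dfg_phe else rid(dfg_asp$chain, dfg_asp$resno + 1L)
    dfg_gly <- if (!is.null(ov$dfg_gly)) ov$dfg_gly else rid(dfg_asp$chain, dfg_asp$resno + 2L)
  } else {
    if (is.na(cat_pos)) stop("find_anchors: cannot window DFG scan (catalytic loop not on this chain)")
    dfg_pos <- windowed("DFG", cat_pos, W$dfg, "DFG")
    dfg_asp <- at_pos(dfg_pos); dfg_phe <- at_pos(dfg_pos + 1L); dfg_gly <- at_pos(dfg_pos + 2L)
  }

  # --- APE / activation segment -----------------------------------------
  ape_end <- NULL
  if (!is.null(ov$ape_end)) {
    ape_end <- ov$ape_end
  } else if (!is.na(dfg_pos)) {
    hits <- all_matches("APE")
    hits <- hits[hits - dfg_pos >= W$ape[1] & hits - dfg_pos <= W$ape[2]]
    if (!length(hits)) {
      hits <- all_matches(".PE")
      hits <- hits[hits - dfg_pos >= W$ape[1] & hits - dfg_pos <= W$ape[2]]
    }
    if (length(hits)) ape_end <- at_pos(hits[1] + 2L)
  }
  activation_segment <- c(dfg_asp$resno,
                          if (!is.null(ape_end)) ape_end$resno else dfg_asp$resno + 30L)

  # --- positionally derived members -------------------------------------
  # tolerant: a spine/hinge member that cannot be located is carried as NULL
  # and surfaces downstream as spine incompleteness, not as a hard error
  soft <- function(expr) tryCatch(expr, error = function(e) NULL)
  derived <- function(name, default) if (!is.null(ov[[name]])) ov[[name]] else soft(default())
  beta4 <- derived("r_spine_beta4", function()
    at_pos(scan_near(e_pos + OFF$beta4, "[LIVMF]", 2L, "beta4 hydrophobic (R-spine)")))
  hinge <- if (!is.null(ov$hinge)) list(ov$hinge) else
    lapply(e_pos + OFF$hinge + 0:3, function(p) soft(at_pos(p)))
  beta2 <- derived("c_spine_beta2", function()
    at_pos(scan_near(gly1_pos + OFF$beta2, "[VILMFA]", 1L, "beta2 hydrophobic (C-spine)")))
  alphaD <- derived("c_spine_alphaD", function()
    at_pos(scan_near(e_pos + OFF$alphaD, "[LIVMFA]", 2L, "alphaD hydrophobic (C-spine)")))
  catloop_c <- lapply(cat_pos + OFF$catloop_cspine, function(p) soft(at_pos(p)))
  alphaF_asp <- derived("r_spine_anchor", function()
    at_pos(scan_near(cat_pos + OFF$alphaF_asp, "D", 2L, "alphaF Asp (R-spine anchor)")))
  af_pos <- if (is.null(alphaF_asp)) NA_integer_ else pos_of(alphaF_asp)
  alphaF_c <- lapply(OFF$alphaF_cspine, function(o) soft(
    at_pos(scan_near(af_pos + o, "[VILMFA]", 2L, "alphaF hydrophobic (C-spine)"))))

  anchors <- structure(list(
    gly_loop = gly,
    beta3_ala = beta3_ala, beta3_lys = beta3_lys,
    alphaC_glu = alphaC_glu, alphaC_glu_plus4 = alphaC_glu_plus4,
    cat_loop_aromatic = cat_loop_aromatic,
    dfg_asp = dfg_asp, dfg_phe = dfg_phe, dfg_gly = dfg_gly,
    ape_end = ape_end, activation_segment = activation_segment,
    r_spine = list(beta4, alphaC_glu_plus4, dfg_phe, cat_loop_aromatic),
    r_spine_anchor = alphaF_asp,
    c_spine = c(list(beta2, beta3_ala, alphaD), catloop_c, alphaF_c),
    hinge = hinge
  ), class = "kinase_anchors")
  validate_anchors(anchors)
  anchors
}

validate_anchors <- function(a) {
  if (a$beta3_lys$resno >= a$alphaC_glu$resno ||
      a$alphaC_glu$resno >= a$dfg_asp$resno)
    stop("find_anchors: anchor ordering violated (beta3 Lys < alphaC Glu < DFG Asp required)")
  if (a$alphaC_glu_plus4$resno != a$alphaC_glu$resno + 4L)
    stop("find_anchors: alphaC_glu_plus4 must be alphaC_glu + 4")
  if (a$activation_segment[1] != a$dfg_asp$resno)
    stop("find_anchors: activation segment must start at the DFG Asp")
  invisible(a)
}

#' @export
print.kinase_anchors <- function(x, ...) {
  cat("kinase_anchors:\n")
  cat(sprintf("  Gly loop:     %s\n", paste(vapply(x$gly_loop, rid_str, ""), collapse = " ")))
  cat(sprintf("  beta3 Ala/Lys: %s / %s\n", rid_str(x$beta3_ala), rid_str(x$beta3_lys)))
  cat(sprintf("  alphaC Glu (+4): %s (%s)\n", rid_str(x$alphaC_glu), rid_str(x$alphaC_glu_plus4)))
  cat(sprintf("  catalytic loop:  %s\n", rid_str(x$cat_loop_aromatic)))
  cat(sprintf("  DFG:          %s %s %s\n", rid_str(x$dfg_asp), rid_str(x$dfg_phe), rid_str(x$dfg_gly)))
  cat(sprintf("  activation segment: %d..%d\n", x$activation_segment[1], x$activation_segment[2]))
  cat(sprintf("  R-spine: %s (anchor %s)\n",
              paste(vapply(x$r_spine, rid_str, ""), collapse = " "), rid_str(x$r_spine_anchor)))
  cat(sprintf("  C-spine: %s\n", paste(vapply(x$c_spine, rid_str, ""), collapse = " ")))
  invisible(x)
}

#' Categorised ligand inventory of a model
#'
#' @param model A `structure_model`.
#' @return List with `counts` (named: nucleotide, metal, water, other) and
#'   `ligands` data frame (chain, resno, resname, category).
#' @export
list_ligands <- function(model) {
  res <- residue_table(model)
  lig <- res[res$is_het, c("chain", "resno", "icode", "resname", "category"),
             drop = FALSE]
  counts <- vapply(c("nucleotide", "metal", "water", "other"),
                   function(k) sum(lig$category == k), 0L)
  list(counts = counts, ligands = lig)
}
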