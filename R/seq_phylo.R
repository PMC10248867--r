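# Sequence utilities (ORF arithmetic, protein mass, percent identity, motif
# scanning) and distance-based phylogenetics: p-distance with pairwise or
# complete gap deletion, Neighbor-Joining with a deterministic tie-break, and
# nonparametric bootstrap supports.

new_alignment <- function(names, rows) {
  stopifnot(length(names) == length(rows), length(rows) >= 1)
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("alignment rows must all have the same length")
  structure(list(names = as.character(names), rows = unname(toupper(rows)),
                 length = w),
            class = "aa_alignment")
}

#' Read a protein alignment from FASTA
#'
#' Accepts wrapped and unwrapped FASTA; all rows must share one gapped
#' length; the alphabet is the 20 amino acids plus gap ("-"/".") and X.
#'
#' @param path FASTA file path.
#' @return An `aa_alignment`: `names`, `rows` (gapped strings), `length`.
#' @export
read_alignment <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  new_alignment(names(fa), gsub("\\.", "-", toupper(unlist(fa))))
}

#' Write a protein alignment to FASTA
#' @param aln An `aa_alignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  seqinr::write.fasta(as.list(aln$rows), aln$names, path)
  invisible(path)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment: %d sequences x %d columns\n",
              length(x$names), x$length))
  invisible(x)
}

GAPCHARS <- c("-", ".", "X")

#' Proportion of differing sites between two aligned sequences
#'
#' Pairwise deletion: any column where either row carries a gap or X is
#' excluded; the distance is differences over compared sites.
#'
#' @param a,b Equal-length gapped sequences (strings).
#' @return Proportion in [0, 1].
#' @export
p_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]; cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) stop("p_distance: unequal sequence lengths")
  ok <- !(ca %in% GAPCHARS) & !(cb %in% GAPCHARS)
  if (!any(ok)) stop("p_distance: zero comparable sites")
  sum(ca[ok] != cb[ok]) / sum(ok)
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param aln An `aa_alignment`.
#' @param deletion "pairwise" (default) excludes gap/X columns per pair;
#'   "complete" drops every column containing a gap or X in any row first.
#' @return Symmetric matrix with zero diagonal, dimnames = sequence names.
#' @export
p_distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  rows <- aln$rows
  if (deletion == "complete") {
    m <- do.call(rbind, strsplit(toupper(rows), ""))
    keep <- colSums(matrix(m %in% GAPCHARS, nrow(m))) == 0
    if (!any(keep)) stop("p_distance_matrix: no gap-free columns")
    rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  }
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(aln$names, aln$names))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- p_distance(rows[i], rows[j])
  d
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion.  Ties in Q
#' are broken toward the lowest (row, column) index pair in the current
#' matrix ordering, making the topology deterministic; negative branch
#' lengths are clamped to zero.
#'
#' @param d Symmetric distance matrix with dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (is.null(dimnames(d))) dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                                                paste0("t", seq_len(nrow(d))))
  n <- nrow(d)
  if (n < 3L) stop("nj_tree: at least 3 taxa required")
  if (max(abs(d - t(d))) > 1e-8) stop("nj_tree: distance matrix is not symmetric")
  fmt <- function(x) sprintf("%.12g", max(0, x))
  labels <- rownames(d)
  while (n > 3L) {
    R <- rowSums(d)
    Q <- (n - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    # lowest (i, j) among the minima, scanning rows first
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    vi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    newlab <- sprintf("(%s:%s,%s:%s)", labels[i], fmt(vi), labels[j], fmt(vj))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    d[i, ] <- d[, i] <- dk
    d[i, i] <- 0
    labels[i] <- newlab
    d <- d[-j, -j, drop = FALSE]
    labels <- labels[-j]
    n <- n - 1L
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", labels[1], fmt(v1),
                 labels[2], fmt(v2), labels[3], fmt(v3))
  ape::read.tree(text = nwk)
}

# canonical bipartition keys of a tree's internal nodes; the side not
# containing `ref` represents each split; trivial splits get NA
bipartition_keys <- function(tr, ref) {
  pp <- ape::prop.part(tr)
  ntip <- length(tr$tip.label)
  vapply(seq_along(pp), function(k) {
    tips <- tr$tip.label[pp[[k]]]
    if (ref %in% tips) tips <- setdiff(tr$tip.label, tips)
    if (length(tips) < 2L || length(tips) > ntip - 2L) return(NA_character_)
    paste(sort(tips), collapse = "\r")
  }, "")
}

#' Bootstrap supports for the Neighbor-Joining tree of an alignment
#'
#' Columns are resampled with replacement per replicate (seeded), the NJ tree
#' rebuilt on p-distances, and each internal bipartition of the full-data
#' tree scored as the percentage of replicates containing it.  A replicate in
#' which some pairwise distance is undefined (no comparable sites) is redrawn,
#' up to a retry cap.
#'
#' @param aln An `aa_alignment`.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed RNG seed; identical seeds give bit-identical supports.
#' @param deletion Gap-deletion mode, see [p_distance_matrix()].
#' @return The full-data NJ tree with `node.label` carrying supports (0-100;
#'   empty for the root / trivial splits).
#' @export
bootstrap_support <- function(aln, replicates = 1000L, seed = 1L,
                              deletion = "pairwise") {
  stopifnot(inherits(aln, "aa_alignment"), replicates >= 1)
  full <- nj_tree(p_distance_matrix(aln, deletion))
  ref <- sort(aln$names)[1]
  keys <- bipartition_keys(full, ref)
  counts <- stats::setNames(rep(0L, sum(!is.na(keys))), keys[!is.na(keys)])
  chars <- strsplit(aln$rows, "")
  set.seed(seed)
  for (b in seq_len(replicates)) {
    for (try in seq_len(100L)) {
      cols <- sample.int(aln$length, aln$length, replace = TRUE)
      rep_aln <- new_alignment(aln$names,
                               vapply(chars, function(x) paste(x[cols], collapse = ""), ""))
      dm <- tryCatch(p_distance_matrix(rep_aln, deletion), error = function(e) NULL)
      if (!is.null(dm)) break
      if (try == 100L) stop("bootstrap_support: retry cap reached (too many gap-only replicates)")
      message("bootstrap_support: replicate with undefined distance redrawn")
    }
    rk <- bipartition_keys(nj_tree(dm), ref)
    hit <- names(counts) %in% rk
    counts[hit] <- counts[hit] + 1L
  }
  support <- round(100 * counts / replicates, 1)
  full$node.label <- ifelse(is.na(keys), "", as.character(support[keys]))
  attr(full, "support") <- support
  full
}

#' Protein length encoded by an open reading frame
#'
#' The ORF length in base pairs divided by three, minus one for the stop
#' codon.
#'
#' @param orf_bp ORF length in base pairs (divisible by 3, >= 6).
#' @return Amino-acid count.
#' @examples
#' orf_protein_length(1278) # 425
#' @export
orf_protein_length <- function(orf_bp) {
  orf_bp <- as.integer(orf_bp)
  if (any(orf_bp < 6L) || any(orf_bp %% 3L != 0L))
    stop("orf_protein_length: ORF length must be >= 6 and divisible by 3")
  orf_bp %/% 3L - 1L
}

# average (isotope-weighted) residue masses, Da
AA_AVG_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                 C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                 H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                 M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                 T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

#' Average molecular mass of a protein sequence
#'
#' Sum of average residue masses plus one water, in kDa.  Reports the full
#' precision; round to two decimals for display.
#'
#' @param protein 1-letter sequence (standard residues only).
#' @return Mass in kDa.
#' @export
average_mass <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1]]
  if (!length(aa) || !all(aa %in% names(AA_AVG_MASS)))
    stop(sprintf("average_mass: sequence must be non-empty standard residues (offending: %s)",
                 paste(unique(aa[!aa %in% names(AA_AVG_MASS)]), collapse = ",")))
  (sum(AA_AVG_MASS[aa]) + WATER_MASS) / 1000
}

#' Percent identity of two aligned sequences
#'
#' Identities over a configurable denominator: "compared" (columns where both
#' rows are non-gap; default), "alignment" (columns with at least one
#' non-gap) or "shorter" (ungapped length of the shorter row).
#'
#' @param a,b Equal-length aligned sequences.
#' @param denominator Policy, see above.
#' @return Percentage in [0, 100].
#' @export
percent_identity <- function(a, b, denominator = c("compared", "alignment", "shorter")) {
  denominator <- match.arg(denominator)
  ca <- strsplit(toupper(a), "")[[1]]; cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) stop("percent_identity: unequal lengths")
  gap <- c("-", ".")
  both <- !(ca %in% gap) & !(cb %in% gap)
  ident <- sum(both & ca == cb)
  den <- switch(denominator,
                compared = sum(both),
                alignment = sum(!(ca %in% gap) | !(cb %in% gap)),
                shorter = min(sum(!(ca %in% gap)), sum(!(cb %in% gap))))
  if (den == 0) stop("percent_identity: zero denominator")
  100 * ident / den
}

#' Scan a sequence for a motif pattern
#'
#' Restricted regular expressions over the amino-acid alphabet: literals,
#' character classes in brackets, and "." or "x" wildcards.  All
#' non-overlapping leftmost matches are returned with 1-based inclusive
#' coordinates.
#'
#' @param sequence 1-letter sequence.
#' @param pattern Pattern, e.g. `"[FY]T..F.K"`.
#' @return Data frame (start, end, match); zero rows when no match.
#' @export
motif_scan <- function(sequence, pattern) {
  chars <- strsplit(pattern, "")[[1]]
  allowed <- c(LETTERS, letters, as.character(0:9), "[", "]", ".", "^")
  if (!length(chars) || !all(chars %in% allowed) ||
      sum(chars == "[") != sum(chars == "]"))
    stop(sprintf("motif_scan: malformed pattern '%s'", pattern))
  pat <- gsub("x", ".", pattern)
  sequence <- toupper(sequence)
  m <- tryCatch(gregexpr(pat, sequence, perl = TRUE)[[1]],
                error = function(e) stop(sprintf("motif_scan: malformed pattern '%s'", pattern)))
  if (m[1] == -1L)
    return(data.frame(start = integer(), end = integer(), match = character(),
                      stringsAsFactors = FALSE))
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m), end = as.integer(m) + len - 1L,
             match = substring(sequence, m, m + len - 1L),
             stringsAsFactors = FALSE)
}
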