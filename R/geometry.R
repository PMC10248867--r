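# Exact vector geometry on coordinate models: distances, backbone and
# side-chain dihedrals, and rigid-body (Kabsch) superposition with optional
# iterative outlier trimming.

#' Euclidean distance between two points
#'
#' @param a,b Numeric 3-vectors (Angstrom).
#' @return Non-negative distance in Angstrom.
#' @examples
#' vec_distance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
vec_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3L || length(b) != 3L || !all(is.finite(c(a, b))))
    stop("vec_distance: inputs must be finite 3-vectors")
  sqrt(sum((a - b)^2))
}

#' Dihedral (torsion) angle of four points
#'
#' Right-handed IUPAC sign convention: the cis (eclipsed) arrangement is 0
#' degrees, trans is 180.  The result is normalised to (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  p <- lapply(list(p1, p2, p3, p4), as.numeric)
  if (!all(vapply(p, function(x) length(x) == 3L && all(is.finite(x)), TRUE)))
    stop("dihedral_angle: inputs must be finite 3-vectors")
  b1 <- p[[2]] - p[[1]]; b2 <- p[[3]] - p[[2]]; b3 <- p[[4]] - p[[3]]
  if (sum(b2^2) < 1e-12) stop("dihedral_angle: degenerate geometry (p2 == p3)")
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stop("dihedral_angle: degenerate geometry (collinear points)")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  normalize_angle(ang)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Map any angle in degrees to (-180, 180].
normalize_angle <- function(x) {
  x <- x %% 360
  x[x > 180] <- x[x > 180] - 360
  x[x <= -180] <- x[x <= -180] + 360
  x
}

# Internal-coordinate atom placement (NeRF): position a fourth point at the
# given bond length from p3, bond angle at p3, and dihedral p1-p2-p3-p4.
place_atom <- function(p1, p2, p3, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  bc <- p3 - p2; bc <- bc / sqrt(sum(bc^2))
  ab <- p2 - p1
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  p3 + d[1] * bc + d[2] * m + d[3] * n
}

#' Backbone phi/psi dihedrals of one residue
#'
#' phi is computed from C(i-1)-N-CA-C and psi from N-CA-C-N(i+1).  An absent
#' chain neighbour (or missing atom) leaves that angle `NA` with its
#' completeness flag `FALSE`; atoms are never invented.
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @param resno Author residue number.
#' @param icode Insertion code (default none).
#' @return List with `phi`, `psi` (degrees or `NA`) and logical
#'   `phi_complete`, `psi_complete`.
#' @export
backbone_dihedrals <- function(model, chain, resno, icode = "") {
  res <- residue_table(model)
  res <- res[res$chain == chain & !res$is_het, , drop = FALSE]
  idx <- which(res$resno == resno & res$icode == icode)
  if (length(idx) != 1L)
    stop(sprintf("backbone_dihedrals: residue %s:%s%s not found", chain, resno, icode))
  at <- function(i, name) {
    if (i < 1L || i > nrow(res)) return(NULL)
    atom_xyz(model, res$chain[i], res$resno[i], name, res$icode[i])
  }
  n  <- at(idx, "N");  ca <- at(idx, "CA"); cc <- at(idx, "C")
  cp <- at(idx - 1L, "C"); nn <- at(idx + 1L, "N")
  phi <- psi <- NA_real_
  phi_ok <- !is.null(cp) && !is.null(n) && !is.null(ca) && !is.null(cc)
  psi_ok <- !is.null(n) && !is.null(ca) && !is.null(cc) && !is.null(nn)
  if (phi_ok) phi <- dihedral_angle(cp, n, ca, cc)
  if (psi_ok) psi <- dihedral_angle(n, ca, cc, nn)
  list(phi = phi, psi = psi, phi_complete = phi_ok, psi_complete = psi_ok)
}

# Standard gamma atom defining chi1 per residue type.
chi1_gamma_atom <- function(resname) {
  switch(resname,
    SER = "OG", THR = "OG1", SEP = "OG", TPO = "OG1",
    VAL = "CG1", ILE = "CG1", CYS = "SG", ALA = NA_character_,
    GLY = NA_character_, "CG")
}

#' Side-chain chi1 dihedral (N-CA-CB-gamma)
#'
#' @inheritParams backbone_dihedrals
#' @return Angle in degrees in (-180, 180].
#' @export
chi1_angle <- function(model, chain, resno, icode = "") {
  res <- residue_table(model)
  row <- res[res$chain == chain & res$resno == resno & res$icode == icode &
               !res$is_het, , drop = FALSE]
  if (nrow(row) != 1L)
    stop(sprintf("chi1_angle: residue %s:%s not found", chain, resno))
  gname <- chi1_gamma_atom(row$resname)
  pts <- lapply(c("N", "CA", "CB", gname), function(nm) {
    if (is.na(nm)) NULL else atom_xyz(model, chain, resno, nm, icode)
  })
  if (is.na(gname) || any(vapply(pts, is.null, TRUE)))
    stop(sprintf("chi1_angle: incomplete side chain for %s %s:%s",
                 row$resname, chain, resno))
  dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
}

#' Rigid-body superposition of two models (Kabsch) with optional trimming
#'
#' C-alpha atoms are paired by shared (mapped chain, residue number, insertion
#' code).  The least-squares rotation is found by singular value
#' decomposition.  With trimming enabled, after each fit all pairs deviating
#' by more than `trim_factor` times the current RMSD are rejected and the fit
#' repeated, up to `trim_cycles` cycles or convergence; both the untrimmed and
#' final RMSD are reported.
#'
#' @param mobile,reference `structure_model` objects.
#' @param chain_map Named character vector mapping mobile chains to reference
#'   chains, e.g. `c(A = "A")`.  Default pairs identical chain ids.
#' @param trim `FALSE` for a single fit, or `TRUE` / `list(cycles=, factor=)`
#'   for iterative outlier rejection (defaults: 5 cycles, factor 2.0).
#' @return Object of class `superposition`: rotation (3x3, det +1),
#'   translation, `rmsd_all`, `rmsd_trimmed`, `n_pairs_initial`,
#'   `n_pairs_final`, and the rejected residue ids.
#' @export
superpose <- function(mobile, reference, chain_map = NULL, trim = TRUE) {
  stopifnot(inherits(mobile, "structure_model"), inherits(reference, "structure_model"))
  ca_m <- ca_table(mobile); ca_r <- ca_table(reference)
  if (is.null(chain_map)) {
    shared <- intersect(unique(ca_m$chain), unique(ca_r$chain))
    chain_map <- stats::setNames(shared, shared)
  }
  ca_m <- ca_m[ca_m$chain %in% names(chain_map), , drop = FALSE]
  ca_m$ref_chain <- unname(chain_map[ca_m$chain])
  key_m <- paste(ca_m$ref_chain, ca_m$resno, ca_m$icode)
  key_r <- paste(ca_r$chain, ca_r$resno, ca_r$icode)
  common <- intersect(key_m, key_r)
  if (length(common) < 3L)
    stop(sprintf("superpose: insufficient pairs (%d < 3)", length(common)))
  im <- match(common, key_m); ir <- match(common, key_r)
  X <- as.matrix(ca_m[im, c("x", "y", "z")])
  Y <- as.matrix(ca_r[ir, c("x", "y", "z")])
  ids <- paste0(ca_m$chain[im], ":", ca_m$resno[im], ca_m$icode[im])

  if (isTRUE(trim)) trim <- list(cycles = 5L, factor = 2.0)
  fit <- kabsch_fit(X, Y)
  rmsd_all <- fit$rmsd
  keep <- rep(TRUE, nrow(X))
  if (is.list(trim)) {
    cycles <- if (!is.null(trim$cycles)) as.integer(trim$cycles) else 5L
    factor <- if (!is.null(trim$factor)) as.numeric(trim$factor) else 2.0
    cur <- fit
    for (cy in seq_len(cycles)) {
      dev <- sqrt(rowSums((apply_rigid(X, cur$R, cur$t) - Y)^2))
      dev[!keep] <- 0
      # floor keeps an (essentially) exact fit from rejecting pairs on
      # machine-precision noise
      bad <- keep & dev > factor * max(cur$rmsd, 1e-6)
      if (!any(bad) || sum(keep & !bad) < 3L) break
      keep <- keep & !bad
      cur <- kabsch_fit(X[keep, , drop = FALSE], Y[keep, , drop = FALSE])
    }
    fit <- cur
  }
  structure(list(
    rotation = fit$R, translation = fit$t,
    rmsd_all = rmsd_all, rmsd_trimmed = fit$rmsd,
    n_pairs_initial = nrow(X), n_pairs_final = sum(keep),
    rejected = ids[!keep]
  ), class = "superposition")
}

# Least-squares rotation R and translation t with row-vector convention:
# X %*% R + t  approximates  Y.
kabsch_fit <- function(X, Y) {
  cm <- colMeans(X); cr <- colMeans(Y)
  Xc <- sweep(X, 2, cm); Yc <- sweep(Y, 2, cr)
  s <- svd(t(Xc) %*% Yc)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cr - as.numeric(cm %*% R)
  rmsd <- sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

apply_rigid <- function(X, R, t) sweep(X %*% R, 2, -t)

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: %d/%d C-alpha pairs kept\n",
              x$n_pairs_final, x$n_pairs_initial))
  cat(sprintf("  RMSD (all pairs):     %.3f A\n", x$rmsd_all))
  cat(sprintf("  RMSD (after trim):    %.3f A\n", x$rmsd_trimmed))
  if (length(x$rejected))
    cat("  rejected:", paste(x$rejected, collapse = ", "), "\n")
  invisible(x)
}
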