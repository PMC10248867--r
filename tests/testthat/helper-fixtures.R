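# Shared fixtures built in code: tiny hand-written PDB files and rigid-motion
# helpers.

# three residues (ALA, GLY, LYS) with an ATP, a Mg and waters; coordinates
# arbitrary but fixed
write_mini_pdb <- function(path, altloc = FALSE, phospho = FALSE) {
  l <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00 10.00           O",
    if (altloc) c(
      "ATOM      5  CB AALA A   1       2.000  -1.200   0.500  0.60 10.00           C",
      "ATOM      6  CB BALA A   1       2.100  -1.300   0.700  0.40 10.00           C")
    else
      "ATOM      5  CB  ALA A   1       2.000  -1.200   0.500  1.00 10.00           C",
    "ATOM      7  N   GLY A   2       3.332   1.536   0.000  1.00 10.00           N",
    "ATOM      8  CA  GLY A   2       4.076   2.785   0.100  1.00 10.00           C",
    "ATOM      9  C   GLY A   2       5.567   2.523   0.200  1.00 10.00           C",
    "ATOM     10  O   GLY A   2       6.021   1.380   0.300  1.00 10.00           O",
    if (phospho) c(
      "HETATM   11  N   TPO A   3       6.368   3.590   0.000  1.00 10.00           N",
      "HETATM   12  CA  TPO A   3       7.820   3.470   0.000  1.00 10.00           C",
      "HETATM   13  C   TPO A   3       8.450   4.860   0.000  1.00 10.00           C",
      "HETATM   14  O   TPO A   3       7.750   5.880   0.000  1.00 10.00           O")
    else c(
      "ATOM     11  N   LYS A   3       6.368   3.590   0.000  1.00 10.00           N",
      "ATOM     12  CA  LYS A   3       7.820   3.470   0.000  1.00 10.00           C",
      "ATOM     13  C   LYS A   3       8.450   4.860   0.000  1.00 10.00           C",
      "ATOM     14  O   LYS A   3       7.750   5.880   0.000  1.00 10.00           O"),
    "HETATM   15  PG  ATP A 101      10.000  10.000  10.000  1.00 20.00           P",
    "HETATM   16  O1G ATP A 101      11.000  10.500  10.000  1.00 20.00           O",
    "HETATM   17  N9  ATP A 101      12.000  11.000  10.500  1.00 20.00           N",
    "HETATM   18 MG    MG A 102       9.000   9.000   9.000  1.00 20.00          MG",
    "HETATM   19  O   HOH A 201       5.000   5.000   5.000  1.00 30.00           O",
    "HETATM   20  O   HOH A 202       6.000   5.000   5.000  1.00 30.00           O",
    "HETATM   21  O   HOH A 203       7.000   5.000   5.000  1.00 30.00           O",
    "HETATM   22  O   HOH A 204       8.000   5.000   5.000  1.00 30.00           O",
    "HETATM   23  O   HOH A 205       9.000   5.000   5.000  1.00 30.00           O",
    "END")
  writeLines(unlist(l), path)
  path
}

rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# apply a rigid motion (row-vector convention) to every atom of a model
transform_model <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% R
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}

random_rigid <- function() {
  R <- rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
  list(R = R, t = stats::rnorm(3, 0, 20))
}

# 120-residue sequence with one match per anchor motif, used by the anchor
# scanner tests (Gly loop at 10, AxK at 35, alphaC E at 50, YRD at 80, DFG at
# 95, APE at 118)
anchor_demo_sequence <- function(drop_dfg = FALSE) {
  s <- rep("H", 120)
  s[10 + c(0, 2, 5)] <- "G"          # GAGSFG-style pattern
  s[11] <- "A"; s[13] <- "S"; s[14] <- "F"
  s[35] <- "A"; s[36] <- "Y"; s[37] <- "K"
  s[50] <- "E"
  s[80] <- "Y"; s[81] <- "R"; s[82] <- "D"
  if (!drop_dfg) { s[95] <- "D"; s[96] <- "F"; s[97] <- "G" }
  s[118] <- "A"; s[119] <- "P"; s[120] <- "E"
  paste(s, collapse = "")
}

# wrap a bare string as a chain_sequence on chain A, resno = position
as_chain_sequence <- function(s, chain = "A", start = 1L) {
  n <- nchar(s)
  structure(list(
    sequence = s,
    map = data.frame(pos = seq_len(n), chain = chain,
                     resno = start + seq_len(n) - 1L, icode = "",
                     resname = "UNK", one_letter = strsplit(s, "")[[1]],
                     is_phospho = FALSE, stringsAsFactors = FALSE)),
    class = "chain_sequence")
}
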