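# Relative expression from qPCR threshold cycles (2^-ddCt) and the group
# comparisons used alongside it: Duncan's multiple range test (letters) and
# Student's t-test.

#' Read a Ct table from delimited text
#'
#' Expects a header row with columns sample, group, ct_target, ct_reference;
#' comma or tab separated (auto-detected).
#'
#' @param path CSV/TSV file path.
#' @return A `ct_table` data frame.
#' @export
read_ct_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("sample", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(x)))
    stop(sprintf("read_ct_table: missing column(s): %s",
                 paste(setdiff(need, names(x)), collapse = ", ")))
  x$ct_target <- as.numeric(x$ct_target)
  x$ct_reference <- as.numeric(x$ct_reference)
  class(x) <- c("ct_table", "data.frame")
  x
}

#' Write a Ct table to CSV
#' @param table A `ct_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ct_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, dCt = Ct(target) - Ct(reference); per group, ddCt is the
#' group mean dCt minus the calibrator group's mean dCt, and the fold change
#' is 2^-ddCt (amplification efficiency fixed at 2).  Per-replicate folds use
#' the replicate dCt against the calibrator mean, so that error bars are
#' computable.  Rows with a missing Ct are rejected with a log message.
#'
#' @param table A `ct_table` (or data frame with the same columns).
#' @param calibrator Calibrator group label (fold = 1 by construction).
#' @return Object of class `expression_result`: `groups` data frame (group,
#'   n, mean_dct, ddct, fold), `replicates` data frame (sample, group, dct,
#'   fold), `calibrator`.
#' @export
delta_delta_ct <- function(table, calibrator) {
  x <- as.data.frame(table)
  if (!calibrator %in% x$group)
    stop(sprintf("delta_delta_ct: calibrator group '%s' not present", calibrator))
  bad <- !is.finite(x$ct_target) | !is.finite(x$ct_reference) |
    x$ct_target <= 0 | x$ct_reference <= 0
  if (any(bad)) {
    message(sprintf("delta_delta_ct: rejected %d row(s) with missing/invalid Ct: %s",
                    sum(bad), paste(x$sample[bad], collapse = ", ")))
    x <- x[!bad, , drop = FALSE]
  }
  x$dct <- x$ct_target - x$ct_reference
  mean_dct <- tapply(x$dct, x$group, mean)
  cal <- mean_dct[[calibrator]]
  groups <- data.frame(group = names(mean_dct),
                       n = as.integer(table(x$group)[names(mean_dct)]),
                       mean_dct = as.numeric(mean_dct),
                       ddct = as.numeric(mean_dct) - cal,
                       stringsAsFactors = FALSE)
  groups$fold <- 2^(-groups$ddct)
  reps <- data.frame(sample = x$sample, group = x$group, dct = x$dct,
                     fold = 2^(-(x$dct - cal)), stringsAsFactors = FALSE)
  structure(list(groups = groups, replicates = reps, calibrator = calibrator),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("2^-ddCt relative expression (calibrator: %s)\n", x$calibrator))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Duncan's multiple range test
#'
#' Post-ANOVA stepwise multiple comparison.  With k group means ordered, a
#' span of p means differs when its range exceeds the critical range
#' r_p = q(1-(1-alpha)^(p-1); p, df) * sqrt(MSE/n), the studentized-range
#' quantile at Duncan's protection levels (computed by numerical inversion of
#' the range distribution, `stats::qtukey`); a span contained in a
#' non-significant wider span is itself declared non-significant.  Groups
#' sharing a letter are not significantly different at `alpha`.  Unbalanced
#' group sizes use the harmonic mean n.
#'
#' @param values Numeric response values.
#' @param groups Group labels (same length).
#' @param alpha Significance level (default 0.05).
#' @return Data frame (group, n, mean, letters), ordered by decreasing mean.
#' @export
duncan_mrt <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  ns <- table(groups)
  if (length(ns) < 2L || any(ns < 2L))
    stop("duncan_mrt: need >= 2 groups with >= 2 replicates each")
  k <- length(ns)
  means <- tapply(values, groups, mean)
  df <- length(values) - k
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / df
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]; labs <- names(means)[ord]
  n_h <- k / sum(1 / ns)

  if (mse == 0) {
    if (length(unique(m)) > 1L)
      warning("duncan_mrt: zero within-group variance; unequal means declared distinct")
    sig <- function(i, j) m[i] != m[j]
  } else {
    r_p <- vapply(2:k, function(p)
      stats::qtukey((1 - alpha)^(p - 1), p, df) * sqrt(mse / n_h), 0)
    raw_sig <- function(i, j) (m[i] - m[j]) > r_p[j - i]
    # protection: a span inside any non-significant wider span is non-significant
    nonsig <- matrix(FALSE, k, k)
    for (span in rev(2:k)) for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      if (!raw_sig(i, j) || (span < k && any(nonsig[seq_len(i), j:k])))
        nonsig[i, j] <- TRUE
    }
    sig <- function(i, j) !nonsig[min(i, j), max(i, j)]
  }

  # letters: maximal stretches of mutually non-significant ordered means
  letts <- rep("", k)
  nextl <- 1L
  prev_end <- 0L
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !sig(i, j + 1L)) j <- j + 1L
    if (j > prev_end || i == 1L) {
      lab <- letters[(nextl - 1L) %% 26L + 1L]
      letts[i:j] <- paste0(letts[i:j], lab)
      nextl <- nextl + 1L
      prev_end <- j
    }
  }
  # singletons skipped above (fully significant against neighbours) still
  # need their own letter
  for (i in which(letts == "")) {
    letts[i] <- letters[(nextl - 1L) %% 26L + 1L]
    nextl <- nextl + 1L
  }
  data.frame(group = labs, n = as.integer(ns[labs]), mean = as.numeric(m),
             letters = letts, stringsAsFactors = FALSE)
}

#' Two-sample t-test on replicate values
#'
#' Standard two-sided two-sample t (pooled-variance "student" or Welch).
#' When both groups have zero variance and equal means the convention t = 0,
#' p = 1 applies (t undefined otherwise under zero variance: p = 0 for
#' unequal means).
#'
#' @param a,b Numeric replicate vectors (each n >= 2).
#' @param variant "pooled" (classical Student) or "welch".
#' @return List: `statistic`, `df`, `p_value`.
#' @export
t_test_groups <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0, df = length(a) + length(b) - 2L,
                                        p_value = 1))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p_value = 0))
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Relative expression with Duncan letters and pairwise t-tests
#'
#' Convenience composition: 2^-ddCt folds, Duncan's multiple range test on
#' the per-replicate folds, and pairwise t-tests of every group against the
#' calibrator.
#'
#' @inheritParams delta_delta_ct
#' @param alpha Significance level for the letters.
#' @param variant t-test variant, see [t_test_groups()].
#' @return An `expression_result` whose `groups` table gains `letters` and
#'   `p_vs_calibrator`.
#' @export
analyze_expression <- function(table, calibrator, alpha = 0.05,
                               variant = "pooled") {
  res <- delta_delta_ct(table, calibrator)
  mrt <- duncan_mrt(res$replicates$fold, res$replicates$group, alpha)
  res$groups$letters <- mrt$letters[match(res$groups$group, mrt$group)]
  cal_folds <- res$replicates$fold[res$replicates$group == calibrator]
  res$groups$p_vs_calibrator <- vapply(res$groups$group, function(g) {
    if (g == calibrator) return(NA_real_)
    t_test_groups(res$replicates$fold[res$replicates$group == g],
                  cal_folds, variant)$p_value
  }, 0)
  res$alpha <- alpha
  res
}
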