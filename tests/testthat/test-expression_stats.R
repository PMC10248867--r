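# 2^-ddCt fold changes, Duncan's multiple range test against published
# critical ranges, and the t-test conventions.

ct_rows <- function(group, ct_t, ct_r) {
  data.frame(sample = paste0(group, "_", seq_along(ct_t)), group = group,
             ct_target = ct_t, ct_reference = ct_r, stringsAsFactors = FALSE)
}

test_that("2^-ddCt matches hand arithmetic and the calibrator is 1", {
  tab <- rbind(ct_rows("cal", c(24, 24), c(20, 20)),
               ct_rows("trt", c(25, 25), c(20, 20)))
  res <- delta_delta_ct(tab, "cal")
  g <- res$groups
  expect_equal(g$ddct[g$group == "trt"], 1)
  expect_equal(g$fold[g$group == "trt"], 0.5)
  expect_equal(g$fold[g$group == "cal"], 1)
})

test_that("simulated tables recover the true fold exactly at zero noise", {
  tab <- simulate_ct_table(c(cal = 1, up = 2, down = 0.25), n_reps = 4,
                           noise_sd = 0, seed = 3)
  g <- delta_delta_ct(tab, "cal")$groups
  expect_equal(g$fold[g$group == "up"], 2)
  expect_equal(g$fold[g$group == "down"], 0.25)
  expect_equal(g$fold[g$group == "cal"], 1)
})

test_that("rows with missing reference Ct are rejected with a message", {
  tab <- rbind(ct_rows("cal", c(24, 24, 24), c(20, 20, NA)),
               ct_rows("trt", c(25, 25), c(20, 20)))
  expect_message(res <- delta_delta_ct(tab, "cal"), "rejected 1 row")
  expect_equal(res$groups$n[res$groups$group == "cal"], 2L)
  expect_error(delta_delta_ct(tab, "nope"), "calibrator")
})

test_that("2^-ddCt is invariant to a constant Ct shift on target and reference", {
  tab <- simulate_ct_table(c(cal = 1, trt = 4), n_reps = 5, noise_sd = 0.3,
                           seed = 11)
  f1 <- delta_delta_ct(tab, "cal")$groups$fold
  tab2 <- tab
  tab2$ct_target <- tab2$ct_target + 3.7
  tab2$ct_reference <- tab2$ct_reference + 3.7
  f2 <- delta_delta_ct(tab2, "cal")$groups$fold
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("median recovered fold stays within 5% under realistic Ct noise", {
  for (true_fold in c(0.25, 1, 4)) {
    est <- vapply(1:500, function(s) {
      tab <- simulate_ct_table(c(cal = 1, trt = true_fold), n_reps = 10,
                               noise_sd = 0.3, seed = s)
      g <- delta_delta_ct(tab, "cal")$groups
      g$fold[g$group == "trt"]
    }, 0)
    expect_lt(abs(stats::median(est) - true_fold) / true_fold, 0.05)
  }
})

test_that("identical groups share one Duncan letter; extreme groups do not", {
  vals <- rep(c(1, 2, 3, 4, 5), 3)
  grp <- rep(c("a", "b", "c"), each = 5)
  out <- duncan_mrt(vals, grp)
  expect_true(all(out$letters == out$letters[1]))
  set.seed(2)
  out2 <- duncan_mrt(c(rnorm(5, 0, 1), rnorm(5, 100, 1)),
                     rep(c("lo", "hi"), each = 5))
  expect_false(out2$letters[1] == out2$letters[2])
})

test_that("Duncan letters match published critical ranges on a 3-group design", {
  # groups with exact means 0 / 0.1 / 5 and exact unit within-group variance
  # (df = 24); published Duncan significant ranges at alpha 0.05:
  # p = 2 -> 2.919, p = 3 -> 3.066
  base <- c(-2, -1.5, -1, -0.5, 0, 0.5, 1, 1.5, 2) * sqrt(8 / 15)
  vals <- c(base + 0, base + 0.1, base + 5)
  grp <- rep(c("g0", "g01", "g5"), each = 9)
  # hand oracle with the tabulated values: r_p = q_p * sqrt(MSE/n) = q_p / 3
  r2 <- 2.919 / 3; r3 <- 3.066 / 3
  expect_true(5 - 0.1 > r2)   # g5 vs g01 significant
  expect_true(5 - 0 > r3)     # g5 vs g0 significant
  expect_true(0.1 - 0 <= r2)  # g01 vs g0 not significant
  out <- duncan_mrt(vals, grp, alpha = 0.05)
  expect_equal(out$group, c("g5", "g01", "g0"))
  expect_equal(out$letters, c("a", "b", "b"))
  # and the internal critical ranges match the published table
  mse <- 1
  expect_equal(stats::qtukey(0.95, 2, 24) * sqrt(mse / 9), r2, tolerance = 2e-4)
  expect_equal(stats::qtukey(0.95^2, 3, 24) * sqrt(mse / 9), r3, tolerance = 2e-4)
})

test_that("Duncan letters are invariant to relabeling and constant shifts", {
  set.seed(8)
  vals <- c(rnorm(6, 0), rnorm(6, 1.5), rnorm(6, 8))
  grp <- rep(c("x", "y", "z"), each = 6)
  out1 <- duncan_mrt(vals, grp)
  out2 <- duncan_mrt(vals + 42, grp)
  expect_equal(out1$letters, out2$letters)
  relabel <- c(x = "z", y = "x", z = "y")
  out3 <- duncan_mrt(vals, unname(relabel[grp]))
  expect_equal(out3$letters[match(relabel[out1$group], out3$group)],
               out1$letters)
  ord <- sample(length(vals))
  out4 <- duncan_mrt(vals[ord], grp[ord])
  expect_equal(out4, out1)
})

test_that("all-equal groups under zero variance keep one letter with a warning path", {
  out <- duncan_mrt(rep(1, 8), rep(c("a", "b"), each = 4))
  expect_true(all(out$letters == out$letters[1]))
  expect_warning(out2 <- duncan_mrt(rep(c(1, 2), each = 4),
                                    rep(c("a", "b"), each = 4)),
                 "zero within-group variance")
  expect_false(out2$letters[1] == out2$letters[2])
})

test_that("t-test conventions: identical groups, symmetry, zero variance", {
  r <- t_test_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  a <- c(0.3, 1.2, -0.5, 0.8, 0.1); b <- c(2.1, 1.7, 2.9, 1.4, 2.2)
  r1 <- t_test_groups(a, b); r2 <- t_test_groups(b, a)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, -r2$statistic)
  z <- t_test_groups(c(1, 1, 1), c(1, 1, 1))
  expect_equal(z$p_value, 1)
  z2 <- t_test_groups(c(1, 1, 1), c(2, 2, 2))
  expect_equal(z2$p_value, 0)
})

test_that("the pooled t-test p-value tracks an exact permutation oracle", {
  base <- c(-2, -1, 0, 1, 2) / sqrt(2.5)       # mean 0, sd 1 exactly
  a <- base; b <- base + 1.5
  obs <- abs(t_test_groups(a, b, "pooled")$statistic)
  pooled_t <- function(x, y) {
    sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
  }
  pool <- c(a, b)
  splits <- utils::combn(10, 5)
  perm <- apply(splits, 2, function(ix) abs(pooled_t(pool[ix], pool[-ix])))
  p_perm <- mean(perm >= obs - 1e-12)
  p_param <- t_test_groups(a, b, "pooled")$p_value
  expect_lt(abs(p_param - p_perm), 0.02)
})

test_that("Ct tables round-trip through CSV and feed the full analysis", {
  tab <- simulate_ct_table(c(cal = 1, up = 4), n_reps = 5, noise_sd = 0.2,
                           seed = 9)
  p <- tempfile(fileext = ".csv")
  write_ct_table(tab, p)
  back <- read_ct_table(p)
  expect_equal(back$ct_target, tab$ct_target, tolerance = 1e-9)
  res <- analyze_expression(back, "cal")
  expect_true(all(c("letters", "p_vs_calibrator") %in% names(res$groups)))
  expect_true(is.na(res$groups$p_vs_calibrator[res$groups$group == "cal"]))
  expect_false(res$groups$letters[res$groups$group == "up"] ==
                 res$groups$letters[res$groups$group == "cal"])
})
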