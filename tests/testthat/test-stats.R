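make_table <- function(mat, bees = rownames(mat), stims = colnames(mat)) {
  amplitude_table(data.frame(
    bee = rep(bees, times = ncol(mat)),
    stimulus = rep(stims, each = nrow(mat)),
    amplitude = as.vector(mat)))
}

test_that("repeated-measures ANOVA matches a hand sums-of-squares oracle", {
  # no stimulus effect within any bee -> F = 0
  flat <- make_table(matrix(c(1, 2, 3), 3, 4,
                            dimnames = list(paste0("b", 1:3),
                                            paste0("s", 1:4))))
  expect_equal(rm_anova(flat)$F, 0)

  set.seed(20)
  m <- matrix(rnorm(9, 5), 3, 3,
              dimnames = list(paste0("b", 1:3), paste0("s", 1:3)))
  fit <- rm_anova(make_table(m))
  # hand-computed sums of squares (subject, effect, error)
  grand <- mean(m)
  ss_subj <- 3 * sum((rowMeans(m) - grand)^2)
  ss_eff <- 3 * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_eff
  F_hand <- (ss_eff / 2) / (ss_err / 4)
  expect_equal(fit$F, F_hand, tolerance = 1e-10)
  expect_equal(fit$df_effect, 2)
  expect_equal(fit$df_error, 4)
  expect_equal(fit$p, pf(F_hand, 2, 4, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("df structure matches the 11-bee, 17-stimulus design", {
  set.seed(21)
  m <- matrix(rnorm(11 * 17, 5), 11, 17,
              dimnames = list(paste0("b", 1:11), paste0("s", 1:17)))
  fit <- rm_anova(make_table(m))
  expect_equal(fit$df_effect, 16)
  expect_equal(fit$df_error, 160)
  # Greenhouse-Geisser option shifts only the p-value
  fit_gg <- rm_anova(make_table(m), gg_correction = TRUE)
  expect_equal(fit_gg$F, fit$F)
  expect_true(fit_gg$epsilon <= 1 && fit_gg$epsilon > 0)
  expect_gte(fit_gg$p, fit$p)
})

test_that("Dunnett comparisons: null stimulus, monotonicity and a
          Monte-Carlo oracle", {
  set.seed(22)
  n <- 8
  m <- matrix(rnorm(n * 4, 5), n, 4,
              dimnames = list(paste0("b", 1:n),
                              c("air", "s1", "s2", "s3")))
  m[, "s1"] <- m[, "air"]         # equal to control in every bee
  m[, "s3"] <- m[, "s3"] + 3      # clearly above control
  tab <- make_table(m)
  dn <- dunnett_vs_control(tab, control = "air")
  expect_setequal(dn$stimulus, c("s1", "s2", "s3"))
  expect_gt(dn$p_adj[dn$stimulus == "s1"], 0.99)
  expect_lt(dn$p_adj[dn$stimulus == "s3"], 0.01)
  expect_true(all(dn$p_adj >= dn$p_raw - 1e-12))
  # adjusted p monotone in |t|
  ord <- order(abs(dn$t))
  expect_true(all(diff(dn$p_adj[ord]) <= 1e-12))
  expect_error(dunnett_vs_control(tab, control = "water"), "not present")

  # Monte-Carlo oracle for the equicorrelated max-|t| null:
  # T_i = (X0 + X_i)/sqrt(2) / sqrt(W/df), rho = 1/2 exactly
  fit <- rm_anova(tab)
  k <- 3; df <- fit$df_error
  R <- 2e5
  set.seed(23)
  x0 <- rnorm(R)
  maxt <- matrix(rnorm(R * k), R, k)
  maxt <- abs((x0 + maxt) / sqrt(2)) / sqrt(rchisq(R, df) / df)
  maxt <- apply(maxt, 1, max)
  for (s in c("s2", "s3")) {
    tt <- abs(dn$t[dn$stimulus == s])
    p_mc <- mean(maxt >= tt)
    tol <- 4 * sqrt(max(p_mc, 1e-4) * (1 - p_mc) / R) + 5e-4
    expect_lt(abs(dn$p_adj[dn$stimulus == s] - p_mc), tol)
  }
})

test_that("paired t: closed form, antisymmetry and degeneracy", {
  y <- c(10, 20, 30)
  x <- y + c(1, 2, 3)
  res <- paired_t(x, y)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  swapped <- paired_t(y, x)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("Wilcoxon matched-pairs: extreme case, exhaustive enumeration and
          rank invariance", {
  # n = 5, all differences positive: V = 15, exact two-sided p = 2/32
  res <- wilcoxon_matched(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, 15)
  expect_equal(res$p, 0.0625)
  expect_equal(res$method, "exact")

  # n = 8 vs exhaustive enumeration of all 2^8 sign assignments
  set.seed(24)
  d <- round(rnorm(8, 0.4), 3)
  stopifnot(!any(duplicated(abs(d))), !any(d == 0))
  res8 <- wilcoxon_matched(d, rep(0, 8))
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 8)))
  Vs <- signs %*% r
  p_enum <- min(1, 2 * min(mean(Vs <= res8$statistic),
                           mean(Vs >= res8$statistic)))
  expect_equal(res8$p, p_enum, tolerance = 1e-12)

  # invariance under a monotone transform of the magnitudes
  d2 <- sign(d) * abs(d)^3
  res8b <- wilcoxon_matched(d2, rep(0, 8))
  expect_equal(res8b$statistic, res8$statistic)
  expect_equal(res8b$p, res8$p)

  # zeros are dropped; all-zero input is degenerate
  resz <- wilcoxon_matched(c(0, d), c(0, rep(0, 8)))
  expect_equal(resz$n, 8)
  expect_error(wilcoxon_matched(1:4, 1:4), "all differences")

  # ties or large n fall back to the normal approximation
  rest <- wilcoxon_matched(c(1, 1, 2, -1, 3, -1, 2, 4), rep(0, 8))
  expect_equal(rest$method, "normal-approximation")
})

test_that("Friedman test: concordance bound and rank-formula oracle", {
  # all tied within each bee -> statistic 0
  flat <- make_table(matrix(5, 3, 3, dimnames = list(paste0("b", 1:3),
                                                     paste0("s", 1:3))))
  expect_equal(friedman_rm(flat)$statistic, 0)

  # strict common ordering across 3 bees x 3 stimuli -> n(k-1) = 6
  ord <- make_table(matrix(c(1, 2, 3), 3, 3, byrow = TRUE,
                           dimnames = list(paste0("b", 1:3),
                                           paste0("s", 1:3))) +
                    matrix(0.1 * (1:3), 3, 3))
  expect_equal(friedman_rm(ord)$statistic, 6)
  expect_equal(friedman_rm(ord)$df, 2)

  # random 6 x 4 table vs the rank formula
  set.seed(25)
  m <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("b", 1:6),
                                               paste0("s", 1:4)))
  res <- friedman_rm(make_table(m))
  Rj <- colSums(t(apply(m, 1, rank)))
  chi_hand <- 12 / (6 * 4 * 5) * sum(Rj^2) - 3 * 6 * 5
  expect_equal(res$statistic, chi_hand, tolerance = 1e-10)
  expect_equal(res$df, 3)

  # invariant under rank-preserving monotone transforms
  res_t <- friedman_rm(make_table(exp(m)))
  expect_equal(res_t$statistic, res$statistic)
})

test_that("vapor-pressure regression: closed-form OLS and identities", {
  # amplitudes exactly affine in log VP -> R^2 = 1
  vp <- 10^(0:3)
  amp <- setNames(c(1, 3, 5, 7), paste0("o", 1:4))
  vr <- vp_regression(amp, vp)
  expect_equal(vr$slope, 2, tolerance = 1e-12)
  expect_equal(vr$intercept, 1, tolerance = 1e-12)
  expect_equal(vr$r_squared, 1, tolerance = 1e-12)

  set.seed(26)
  amp2 <- setNames(rnorm(8, 5), paste0("o", 1:8))
  vp2 <- runif(8, 0.01, 10)
  v1 <- vp_regression(amp2, vp2)
  # permutation invariance
  perm <- sample(8)
  v2 <- vp_regression(amp2[perm], vp2[perm])
  expect_equal(v1$slope, v2$slope, tolerance = 1e-12)
  expect_equal(v1$r_squared, v2$r_squared, tolerance = 1e-12)
  # R^2 equals the squared Pearson correlation with log VP
  expect_equal(v1$r_squared, cor(amp2, log10(vp2))^2, tolerance = 1e-12)
  # F has (1, n-2) df; p from the F tail
  expect_equal(v1$df, c(1, 6))
  expect_equal(v1$p, pf(v1$F, 1, 6, lower.tail = FALSE), tolerance = 1e-12)

  expect_error(vp_regression(amp, c(-1, 1, 2, 3)), "positive")
  expect_error(vp_regression(amp[1:2], vp[1:2]), "at least 3")

  # panel lookup drops controls
  panel <- aliphatic_panel()
  amps <- setNames(seq_len(nrow(panel)), panel$name)
  vp_fit <- vp_regression(amps, panel)
  expect_equal(vp_fit$n, 16)
  expect_equal(vp_fit$df, c(1, 14))
})

test_that("Fisher z comparison of correlations", {
  eq <- compare_correlations_fisher(0.6, 20, 0.6, 30)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  # independent arithmetic for r1 = 0.9, r2 = 0.5, n = 20 each
  z_hand <- (0.5 * log(1.9 / 0.1) - 0.5 * log(1.5 / 0.5)) /
    sqrt(1 / 17 + 1 / 17)
  res <- compare_correlations_fisher(0.9, 20, 0.5, 20)
  expect_equal(res$z, z_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)
  # antisymmetry
  expect_equal(compare_correlations_fisher(0.5, 20, 0.9, 20)$z, -res$z)
  expect_error(compare_correlations_fisher(1, 10, 0.5, 10), "degenerate")
  expect_error(compare_correlations_fisher(0.5, 3, 0.5, 10), "n >= 4")
})

test_that("normality-guided paired comparison reports both tests", {
  set.seed(27)
  x <- rnorm(12, 1); y <- rnorm(12)
  pc <- paired_comparison(x, y)
  expect_s3_class(pc$t, "paired_t_result")
  expect_s3_class(pc$wilcoxon, "wilcoxon_result")
  expect_true(pc$recommended %in% c("t", "wilcoxon"))
})
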