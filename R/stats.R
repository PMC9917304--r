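#' Repeated-measures ANOVA on an amplitude table
#'
#' One-way within-subject ANOVA with bees as subjects and odors as the
#' within-group factor, fitted through `aov` with a subject error stratum.
#' Degrees of freedom are the uncorrected `(k - 1, (k - 1)(n - 1))` — for
#' n = 11 bees and 17 stimuli, `F` on (16, 160) df. A Greenhouse-Geisser
#' sphericity correction is available but off by default, matching the
#' convention of reporting plain df for this design.
#'
#' @param table an [amplitude_table()] (complete block design).
#' @param gg_correction apply the Greenhouse-Geisser epsilon to the df and
#'   p-value.
#' @return An object of class `rm_anova_result`: `F`, `df_effect`,
#'   `df_error`, `p`, `ms_error`, per-stimulus `means`, `n_bees`,
#'   `n_stimuli` (plus `epsilon` when corrected).
#' @export
rm_anova <- function(table, gg_correction = FALSE) {
  table <- amplitude_table(table)
  dat <- data.frame(bee = factor(table$bee), stimulus = factor(table$stimulus),
                    amplitude = table$amplitude)
  fit <- aov(amplitude ~ stimulus + Error(bee), data = dat)
  tab <- summary(fit)[["Error: Within"]][[1]]
  F_val <- tab["stimulus", "F value"]
  df_e <- tab["stimulus", "Df"]
  df_r <- tab["Residuals", "Df"]
  ms_err <- tab["Residuals", "Mean Sq"]
  # guard against floating-point dust when the stimulus effect is exactly null
  scale <- sum((dat$amplitude - mean(dat$amplitude))^2)
  if (tab["stimulus", "Sum Sq"] <= 1e-12 * max(scale, 1)) F_val <- 0
  p <- pf(F_val, df_e, df_r, lower.tail = FALSE)
  out <- list(F = F_val, df_effect = df_e, df_error = df_r, p = p,
              ms_error = ms_err,
              means = tapply(dat$amplitude, dat$stimulus, mean),
              n_bees = nlevels(dat$bee), n_stimuli = nlevels(dat$stimulus),
              effect_name = "odor")
  if (gg_correction) {
    wide <- tapply(dat$amplitude, list(dat$bee, dat$stimulus), identity)
    eps <- gg_epsilon(wide)
    out$epsilon <- eps
    out$p <- pf(F_val, df_e * eps, df_r * eps, lower.tail = FALSE)
  }
  structure(out, class = "rm_anova_result")
}

# Greenhouse-Geisser epsilon from the within-subject covariance matrix
gg_epsilon <- function(wide) {
  S <- cov(wide)
  k <- ncol(S)
  C <- diag(k) - 1 / k
  SC <- C %*% S %*% C
  sum(diag(SC))^2 / ((k - 1) * sum(SC^2))
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat("Repeated-measures ANOVA (", x$effect_name, " effect): F(",
      x$df_effect, ", ", x$df_error, ") = ", round(x$F, 3), ", p = ",
      format(x$p, digits = 3), "\n", sep = "")
  if (!is.null(x$epsilon))
    cat("  Greenhouse-Geisser epsilon = ", round(x$epsilon, 3), "\n", sep = "")
  invisible(x)
}

#' Dunnett many-to-one post hoc comparisons
#'
#' Compares every stimulus with a common reference (the air control) using
#' the repeated-measures ANOVA error term: for stimulus i,
#' \eqn{t_i = (\bar y_i - \bar y_0) / \sqrt{2\,MS_E / n}} on the ANOVA error
#' df. Two-sided adjusted p-values come from the equicorrelated
#' (\eqn{\rho = 1/2}) multivariate-t distribution of the joint maximum,
#' evaluated numerically.
#'
#' @param table an [amplitude_table()], or the [rm_anova()] fit plus `table`.
#' @param control label of the reference stimulus (e.g. `"air"`).
#' @param fit optional precomputed [rm_anova()] result for `table`.
#' @return A data frame with one row per non-control stimulus: `stimulus`,
#'   `diff`, `t`, `p_raw`, `p_adj` (class `dunnett_result`).
#' @export
dunnett_vs_control <- function(table, control = "air", fit = NULL) {
  table <- amplitude_table(table)
  if (!control %in% table$stimulus)
    stop("control stimulus '", control, "' not present")
  if (is.null(fit)) fit <- rm_anova(table)
  means <- fit$means
  others <- setdiff(names(means), control)
  n <- fit$n_bees
  se <- sqrt(2 * fit$ms_error / n)
  tstat <- (means[others] - means[[control]]) / se
  df <- fit$df_error
  k <- length(others)
  corr <- matrix(0.5, k, k); diag(corr) <- 1
  # quasi-Monte-Carlo integration; local seed for reproducible p-values
  p_adj <- with_preserved_seed(2202, vapply(abs(tstat), function(tt) {
    1 - mvtnorm::pmvt(lower = rep(-tt, k), upper = rep(tt, k), df = df,
                      corr = corr, algorithm =
                        mvtnorm::GenzBretz(abseps = 1e-5, maxpts = 100000))[1]
  }, numeric(1)))
  p_adj <- pmin(pmax(p_adj, 0), 1)
  p_raw <- 2 * pt(-abs(tstat), df)
  out <- data.frame(stimulus = others,
                    diff = as.numeric(means[others] - means[[control]]),
                    t = as.numeric(tstat), p_raw = as.numeric(p_raw),
                    p_adj = as.numeric(pmax(p_adj, p_raw)),
                    row.names = NULL)
  class(out) <- c("dunnett_result", "data.frame")
  out
}

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Paired t test
#'
#' Classical paired t on per-subject value pairs: `t = mean(d)/(sd(d)/sqrt(n))`
#' with `df = n - 1` and a two-sided p-value.
#'
#' @param x,y numeric vectors of equal length (one value per subject).
#' @return A list with `t`, `df`, `p`, `mean_diff` (class `paired_t_result`).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 subjects")
  d <- x - y
  if (sd(d) == 0) stop("degenerate input: zero variance of the differences")
  ht <- t.test(x, y, paired = TRUE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_diff = mean(d)),
            class = "paired_t_result")
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Signed-rank statistic on the paired differences with zero differences
#' dropped and average ranks for ties. The two-sided p-value uses the exact
#' null distribution of V for `n <= 25` without ties, and the normal
#' approximation (with tie correction) otherwise.
#'
#' @param x,y numeric vectors of equal length.
#' @return A list with `statistic` (V, sum of positive ranks), `n`
#'   (nonzero pairs), `p`, `method` (class `wilcoxon_result`).
#' @export
wilcoxon_matched <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate input: all differences are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (n <= 25 && !ties) {
    p <- if (V > n * (n + 1) / 4)
      2 * (1 - stats::psignrank(V - 1, n))
    else
      2 * stats::psignrank(V, n)
    p <- min(p, 1)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal-approximation"
  }
  structure(list(statistic = V, n = n, p = p, method = method),
            class = "wilcoxon_result")
}

#' Friedman rank ANOVA on an amplitude table
#'
#' Nonparametric within-subject comparison of the stimuli: Friedman
#' chi-square on within-bee ranks (average ranks for ties) with
#' `df = k - 1`.
#'
#' @param table an [amplitude_table()] (complete block design).
#' @return A list with `statistic` (chi-square), `df`, `p`
#'   (class `friedman_result`).
#' @export
friedman_rm <- function(table) {
  table <- amplitude_table(table)
  wide <- tapply(table$amplitude, list(table$bee, table$stimulus), identity)
  wide <- as.matrix(wide)
  if (all(apply(wide, 1, function(r) max(r) == min(r)))) {
    # every block fully tied: the tie-corrected statistic is 0/0; define 0
    return(structure(list(statistic = 0, df = ncol(wide) - 1L, p = 1),
                     class = "friedman_result"))
  }
  ht <- friedman.test(wide)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value),
            class = "friedman_result")
}

#' Vapor-pressure regression of response intensity
#'
#' Ordinary least squares of per-odorant mean response amplitude on
#' \eqn{\log_{10}} vapor pressure (mmHg). For the 16-odorant aliphatic panel
#' the F test has (1, 14) df.
#'
#' @param amplitudes named numeric vector of per-odorant mean amplitudes.
#' @param vapor_pressures vapor pressures (mmHg) in the same order, or an
#'   [odor_panel()] from which they are looked up by name (controls and
#'   odorants without a vapor pressure are dropped).
#' @return A list with `slope`, `intercept`, `r_squared`, `F`, `df`, `p`,
#'   `n` (class `vp_regression_result`).
#' @export
vp_regression <- function(amplitudes, vapor_pressures) {
  if (inherits(vapor_pressures, "odor_panel")) {
    panel <- vapor_pressures
    keep <- intersect(names(amplitudes),
                      panel$name[!panel$is_control & !is.na(panel$vapor_pressure)])
    vapor_pressures <- panel$vapor_pressure[match(keep, panel$name)]
    amplitudes <- amplitudes[keep]
  }
  if (length(amplitudes) != length(vapor_pressures))
    stop("amplitudes and vapor pressures differ in length")
  if (length(amplitudes) < 3) stop("need at least 3 odorants")
  if (any(!is.finite(vapor_pressures)) || any(vapor_pressures <= 0))
    stop("vapor pressures must be positive")
  lvp <- log10(vapor_pressures)
  fit <- lm(amplitudes ~ lvp)
  sm <- suppressWarnings(summary(fit))  # silence the perfect-fit warning
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 F = unname(sm$fstatistic[1]),
                 df = unname(sm$fstatistic[2:3]),
                 p = unname(pf(sm$fstatistic[1], sm$fstatistic[2],
                               sm$fstatistic[3], lower.tail = FALSE)),
                 n = length(amplitudes)),
            class = "vp_regression_result")
}

#' @export
print.vp_regression_result <- function(x, ...) {
  cat("Regression on log10 vapor pressure (n = ", x$n, "): R^2 = ",
      round(x$r_squared, 3), ", F(", x$df[1], ", ", x$df[2], ") = ",
      round(x$F, 3), ", p = ", format(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Fisher z comparison of two correlation coefficients
#'
#' Tests whether two independent Pearson correlations differ:
#' \deqn{z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'            {\sqrt{1/(n_1-3) + 1/(n_2-3)}}}
#' with a two-sided p from the standard normal.
#'
#' @param r1,r2 correlation coefficients (|r| < 1).
#' @param n1,n2 sample sizes (>= 4).
#' @return A list with `z` and `p` (class `fisher_z_result`).
#' @export
compare_correlations_fisher <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("degenerate input: |r| must be < 1")
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in both samples")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(z = z, p = 2 * pnorm(-abs(z))), class = "fisher_z_result")
}

#' Shapiro-Wilk-guided paired comparison
#'
#' For comparisons where the distributional assumption is uncertain (e.g.
#' pheromone responses against a control), runs both the paired t test and
#' the Wilcoxon matched-pairs test and reports which one a Shapiro-Wilk
#' normality check on the differences (alpha = 0.05) recommends.
#'
#' @param x,y numeric vectors of equal length.
#' @return A list with `t`, `wilcoxon`, `shapiro_p`, `recommended`
#'   (`"t"` or `"wilcoxon"`).
#' @export
paired_comparison <- function(x, y) {
  sw <- stats::shapiro.test(x - y)
  list(t = paired_t(x, y), wilcoxon = wilcoxon_matched(x, y),
       shapiro_p = sw$p.value,
       recommended = if (sw$p.value >= 0.05) "t" else "wilcoxon")
}
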