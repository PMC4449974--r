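#' Independence-null simulation of the maximum chi-square statistic
#'
#' Emulates the threshold search applied to a gene whose differential
#' expression and differential co-expression are independent: per replicate,
#' `m` pairs (|t|, |Z|) are drawn independently (|t| from a Student t with
#' `t_df` degrees of freedom, |Z| standard normal, both folded to absolute
#' values), the chi-square-maximizing threshold pair is selected, and the
#' maximum chi-square is recorded. Because the statistic depends on the data
#' only through ranks, its null distribution depends only on `m`, not on the
#' marginal shapes. Raw p-values (df = 1 upper tail of the maximum) are then
#' pushed through the two-stage cascade: Bonferroni times `m` candidate
#' tests, then Benjamini-Hochberg across replicates.
#'
#' @param m points (genes) per replicate scatter.
#' @param replicates number of replicate scatters.
#' @param seed optional RNG seed; with a fixed seed the result is
#'   bit-reproducible.
#' @param t_df degrees of freedom of the |t| marginal (default 100;
#'   irrelevant to the null distribution by rank invariance).
#' @param min_expected candidate-validity floor passed to
#'   [select_optimal_thresholds()].
#' @param alpha significance level for the survival counts.
#' @return Object of class `"dcde_null_sim"`: list with `max_chi2`
#'   (per-replicate maxima), `mean_max_chi2`, `q95_max_chi2` (empirical 95th
#'   percentile), `n_sig_raw`, `n_sig_bonferroni`, `n_sig_bh`, and the
#'   simulation parameters.
#' @export
simulate_null <- function(m, replicates, seed = NULL, t_df = 100,
                          min_expected = 5, alpha = 0.05) {
  stopifnot(m >= 100, replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  maxima <- numeric(replicates)
  for (r in seq_len(replicates)) {
    tt <- abs(rt(m, df = t_df))
    zz <- abs(rnorm(m))
    res <- select_optimal_thresholds(zz, tt, min_expected = min_expected)
    maxima[r] <- if (res$no_threshold) NA_real_ else res$chi2
  }
  if (anyNA(maxima)) stop("a replicate produced no valid candidate")
  p_raw <- pchisq(maxima, df = 1, lower.tail = FALSE)
  adj <- adjust_pvalues(p_raw, m)
  structure(list(m = m, replicates = replicates, seed = seed, t_df = t_df,
                 min_expected = min_expected, alpha = alpha,
                 max_chi2 = maxima,
                 mean_max_chi2 = mean(maxima),
                 q95_max_chi2 = unname(quantile(maxima, 0.95)),
                 n_sig_raw = sum(p_raw < alpha),
                 n_sig_bonferroni = sum(adj$bonferroni < alpha),
                 n_sig_bh = sum(adj$bh < alpha)),
            class = "dcde_null_sim")
}

#' @export
print.dcde_null_sim <- function(x, ...) {
  cat("Independence-null simulation of the maximum chi-square\n")
  cat(sprintf("  m = %d points/replicate, %d replicates (t_df = %d, min_expected = %g)\n",
              x$m, x$replicates, x$t_df, x$min_expected))
  cat(sprintf("  mean max chi2 = %.2f, 95th percentile = %.2f\n",
              x$mean_max_chi2, x$q95_max_chi2))
  cat(sprintf("  significant at alpha = %g: raw %d, after Bonferroni %d, after BH %d\n",
              x$alpha, x$n_sig_raw, x$n_sig_bonferroni, x$n_sig_bh))
  invisible(x)
}

#' Power of the two-sided two-sample t test
#'
#' Exact power from the noncentral t distribution for two equal groups of
#' size `n_per_group` at standardized effect size `d` (Cohen's d):
#' noncentrality `d * sqrt(n/2)`, `2n - 2` degrees of freedom.
#'
#' @param n_per_group per-group sample size (>= 2).
#' @param d Cohen's d effect size (> 0).
#' @param alpha two-sided significance level.
#' @return Power in (0, 1).
#' @export
power_two_sample_t <- function(n_per_group, d, alpha = 0.05) {
  stopifnot(n_per_group >= 2, d > 0, alpha > 0, alpha < 1)
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  tcrit <- qt(1 - alpha / 2, df)
  pt(tcrit, df, ncp = ncp, lower.tail = FALSE) + pt(-tcrit, df, ncp = ncp)
}

#' Minimum total sample size for a two-sided two-sample t test
#'
#' Smallest even total `N = 2n` (two equal groups) whose noncentral-t power
#' at effect size `d` and level `alpha` reaches the requested power. The
#' noncentral t computation is used rather than the normal approximation;
#' the two differ at the margin (e.g. 128 vs 126 total at d = 0.5,
#' alpha = 0.05, power 0.8).
#'
#' @param d Cohen's d effect size (> 0).
#' @param alpha two-sided significance level.
#' @param power requested power in (0, 1).
#' @param n_max per-group search bound.
#' @return Total sample size (both groups combined).
#' @export
min_sample_size_t <- function(d, alpha = 0.05, power = 0.8, n_max = 1e6) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 2:n_max) {
    if (power_two_sample_t(n, d, alpha) >= power) return(2L * n)
  }
  stop("requested power not reachable within n_max per group")
}
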