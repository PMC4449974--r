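#' Partition a DC/DE scatter at a threshold pair
#'
#' Each point (z, t) — gene j's differential co-expression with the focal
#' gene and its differential expression — is assigned to exactly one of four
#' partitions. "High" is inclusive (`>=` the threshold), "low" is strict
#' (`<`):
#' HDC_HDE: `z >= z_thr & t >= t_thr`; HDC_LDE: `z >= z_thr & t < t_thr`;
#' LDC_HDE: `z < z_thr & t >= t_thr`; LDC_LDE: `z < z_thr & t < t_thr`.
#'
#' @param z,t numeric vectors of equal positive length (|Z| and |t| values).
#' @param z_thr,t_thr finite thresholds.
#' @return list with `labels` (character vector) and `table` (2x2 matrix,
#'   rows HDC/LDC, columns HDE/LDE).
#' @export
quadrant_partition <- function(z, t, z_thr, t_thr) {
  if (length(z) == 0L) stop("empty point list")
  stopifnot(length(z) == length(t), is.finite(z_thr), is.finite(t_thr))
  hdc <- z >= z_thr
  hde <- t >= t_thr
  labels <- ifelse(hdc & hde, "HDC_HDE",
            ifelse(hdc & !hde, "HDC_LDE",
            ifelse(!hdc & hde, "LDC_HDE", "LDC_LDE")))
  tab <- matrix(c(sum(hdc & hde), sum(!hdc & hde),
                  sum(hdc & !hde), sum(!hdc & !hde)),
                nrow = 2, dimnames = list(DC = c("HDC", "LDC"),
                                          DE = c("HDE", "LDE")))
  list(labels = labels, table = tab)
}

#' Expected counts of a 2x2 contingency table under independence
#'
#' `exp[A, B] = rowtotal(A) * coltotal(B) / n` with the table's own grand
#' total as denominator.
#'
#' @param table 2x2 numeric matrix of observed counts.
#' @return 2x2 matrix of expected counts (sums to the grand total).
#' @export
expected_counts <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  n <- sum(table)
  if (n <= 0) stop("empty table")
  outer(rowSums(table), colSums(table)) / n
}

#' Pearson chi-square statistic of a 2x2 table
#'
#' `sum((obs - exp)^2 / exp)` over the four cells, algebraically equal to
#' `n (ad - bc)^2 / (r1 r2 c1 c2)`. Undefined when a margin is zero; such
#' threshold candidates are treated as invalid by the search.
#'
#' @param table 2x2 numeric matrix of observed counts.
#' @return The chi-square statistic (df = 1).
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  e <- expected_counts(table)
  if (any(e == 0)) stop("zero margin: chi-square undefined")
  sum((table - e)^2 / e)
}

# Closed form n(ad-bc)^2/(r1 r2 c1 c2) from the HDC_HDE count `a`, the HDC
# margin r1, the HDE margin c1 and the grand total n; vectorized over
# candidates. Shared by the fast search and the naive oracle so that the
# two are bit-identical.
.chi2_from_counts <- function(a, r1, c1, n) {
  b <- r1 - a
  cc <- c1 - a
  d <- n - r1 - c1 + a
  (n * (a * d - b * cc)^2) / (r1 * (n - r1) * c1 * (n - c1))
}

#' Select the optimal DC/DE threshold pair by chi-square maximization
#'
#' The candidate set is the observed points themselves: every pair
#' `(z[j], t[j])` is tried as thresholds, the scatter is split into the four
#' high/low partitions, and the candidate maximizing the Pearson chi-square
#' of the 2x2 table is returned. Candidates with a zero margin (chi-square
#' undefined) or with any expected cell below `min_expected` are invalid.
#' Ties on the maximum are broken deterministically by the lexicographically
#' smallest `(z, t)`. The search runs in O(n log n) via plane-sweep dominance
#' counting and is exactly equivalent to the naive all-candidates scan.
#'
#' @param z,t numeric vectors (|Z| and |t| per gene in the scatter).
#' @param min_expected smallest admissible expected cell count (default 5,
#'   the classical validity rule for the chi-square approximation; 3 or 0
#'   relax it).
#' @param candidate_ok optional logical vector: points that may serve as
#'   threshold candidates (degenerate, zero-information points are kept in
#'   the scatter but excluded as candidates).
#' @return list with `z_star`, `t_star`, `chi2`, `p_raw` (df = 1 upper
#'   tail), `table` (2x2 counts at the optimum), `n`, `n_valid_candidates`,
#'   and `no_threshold` (TRUE when no candidate is valid; all other fields
#'   are then NA).
#' @export
select_optimal_thresholds <- function(z, t, min_expected = 5,
                                      candidate_ok = NULL) {
  n <- length(z)
  stopifnot(length(t) == n)
  if (n < 2) stop("need at least 2 points")
  if (is.null(candidate_ok)) candidate_ok <- rep(TRUE, n)

  a <- as.numeric(dominance_counts(z, t))
  r1 <- n - rank(z, ties.method = "min") + 1  # #{z_j >= z_i}
  c1 <- n - rank(t, ties.method = "min") + 1  # #{t_j >= t_i}
  valid <- candidate_ok & r1 < n & c1 < n
  if (min_expected > 0) {
    e11 <- r1 * c1 / n
    e12 <- r1 * (n - c1) / n
    e21 <- (n - r1) * c1 / n
    e22 <- (n - r1) * (n - c1) / n
    valid <- valid & e11 >= min_expected & e12 >= min_expected &
      e21 >= min_expected & e22 >= min_expected
  }
  if (!any(valid)) {
    return(list(z_star = NA_real_, t_star = NA_real_, chi2 = NA_real_,
                p_raw = NA_real_, table = NULL, n = n,
                n_valid_candidates = 0L, no_threshold = TRUE))
  }
  chi2 <- .chi2_from_counts(a, r1, c1, n)
  chi2[!valid] <- -Inf
  mx <- max(chi2)
  cand <- which(chi2 == mx)
  best <- cand[order(z[cand], t[cand])[1L]]
  tab <- matrix(c(a[best], c1[best] - a[best],
                  r1[best] - a[best], n - r1[best] - c1[best] + a[best]),
                nrow = 2, dimnames = list(DC = c("HDC", "LDC"),
                                          DE = c("HDE", "LDE")))
  list(z_star = z[best], t_star = t[best], chi2 = mx,
       p_raw = pchisq(mx, df = 1, lower.tail = FALSE), table = tab,
       n = n, n_valid_candidates = sum(valid), no_threshold = FALSE)
}

#' Two-stage multiple-testing cascade for maximum chi-square p-values
#'
#' Stage 1 is a Bonferroni correction for the per-gene threshold search:
#' each raw p-value (df = 1 upper tail of the maximum chi-square) is
#' multiplied by `n_tests` — the number of candidate threshold tests — and
#' capped at 1. Stage 2 applies the Benjamini-Hochberg step-up across the
#' vector of stage-1 values (one maximum per gene).
#'
#' @param p_raw numeric vector of raw p-values, one per gene.
#' @param n_tests scalar or per-gene vector of candidate-test counts.
#' @return list with `bonferroni` and `bh` vectors.
#' @export
adjust_pvalues <- function(p_raw, n_tests) {
  bonf <- pmin(1, p_raw * n_tests)
  list(bonferroni = bonf, bh = p.adjust(bonf, method = "BH"))
}

#' Adjusted residual of the high-DC/high-DE cell
#'
#' Standardized residual of the HDC_HDE cell,
#' `d = (obs11 - exp11) / sqrt(exp11 (1 - r1/n)(1 - c1/n))`, approximately
#' standard normal under independence. The association is positive when the
#' observed count exceeds the expected one; the one-sided p-value is the
#' standard-normal upper tail of `d`.
#'
#' @param table 2x2 matrix with the HDC_HDE cell at `[1, 1]`.
#' @return list with `residual`, `direction` (`"positive"`/`"negative"`),
#'   and one-sided `p`.
#' @export
adjusted_residual <- function(table) {
  table <- as.matrix(table)
  e <- expected_counts(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin")
  n <- sum(table)
  r1 <- rowSums(table)[1]; c1 <- colSums(table)[1]
  d <- (table[1, 1] - e[1, 1]) /
    sqrt(e[1, 1] * (1 - r1 / n) * (1 - c1 / n))
  list(residual = unname(d),
       direction = if (table[1, 1] > e[1, 1]) "positive" else "negative",
       p = unname(pnorm(d, lower.tail = FALSE)))
}
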