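# Independent oracles and fixture builders used across the suite.
# Every oracle deliberately avoids the code path it checks.

# Naive O(n^2) threshold scan: every observed point tried as a candidate,
# counts obtained by direct logical comparison, chi-square from the same
# closed form as the implementation (so agreement can be bit-identical).
naive_max_chi2 <- function(z, t, min_expected = 5, candidate_ok = NULL) {
  n <- as.numeric(length(z))
  if (is.null(candidate_ok)) candidate_ok <- rep(TRUE, length(z))
  best <- NULL
  for (j in seq_along(z)) {
    if (!candidate_ok[j]) next
    hdc <- z >= z[j]
    hde <- t >= t[j]
    a <- as.numeric(sum(hdc & hde))
    r1 <- as.numeric(sum(hdc))
    c1 <- as.numeric(sum(hde))
    if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) next
    e <- outer(c(r1, n - r1), c(c1, n - c1)) / n
    if (min_expected > 0 && any(e < min_expected)) next
    b <- r1 - a; cc <- c1 - a; d <- n - r1 - c1 + a
    chi2 <- (n * (a * d - b * cc)^2) /
      (r1 * (n - r1) * c1 * (n - c1))
    if (is.null(best) || chi2 > best$chi2 ||
        (chi2 == best$chi2 &&
         (z[j] < best$z_star ||
          (z[j] == best$z_star && t[j] < best$t_star)))) {
      best <- list(z_star = z[j], t_star = t[j], chi2 = chi2,
                   table = matrix(c(a, cc, b, d), nrow = 2))
    }
  }
  best
}

# Exhaustive two-tailed Fisher p-value by enumerating the hypergeometric
# support with choose() ratios (no dhyper, no package code).
fisher_enum <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  lo <- max(0, k - m2); hi <- min(k, m1)
  prob <- vapply(lo:hi, function(x) {
    exp(lchoose(m1, x) + lchoose(m2, k - x) - lchoose(n, k))
  }, numeric(1))
  p_obs <- prob[a - lo + 1]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Per-pair DC statistic computed from first principles with cor() on
# explicit sample subsets (no matrix shortcuts).
naive_dc_pair <- function(values, cls, i, j) {
  ci <- values[i, cls == "case"]; cj <- values[j, cls == "case"]
  ni <- values[i, cls == "control"]; nj <- values[j, cls == "control"]
  fz <- function(r) 0.5 * log((1 + r) / (1 - r))
  zd <- fz(cor(ci, cj)); zn <- fz(cor(ni, nj))
  abs(zn - zd) / sqrt(1 / (length(ni) - 3) + 1 / (length(ci) - 3))
}

# Minimal dataset fixture: deterministic values unless noise is requested.
make_dataset <- function(m = 10, n_case = 6, n_control = 6, seed = 1) {
  set.seed(seed)
  values <- matrix(rnorm(m * (n_case + n_control)), nrow = m,
                   dimnames = list(sprintf("g%02d", seq_len(m)),
                                   sprintf("s%02d", seq_len(n_case + n_control))))
  cls <- setNames(rep(c("case", "control"), c(n_case, n_control)),
                  colnames(values))
  expression_dataset(values, cls)
}

# Write a small matrix + labels TSV pair; returns the two paths.
write_tsv_pair <- function(values, cls, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("tsvpair")
    dir.create(dir)
  }
  mp <- file.path(dir, "matrix.tsv")
  lp <- file.path(dir, "labels.tsv")
  df <- data.frame(gene_id = rownames(values), values, check.names = FALSE)
  write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(cls), class = unname(cls)),
              lp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mp, labels = lp)
}
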