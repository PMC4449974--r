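test_that("quadrant_partition uses inclusive high and exclusive low", {
  # all points strictly below both thresholds
  p <- quadrant_partition(c(1, 2), c(1, 2), 10, 10)
  expect_equal(unname(p$table["LDC", "LDE"]), 2)
  expect_equal(sum(p$table), 2)

  # boundary: a point exactly at the thresholds is high-high
  p2 <- quadrant_partition(c(1, 5), c(1, 5), 5, 5)
  expect_equal(unname(p2$table["HDC", "HDE"]), 1)
  expect_equal(unname(p2$table["LDC", "LDE"]), 1)
  expect_equal(unname(p2$table["HDC", "LDE"]), 0)

  expect_error(quadrant_partition(numeric(0), numeric(0), 1, 1), "empty")
})

test_that("partition labels match direct set definitions on random points", {
  set.seed(31)
  z <- runif(100, 0, 5); t <- runif(100, 0, 8)
  z_thr <- z[17]; t_thr <- t[56]
  p <- quadrant_partition(z, t, z_thr, t_thr)
  # brute-force set membership
  expect_equal(sum(p$labels == "HDC_HDE"), sum(z >= z_thr & t >= t_thr))
  expect_equal(sum(p$labels == "HDC_LDE"), sum(z >= z_thr & t < t_thr))
  expect_equal(sum(p$labels == "LDC_HDE"), sum(z < z_thr & t >= t_thr))
  expect_equal(sum(p$labels == "LDC_LDE"), sum(z < z_thr & t < t_thr))
  expect_equal(unname(p$table["HDC", "HDE"]), sum(z >= z_thr & t >= t_thr))
  # every point labeled exactly once
  expect_equal(sum(p$table), 100)
})

test_that("pearson_chi2 matches the 2x2 closed form and edge cases", {
  # exact independence
  expect_equal(pearson_chi2(matrix(c(10, 30, 20, 60), 2)), 0)
  # diagonal table: n(ad-bc)^2/(r1 r2 c1 c2) = 6*81/(9*9*... ) = 6
  expect_equal(pearson_chi2(matrix(c(3, 0, 0, 3), 2)), 6)
  # partition counts at the reported optimum of the worked example
  tab <- matrix(c(999, 8403, 1090, 14744), 2, byrow = TRUE)
  n <- sum(tab)
  closed <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
  expect_equal(pearson_chi2(tab), closed, tolerance = 1e-9)
  # zero margin undefined
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
})

test_that("expected counts follow the margin product rule", {
  tab <- matrix(c(999, 8403, 1090, 14744), 2, byrow = TRUE,
                dimnames = list(DC = c("HDC", "LDC"), DE = c("HDE", "LDE")))
  e <- expected_counts(tab)
  expect_equal(round(e["HDC", "HDE"], 1), 778.3)
  expect_equal(expected_counts(matrix(5, 2, 2)), matrix(5, 2, 2))
  # expected cells conserve the grand total on random tables
  set.seed(8)
  for (k in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(sum(expected_counts(tab)), sum(tab))
  }
})

test_that("threshold selection maximizes chi-square over observed candidates", {
  # six points, three at (1,1) and three at (5,5): candidate (5,5) isolates
  # the diagonal table (3,0 / 0,3) with chi2 = 6
  z <- c(1, 1, 1, 5, 5, 5); t <- c(1, 1, 1, 5, 5, 5)
  res <- select_optimal_thresholds(z, t, min_expected = 0)
  expect_equal(res$z_star, 5)
  expect_equal(res$t_star, 5)
  expect_equal(res$chi2, 6)
  expect_equal(unname(res$table[1, 1]), 3)

  # all points identical: every split has a zero margin
  res2 <- select_optimal_thresholds(rep(2, 10), rep(3, 10), min_expected = 0)
  expect_true(res2$no_threshold)
  expect_equal(res2$n_valid_candidates, 0L)

  # perfectly associated scatter: the high-z points are exactly the high-t
  # points and one observed point sits at the cluster corner, so a candidate
  # isolates the association perfectly and max chi2 = n
  set.seed(4)
  hi <- 1:20 %in% sample(20, 10)
  zp <- ifelse(hi, runif(20, 3, 4), runif(20, 0, 1))
  tp <- ifelse(hi, runif(20, 5, 6), runif(20, 0, 2))
  corner <- which(hi)[1]
  zp[corner] <- 3; tp[corner] <- 5
  res3 <- select_optimal_thresholds(zp, tp, min_expected = 0)
  expect_equal(res3$chi2, 20)
  expect_equal(adjusted_residual(res3$table)$direction, "positive")
})

test_that("fast search is bit-identical to the naive O(n^2) scan", {
  set.seed(12)
  for (n in c(20, 100, 500)) {
    for (rep in 1:5) {
      z <- abs(rnorm(n)); t <- abs(rt(n, df = 10))
      for (floor in c(0, 5)) {
        fast <- select_optimal_thresholds(z, t, min_expected = floor)
        slow <- naive_max_chi2(z, t, min_expected = floor)
        if (fast$no_threshold) {
          expect_null(slow)  # both paths agree no candidate is valid
          next
        }
        expect_identical(fast$chi2, slow$chi2)
        expect_identical(fast$z_star, slow$z_star)
        expect_identical(fast$t_star, slow$t_star)
        expect_equal(unname(fast$table), unname(slow$table))
      }
    }
  }
  # ties in both coordinates still agree with the scan
  z <- rep(c(0.5, 1.5, 2.5), times = 10)
  t <- rep(c(2, 4), times = 15)
  fast <- select_optimal_thresholds(z, t, min_expected = 0)
  slow <- naive_max_chi2(z, t, min_expected = 0)
  expect_identical(fast$chi2, slow$chi2)
  expect_identical(c(fast$z_star, fast$t_star), c(slow$z_star, slow$t_star))
})

test_that("degenerate points are kept in the scatter but never candidates", {
  set.seed(77)
  z <- c(abs(rnorm(40)), 0, 0)
  t <- c(abs(rnorm(40)), 9, 9)
  ok <- c(rep(TRUE, 40), FALSE, FALSE)
  res <- select_optimal_thresholds(z, t, min_expected = 0, candidate_ok = ok)
  slow <- naive_max_chi2(z, t, min_expected = 0, candidate_ok = ok)
  expect_identical(res$chi2, slow$chi2)
  expect_equal(res$n, 42)
  # the excluded points can never be the selected thresholds
  expect_false(res$z_star == 0 && res$t_star == 9)
})

test_that("the Bonferroni/BH cascade follows its definitions", {
  adj <- adjust_pvalues(0.004, 10)
  expect_equal(adj$bonferroni, 0.04)
  expect_equal(adjust_pvalues(0.5, 10)$bonferroni, 1)
  # BH step-up on the stage-1 vector
  adj2 <- adjust_pvalues(c(0.001, 0.002, 0.003), 10)
  expect_equal(adj2$bonferroni, c(0.01, 0.02, 0.03))
  expect_equal(adj2$bh, c(0.03, 0.03, 0.03))
  # cascade never reorders significance monotonicity
  set.seed(2)
  p <- runif(50)
  adj3 <- adjust_pvalues(p, 50)
  expect_true(all(adj3$bonferroni >= p - 1e-15))
  expect_true(all(adj3$bh >= adj3$bonferroni - 1e-15 | adj3$bh == 1))
})

test_that("adjusted residual signs the high-high cell and squares to chi2", {
  # independence: residual 0, one-sided p = 0.5
  r0 <- adjusted_residual(matrix(c(10, 20, 30, 60), 2))
  expect_equal(r0$residual, 0)
  expect_equal(r0$p, 0.5)

  # hand evaluation: (3,1 / 1,3), exp11 = 2, denom = sqrt(2 * .5 * .5)
  r1 <- adjusted_residual(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(r1$residual, 1 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(r1$direction, "positive")

  # residual^2 equals the Pearson chi-square on random valid 2x2 tables
  set.seed(6)
  for (k in 1:30) {
    tab <- matrix(rpois(4, 15) + 1, 2)
    expect_equal(adjusted_residual(tab)$residual^2, pearson_chi2(tab),
                 tolerance = 1e-9)
  }

  expect_error(adjusted_residual(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("stored thresholds reproduce stored partition counts", {
  syn <- synth_dataset(m = 80, n_case = 25, n_control = 25, block_size = 12,
                       n_decoy_sets = 0, seed = 13)
  fit <- dcde(syn$dataset)
  ok <- which(!fit$results$no_threshold)
  for (i in ok[seq(1, length(ok), by = 7)]) {
    lab <- partition_labels(fit, fit$results$gene_id[i])
    expect_equal(sum(lab == "HDC_HDE"), fit$results$n_hdc_hde[i])
    expect_equal(sum(lab == "HDC_LDE"), fit$results$n_hdc_lde[i])
    expect_equal(sum(lab == "LDC_HDE"), fit$results$n_ldc_hde[i])
    expect_equal(sum(lab == "LDC_LDE"), fit$results$n_ldc_lde[i])
    # partition sizes sum to the scatter size
    expect_equal(fit$results$n_hdc_hde[i] + fit$results$n_hdc_lde[i] +
                   fit$results$n_ldc_hde[i] + fit$results$n_ldc_lde[i],
                 length(lab))
  }
})
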