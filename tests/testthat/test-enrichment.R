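test_that("two-tailed Fisher test matches enumeration and fisher.test", {
  expect_equal(fisher_exact_two_tailed(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_two_tailed(1, 9, 11, 3),
               fisher_enum(1, 9, 11, 3), tolerance = 1e-10)
  # a zero row leaves a single possible table
  expect_equal(fisher_exact_two_tailed(0, 0, 3, 5), 1)
  expect_error(fisher_exact_two_tailed(0, 0, 0, 0), "all-zero")

  # grid of tables with margins <= 60 against the choose()-based oracle
  # and the stats implementation
  set.seed(21)
  for (k in 1:200) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c <- sample(0:15, 1); d <- sample(0:15, 1)
    if (a + b + c + d == 0) next
    p <- fisher_exact_two_tailed(a, b, c, d)
    expect_equal(p, fisher_enum(a, b, c, d), tolerance = 1e-10)
    expect_equal(p,
                 fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("functional information is -log2(p) with underflow protection", {
  # worked-example values: printed adjusted p-values and their FI in bits
  expect_equal(round(functional_information(2.73e-18), 1), 58.3)
  expect_equal(round(functional_information(4.18e-12), 1), 37.8)
  expect_equal(round(functional_information(1.85e-2), 1), 5.8)
  expect_equal(functional_information(1), 0)
  expect_error(functional_information(1.5), "above 1")
  # monotone decreasing in p, additive over products
  p <- c(1e-10, 1e-5, 1e-2, 0.5, 1)
  expect_true(all(diff(functional_information(p)) < 0))
  expect_equal(functional_information(1e-7 * 1e-9),
               functional_information(1e-7) + functional_information(1e-9),
               tolerance = 1e-9)
  # flooring keeps FI finite
  expect_true(is.finite(functional_information(1e-320)))
})

test_that("FI gains take the minimum of the two single-criterion gains", {
  g <- fi_gains(functional_information(2.73e-18),
                functional_information(4.18e-12),
                functional_information(1.85e-2))
  expect_equal(round(unname(g["min_gain"]), 1), 20.5)
  expect_equal(unname(g["min_gain"]),
               min(g["gain_over_de"], g["gain_over_dc"]))
  expect_equal(unname(fi_gains(3, 3, 3)), c(0, 0, 0))
  # combined below both criteria gives a negative minimum gain
  expect_lt(fi_gains(2, 5, 4)[["min_gain"]], 0)
})

test_that("combined partitions are unions of the base quadrants", {
  set.seed(17)
  labels <- setNames(sample(c("HDC_HDE", "HDC_LDE", "LDC_HDE", "LDC_LDE"),
                            200, replace = TRUE), sprintf("g%03d", 1:200))
  parts <- combined_partitions(labels)
  expect_equal(length(parts$HDC),
               length(parts$HDC_HDE) + length(parts$HDC_LDE))
  expect_setequal(parts$HDE, union(parts$HDC_HDE, parts$LDC_HDE))
  expect_setequal(parts$LDC, union(parts$LDC_HDE, parts$LDC_LDE))
  # every gene in exactly one base partition
  expect_setequal(unlist(parts[c("HDC_HDE", "HDC_LDE", "LDC_HDE", "LDC_LDE")]),
                  names(labels))
  expect_equal(sum(lengths(parts[c("HDC_HDE", "HDC_LDE",
                                   "LDC_HDE", "LDC_LDE")])), 200)

  # the worked example's partition sizes: HDC = 999 + 1090, HDE = 999 + 8403
  counts <- c(HDC_HDE = 999, HDC_LDE = 1090, LDC_HDE = 8403, LDC_LDE = 14744)
  big <- setNames(rep(names(counts), counts), sprintf("g%05d", 1:sum(counts)))
  bp <- combined_partitions(big)
  expect_equal(length(bp$HDC), 2089)
  expect_equal(length(bp$HDE), 9402)
})

test_that("best associated set minimizes the Fisher p-value over the collection", {
  universe <- sprintf("g%02d", 1:40)
  gs <- gene_set_collection(list(exact = universe[1:8],
                                 off = universe[21:30],
                                 half = universe[c(1:4, 31:34)]))
  # partition equal to one set, disjoint from the rest
  best <- best_associated_set(universe[1:8], gs, universe)
  expect_equal(best$set_id, "exact")
  expect_equal(best$overlap, 8L)
  expect_equal(best$p_bonferroni, min(1, best$p_raw * 3))

  # zero overlap with every set: all p near 1
  none <- best_associated_set(universe[35:36],
                              gene_set_collection(list(A = universe[1:5])),
                              universe)
  expect_gt(none$p_bonferroni, 0.5)

  # empty partition yields no record
  expect_null(best_associated_set(character(0), gs, universe))

  # selected minimum matches a naive loop over all sets
  set.seed(23)
  for (rep in 1:50) {
    sets <- lapply(1:4, function(k) sample(universe, sample(3:10, 1)))
    names(sets) <- paste0("S", 1:4)
    col <- gene_set_collection(sets)
    members <- sample(universe, sample(2:12, 1))
    got <- best_associated_set(members, col, universe)
    ps <- vapply(names(sets), function(id) {
      s <- sets[[id]]
      a <- length(intersect(members, s))
      fisher_enum(a, length(members) - a, length(s) - a,
                  40 - length(members) - length(s) + a)
    }, numeric(1))
    # the oracle computes probabilities through lchoose rather than dhyper,
    # so mathematically tied minima can differ in the last float digits;
    # accept any set within that tolerance of the oracle minimum
    near_min <- names(sets)[ps <= min(ps) * (1 + 1e-9)]
    expect_true(got$set_id %in% near_min)
    expect_equal(got$p_raw, unname(min(ps)), tolerance = 1e-10)
  }
})

test_that("gene-set summary groups by best set and ranks by mean gain", {
  records <- data.frame(set_id = c("A", "A", "B"), min_gain = c(2, 4, 3.5))
  s <- summarize_by_gene_set(records)
  expect_equal(s$set_id[1], "B")
  expect_equal(s$mean_min_gain[s$set_id == "A"], 3)
  expect_equal(s$n_partitions[s$set_id == "A"], 2L)

  single <- summarize_by_gene_set(data.frame(set_id = "X", min_gain = 1.25))
  expect_equal(single$mean_min_gain, 1.25)

  # random records against a tapply oracle
  set.seed(3)
  rec <- data.frame(set_id = sample(LETTERS[1:5], 60, replace = TRUE),
                    min_gain = rnorm(60))
  s2 <- summarize_by_gene_set(rec)
  oracle <- tapply(rec$min_gain, rec$set_id, mean)
  expect_equal(unname(setNames(s2$mean_min_gain, s2$set_id)[names(oracle)]),
               as.numeric(oracle), tolerance = 1e-12)
  expect_false(is.unsorted(rev(s2$mean_min_gain)))
})
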