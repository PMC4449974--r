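#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test with the usual two-tail convention: the p-value
#' is the sum of the point probabilities of all tables sharing the observed
#' margins whose probability does not exceed that of the observed table
#' (within a relative tolerance of 1e-7 for floating-point ties).
#'
#' @param a,b,c,d non-negative integer cell counts; `a` is the overlap of
#'   interest (partition members inside the gene set).
#' @return The two-tailed p-value.
#' @export
fisher_exact_two_tailed <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative count")
  n <- a + b + c + d
  if (n == 0) stop("all-zero table")
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  probs <- dhyper(lo:hi, m1, m2, k)
  p_obs <- probs[a - lo + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Best-associated gene set of a partition
#'
#' Tests the partition against every set in the collection with the
#' two-tailed Fisher exact test over the dataset universe, Bonferroni-adjusts
#' by the number of sets `k`, and returns the set with the smallest p-value
#' (ties broken by set id). Benjamini-Hochberg across partitions is applied
#' by the caller over the best values.
#'
#' @param members character vector of partition gene ids.
#' @param collection a [gene_set_collection()], already restricted to the
#'   universe (see [filter_gene_sets()]).
#' @param universe character vector: all gene ids of the dataset.
#' @return list with `set_id`, `p_raw`, `p_bonferroni`, `overlap`, `k`; or
#'   `NULL` for an empty partition.
#' @export
best_associated_set <- function(members, collection, universe) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0) stop("empty gene set collection")
  if (length(members) == 0) return(NULL)
  k <- length(collection$sets)
  ids <- names(collection$sets)
  res <- vapply(ids, function(id) {
    .partition_set_fisher(members, collection$sets[[id]], universe)
  }, numeric(2))
  p <- res[1, ]; overlap <- res[2, ]
  best <- order(p, ids)[1L]
  list(set_id = ids[best], p_raw = p[[best]],
       p_bonferroni = min(1, p[[best]] * k),
       overlap = as.integer(overlap[[best]]), k = k)
}

# Fisher p and overlap for one partition x set pair over the universe.
.partition_set_fisher <- function(members, set, universe) {
  a <- length(intersect(members, set))
  b <- length(members) - a
  c <- length(set) - a
  d <- length(universe) - length(members) - length(set) + a
  c(fisher_exact_two_tailed(a, b, c, d), a)
}

#' Functional information of an adjusted p-value
#'
#' `FI = -log2(p)` in bits, with `p` floored at 1e-300 to keep the value
#' finite under numeric underflow. Smaller p-values carry more functional
#' information; `p = 1` carries none.
#'
#' @param p_adjusted numeric vector of p-values in (0, 1].
#' @return numeric vector of FI values in bits.
#' @export
functional_information <- function(p_adjusted) {
  if (any(p_adjusted > 1, na.rm = TRUE)) stop("p-values above 1")
  -log2(pmax(p_adjusted, 1e-300))
}

#' Functional information gains of combined over individual criteria
#'
#' Given the FI of a gene set's association with the combined high-DC/high-DE
#' partition and with the single-criterion HDC and HDE partitions (all at the
#' same optimal thresholds), the gains are
#' `gain_over_de = fi_combined - fi_hde`, `gain_over_dc = fi_combined -
#' fi_hdc`, and `min_gain = min(gain_over_de, gain_over_dc)`. The minimum
#' gain is high only when combining the two criteria beats both single
#' criteria; negative values are meaningful (combining lost information).
#'
#' @param fi_combined,fi_hdc,fi_hde FI values in bits.
#' @return named numeric vector `c(gain_over_de, gain_over_dc, min_gain)`.
#' @export
fi_gains <- function(fi_combined, fi_hdc, fi_hde) {
  stopifnot(is.finite(fi_combined), is.finite(fi_hdc), is.finite(fi_hde))
  g_de <- fi_combined - fi_hde
  g_dc <- fi_combined - fi_hdc
  c(gain_over_de = g_de, gain_over_dc = g_dc, min_gain = min(g_de, g_dc))
}

#' Single-criterion partitions from the four base partitions
#'
#' Unions of the base quadrants at the same thresholds: HDC = HDC_HDE U
#' HDC_LDE, HDE = HDC_HDE U LDC_HDE, LDC = LDC_HDE U LDC_LDE, LDE =
#' HDC_LDE U LDC_LDE.
#'
#' @param labels character vector of base partition labels (values among
#'   HDC_HDE, HDC_LDE, LDC_HDE, LDC_LDE), named by gene id.
#' @return named list of gene-id vectors: `HDC_HDE`, `HDC_LDE`, `LDC_HDE`,
#'   `LDC_LDE`, `HDC`, `HDE`, `LDC`, `LDE`.
#' @export
combined_partitions <- function(labels) {
  if (is.null(names(labels))) stop("labels must be named by gene id")
  ids <- names(labels)
  base <- lapply(c(HDC_HDE = "HDC_HDE", HDC_LDE = "HDC_LDE",
                   LDC_HDE = "LDC_HDE", LDC_LDE = "LDC_LDE"),
                 function(l) ids[labels == l])
  c(base,
    list(HDC = c(base$HDC_HDE, base$HDC_LDE),
         HDE = c(base$HDC_HDE, base$LDC_HDE),
         LDC = c(base$LDC_HDE, base$LDC_LDE),
         LDE = c(base$HDC_LDE, base$LDC_LDE)))
}

#' Rank gene sets by mean minimum functional-information gain
#'
#' Groups enrichment records by their best-associated gene set and reports,
#' per set, how many partitions selected it and the mean minimum FI gain,
#' sorted by decreasing mean gain (ties broken by set id).
#'
#' @param records data frame with columns `set_id` and `min_gain` (one row
#'   per selected partition, as in `fit$enrichment` of a [dcde()] fit).
#' @return data frame: `set_id`, `n_partitions`, `mean_min_gain`.
#' @export
summarize_by_gene_set <- function(records) {
  stopifnot(all(c("set_id", "min_gain") %in% names(records)))
  if (nrow(records) == 0)
    return(data.frame(set_id = character(0), n_partitions = integer(0),
                      mean_min_gain = numeric(0), stringsAsFactors = FALSE))
  sp <- split(records$min_gain, records$set_id)
  out <- data.frame(set_id = names(sp),
                    n_partitions = lengths(sp),
                    mean_min_gain = vapply(sp, mean, numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$mean_min_gain, out$set_id), , drop = FALSE]
}
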