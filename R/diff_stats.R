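#' Per-gene differential expression (Welch t statistic)
#'
#' For each gene the signed statistic
#' \deqn{t_i = (\bar{x}_D - \bar{x}_N) / \sqrt{s_D^2/n_D + s_N^2/n_N}}
#' is computed with unpooled (Welch) variances, where D is the case class and
#' N the control class. A positive value means up-regulation in cases. Genes
#' with zero variance in both classes get `t = 0` and `degenerate = TRUE`.
#'
#' @param dataset an [expression_dataset()].
#' @return data frame with one row per gene: `gene_id`, `t`, `abs_t`,
#'   `mean_case`, `mean_control`, `sd_case`, `sd_control`, `degenerate`.
#' @export
compute_de <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  xd <- dataset$values[, dataset$class == "case", drop = FALSE]
  xn <- dataset$values[, dataset$class == "control", drop = FALSE]
  nd <- ncol(xd); nn <- ncol(xn)
  if (nd < 2 || nn < 2) stop("both classes need at least 2 samples")
  md <- rowMeans(xd); mn <- rowMeans(xn)
  vd <- rowSums((xd - md)^2) / (nd - 1)
  vn <- rowSums((xn - mn)^2) / (nn - 1)
  degenerate <- vd == 0 & vn == 0
  denom <- sqrt(vd / nd + vn / nn)
  t <- ifelse(degenerate, 0, (md - mn) / denom)
  data.frame(gene_id = dataset$gene_ids, t = t, abs_t = abs(t),
             mean_case = md, mean_control = mn,
             sd_case = sqrt(vd), sd_control = sqrt(vn),
             degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher z-transform of a correlation
#'
#' `z = log((1 + r) / (1 - r)) / 2`, with `r` clamped to `|r| <= 1 - 1e-12`
#' so the endpoints stay finite. Odd and strictly increasing on (-1, 1);
#' for a sample correlation over n observations the transform is
#' approximately normal with variance `1/(n - 3)`.
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @return numeric vector of transformed values.
#' @export
fisher_z <- function(r) {
  eps <- 1e-12
  r <- pmin(pmax(r, -1 + eps), 1 - eps)
  0.5 * log((1 + r) / (1 - r))
}

#' Differential co-expression of one focal gene against all others
#'
#' For focal gene i and every other gene j, Pearson correlations are computed
#' separately in the control and case classes and compared on the Fisher-z
#' scale:
#' \deqn{Z_{ij} = |z^N_{ij} - z^D_{ij}| / \sqrt{1/(n_N-3) + 1/(n_D-3)}}
#' A gene that is constant within a class contributes correlation 0 in that
#' class and the pair is flagged `degenerate` (it still appears in the
#' scatter, but threshold selection never uses it as a candidate).
#'
#' @param dataset an [expression_dataset()]; both classes must have more than
#'   3 samples (the Fisher-z variances `1/(n-3)` must be positive).
#' @param focal_gene gene id of the focal gene i.
#' @return data frame over the m - 1 genes j != i: `gene_id`, `r_case`,
#'   `r_control`, `z_case`, `z_control`, `abs_z`, `degenerate`.
#' @export
compute_dc_row <- function(dataset, focal_gene) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$n_case <= 3 || dataset$n_control <= 3)
    stop("differential co-expression needs more than 3 samples per class ",
         "(n - 3 must be positive); have n_case = ", dataset$n_case,
         ", n_control = ", dataset$n_control)
  i <- match(focal_gene, dataset$gene_ids)
  if (is.na(i)) stop("focal gene '", focal_gene, "' not in dataset")
  others <- dataset$gene_ids[-i]
  rc <- .cor_one_vs_rest(dataset$values, i, dataset$class == "case")
  rn <- .cor_one_vs_rest(dataset$values, i, dataset$class == "control")
  degenerate <- attr(rc, "degenerate") | attr(rn, "degenerate")
  zc <- fisher_z(rc); zn <- fisher_z(rn)
  denom <- sqrt(1 / (dataset$n_control - 3) + 1 / (dataset$n_case - 3))
  data.frame(gene_id = others,
             r_case = as.vector(rc), r_control = as.vector(rn),
             z_case = as.vector(zc), z_control = as.vector(zn),
             abs_z = abs(as.vector(zn) - as.vector(zc)) / denom,
             degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Correlation of gene i with every other gene over the given samples.
# Constant genes (zero variance) get r = 0 and are marked degenerate.
.cor_one_vs_rest <- function(values, i, cols) {
  x <- values[i, cols]
  y <- values[-i, cols, drop = FALSE]
  sds <- apply(y, 1L, sd)
  const_focal <- sd(x) == 0
  const_other <- sds == 0
  r <- rep(0, nrow(y))
  ok <- !const_focal & !const_other
  if (any(ok)) r[ok] <- as.vector(cor(x, t(y[ok, , drop = FALSE])))
  attr(r, "degenerate") <- const_focal | const_other
  r
}

# All-pairs |Z| matrix and per-gene degeneracy, computed once for the full
# pipeline (equivalent to m calls of compute_dc_row, but via two m x m
# correlation matrices).
.dc_matrix <- function(dataset) {
  vc <- dataset$values[, dataset$class == "case", drop = FALSE]
  vn <- dataset$values[, dataset$class == "control", drop = FALSE]
  sd_c <- apply(vc, 1L, sd); sd_n <- apply(vn, 1L, sd)
  degenerate_gene <- sd_c == 0 | sd_n == 0
  rc <- suppressWarnings(cor(t(vc)))
  rn <- suppressWarnings(cor(t(vn)))
  rc[degenerate_gene, ] <- 0; rc[, degenerate_gene] <- 0
  rn[degenerate_gene, ] <- 0; rn[, degenerate_gene] <- 0
  denom <- sqrt(1 / (dataset$n_control - 3) + 1 / (dataset$n_case - 3))
  z <- abs(fisher_z(rn) - fisher_z(rc)) / denom
  diag(z) <- NA_real_
  list(z = z, degenerate_gene = degenerate_gene)
}
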