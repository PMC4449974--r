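#' Synthetic two-class expression data with a planted DC/DE block
#'
#' Generates a genes x samples matrix in which a block of `block_size` genes
#' is simultaneously differentially co-expressed and differentially
#' expressed, the exact structure the integrated DC/DE analysis is built to
#' detect. Control samples are pure Gaussian noise for every gene. In case
#' samples, each block gene is
#' `sqrt(rho) * f + sqrt(1 - rho) * noise + delta * noise_sd`, where `f` is a
#' latent factor shared by the block within each case sample: block pairs
#' then have population correlation `rho` in cases and 0 in controls (high
#' DC), and a case mean shift of `delta` noise standard deviations (high DE).
#' Background genes are noise in both classes. A gene-set collection holding
#' the planted block plus `n_decoy_sets` random decoy sets of the same size
#' makes the enrichment stage testable end to end.
#'
#' @param m total number of genes.
#' @param n_case,n_control samples per class.
#' @param block_size number of planted block genes (must be < m).
#' @param rho case-class pairwise latent correlation of block genes, in
#'   `[0, 1)`.
#' @param delta case mean shift of block genes, in units of `noise_sd`.
#' @param noise_sd standard deviation of the background noise.
#' @param n_decoy_sets random same-size decoy gene sets added to the
#'   collection.
#' @param seed optional RNG seed; identical seeds give identical output.
#' @return list with `dataset` (an [expression_dataset()]), `truth`
#'   (character vector of planted gene ids), and `gene_sets` (a
#'   [gene_set_collection()]; the planted set is `"planted_block"`).
#' @export
synth_dataset <- function(m = 1000, n_case = 100, n_control = 100,
                          block_size = 50, rho = 0.8, delta = 1.5,
                          noise_sd = 1, n_decoy_sets = 20, seed = NULL) {
  stopifnot(m >= 2, block_size >= 0, block_size < m,
            rho >= 0, rho < 1, noise_sd > 0,
            n_case >= 2, n_control >= 2)
  if (!is.null(seed)) set.seed(seed)
  gene_ids <- sprintf("g%04d", seq_len(m))
  block <- gene_ids[seq_len(block_size)]

  ctrl <- matrix(rnorm(m * n_control, sd = noise_sd), nrow = m)
  case <- matrix(rnorm(m * n_case, sd = noise_sd), nrow = m)
  if (block_size > 0) {
    f <- rnorm(n_case)  # latent factor, one value per case sample
    bi <- seq_len(block_size)
    case[bi, ] <- sqrt(rho) * matrix(f, nrow = block_size, ncol = n_case,
                                     byrow = TRUE) * noise_sd +
      sqrt(1 - rho) * case[bi, ] + delta * noise_sd
  }
  values <- cbind(case, ctrl)
  rownames(values) <- gene_ids
  colnames(values) <- c(sprintf("case_%03d", seq_len(n_case)),
                        sprintf("ctrl_%03d", seq_len(n_control)))
  cls <- setNames(rep(c("case", "control"), c(n_case, n_control)),
                  colnames(values))
  dataset <- expression_dataset(values, cls)

  sets <- list()
  desc <- character(0)
  if (block_size > 0) {
    sets$planted_block <- block
    desc["planted_block"] <- "synthetic planted DC/DE block"
  }
  if (n_decoy_sets > 0) {
    size <- max(2, block_size)
    for (k in seq_len(n_decoy_sets)) {
      id <- sprintf("decoy_%02d", k)
      sets[[id]] <- sample(gene_ids, min(size, m))
      desc[id] <- "synthetic random decoy set"
    }
  }
  list(dataset = dataset, truth = block,
       gene_sets = gene_set_collection(sets, desc))
}
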