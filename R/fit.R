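#' Integrated differential co-expression / differential expression analysis
#'
#' Fits the full analysis to a two-class expression dataset. For every focal
#' gene i: (i) the absolute Welch t statistic of each gene measures
#' differential expression; (ii) the Fisher-z correlation-difference
#' statistic |Z| between i and each other gene measures differential
#' co-expression; (iii) an optimal threshold pair (z*, t*) on the (|Z|, |t|)
#' scatter is selected by maximizing the Pearson chi-square of the induced
#' 2x2 high/low table; (iv) the dependency is tested via the df = 1
#' chi-square upper tail, carried through a Bonferroni (per-gene candidate
#' tests) then Benjamini-Hochberg (across genes) cascade, and signed via the
#' adjusted residual of the high-DC/high-DE cell; (v) optionally, the
#' partitions of significantly positive genes are scored against functional
#' gene sets, and the functional-information gain of the combined
#' high-DC/high-DE criterion over each single criterion is reported.
#'
#' @param dataset an [expression_dataset()]; both classes need more than 3
#'   samples.
#' @param gene_sets optional [gene_set_collection()]; when `NULL`, the
#'   enrichment stage is skipped.
#' @param alpha significance level used for selecting partitions for
#'   enrichment and in summaries.
#' @param min_expected candidate-validity floor on expected cell counts
#'   (see [select_optimal_thresholds()]).
#' @param bonferroni `"genes"` multiplies each raw p by the number of genes
#'   m (the nominal candidate-test count); `"valid"` multiplies by the
#'   per-gene number of valid candidates actually scanned.
#' @param min_set_size gene sets smaller than this after intersection with
#'   the dataset are dropped.
#' @param workers forked workers for the per-gene loop (unix only; results
#'   are independent of the worker count).
#' @param verbose emit one progress message per pipeline stage.
#' @return Object of class `"dcde"`: list with `results` (per-gene data
#'   frame, see [write_results()] for the column contract), `de` (the
#'   [compute_de()] table), `enrichment` and `set_summary` (data frames or
#'   `NULL`), `z` (the m x m |Z| matrix), `dataset`, `gene_sets` (filtered
#'   collection or `NULL`), `params`, and `call`.
#' @examples
#' syn <- synth_dataset(m = 60, n_case = 30, n_control = 30, block_size = 10,
#'                      n_decoy_sets = 3, seed = 1)
#' fit <- dcde(syn$dataset, syn$gene_sets)
#' fit
#' @export
dcde <- function(dataset, gene_sets = NULL, alpha = 0.05, min_expected = 5,
                 bonferroni = c("genes", "valid"), min_set_size = 2,
                 workers = 1L, verbose = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  bonferroni <- match.arg(bonferroni)
  if (dataset$n_case <= 3 || dataset$n_control <= 3)
    stop("differential co-expression needs more than 3 samples per class")
  m <- length(dataset$gene_ids)
  say <- function(...) if (verbose) message("dcde: ", ...)

  say("differential expression for ", m, " genes")
  de <- compute_de(dataset)
  say("differential co-expression (", m, " x ", m, " pairs)")
  dc <- .dc_matrix(dataset)

  say("threshold selection (min_expected = ", min_expected, ")")
  fit_one <- function(i) {
    zvec <- dc$z[i, -i]
    tvec <- de$abs_t[-i]
    pair_deg <- dc$degenerate_gene[i] | dc$degenerate_gene[-i]
    thr <- select_optimal_thresholds(zvec, tvec, min_expected = min_expected,
                                     candidate_ok = !pair_deg)
    if (thr$no_threshold) {
      return(data.frame(gene_id = de$gene_id[i], t = de$t[i],
                        abs_t = de$abs_t[i], z_star = NA_real_,
                        t_star = NA_real_, max_chi2 = NA_real_,
                        p_raw = NA_real_, direction = NA_character_,
                        adj_residual = NA_real_, residual_p = NA_real_,
                        n_hdc_hde = NA_integer_, n_hdc_lde = NA_integer_,
                        n_ldc_hde = NA_integer_, n_ldc_lde = NA_integer_,
                        n_valid_candidates = 0L, no_threshold = TRUE,
                        stringsAsFactors = FALSE))
    }
    res <- adjusted_residual(thr$table)
    data.frame(gene_id = de$gene_id[i], t = de$t[i], abs_t = de$abs_t[i],
               z_star = thr$z_star, t_star = thr$t_star,
               max_chi2 = thr$chi2, p_raw = thr$p_raw,
               direction = res$direction, adj_residual = res$residual,
               residual_p = res$p,
               n_hdc_hde = thr$table[1, 1], n_hdc_lde = thr$table[1, 2],
               n_ldc_hde = thr$table[2, 1], n_ldc_lde = thr$table[2, 2],
               n_valid_candidates = thr$n_valid_candidates,
               no_threshold = FALSE, stringsAsFactors = FALSE)
  }
  rows <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(m), fit_one, mc.cores = workers)
  } else {
    lapply(seq_len(m), fit_one)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  n_tests <- if (bonferroni == "genes") m else results$n_valid_candidates
  adj <- adjust_pvalues(results$p_raw, n_tests)
  results$p_bonferroni <- adj$bonferroni
  results$p_bh <- adj$bh
  results$residual_p_bh <- p.adjust(results$residual_p, method = "BH")
  results <- results[, .result_columns]
  say(sum(!results$no_threshold), " genes with valid thresholds; ",
      sum(results$p_bh < alpha, na.rm = TRUE), " significant after the cascade")

  fit <- structure(list(results = results, de = de, z = dc$z,
                        degenerate_gene = dc$degenerate_gene,
                        dataset = dataset, gene_sets = NULL,
                        enrichment = NULL, set_summary = NULL,
                        params = list(alpha = alpha,
                                      min_expected = min_expected,
                                      bonferroni = bonferroni,
                                      min_set_size = min_set_size,
                                      m = m, n_case = dataset$n_case,
                                      n_control = dataset$n_control),
                        call = match.call()),
                   class = "dcde")

  if (!is.null(gene_sets)) {
    fsets <- filter_gene_sets(gene_sets, dataset$gene_ids, min_set_size)
    if (length(fsets$sets) == 0) {
      warning("no gene sets left after filtering; enrichment skipped")
    } else {
      fit$gene_sets <- fsets
      fit <- .run_enrichment(fit, say)
    }
  } else {
    say("no gene sets supplied; enrichment skipped")
  }
  fit
}

# Enrichment stage: for every significant, positively-associated focal gene,
# find the best-associated set of its HDC_HDE partition (Bonferroni x k),
# evaluate the same set on the single-criterion HDC and HDE partitions at
# the same thresholds, BH-adjust each kind across the selected genes, and
# convert to functional information and gains.
.run_enrichment <- function(fit, say = function(...) NULL) {
  r <- fit$results
  alpha <- fit$params$alpha
  sel <- which(!r$no_threshold & !is.na(r$p_bh) & r$p_bh < alpha &
                 r$direction == "positive")
  say(length(sel), " significant positive partitions enter enrichment")
  if (length(sel) == 0) {
    fit$enrichment <- data.frame()
    fit$set_summary <- summarize_by_gene_set(
      data.frame(set_id = character(0), min_gain = numeric(0)))
    return(fit)
  }
  universe <- fit$dataset$gene_ids
  k <- length(fit$gene_sets$sets)
  recs <- lapply(sel, function(i) {
    parts <- .gene_partitions(fit, i)
    best <- best_associated_set(parts$HDC_HDE, fit$gene_sets, universe)
    if (is.null(best)) return(NULL)  # empty HDC_HDE partition
    g <- fit$gene_sets$sets[[best$set_id]]
    hdc <- .partition_set_fisher(parts$HDC, g, universe)
    hde <- .partition_set_fisher(parts$HDE, g, universe)
    data.frame(gene_id = r$gene_id[i], set_id = best$set_id,
               overlap_combined = best$overlap,
               overlap_hdc = as.integer(hdc[2]),
               overlap_hde = as.integer(hde[2]),
               p_raw_combined = best$p_raw,
               p_bonf_combined = best$p_bonferroni,
               p_bonf_hdc = min(1, hdc[1] * k),
               p_bonf_hde = min(1, hde[1] * k),
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(recs) || nrow(recs) == 0) {
    fit$enrichment <- data.frame()
    fit$set_summary <- summarize_by_gene_set(
      data.frame(set_id = character(0), min_gain = numeric(0)))
    return(fit)
  }
  recs$p_adj_combined <- p.adjust(recs$p_bonf_combined, method = "BH")
  recs$p_adj_hdc <- p.adjust(recs$p_bonf_hdc, method = "BH")
  recs$p_adj_hde <- p.adjust(recs$p_bonf_hde, method = "BH")
  recs$fi_combined <- functional_information(recs$p_adj_combined)
  recs$fi_hdc <- functional_information(recs$p_adj_hdc)
  recs$fi_hde <- functional_information(recs$p_adj_hde)
  gains <- t(mapply(fi_gains, recs$fi_combined, recs$fi_hdc, recs$fi_hde))
  recs <- cbind(recs, as.data.frame(gains))
  # a partition whose best association is itself not significant carries no
  # functional signal; it stays in the records (flagged) but is excluded
  # from the per-set ranking
  recs$significant <- recs$p_adj_combined < alpha
  fit$enrichment <- recs
  fit$set_summary <- summarize_by_gene_set(recs[recs$significant, ])
  fit
}

# The (|Z|, |t|) scatter of focal gene index i, from the stored matrices.
.gene_scatter <- function(fit, i) {
  list(gene_id = fit$results$gene_id[-i],
       z = fit$z[i, -i],
       t = fit$de$abs_t[-i])
}

.gene_partitions <- function(fit, i) {
  sc <- .gene_scatter(fit, i)
  part <- quadrant_partition(sc$z, sc$t,
                             fit$results$z_star[i], fit$results$t_star[i])
  combined_partitions(setNames(part$labels, sc$gene_id))
}

#' Partition labels induced by a fitted gene's optimal thresholds
#'
#' Recomputes, from the stored |Z| matrix and |t| vector, the partition
#' label of every gene j with respect to focal gene `gene`'s optimal
#' threshold pair. Labels are a pure function of (z*, t*): the induced
#' counts always reproduce the contingency table stored at fit time.
#'
#' @param fit a [dcde()] object.
#' @param gene focal gene id.
#' @return named character vector of labels over the other genes.
#' @export
partition_labels <- function(fit, gene) {
  stopifnot(inherits(fit, "dcde"))
  i <- match(gene, fit$results$gene_id)
  if (is.na(i)) stop("gene '", gene, "' not in fit")
  if (isTRUE(fit$results$no_threshold[i]))
    stop("gene '", gene, "' has no valid threshold pair")
  sc <- .gene_scatter(fit, i)
  part <- quadrant_partition(sc$z, sc$t,
                             fit$results$z_star[i], fit$results$t_star[i])
  setNames(part$labels, sc$gene_id)
}

#' @export
print.dcde <- function(x, ...) {
  r <- x$results
  cat("Integrated DC/DE analysis (chi-square maximization)\n")
  cat(sprintf("  %d genes, %d case / %d control samples\n",
              x$params$m, x$params$n_case, x$params$n_control))
  cat(sprintf("  thresholds selected for %d genes (%d without valid candidates)\n",
              sum(!r$no_threshold), sum(r$no_threshold)))
  cat(sprintf("  significant DC-DE dependency after Bonferroni+BH at alpha = %g: %d (%d positive)\n",
              x$params$alpha, sum(r$p_bh < x$params$alpha, na.rm = TRUE),
              sum(r$p_bh < x$params$alpha & r$direction == "positive",
                  na.rm = TRUE)))
  if (!is.null(x$enrichment)) {
    cat(sprintf("  enrichment: %d partitions scored against %d gene sets\n",
                nrow(x$enrichment), length(x$gene_sets$sets)))
    if (nrow(x$set_summary) > 0)
      cat(sprintf("  top set by mean minimum FI gain: %s (%.1f bits over %d partitions)\n",
                  x$set_summary$set_id[1], x$set_summary$mean_min_gain[1],
                  x$set_summary$n_partitions[1]))
  }
  invisible(x)
}

#' @export
summary.dcde <- function(object, n_top = 10, ...) {
  r <- object$results
  ok <- !r$no_threshold
  top <- r[ok, ][order(-r$max_chi2[ok]), ]
  structure(list(fit = object,
                 top_genes = utils::head(top, n_top),
                 top_sets = if (!is.null(object$set_summary))
                   utils::head(object$set_summary, n_top) else NULL),
            class = "summary.dcde")
}

#' @export
print.summary.dcde <- function(x, ...) {
  print(x$fit)
  cat("\nTop genes by maximum chi-square:\n")
  print(x$top_genes[, c("gene_id", "abs_t", "z_star", "t_star", "max_chi2",
                        "p_bh", "direction")], row.names = FALSE)
  if (!is.null(x$top_sets) && nrow(x$top_sets) > 0) {
    cat("\nTop gene sets by mean minimum FI gain (bits):\n")
    print(x$top_sets, row.names = FALSE)
  }
  invisible(x)
}

#' Scatter of a focal gene's DC/DE plane with its optimal thresholds
#'
#' @param x a [dcde()] object.
#' @param gene focal gene id; defaults to the gene with the largest maximum
#'   chi-square.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dcde <- function(x, gene = NULL, ...) {
  r <- x$results
  if (is.null(gene)) {
    ok <- which(!r$no_threshold)
    if (length(ok) == 0) stop("no gene with a valid threshold pair")
    gene <- r$gene_id[ok[which.max(r$max_chi2[ok])]]
  }
  i <- match(gene, r$gene_id)
  if (is.na(i)) stop("gene '", gene, "' not in fit")
  sc <- .gene_scatter(x, i)
  graphics::plot(sc$z, sc$t, xlab = "|Z| (differential co-expression)",
                 ylab = "|t| (differential expression)",
                 main = paste0("Focal gene ", gene, " (max chi2 = ",
                               signif(r$max_chi2[i], 4), ")"),
                 pch = 20, col = "grey40", ...)
  if (!r$no_threshold[i]) {
    graphics::abline(v = r$z_star[i], h = r$t_star[i],
                     col = "red", lty = 2)
  }
  invisible(x)
}

#' Write the enrichment records of a fit as TSV
#'
#' Long format: one row per (focal gene, partition kind) with the
#' best-associated set of the gene's HDC_HDE partition, the Fisher p-values,
#' the functional information, and the per-gene FI gains.
#'
#' @param fit a [dcde()] object with a non-`NULL` enrichment table.
#' @param path output path.
#' @export
write_enrichment <- function(fit, path) {
  stopifnot(inherits(fit, "dcde"))
  e <- fit$enrichment
  if (is.null(e)) stop("fit has no enrichment results")
  if (nrow(e) == 0) {
    writeLines(paste(c("gene_id", "partition", "set_id", "overlap", "p_raw",
                       "p_adjusted", "fi", "gain_over_de", "gain_over_dc",
                       "min_gain"), collapse = "\t"), path)
    return(invisible(path))
  }
  long <- do.call(rbind, lapply(c("combined", "hdc", "hde"), function(kind) {
    data.frame(gene_id = e$gene_id,
               partition = c(combined = "HDC_HDE", hdc = "HDC",
                             hde = "HDE")[[kind]],
               set_id = e$set_id,
               overlap = e[[paste0("overlap_", kind)]],
               p_raw = if (kind == "combined") e$p_raw_combined else NA_real_,
               p_adjusted = e[[paste0("p_adj_", kind)]],
               fi = e[[paste0("fi_", kind)]],
               gain_over_de = e$gain_over_de,
               gain_over_dc = e$gain_over_dc,
               min_gain = e$min_gain,
               stringsAsFactors = FALSE)
  }))
  long <- long[order(long$gene_id, long$partition), ]
  num <- vapply(long, is.numeric, logical(1)) &
    !vapply(long, is.integer, logical(1))
  long[num] <- lapply(long[num], function(v) sprintf("%.10g", v))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment
#' @export
write_set_summary <- function(fit, path) {
  stopifnot(inherits(fit, "dcde"))
  if (is.null(fit$set_summary)) stop("fit has no gene-set summary")
  write.table(fit$set_summary, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
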