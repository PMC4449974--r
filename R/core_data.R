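#' Construct a two-class expression dataset
#'
#' Bundles a genes x samples expression matrix with a case/control assignment
#' for every sample. This is the raw input of the whole analysis: the
#' differential-expression statistic compares the two sample groups per gene,
#' and the differential-co-expression statistic compares per-class Pearson
#' correlations between gene pairs.
#'
#' @param values numeric matrix, genes in rows (unique rownames = gene ids),
#'   samples in columns (colnames = sample ids). No missing values.
#' @param class_of_sample named character vector mapping every sample id to
#'   `"case"` or `"control"` (after token mapping).
#' @return An object of class `"expression_dataset"`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `class` (character vector aligned
#'   with columns), `n_case`, `n_control`.
#' @seealso [read_expression()] to build one from TSV files.
#' @export
expression_dataset <- function(values, class_of_sample) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (nrow(values) < 2) stop("need at least 2 genes")
  miss <- setdiff(colnames(values), names(class_of_sample))
  if (length(miss))
    stop("samples without a class label: ", paste(miss, collapse = ", "))
  cls <- unname(class_of_sample[colnames(values)])
  bad <- setdiff(unique(cls), c("case", "control"))
  if (length(bad)) stop("unknown class value(s): ", paste(bad, collapse = ", "))
  n_case <- sum(cls == "case")
  n_control <- sum(cls == "control")
  if (n_case == 0) stop("class 'case' has no samples")
  if (n_control == 0) stop("class 'control' has no samples")
  if (n_case < 2) stop("class 'case' has fewer than 2 samples")
  if (n_control < 2) stop("class 'control' has fewer than 2 samples")
  if (n_case < 4 || n_control < 4)
    warning("a class has fewer than 4 samples; differential co-expression ",
            "requires n - 3 > 0 in both classes and will refuse to run")
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = colnames(values),
                 class = cls,
                 n_case = n_case,
                 n_control = n_control),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Two-class expression dataset:", length(x$gene_ids), "genes,",
      x$n_case, "case /", x$n_control, "control samples\n")
  invisible(x)
}

#' Read a two-class expression dataset from TSV files
#'
#' The matrix file is tab-delimited with a header row of sample ids and a
#' first column named `gene_id`; the labels file is tab-delimited with
#' columns `sample_id` and `class`. Rows containing any missing value are
#' dropped (never imputed: a correlation over a varying sample subset would
#' silently change the effective sample size of the Fisher-z test) and the
#' number dropped is reported via a message and the `"n_dropped"` attribute.
#'
#' @param matrix_path path to the expression TSV.
#' @param labels_path path to the sample-to-class TSV.
#' @param case_token,control_token class tokens in the labels file mapped to
#'   case and control respectively.
#' @return An [expression_dataset()]; attribute `"n_dropped"` holds the
#'   number of gene rows removed because of missing values.
#' @export
read_expression <- function(matrix_path, labels_path,
                            case_token = "case", control_token = "control") {
  mat <- read.delim(matrix_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(mat) < 2) stop("expression matrix needs a gene_id column and at least one sample")
  gene_ids <- as.character(mat[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", matrix_path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- as.matrix(mat[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- gene_ids

  labs <- read.delim(labels_path, header = TRUE, sep = "\t",
                     check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(labs)))
    stop("labels file must have columns 'sample_id' and 'class'")
  unknown <- setdiff(labs$sample_id, colnames(vals))
  if (length(unknown))
    stop("labels reference samples absent from the matrix: ",
         paste(unknown, collapse = ", "))
  tok <- labs$class
  cls <- ifelse(tok == case_token, "case",
                ifelse(tok == control_token, "control", NA_character_))
  if (anyNA(cls))
    stop("unrecognized class token(s): ",
         paste(unique(tok[is.na(cls)]), collapse = ", "))
  names(cls) <- labs$sample_id

  keep <- !apply(vals, 1L, anyNA)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("read_expression: dropped ", n_dropped,
            " gene row(s) with missing values")
    vals <- vals[keep, , drop = FALSE]
  }
  ds <- expression_dataset(vals, cls)
  attr(ds, "n_dropped") <- n_dropped
  ds
}

#' Write an expression dataset to the canonical TSV pair
#'
#' @param dataset an [expression_dataset()].
#' @param matrix_path,labels_path output paths.
#' @return Invisibly, `dataset`.
#' @export
write_expression <- function(dataset, matrix_path, labels_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene_id = dataset$gene_ids, dataset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  labs <- data.frame(sample_id = dataset$sample_ids, class = dataset$class,
                     stringsAsFactors = FALSE)
  write.table(labs, labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

#' Read functional gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated as
#' `set_id<TAB>description<TAB>member<TAB>member...`. Duplicate member ids
#' within a set are collapsed; duplicate set ids across lines are an error.
#'
#' @param path path to the GMT file.
#' @return Object of class `"gene_set_collection"`: list with `sets`
#'   (named list of character vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (k in seq_along(lines)) {
    f <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", k, ": fewer than 3 tab-separated fields")
    id <- f[1]
    if (id %in% names(sets)) stop("GMT line ", k, ": duplicate set id '", id, "'")
    sets[[id]] <- unique(f[-(1:2)])
    desc[id] <- f[2]
  }
  gene_set_collection(sets, desc)
}

#' @rdname read_gmt
#' @param sets named list of character vectors of member gene ids.
#' @param descriptions optional named character vector of set descriptions.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) && is.null(names(sets))) stop("sets must be named")
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene set collection:", length(x$sets), "sets\n")
  invisible(x)
}

#' Write a gene set collection in GMT format
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(collection)
}

#' Restrict gene sets to an expression universe
#'
#' Members outside `universe` are removed; sets falling below `min_set_size`
#' are dropped (with a message). The enrichment universe is always the gene
#' ids of the expression dataset being partitioned.
#'
#' @param collection a [gene_set_collection()].
#' @param universe character vector of gene ids.
#' @param min_set_size smallest retained set size after intersection.
#' @return Filtered [gene_set_collection()].
#' @export
filter_gene_sets <- function(collection, universe, min_set_size = 2) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sets <- lapply(collection$sets, intersect, y = universe)
  keep <- lengths(sets) >= min_set_size
  if (any(!keep))
    message("filter_gene_sets: dropped ", sum(!keep),
            " set(s) below min_set_size after intersecting with the dataset")
  gene_set_collection(sets[keep], collection$descriptions[keep])
}

.result_columns <- c("gene_id", "t", "abs_t", "z_star", "t_star", "max_chi2",
                     "p_raw", "p_bonferroni", "p_bh", "direction",
                     "adj_residual", "residual_p", "residual_p_bh",
                     "n_hdc_hde", "n_hdc_lde", "n_ldc_hde", "n_ldc_lde",
                     "n_valid_candidates", "no_threshold")

#' Write / read a per-gene result table
#'
#' Serializes the per-gene threshold-selection results (one row per focal
#' gene) as TSV with a fixed column order and at least 8 significant digits,
#' so that a read-back reproduces values to serialization precision.
#'
#' @param results a data frame as found in `fit$results` of a [dcde()] fit,
#'   or a `"dcde"` object.
#' @param path output path.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "dcde")) results <- results$results
  stopifnot(is.data.frame(results))
  miss <- setdiff(.result_columns, names(results))
  if (length(miss)) stop("results table missing columns: ",
                         paste(miss, collapse = ", "))
  out <- results[, .result_columns]
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.10g", v))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(.result_columns, names(df))
  if (length(miss)) stop("result file missing columns: ",
                         paste(miss, collapse = ", "))
  df$no_threshold <- as.logical(df$no_threshold)
  df
}
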