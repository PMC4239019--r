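#' Read an expression matrix and its sample metadata from TSV files
#'
#' The expression file has gene ids in the first column and one column per
#' sample, with a header row of sample ids. The metadata file has columns
#' `sample_id`, `group`, `kind` and (for controls) `stage_index`. Both
#' Unix and CRLF line endings and stray surrounding whitespace are
#' tolerated.
#'
#' @param expression_path Path to the expression TSV.
#' @param metadata_path Path to the metadata TSV.
#' @param scale Scale tag of the stored values, `"log2"` (default) or
#'   `"linear"`. Linear input is converted to log2 once at ingest.
#'
#' @return An [expression_matrix()] on the log2 scale.
#' @export
read_expression <- function(expression_path, metadata_path,
                            scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  for (p in c(expression_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p)
  expr <- utils::read.delim(expression_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            strip.white = TRUE)
  names(expr) <- trimws(names(expr))
  gene_ids <- trimws(as.character(expr[[1]]))
  values <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  md <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          strip.white = TRUE)
  names(md) <- trimws(names(md))
  for (col in c("sample_id", "group", "kind"))
    if (col %in% names(md)) md[[col]] <- trimws(as.character(md[[col]]))
  if (scale == "linear") {
    if (any(values <= 0)) stop("linear-scale input must be positive")
    values <- log2(values)
    scale <- "log2"
  }
  expression_matrix(values, md, scale = scale)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution:
#' each column's order statistics are replaced by the across-sample mean
#' of the order statistics. This is the cross-array component of RMA,
#' applied here at probe-set level.
#'
#' @param x An [expression_matrix()].
#' @return An [expression_matrix()] with identical sorted value vectors in
#'   every column. A single-sample matrix is returned unchanged with a
#'   warning.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ncol(x$values) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged")
    return(x)
  }
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  expression_matrix(v, x$metadata, scale = x$scale)
}

# internal: FilterReport constructor (partition invariant: each removed
# gene is counted once, in the first filter that removed it)
filter_report <- function(flags) {
  stopifnot(!is.null(names(flags)))
  report <- structure(list(
    n_input = length(flags),
    n_below_detection = sum(flags == "below_detection"),
    n_suffix_removed = sum(flags == "suffix"),
    n_low_variance_removed = sum(flags == "low_variance"),
    n_retained = sum(flags == "retained"),
    flags = flags
  ), class = "FilterReport")
  stopifnot(report$n_input == report$n_retained + report$n_below_detection +
              report$n_suffix_removed + report$n_low_variance_removed)
  report
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf(paste0("FilterReport: %d genes in; %d below detection, ",
                     "%d suffix-removed, %d low-variance; %d retained\n"),
              x$n_input, x$n_below_detection, x$n_suffix_removed,
              x$n_low_variance_removed, x$n_retained))
  invisible(x)
}

#' Remove genes below the linear-scale detection limit
#'
#' A gene is deemed below the detection limit, and removed, when its
#' maximum linear-scale intensity across all samples is below the
#' threshold (200 linear units by default). Using the maximum keeps genes
#' detected in any single group, which is what per-subgroup
#' over-expression queries need.
#'
#' @param x An [expression_matrix()].
#' @param threshold_linear Detection threshold on the linear scale
#'   (default 200). Zero disables the filter; negative values error.
#'
#' @return A list with elements `matrix` (filtered, original gene order)
#'   and `report` (a `FilterReport`).
#' @export
detection_filter <- function(x, threshold_linear = 200) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (threshold_linear < 0) stop("threshold_linear must be non-negative")
  lin <- linear_values(x)
  max_lin <- apply(lin, 1, max)
  keep <- max_lin >= threshold_linear
  flags <- stats::setNames(ifelse(keep, "retained", "below_detection"),
                           rownames(x$values))
  list(matrix = em_subset(x, genes = rownames(x$values)[keep]),
       report = filter_report(flags))
}

#' Prefilter genes for network analysis
#'
#' Drops probe sets whose id carries a cross-hybridizing suffix
#' (`"_x_at"` by default), then keeps the top `1 - variance_quantile`
#' fraction of the remaining genes by variance. Ties in variance are
#' broken deterministically by gene id; input gene order is preserved in
#' the output.
#'
#' @param x An [expression_matrix()].
#' @param suffix Character vector of id suffixes to drop (default
#'   `"_x_at"`).
#' @param variance_quantile Fraction of (non-suffix) genes to drop from
#'   the bottom of the variance distribution, in `[0, 1)`. 0 applies the
#'   suffix filter only.
#'
#' @return A list with elements `matrix` and `report`. An empty result is
#'   allowed and flagged in the report.
#' @export
network_prefilter <- function(x, suffix = "_x_at", variance_quantile = 0.75) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (variance_quantile < 0 || variance_quantile >= 1)
    stop("variance_quantile must lie in [0, 1)")
  ids <- rownames(x$values)
  is_suffix <- Reduce(`|`, lapply(suffix, function(s) endsWith(ids, s)),
                      accumulate = FALSE, init = rep(FALSE, length(ids)))
  flags <- stats::setNames(rep("retained", length(ids)), ids)
  flags[is_suffix] <- "suffix"
  candidates <- ids[!is_suffix]
  if (length(candidates)) {
    v <- row_variances(x$values[candidates, , drop = FALSE])
    n_keep <- ceiling((1 - variance_quantile) * length(candidates))
    ord <- order(-v, candidates)
    drop_ids <- candidates[ord][-seq_len(n_keep)]
    flags[drop_ids] <- "low_variance"
  }
  keep_ids <- ids[flags[ids] == "retained"]
  report <- filter_report(flags)
  if (!length(keep_ids))
    warning("network prefilter removed every gene")
  mat <- if (length(keep_ids)) em_subset(x, genes = keep_ids) else {
    y <- x
    y$values <- x$values[integer(0), , drop = FALSE]
    y
  }
  list(matrix = mat, report = report)
}

#' Write a FilterReport as TSV
#'
#' @param report A `FilterReport`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "FilterReport"))
  df <- data.frame(gene_id = names(report$flags), flag = report$flags,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: unbiased per-row variances
row_variances <- function(m) {
  if (ncol(m) < 2) return(stats::setNames(rep(NA_real_, nrow(m)), rownames(m)))
  mu <- rowMeans(m)
  stats::setNames(rowSums((m - mu)^2) / (ncol(m) - 1), rownames(m))
}
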