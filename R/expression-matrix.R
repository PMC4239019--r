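#' Expression matrix with sample metadata
#'
#' The common currency of the pipeline: a genes x samples matrix of
#' intensities together with per-sample metadata. Values are log2
#' intensities by default; the `scale` tag records whether values are
#' `"log2"` or `"linear"` so that the 200-unit detection rule (a
#' linear-scale statement) can be applied correctly.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#'   Row names are gene (probe-set) ids, column names are sample ids.
#' @param metadata Data frame with columns `sample_id`, `group`,
#'   `kind` (`"tumor"` or `"control"`) and `stage_index` (integer stage
#'   for control groups, `NA` for tumors).
#' @param scale `"log2"` (default) or `"linear"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `metadata` and `scale`.
#' @export
expression_matrix <- function(values, metadata, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as row names and sample ids as column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("`values` must be finite")
  metadata <- validate_metadata(metadata, colnames(values))
  structure(list(values = values, metadata = metadata, scale = scale),
            class = "ExpressionMatrix")
}

validate_metadata <- function(metadata, sample_ids) {
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  needed <- c("sample_id", "group", "kind")
  missing_cols <- setdiff(needed, names(metadata))
  if (length(missing_cols))
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"stage_index" %in% names(metadata)) metadata$stage_index <- NA_integer_
  metadata$stage_index <- suppressWarnings(as.integer(metadata$stage_index))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]), collapse = ", "))
  absent <- setdiff(sample_ids, metadata$sample_id)
  if (length(absent))
    stop("metadata missing samples: ", paste(absent, collapse = ", "))
  extra <- setdiff(metadata$sample_id, sample_ids)
  if (length(extra))
    stop("metadata lists samples absent from the matrix: ",
         paste(extra, collapse = ", "))
  if (!all(metadata$kind %in% c("tumor", "control")))
    stop("metadata `kind` must be 'tumor' or 'control'")
  if (any(is.na(metadata$group)) || any(!nzchar(metadata$group)))
    stop("every sample must have a group")
  # align metadata row order with matrix column order
  metadata <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  metadata
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  tab <- table(x$metadata$group)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Subset an ExpressionMatrix by genes and/or samples
#'
#' @param x An `ExpressionMatrix`.
#' @param genes Character vector of gene ids to keep (default all).
#' @param samples Character vector of sample ids to keep (default all).
#' @return An `ExpressionMatrix` restricted to the requested ids, in the
#'   order given.
#' @export
em_subset <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(genes)) genes <- rownames(x$values)
  if (is.null(samples)) samples <- colnames(x$values)
  bad <- setdiff(genes, rownames(x$values))
  if (length(bad)) stop("unknown gene ids: ", paste(utils::head(bad, 5), collapse = ", "))
  bad <- setdiff(samples, colnames(x$values))
  if (length(bad)) stop("unknown sample ids: ", paste(utils::head(bad, 5), collapse = ", "))
  expression_matrix(x$values[genes, samples, drop = FALSE],
                    x$metadata[match(samples, x$metadata$sample_id), , drop = FALSE],
                    scale = x$scale)
}

#' Sample ids belonging to one group
#'
#' @param x An `ExpressionMatrix`.
#' @param group A group label present in the metadata.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(x, group) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  ids <- x$metadata$sample_id[x$metadata$group == group]
  if (!length(ids)) stop("empty or unknown group: ", group)
  ids
}

#' Group labels by kind
#'
#' @param x An `ExpressionMatrix`.
#' @param kind `"tumor"` or `"control"`.
#' @return Character vector of group labels, in metadata order (controls
#'   are ordered by `stage_index`).
#' @export
group_labels <- function(x, kind = c("tumor", "control")) {
  kind <- match.arg(kind)
  md <- x$metadata[x$metadata$kind == kind, , drop = FALSE]
  if (kind == "control") {
    md <- md[order(md$stage_index), , drop = FALSE]
  }
  unique(md$group)
}

#' Per-group sample counts
#'
#' @param x An `ExpressionMatrix`.
#' @return Named integer vector of group sizes.
#' @export
group_sizes <- function(x) {
  tab <- table(x$metadata$group)
  stats::setNames(as.integer(tab), names(tab))
}

# internal: matrix on the linear scale regardless of the stored tag
linear_values <- function(x) {
  if (x$scale == "linear") x$values else 2^x$values
}
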