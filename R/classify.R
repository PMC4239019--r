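#' Read a classifier gene panel
#'
#' Panels are plain text, one gene id per line; blank lines and lines
#' starting with `#` are ignored. The package ships a default 24-gene
#' subgroup classifier panel at
#' `system.file("extdata", "classifier_panel_24.txt", package = "devalign")`;
#' on U133A-style data four of its genes are typically absent and the
#' classifier proceeds on the remaining twenty.
#'
#' @param path Path to the panel file.
#' @return Character vector of unique gene ids.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (!length(ids)) stop("panel file contains no gene ids")
  unique(ids)
}

#' Classify query samples by PCA alignment to a labelled reference cohort
#'
#' Fits a PCA on the reference samples restricted to the classifier panel
#' genes available in both cohorts, projects the query samples into that
#' fixed reference space (no refitting), and assigns each query sample
#' the label of the nearest reference-group centroid by Euclidean
#' distance in the first `n_components` components.
#'
#' @param reference An [expression_matrix()] whose metadata `group` column
#'   carries the known subgroup labels.
#' @param query An [expression_matrix()] in the same gene space.
#' @param panel Character vector of classifier gene ids (see
#'   [read_panel()]). Panel genes absent from the data are dropped with a
#'   warning reporting their count.
#' @param n_components Number of leading components used for distances
#'   (default 4, the number of discriminative components in the
#'   subgroup-classification setting this implements).
#'
#' @return A `SubgroupAssignment` data frame with columns `sample_id`,
#'   `label`, and one `dist.<label>` column per reference label. The
#'   assigned label always attains the minimum distance (ties broken by
#'   label order).
#' @export
classify_by_reference <- function(reference, query, panel, n_components = 4) {
  stopifnot(inherits(reference, "ExpressionMatrix"),
            inherits(query, "ExpressionMatrix"))
  labels <- unique(reference$metadata$group)
  if (length(labels) < 2)
    stop("reference must contain at least 2 distinct labels")
  present <- intersect(panel, intersect(rownames(reference$values),
                                        rownames(query$values)))
  if (!length(present))
    stop("no panel gene present in both reference and query")
  n_absent <- length(setdiff(panel, present))
  if (n_absent > 0)
    warning(sprintf("%d panel genes absent; classifying on the remaining %d",
                    n_absent, length(present)))
  if (ncol(query$values) < 1) stop("query contains no samples")

  ref_x <- t(reference$values[present, , drop = FALSE])
  fit <- stats::prcomp(ref_x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  ref_scores <- fit$x[, seq_len(k), drop = FALSE]
  qry_x <- t(query$values[present, , drop = FALSE])
  qry_scores <- scale(qry_x, center = fit$center, scale = FALSE) %*%
    fit$rotation[, seq_len(k), drop = FALSE]

  centroids <- do.call(rbind, lapply(labels, function(l) {
    colMeans(ref_scores[reference$metadata$group == l, , drop = FALSE])
  }))
  rownames(centroids) <- labels

  d <- vapply(seq_len(nrow(centroids)), function(i) {
    sqrt(rowSums(sweep(qry_scores, 2, centroids[i, ])^2))
  }, numeric(nrow(qry_scores)))
  d <- matrix(d, nrow = nrow(qry_scores),
              dimnames = list(rownames(qry_scores), labels))
  assigned <- labels[apply(d, 1, which.min)]

  out <- data.frame(sample_id = rownames(qry_scores), label = assigned,
                    stringsAsFactors = FALSE)
  dists <- as.data.frame(d)
  names(dists) <- paste0("dist.", labels)
  out <- cbind(out, dists)
  rownames(out) <- NULL
  attr(out, "n_panel_absent") <- n_absent
  attr(out, "panel_used") <- present
  class(out) <- c("SubgroupAssignment", "data.frame")
  out
}

#' Write subgroup assignments as TSV
#'
#' @param assignment A `SubgroupAssignment` from [classify_by_reference()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_assignments <- function(assignment, path) {
  utils::write.table(as.data.frame(assignment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
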