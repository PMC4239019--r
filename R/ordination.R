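#' Principal component analysis of an expression cohort
#'
#' Samples are the observations, genes the variables; genes are centered
#' internally (no scaling). Variance fractions are computed from the
#' eigenvalues of the sample covariance and sum to 1 over all computed
#' components.
#'
#' @param x An [expression_matrix()].
#' @param n_components Number of components to retain in the scores and
#'   loadings (default: all computed).
#'
#' @return An `OrdinationResult`: list with `scores` (samples x
#'   components), `loadings` (genes x components), `variance_fraction`
#'   (over all computed components), `center` and `metadata`.
#' @export
pca_ordination <- function(x, n_components = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ncol(x$values) < 2) stop("PCA needs at least 2 samples")
  m <- t(x$values)
  total_var <- sum(apply(m, 2, stats::var))
  if (total_var <= 0) stop("constant matrix: no variance to decompose")
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  k <- if (is.null(n_components)) ncol(fit$x) else min(n_components, ncol(fit$x))
  structure(list(scores = fit$x[, seq_len(k), drop = FALSE],
                 loadings = fit$rotation[, seq_len(k), drop = FALSE],
                 variance_fraction = vf,
                 center = fit$center,
                 metadata = x$metadata),
            class = "OrdinationResult")
}

#' @export
print.OrdinationResult <- function(x, ...) {
  cat(sprintf("OrdinationResult: %d samples, %d components retained\n",
              nrow(x$scores), ncol(x$scores)))
  vf <- utils::head(x$variance_fraction, 5)
  cat("variance fractions:",
      paste(sprintf("PC%d %.3f", seq_along(vf), vf), collapse = ", "), "\n")
  invisible(x)
}

#' Group centroids and centroid distances in a selected PC subspace
#'
#' Computes each group's centroid (mean score vector) on the chosen
#' components, all pairwise Euclidean centroid distances (the "geometric
#' vector length" between group centers), and, for every tumor subgroup,
#' the ranking of control groups by ascending distance. The default
#' component set `c(1, 2, 4)` reflects the discriminative-component
#' choice used in the subgroup-alignment setting; it is configuration,
#' not an automatic selection.
#'
#' @param ordination An `OrdinationResult` from [pca_ordination()].
#' @param components Integer vector of component indices (default
#'   `c(1, 2, 4)`, truncated to the computed components must all exist).
#'
#' @return A `CentroidDistanceTable`: list with `centroids` (groups x
#'   components), `distances` (symmetric matrix), `control_ranking`
#'   (named list: tumor subgroup -> control labels, nearest first) and
#'   `components`.
#' @export
group_centroids <- function(ordination, components = c(1, 2, 4)) {
  stopifnot(inherits(ordination, "OrdinationResult"))
  if (any(components < 1) || any(components > ncol(ordination$scores)))
    stop("unknown component index; computed components are 1..",
         ncol(ordination$scores))
  md <- ordination$metadata
  scores <- ordination$scores[, components, drop = FALSE]
  groups <- unique(md$group)
  centroids <- do.call(rbind, lapply(groups, function(g) {
    colMeans(scores[md$group == g, , drop = FALSE])
  }))
  rownames(centroids) <- groups
  distances <- as.matrix(stats::dist(centroids))
  check_metric(distances)
  tumors <- unique(md$group[md$kind == "tumor"])
  controls <- unique(md$group[md$kind == "control"])
  control_ranking <- lapply(tumors, function(s) {
    d <- distances[s, controls]
    controls[order(d)]
  })
  names(control_ranking) <- tumors
  structure(list(centroids = centroids, distances = distances,
                 control_ranking = control_ranking, components = components),
            class = "CentroidDistanceTable")
}

# internal: assert metric axioms on a distance matrix
check_metric <- function(d, tol = 1e-8) {
  stopifnot(isTRUE(all.equal(d, t(d), tolerance = tol)),
            all(d >= -tol), all(abs(diag(d)) <= tol))
  n <- nrow(d)
  if (n <= 3 * 20) { # full check only for small tables
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
      if (d[i, j] > d[i, k] + d[k, j] + tol)
        stop("triangle inequality violated")
  }
  invisible(TRUE)
}

#' Hierarchical clustering of samples
#'
#' Clusters samples on correlation distance (`1 - Pearson`, the default)
#' or Euclidean distance, with a chosen linkage. The tree can be exported
#' as Newick with [dendrogram_newick()].
#'
#' @param x An [expression_matrix()].
#' @param linkage Linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @param distance `"correlation"` (default) or `"euclidean"`.
#'
#' @return An object of class `hclust`.
#' @export
hierarchical_cluster <- function(x, linkage = "average",
                                 distance = c("correlation", "euclidean")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  distance <- match.arg(distance)
  if (ncol(x$values) < 2) stop("clustering needs at least 2 samples")
  d <- switch(distance,
              correlation = stats::as.dist(1 - stats::cor(x$values)),
              euclidean = stats::dist(t(x$values)))
  stats::hclust(d, method = linkage)
}

#' Export an hclust tree as a Newick string
#'
#' @param hc An `hclust` object.
#' @param path Optional file path; when given the Newick string is also
#'   written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write ordination scores and centroid tables as TSV
#'
#' @param ordination An `OrdinationResult`.
#' @param centroid_table A `CentroidDistanceTable`.
#' @param dir Output directory.
#' @return Named vector of paths written, invisibly.
#' @export
write_ordination <- function(ordination, centroid_table, dir) {
  paths <- c(scores = file.path(dir, "pca_scores.tsv"),
             variance = file.path(dir, "pca_variance.tsv"),
             centroids = file.path(dir, "centroids.tsv"),
             distances = file.path(dir, "centroid_distances.tsv"))
  sc <- data.frame(sample_id = rownames(ordination$scores),
                   ordination$scores, check.names = FALSE)
  utils::write.table(sc, paths[["scores"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  vf <- data.frame(component = seq_along(ordination$variance_fraction),
                   variance_fraction = ordination$variance_fraction)
  utils::write.table(vf, paths[["variance"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ce <- data.frame(group = rownames(centroid_table$centroids),
                   centroid_table$centroids, check.names = FALSE)
  utils::write.table(ce, paths[["centroids"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  di <- data.frame(group = rownames(centroid_table$distances),
                   centroid_table$distances, check.names = FALSE)
  utils::write.table(di, paths[["distances"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
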