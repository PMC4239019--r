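#' Co-expression adjacency matrix
#'
#' Pearson correlation between genes raised to a soft power:
#' `|cor|^power` for an unsigned network (default), or
#' `((1 + cor)/2)^power` for a signed network. Values lie in `[0, 1]`
#' with unit diagonal.
#'
#' @param x An [expression_matrix()] (or a genes x samples matrix).
#' @param power Soft-threshold power (>= 1).
#' @param type `"unsigned"` (default) or `"signed"`.
#' @return Symmetric adjacency matrix in `[0, 1]`.
#' @export
adjacency_matrix <- function(x, power, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  v <- if (inherits(x, "ExpressionMatrix")) x$values else x
  if (power < 1) stop("power must be >= 1")
  if (nrow(v) < 2) stop("need at least 2 genes")
  cc <- stats::cor(t(v))
  a <- if (type == "unsigned") abs(cc)^power else ((1 + cc) / 2)^power
  diag(a) <- 1
  a
}

#' Select the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, builds the adjacency, computes each gene's
#' connectivity `k_i = sum_j a_ij (j != i)`, bins `k` into equal-width
#' bins and regresses `log10` of the bin frequencies on `log10` of the
#' bin centers. The fit R-squared measures how closely the connectivity
#' distribution follows a power law (the scale-free small-world model).
#' The chosen power is the smallest one whose R-squared reaches
#' `r2_target`; if none does, the power with the largest R-squared is
#' taken. A degenerate connectivity distribution (all `k` equal, or
#' fewer than 3 usable bins) yields `NA` fit and falls back to the
#' argmax rule with a warning.
#'
#' @param x An [expression_matrix()], typically after
#'   [network_prefilter()].
#' @param powers Candidate integer powers (default 1:10).
#' @param r2_target Scale-free fit target (default 0.85).
#' @param n_bins Number of connectivity bins (default 10).
#' @param type Network type, see [adjacency_matrix()].
#'
#' @return A list with `power` (the chosen one) and `fit_table` (data
#'   frame: `power`, `r_squared`, `slope`, `mean_k`, `median_k`,
#'   `max_k`).
#' @export
select_soft_power <- function(x, powers = 1:10, r2_target = 0.85,
                              n_bins = 10, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  v <- if (inherits(x, "ExpressionMatrix")) x$values else x
  if (nrow(v) < 3) stop("need at least 3 genes to assess scale-free fit")
  if (r2_target <= 0 || r2_target > 1) stop("r2_target must lie in (0, 1]")
  rows <- lapply(powers, function(b) {
    a <- adjacency_matrix(v, b, type)
    k <- colSums(a) - 1
    fit <- scale_free_fit(k, n_bins)
    data.frame(power = b, r_squared = fit$r_squared, slope = fit$slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  fit_table <- do.call(rbind, rows)
  ok <- !is.na(fit_table$r_squared)
  if (!any(ok)) {
    warning("scale-free fit undefined for every power; choosing the ",
            "smallest candidate")
    chosen <- powers[1]
  } else {
    reach <- ok & fit_table$r_squared >= r2_target
    chosen <- if (any(reach)) fit_table$power[which(reach)[1]] else {
      if (!all(ok))
        warning("scale-free fit undefined for some powers; argmax rule ",
                "applied to the rest")
      fit_table$power[which.max(ifelse(ok, fit_table$r_squared, -Inf))]
    }
  }
  list(power = chosen, fit_table = fit_table)
}

# internal: log10-log10 regression of the binned connectivity histogram
scale_free_fit <- function(k, n_bins = 10) {
  if (max(k) - min(k) < 1e-12)
    return(list(r_squared = NA_real_, slope = NA_real_))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- as.vector(table(bin)) / length(k)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  use <- freq > 0 & centers > 0
  if (sum(use) < 3)
    return(list(r_squared = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[use]) ~ log10(centers[use]))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]))
}

#' Topological overlap matrix
#'
#' Neighborhood-sharing similarity of an adjacency matrix:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj`, unit diagonal. Values lie in
#' `[0, 1]` for adjacencies in `[0, 1]`.
#'
#' @param adj Symmetric adjacency matrix in `[0, 1]` with unit diagonal.
#' @return Symmetric TOM matrix.
#' @export
tom_similarity <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (max(abs(adj - t(adj))) > 1e-10) stop("adjacency must be symmetric")
  k <- colSums(adj) - diag(adj)
  l <- adj %*% adj - outer(diag(adj), rep(1, ncol(adj))) * adj -
    adj * outer(rep(1, nrow(adj)), diag(adj))
  kmin <- outer(k, k, pmin)
  tom <- (l + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules by TOM clustering
#'
#' Builds the unsigned (default) adjacency at the given power, converts
#' it to topological-overlap dissimilarity `1 - TOM`, clusters genes by
#' average-linkage hierarchical clustering, and cuts the tree statically
#' at `cut_height`. Clusters smaller than `min_module_size` are assigned
#' the unassigned label 0. Module labels 1, 2, ... are ordered by
#' decreasing size.
#'
#' @param x An [expression_matrix()] (typically prefiltered).
#' @param power Soft power, e.g. from [select_soft_power()].
#' @param min_module_size Smallest retained module (default 20).
#' @param cut_height Static tree-cut height on `1 - TOM` dissimilarity
#'   (default 0.7: on cohorts with well-separated co-expression
#'   structure, within-module TOM dissimilarities sit well below this
#'   while between-module joins occur above it).
#' @param type Network type, see [adjacency_matrix()].
#'
#' @return A `ModuleSet`: list with `labels` (named integer vector,
#'   gene -> module, 0 = unassigned), `sizes`, `tree` (hclust), `power`
#'   and `cut_height`.
#' @export
detect_modules <- function(x, power, min_module_size = 20, cut_height = 0.7,
                           type = c("unsigned", "signed")) {
  type <- match.arg(type)
  if (cut_height <= 0 || cut_height > 1) stop("cut_height must lie in (0, 1]")
  v <- if (inherits(x, "ExpressionMatrix")) x$values else x
  adj <- adjacency_matrix(v, power, type)
  diss <- 1 - tom_similarity(adj)
  tree <- stats::hclust(stats::as.dist(diss), method = "average")
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_module_size]
  if (!length(big)) warning("no cluster reaches min_module_size; all genes unassigned")
  if (length(big) == length(sizes) && length(big) == 1)
    warning("all genes fall in a single module")
  # relabel retained clusters 1..M by decreasing size (ties by raw label)
  big <- big[order(-as.integer(sizes[big]), as.integer(big))]
  labels <- rep(0L, length(raw))
  names(labels) <- names(raw)
  for (i in seq_along(big)) labels[raw == as.integer(big[i])] <- i
  structure(list(labels = labels,
                 sizes = table(labels[labels > 0]),
                 tree = tree, power = power, cut_height = cut_height),
            class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  cat(sprintf("ModuleSet: %d genes, %d modules (%d unassigned)\n",
              length(x$labels), length(x$sizes), sum(x$labels == 0)))
  invisible(x)
}

#' Module eigengenes
#'
#' The eigengene of a module is the unit-norm first right singular vector
#' of the standardized member-gene submatrix: the normalized linear
#' combination of the module's genes with the largest variance. Signs are
#' fixed so that the mean correlation between the eigengene and the
#' member genes is non-negative. A single-gene module's eigengene is the
#' standardized gene itself (unit norm).
#'
#' @param x An [expression_matrix()] containing the module genes.
#' @param modules A `ModuleSet` from [detect_modules()], or a named
#'   integer vector of labels.
#'
#' @return An `EigengeneMatrix`: modules x samples numeric matrix with
#'   rows `ME1`, `ME2`, ... each of unit norm; attribute `module_sizes`.
#' @export
module_eigengenes <- function(x, modules) {
  v <- if (inherits(x, "ExpressionMatrix")) x$values else x
  labels <- if (inherits(modules, "ModuleSet")) modules$labels else modules
  labels <- labels[names(labels) %in% rownames(v)]
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) stop("no assigned module")
  eg <- matrix(NA_real_, length(ids), ncol(v),
               dimnames = list(paste0("ME", ids), colnames(v)))
  for (i in seq_along(ids)) {
    members <- names(labels)[labels == ids[i]]
    m <- v[members, , drop = FALSE]
    ms <- standardize_rows(m)
    e <- if (nrow(ms) == 1) {
      as.vector(ms)
    } else {
      sv <- svd(ms, nu = 0, nv = 1)
      sv$v[, 1]
    }
    e <- e / sqrt(sum(e^2))
    cors <- suppressWarnings(stats::cor(t(ms), e))
    if (mean(cors, na.rm = TRUE) < 0) e <- -e
    eg[i, ] <- e
  }
  structure(eg, module_sizes = stats::setNames(
    as.integer(table(labels[labels > 0])[as.character(ids)]),
    paste0("ME", ids)),
    class = c("EigengeneMatrix", "matrix", "array"))
}

# internal: center and scale rows; constant rows become zero
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  s[s == 0] <- Inf
  (m - mu) / s
}

#' Cluster families of module eigengenes
#'
#' Average-linkage hierarchical clustering of modules on the eigengene
#' correlation distance `1 - cor`, with families by a static cut.
#'
#' @param eigengenes An `EigengeneMatrix` from [module_eigengenes()].
#' @param cut_height Static cut height on `1 - cor` (default 0.5).
#' @return A list with `tree` (hclust), `families` (named integer
#'   vector module -> family) and `newick`.
#' @export
cluster_families <- function(eigengenes, cut_height = 0.5) {
  if (nrow(eigengenes) < 2) stop("need at least 2 modules")
  d <- 1 - stats::cor(t(unclass(eigengenes)))
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  families <- stats::cutree(tree, h = cut_height)
  list(tree = tree, families = families, newick = dendrogram_newick(tree))
}

#' Eigengene-trait association
#'
#' Pearson correlation of every module eigengene with every trait, with
#' a two-sided p-value from the t approximation on `n - 2` degrees of
#' freedom. Traits are typically 0/1 subgroup-membership indicators
#' (see [subgroup_trait_matrix()]). Constant traits give `NA`.
#'
#' @param eigengenes An `EigengeneMatrix`.
#' @param traits Samples x traits numeric matrix (column names are trait
#'   names), sample order matching the eigengene columns.
#'
#' @return A list with matrices `r` and `p` (modules x traits).
#' @export
trait_association <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  if (nrow(traits) != ncol(eigengenes))
    stop("traits must have one row per sample")
  n <- nrow(traits)
  if (n < 3) stop("need at least 3 samples")
  r <- suppressWarnings(stats::cor(t(unclass(eigengenes)), traits))
  p <- correlation_p(r, n)
  dimnames(p) <- dimnames(r)
  list(r = r, p = p, n = n)
}

# internal: two-sided p for a Pearson r on n-2 df
correlation_p <- function(r, n) {
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  at_one <- which(abs(r) >= 1)
  t_stat[at_one] <- Inf * sign(r[at_one])
  2 * stats::pt(-abs(t_stat), n - 2)
}

#' Binary subgroup-membership trait matrix
#'
#' One 0/1 column per tumor subgroup, over all samples of the cohort.
#'
#' @param x An [expression_matrix()] (its metadata is used).
#' @return Samples x subgroups 0/1 matrix.
#' @export
subgroup_trait_matrix <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  subgroups <- group_labels(x, "tumor")
  m <- vapply(subgroups, function(s) as.numeric(x$metadata$group == s),
              numeric(nrow(x$metadata)))
  rownames(m) <- x$metadata$sample_id
  m
}

#' Induced stage trait of one alignment hypothesis
#'
#' Given a candidate map of tumor subgroups onto control stages, each
#' tumor sample receives its subgroup's mapped stage and each control
#' sample its own stage. Encoding `"stage_rank"` (default) uses the
#' stage indices 1..K; `"control_mean"` replaces each stage by the mean
#' log2 intensity of the control group at that stage (requires the
#' expression matrix).
#'
#' @param x An [expression_matrix()].
#' @param map Named numeric vector subgroup -> stage index; must be
#'   injective over the subgroups.
#' @param encoding `"stage_rank"` or `"control_mean"`.
#' @return Named numeric vector over samples, in column order of `x`.
#' @export
alignment_trait <- function(x, map, encoding = c("stage_rank", "control_mean")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  encoding <- match.arg(encoding)
  md <- x$metadata
  subgroups <- group_labels(x, "tumor")
  if (!all(subgroups %in% names(map)))
    stop("map must cover every tumor subgroup")
  if (anyDuplicated(map[subgroups])) stop("map must be injective")
  stage <- ifelse(md$kind == "control", md$stage_index,
                  as.numeric(map[md$group]))
  if (encoding == "control_mean") {
    ctrl <- md[md$kind == "control", , drop = FALSE]
    stage_mean <- tapply(
      colMeans(x$values[, ctrl$sample_id, drop = FALSE])[ctrl$sample_id],
      ctrl$stage_index, mean)
    stage <- as.numeric(stage_mean[as.character(stage)])
  }
  stats::setNames(stage, md$sample_id)
}

#' Score candidate subgroup-to-stage alignment orders
#'
#' Every candidate map induces a per-sample stage trait (see
#' [alignment_trait()]); each module eigengene is correlated with that
#' trait and the hypothesis score is the best module correlation — by
#' default the maximum *signed* r, which breaks the reversal symmetry by
#' requiring positive correlation with the stage order; set
#' `positive_only = FALSE` to score by `max |r|` instead. Hypotheses are
#' ranked by score.
#'
#' @param eigengenes An `EigengeneMatrix`.
#' @param x The [expression_matrix()] the eigengenes were computed from
#'   (metadata and, for the `control_mean` encoding, values are used).
#' @param candidate_maps List of named stage maps; default: all
#'   injective maps of the tumor subgroups onto the control stages
#'   (the full factorial enumeration).
#' @param encoding Trait encoding, see [alignment_trait()].
#' @param positive_only Score by max signed r (default `TRUE`) or by
#'   max `|r|`.
#'
#' @return A data frame, one row per hypothesis, ranked by decreasing
#'   score: columns `map` (readable string), `score`, `best_module`,
#'   `best_p`; attribute `per_module` holds the full r and p matrices
#'   (hypotheses x modules), and `maps` the candidate list in ranked
#'   order.
#' @export
score_alignment_orders <- function(eigengenes, x, candidate_maps = NULL,
                                   encoding = c("stage_rank", "control_mean"),
                                   positive_only = TRUE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  encoding <- match.arg(encoding)
  subgroups <- group_labels(x, "tumor")
  stages <- sort(unique(x$metadata$stage_index[x$metadata$kind == "control"]))
  if (is.null(candidate_maps)) {
    if (length(subgroups) != length(stages))
      stop("default enumeration needs as many subgroups as stages")
    candidate_maps <- lapply(permutations(length(stages)), function(p)
      stats::setNames(stages[p], subgroups))
  }
  n <- ncol(eigengenes)
  r_mat <- matrix(NA_real_, length(candidate_maps), nrow(eigengenes),
                  dimnames = list(NULL, rownames(eigengenes)))
  for (i in seq_along(candidate_maps)) {
    trait <- alignment_trait(x, candidate_maps[[i]], encoding)
    r_mat[i, ] <- as.vector(suppressWarnings(
      stats::cor(t(unclass(eigengenes)), trait)))
  }
  p_mat <- correlation_p(r_mat, n)
  score_of <- if (positive_only) function(r) max(r) else function(r) max(abs(r))
  scores <- apply(r_mat, 1, score_of)
  best_idx <- apply(r_mat, 1, function(r)
    if (positive_only) which.max(r) else which.max(abs(r)))
  ord <- order(-scores)
  out <- data.frame(
    rank = seq_along(ord),
    map = vapply(candidate_maps[ord], function(m)
      paste(sprintf("%s=%d", names(m), as.integer(m)), collapse = ","), ""),
    score = scores[ord],
    best_module = rownames(eigengenes)[best_idx[ord]],
    best_p = p_mat[cbind(ord, best_idx[ord])],
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "per_module") <- list(r = r_mat[ord, , drop = FALSE],
                                  p = p_mat[ord, , drop = FALSE])
  attr(out, "maps") <- candidate_maps[ord]
  attr(out, "encoding") <- encoding
  out
}

# internal: all permutations of 1..n (n small)
permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations(n - 1)
    out <- c(out, lapply(rest, function(p) {
      full <- seq_len(n)[-i]
      c(i, full[p])
    }))
  }
  out
}
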