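#' Per-group summary statistics for every gene
#'
#' Mean, standard deviation, median and (unbiased) variance per gene per
#' group, in log2 units. Single-sample groups report `NA` for sd and
#' variance.
#'
#' @param x An [expression_matrix()].
#' @return A long data frame with columns `gene_id`, `group`, `n`,
#'   `mean`, `sd`, `median`, `variance`.
#' @export
compute_group_stats <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  groups <- unique(x$metadata$group)
  out <- lapply(groups, function(g) {
    ids <- group_samples(x, g)
    m <- x$values[, ids, drop = FALSE]
    n <- ncol(m)
    mu <- rowMeans(m)
    v <- if (n > 1) rowSums((m - mu)^2) / (n - 1) else rep(NA_real_, nrow(m))
    data.frame(gene_id = rownames(m), group = g, n = n, mean = mu,
               sd = sqrt(v), median = apply(m, 1, stats::median),
               variance = v, row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-gene two-sample t test between two groups
#'
#' Two-sided Student's (pooled, default) or Welch t test for every gene
#' between groups A and B, with linear-scale fold change
#' `2^(meanA - meanB)` and a direction call (`up`/`down` when `p < alpha`,
#' else `ns`). When both groups have zero variance and equal means the
#' test is degenerate and reported as `t = 0, p = 1, ns`; zero variance
#' with unequal means gives `p = 0` in the sign's direction.
#'
#' @param x An [expression_matrix()] on the log2 scale.
#' @param group_a,group_b Group labels; both must have n >= 2 (a
#'   single-sample reference belongs in [single_reference_membership()]).
#' @param alpha Significance level (default 0.05).
#' @param variant `"student"` (pooled; default) or `"welch"`.
#'
#' @return A `DEComparisonResult` data frame with columns `gene_id`,
#'   `mean_a`, `mean_b`, `t`, `df`, `p`, `fold_change`, `direction`, and
#'   attributes `subgroup`, `control`, `alpha`, `variant`, `control_n`,
#'   `type = "test"`.
#' @export
pairwise_test <- function(x, group_a, group_b, alpha = 0.05,
                          variant = c("student", "welch")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  variant <- match.arg(variant)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  a <- x$values[, group_samples(x, group_a), drop = FALSE]
  b <- x$values[, group_samples(x, group_b), drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2 || nb < 2)
    stop("both groups need n >= 2; use single_reference_membership() for ",
         "a single-sample reference")
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  va <- rowSums((a - mu_a)^2) / (na - 1)
  vb <- rowSums((b - mu_b)^2) / (nb - 1)
  diff <- mu_a - mu_b
  if (variant == "student") {
    df <- rep(na + nb - 2, nrow(a))
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t_stat <- diff / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  degenerate <- se == 0
  if (any(degenerate)) {
    zero_diff <- degenerate & diff == 0
    t_stat[zero_diff] <- 0; p[zero_diff] <- 1
    inf_diff <- degenerate & diff != 0
    t_stat[inf_diff] <- sign(diff[inf_diff]) * Inf
    p[inf_diff] <- 0
    df[degenerate & is.na(df)] <- na + nb - 2
  }
  direction <- ifelse(p < alpha, ifelse(diff > 0, "up", "down"), "ns")
  out <- data.frame(gene_id = rownames(x$values), mean_a = mu_a,
                    mean_b = mu_b, t = t_stat, df = df, p = p,
                    fold_change = 2^diff, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "subgroup") <- group_a
  attr(out, "control") <- group_b
  attr(out, "alpha") <- alpha
  attr(out, "variant") <- variant
  attr(out, "control_n") <- nb
  attr(out, "type") <- "test"
  class(out) <- c("DEComparisonResult", "data.frame")
  out
}

#' Sigma-fold membership test against a single reference sample
#'
#' For a control represented by one profile only, each gene's reference
#' value is tested for inclusion in the subgroup's sample distribution
#' using the standard deviation as the membership cutoff: the sigma-fold
#' deviation is `(x_ref - mean_S) / sd_S`, and the reference is `inside`
#' when its absolute value is at most `k` (default 2). When the reference
#' falls more than `k` standard deviations *below* the subgroup mean the
#' subgroup is called over-expressed (`up`) relative to the reference;
#' symmetrically `down` above. A zero-sd subgroup is decided by exact
#' equality.
#'
#' @param x An [expression_matrix()].
#' @param subgroup A tumor group label with n >= 2.
#' @param reference Either the label of a single-sample control group or
#'   a sample id.
#' @param k Membership cutoff in standard deviations (default 2).
#'
#' @return A `DEComparisonResult` data frame with columns `gene_id`,
#'   `mean_s`, `sd_s`, `ref_value`, `sigma_fold`, `membership`
#'   (`inside`/`outside`), `fold_change` (`2^(mean_s - ref)`) and
#'   `direction`; attribute `type = "membership"`.
#' @export
single_reference_membership <- function(x, subgroup, reference, k = 2) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (k <= 0) stop("k must be positive")
  s_ids <- group_samples(x, subgroup)
  if (length(s_ids) < 2) stop("subgroup must have n >= 2")
  ref_id <- if (reference %in% x$metadata$group) {
    ids <- group_samples(x, reference)
    if (length(ids) != 1)
      stop("reference group '", reference, "' is not a single sample")
    ids
  } else if (reference %in% x$metadata$sample_id) {
    reference
  } else stop("unknown reference: ", reference)

  m <- x$values[, s_ids, drop = FALSE]
  mu <- rowMeans(m)
  sd_s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  ref <- x$values[, ref_id]
  sigma_fold <- (ref - mu) / sd_s
  zero_sd <- sd_s == 0
  sigma_fold[zero_sd] <- ifelse(ref[zero_sd] == mu[zero_sd], 0,
                                sign(ref[zero_sd] - mu[zero_sd]) * Inf)
  membership <- ifelse(abs(sigma_fold) <= k, "inside", "outside")
  direction <- ifelse(sigma_fold < -k, "up",
                      ifelse(sigma_fold > k, "down", "ns"))
  out <- data.frame(gene_id = rownames(x$values), mean_s = mu, sd_s = sd_s,
                    ref_value = ref, sigma_fold = sigma_fold,
                    membership = membership,
                    fold_change = 2^(mu - ref), direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "subgroup") <- subgroup
  attr(out, "control") <- if (reference %in% x$metadata$group) reference else
    x$metadata$group[x$metadata$sample_id == ref_id]
  attr(out, "k") <- k
  attr(out, "control_n") <- 1L
  attr(out, "type") <- "membership"
  class(out) <- c("DEComparisonResult", "data.frame")
  out
}

#' All subgroup-versus-control comparisons of a cohort
#'
#' Convenience wrapper running [pairwise_test()] for every (tumor
#' subgroup, multi-sample control) pair and
#' [single_reference_membership()] for every single-sample control.
#'
#' @param x An [expression_matrix()].
#' @param alpha Significance level for the t tests.
#' @param k Sigma-fold membership cutoff for n = 1 controls.
#' @param variant t-test variant, see [pairwise_test()].
#' @return A list of `DEComparisonResult` objects covering every
#'   (subgroup, control) pair, named `"<subgroup> vs <control>"`.
#' @export
dia_comparisons <- function(x, alpha = 0.05, k = 2,
                            variant = c("student", "welch")) {
  variant <- match.arg(variant)
  subgroups <- group_labels(x, "tumor")
  controls <- group_labels(x, "control")
  if (!length(subgroups)) stop("cohort contains no tumor subgroups")
  sizes <- group_sizes(x)
  out <- list()
  for (s in subgroups) for (cg in controls) {
    res <- if (sizes[[cg]] > 1)
      pairwise_test(x, s, cg, alpha = alpha, variant = variant)
    else
      single_reference_membership(x, s, cg, k = k)
    out[[paste(s, "vs", cg)]] <- res
  }
  attr(out, "subgroups") <- subgroups
  attr(out, "controls") <- controls
  out
}

#' Step-wise exclusivity intersection across all comparisons
#'
#' Implements the developmental-intersect classification. For each gene
#' and subgroup S, step 1 requires `p < alpha` with the stated direction
#' versus *every* control with n > 1; single-sample controls contribute a
#' sigma-fold membership call (`outside` in the same direction) that is
#' recorded as corroboration but is not required. Step 2 marks a passing
#' gene `exclusive` for S when no other subgroup also passed step 1, and
#' `shared` otherwise; genes failing step 1 are `none`.
#'
#' @param results A list of `DEComparisonResult` objects covering every
#'   (subgroup, control) pair, e.g. from [dia_comparisons()].
#' @param direction Direction of differential expression queried
#'   (`"up"`, the over-expression query, or `"down"`).
#'
#' @return An `ExclusivityCall` data frame with columns `gene_id`,
#'   `subgroup`, `class` (`exclusive`/`shared`/`none`), `direction` and
#'   `corroborated` (logical: every n = 1 control was outside in the same
#'   direction).
#' @export
stepwise_exclusive <- function(results, direction = c("up", "down")) {
  direction <- match.arg(direction)
  subgroups <- attr(results, "subgroups")
  controls <- attr(results, "controls")
  if (is.null(subgroups)) {
    subgroups <- unique(vapply(results, attr, "", "subgroup"))
    controls <- unique(vapply(results, attr, "", "control"))
  }
  genes <- results[[1]]$gene_id
  multi <- controls[vapply(controls, function(cg) {
    key <- paste(subgroups[1], "vs", cg)
    if (is.null(results[[key]])) stop("missing comparison: ", key)
    attr(results[[key]], "control_n") > 1
  }, logical(1))]
  single <- setdiff(controls, multi)

  get_res <- function(s, cg) {
    key <- paste(s, "vs", cg)
    if (is.null(results[[key]]))
      stop("missing comparison: ", key)
    res <- results[[key]]
    if (!identical(res$gene_id, genes))
      stop("comparison ", key, " covers a different gene set")
    res
  }

  pass <- matrix(TRUE, length(genes), length(subgroups),
                 dimnames = list(genes, subgroups))
  corr <- matrix(TRUE, length(genes), length(subgroups),
                 dimnames = list(genes, subgroups))
  for (s in subgroups) {
    for (cg in multi) {
      res <- get_res(s, cg)
      pass[, s] <- pass[, s] & res$direction == direction
    }
    for (cg in single) {
      res <- get_res(s, cg)
      corr[, s] <- corr[, s] & res$membership == "outside" &
        res$direction == direction
    }
  }
  n_pass <- rowSums(pass)
  cls <- matrix("none", length(genes), length(subgroups),
                dimnames = list(genes, subgroups))
  cls[pass & n_pass == 1] <- "exclusive"
  cls[pass & n_pass > 1] <- "shared"
  out <- data.frame(
    gene_id = rep(genes, times = length(subgroups)),
    subgroup = rep(subgroups, each = length(genes)),
    class = as.vector(cls),
    direction = direction,
    corroborated = as.vector(corr),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "direction") <- direction
  attr(out, "multi_controls") <- multi
  attr(out, "single_controls") <- single
  class(out) <- c("ExclusivityCall", "data.frame")
  out
}

#' Genes called exclusive for one subgroup
#'
#' @param calls An `ExclusivityCall` from [stepwise_exclusive()].
#' @param subgroup Subgroup label.
#' @return Character vector of gene ids.
#' @export
exclusive_genes <- function(calls, subgroup) {
  stopifnot(inherits(calls, "ExclusivityCall"))
  calls$gene_id[calls$subgroup == subgroup & calls$class == "exclusive"]
}

#' Top differentially expressed genes for one comparison
#'
#' Filters a t-test comparison to genes significant in the requested
#' direction and ranks them by absolute fold change (descending, ties by
#' gene id). Down-regulated genes are rendered with the signed-fold
#' convention: a ratio r < 1 is reported as `-1/r`, so a 4-fold
#' under-expression prints as -4.
#'
#' @param result A `DEComparisonResult` of type `"test"`.
#' @param n Number of genes to return (default all). If fewer are
#'   available, all are returned and a note is attached.
#' @param direction `"up"` (default) or `"down"`.
#'
#' @return Data frame with columns `gene_id`, `fch` (signed fold),
#'   `fold_change`, `t`, `p`, ranked by `|fch|` descending.
#' @export
top_table <- function(result, n = Inf, direction = c("up", "down")) {
  stopifnot(inherits(result, "DEComparisonResult"))
  if (!identical(attr(result, "type"), "test"))
    stop("top_table requires a t-test comparison")
  direction <- match.arg(direction)
  hits <- result[result$direction == direction, , drop = FALSE]
  signed <- if (direction == "up") hits$fold_change else -1 / hits$fold_change
  ord <- order(-abs(signed), hits$gene_id)
  hits <- hits[ord, , drop = FALSE]
  signed <- signed[ord]
  out <- data.frame(gene_id = hits$gene_id, fch = signed,
                    fold_change = hits$fold_change, t = hits$t, p = hits$p,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (is.finite(n) && n < nrow(out)) {
    out <- out[seq_len(n), , drop = FALSE]
  } else if (is.finite(n) && n > nrow(out)) {
    attr(out, "note") <- sprintf("requested %d genes, only %d available",
                                 n, nrow(out))
  }
  out
}

#' Write DIA comparison tables and exclusivity calls as TSV
#'
#' @param results List of `DEComparisonResult` objects.
#' @param calls An `ExclusivityCall`.
#' @param dir Output directory.
#' @return Character vector of paths, invisibly.
#' @export
write_dia <- function(results, calls, dir) {
  paths <- character(0)
  for (key in names(results)) {
    fn <- file.path(dir, paste0("de_", gsub("[^A-Za-z0-9]+", "_", key), ".tsv"))
    utils::write.table(as.data.frame(results[[key]]), fn, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, fn)
  }
  fn <- file.path(dir, "exclusivity_calls.tsv")
  utils::write.table(as.data.frame(calls), fn, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, fn))
}
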