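# Shared fixture builders. Everything is generated in code; no files.

# A small hand-built cohort: 2 tumor subgroups, 2 multi-sample controls,
# optionally one single-sample control. Values are log2.
tiny_cohort <- function(n_genes = 30, seed = 42, with_single_control = TRUE) {
  set.seed(seed)
  groups <- list(S1 = 4, S2 = 4, C1 = 3, C2 = 3)
  if (with_single_control) groups$C3 <- 1
  ids <- unlist(mapply(function(g, n) sprintf("%s_%d", g, seq_len(n)),
                       names(groups), groups, SIMPLIFY = FALSE))
  md <- data.frame(
    sample_id = ids,
    group = rep(names(groups), unlist(groups)),
    kind = rep(ifelse(startsWith(names(groups), "S"), "tumor", "control"),
               unlist(groups)),
    stage_index = rep(c(S1 = NA, S2 = NA, C1 = 1, C2 = 2, C3 = 3)[names(groups)],
                      unlist(groups)),
    stringsAsFactors = FALSE)
  v <- matrix(stats::rnorm(n_genes * length(ids), 8, 0.5),
              n_genes, length(ids),
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), ids))
  expression_matrix(v, md)
}

# Small simulated cohort at study-design sizes with a reduced gene count.
small_sim <- function(seed = 1, ...) {
  simulate_cohort(cohort_design(), simulation_params(seed = seed, ...))
}

# Stage of each default control group.
control_stages <- c(NSC = 1, NPC = 2, NFGM = 3, NFB = 4)

# Readable map string as emitted by score_alignment_orders().
map_string <- function(map) {
  paste(sprintf("%s=%d", names(map), as.integer(map)), collapse = ",")
}

# Adjusted Rand index between two labelings, restricted to shared names.
ari_of <- function(a, b) {
  shared <- intersect(names(a), names(b))
  mclust::adjustedRandIndex(a[shared], b[shared])
}

# Fabricate a t-test style DEComparisonResult from direction calls.
fake_test_result <- function(genes, directions, subgroup, control, alpha = 0.05) {
  stopifnot(length(genes) == length(directions))
  p <- ifelse(directions == "ns", 0.5, alpha / 2)
  out <- data.frame(gene_id = genes, mean_a = 0, mean_b = 0, t = 0,
                    df = 4, p = p, fold_change = 1, direction = directions,
                    stringsAsFactors = FALSE)
  attr(out, "subgroup") <- subgroup
  attr(out, "control") <- control
  attr(out, "alpha") <- alpha
  attr(out, "control_n") <- 3L
  attr(out, "type") <- "test"
  class(out) <- c("DEComparisonResult", "data.frame")
  out
}

# Fabricate a membership-style result for an n = 1 control.
fake_membership_result <- function(genes, membership, directions,
                                   subgroup, control) {
  out <- data.frame(gene_id = genes, mean_s = 0, sd_s = 1, ref_value = 0,
                    sigma_fold = 0, membership = membership,
                    fold_change = 1, direction = directions,
                    stringsAsFactors = FALSE)
  attr(out, "subgroup") <- subgroup
  attr(out, "control") <- control
  attr(out, "k") <- 2
  attr(out, "control_n") <- 1L
  attr(out, "type") <- "membership"
  class(out) <- c("DEComparisonResult", "data.frame")
  out
}

# Assemble a comparison list with the attributes stepwise_exclusive() uses.
fake_comparisons <- function(results, subgroups, controls) {
  names(results) <- vapply(results, function(r)
    paste(attr(r, "subgroup"), "vs", attr(r, "control")), "")
  attr(results, "subgroups") <- subgroups
  attr(results, "controls") <- controls
  results
}
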