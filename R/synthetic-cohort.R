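#' Cohort design for simulation
#'
#' Describes the group structure of a simulated cohort: ordered control
#' groups mapped onto developmental stages 1..K, and tumor subgroups each
#' carrying a true (planted) stage. Defaults reproduce the study-scale
#' design: four control groups NSC (n=3), NPC (n=3), NFGM (n=2),
#' NFB (n=1) at stages 1..4, and four tumor subgroups WNT (n=8),
#' SHH (n=21), Group 3 (n=22), Group 4 (n=14) planted at stages 1..4.
#'
#' @param controls Data frame with columns `label`, `n`, `stage_index`.
#'   Stage indices must be distinct and cover 1..K.
#' @param tumors Data frame with columns `label`, `n`, `true_stage_index`
#'   (each in 1..K).
#' @param n_genes Number of genes in the simulated matrix.
#'
#' @return A `CohortDesign` object.
#' @export
cohort_design <- function(controls = default_controls(),
                          tumors = default_tumors(),
                          n_genes = 1200) {
  controls <- as.data.frame(controls, stringsAsFactors = FALSE)
  tumors <- as.data.frame(tumors, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "n", "stage_index") %in% names(controls)),
            all(c("label", "n", "true_stage_index") %in% names(tumors)))
  k <- nrow(controls)
  if (!setequal(controls$stage_index, seq_len(k)))
    stop("control stage indices must be distinct and cover 1..", k)
  if (any(controls$n < 1) || any(tumors$n < 1))
    stop("all group sizes must be >= 1")
  if (!all(tumors$true_stage_index %in% seq_len(k)))
    stop("tumor true_stage_index values must lie in 1..", k)
  if (anyDuplicated(c(controls$label, tumors$label)))
    stop("group labels must be unique")
  if (n_genes < 1) stop("n_genes must be positive")
  structure(list(controls = controls, tumors = tumors,
                 n_genes = as.integer(n_genes), n_stages = k),
            class = "CohortDesign")
}

#' @rdname cohort_design
#' @export
default_controls <- function() {
  data.frame(label = c("NSC", "NPC", "NFGM", "NFB"),
             n = c(3L, 3L, 2L, 1L),
             stage_index = 1:4,
             stringsAsFactors = FALSE)
}

#' @rdname cohort_design
#' @export
default_tumors <- function() {
  data.frame(label = c("WNT", "SHH", "Group 3", "Group 4"),
             n = c(8L, 21L, 22L, 14L),
             true_stage_index = 1:4,
             stringsAsFactors = FALSE)
}

#' Simulation parameters
#'
#' Parameters of the generative model used by [simulate_cohort()]. All
#' expression quantities are in log2 units; the 200-unit detection rule
#' applies on the linear scale (`2^x`).
#'
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baselines are drawn
#'   from N(mean, sd). Defaults 8 and 1 put typical linear intensities
#'   around 256, comfortably above the 200-unit detection limit.
#' @param noise_sd Per-observation log2 noise (default 0.5).
#' @param n_gradient_modules,genes_per_module Number and size of planted
#'   co-expression modules whose expected expression is linear in stage.
#' @param gradient_slope Log2 units per stage step (default 1.5).
#' @param n_exclusive_markers_per_subgroup,marker_effect Number of planted
#'   subgroup-exclusive markers and their over-expression in log2 units
#'   (default 2, i.e. 4-fold).
#' @param module_loading_sd Spread of per-gene loadings around 1 within a
#'   module (default 0.2).
#' @param module_activity_sd Per-sample latent wobble of each module's
#'   activity around its stage trend (default 1). This is what makes the
#'   planted modules mutually distinguishable; set to 0 for the noise-free
#'   limit in which module genes are exactly affine in stage.
#' @param fraction_below_detection Fraction of non-module, non-marker genes
#'   whose expected linear intensity is below 200 in every sample.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#'
#' @return A `SimulationParams` object.
#' @export
simulation_params <- function(baseline_log2_mean = 8,
                              baseline_log2_sd = 1,
                              noise_sd = 0.5,
                              n_gradient_modules = 5,
                              genes_per_module = 40,
                              gradient_slope = 1.5,
                              n_exclusive_markers_per_subgroup = 25,
                              marker_effect = 2,
                              module_loading_sd = 0.2,
                              module_activity_sd = 1,
                              fraction_below_detection = 0.1,
                              seed = 1L) {
  if (baseline_log2_sd <= 0) stop("baseline_log2_sd must be > 0")
  if (noise_sd < 0 || module_loading_sd < 0 || module_activity_sd < 0)
    stop("noise and loading/activity sds must be >= 0")
  if (marker_effect <= 0) stop("marker_effect must be > 0")
  if (fraction_below_detection < 0 || fraction_below_detection >= 1)
    stop("fraction_below_detection must lie in [0, 1)")
  structure(list(baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 noise_sd = noise_sd,
                 n_gradient_modules = as.integer(n_gradient_modules),
                 genes_per_module = as.integer(genes_per_module),
                 gradient_slope = gradient_slope,
                 n_exclusive_markers_per_subgroup = as.integer(n_exclusive_markers_per_subgroup),
                 marker_effect = marker_effect,
                 module_loading_sd = module_loading_sd,
                 module_activity_sd = module_activity_sd,
                 fraction_below_detection = fraction_below_detection,
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

#' Simulate a synthetic expression cohort with planted ground truth
#'
#' Draws a genes x samples log2 intensity matrix under a generative model
#' with three planted structures: (i) gradient co-expression modules whose
#' expected log2 intensity is `baseline + gradient_slope * stage` of the
#' sample's group (controls use their `stage_index`, tumors their
#' `true_stage_index`); (ii) subgroup-exclusive markers over-expressed by
#' `marker_effect` log2 units only in their subgroup's samples; and
#' (iii) a fraction of background genes whose expected linear intensity is
#' below the 200-unit detection limit in every sample. Everything else is
#' i.i.d. baseline plus noise.
#'
#' @param design A [cohort_design()].
#' @param params A [simulation_params()].
#'
#' @return A list with elements `matrix` (an [expression_matrix()], log2
#'   scale) and `truth` (a `PlantedTruth` list: `module_membership`,
#'   `marker_sets`, `stage_map`, `below_detection`, `effects`).
#' @export
simulate_cohort <- function(design = cohort_design(),
                            params = simulation_params()) {
  stopifnot(inherits(design, "CohortDesign"), inherits(params, "SimulationParams"))
  n_genes <- design$n_genes
  n_module_genes <- params$n_gradient_modules * params$genes_per_module
  n_marker_genes <- nrow(design$tumors) * params$n_exclusive_markers_per_subgroup
  if (n_module_genes + n_marker_genes > n_genes)
    stop(sprintf(
      "gene budget exceeded: %d module + %d marker genes > n_genes = %d",
      n_module_genes, n_marker_genes, n_genes))

  set.seed(params$seed)

  # --- samples --------------------------------------------------------
  mk_ids <- function(label, n) sprintf("%s_%02d", gsub(" ", "", label), seq_len(n))
  ctrl <- design$controls
  tum <- design$tumors
  meta <- rbind(
    do.call(rbind, lapply(seq_len(nrow(ctrl)), function(i) {
      data.frame(sample_id = mk_ids(ctrl$label[i], ctrl$n[i]),
                 group = ctrl$label[i], kind = "control",
                 stage_index = ctrl$stage_index[i], stringsAsFactors = FALSE)
    })),
    if (nrow(tum)) do.call(rbind, lapply(seq_len(nrow(tum)), function(i) {
      data.frame(sample_id = mk_ids(tum$label[i], tum$n[i]),
                 group = tum$label[i], kind = "tumor",
                 stage_index = NA_integer_, stringsAsFactors = FALSE)
    }))
  )
  n_samples <- nrow(meta)
  # stage driving each sample's expected expression
  stage_map <- stats::setNames(tum$true_stage_index, tum$label)
  sample_stage <- ifelse(meta$kind == "control", meta$stage_index,
                         stage_map[meta$group])

  # --- gene roles -----------------------------------------------------
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  module_idx <- seq_len(n_module_genes)
  marker_idx <- if (n_marker_genes) n_module_genes + seq_len(n_marker_genes) else integer(0)
  background_idx <- setdiff(seq_len(n_genes), c(module_idx, marker_idx))
  n_bd <- round(params$fraction_below_detection * length(background_idx))
  below_idx <- background_idx[seq_len(n_bd)]

  module_membership <- rep(NA_integer_, n_genes)
  module_membership[module_idx] <- rep(seq_len(params$n_gradient_modules),
                                       each = params$genes_per_module)
  marker_sets <- list()
  if (n_marker_genes) {
    owner <- rep(tum$label, each = params$n_exclusive_markers_per_subgroup)
    marker_sets <- split(gene_ids[marker_idx], factor(owner, levels = tum$label))
  }

  # --- draws (fixed order for reproducibility) ------------------------
  baseline <- stats::rnorm(n_genes, params$baseline_log2_mean, params$baseline_log2_sd)
  # below-detection genes: expected linear intensity < 200 everywhere
  baseline[below_idx] <- stats::runif(n_bd, log2(50), log2(180))
  loadings <- rep(1, n_genes)
  if (n_module_genes)
    loadings[module_idx] <- stats::rnorm(n_module_genes, 1, params$module_loading_sd)
  # per-module, per-sample latent activity around the stage trend
  activity <- matrix(0, params$n_gradient_modules, n_samples)
  if (params$n_gradient_modules > 0)
    activity[] <- stats::rnorm(length(activity), 0, params$module_activity_sd)
  noise <- matrix(stats::rnorm(n_genes * n_samples, 0, params$noise_sd),
                  n_genes, n_samples)

  # --- assemble -------------------------------------------------------
  x <- matrix(baseline, n_genes, n_samples) + noise
  if (n_module_genes) {
    z <- params$gradient_slope * matrix(sample_stage, params$n_gradient_modules,
                                        n_samples, byrow = TRUE) + activity
    x[module_idx, ] <- x[module_idx, ] +
      loadings[module_idx] * z[module_membership[module_idx], , drop = FALSE]
  }
  if (n_marker_genes) {
    for (s in tum$label) {
      in_s <- meta$group == s
      rows <- match(marker_sets[[s]], gene_ids)
      x[rows, in_s] <- x[rows, in_s] + params$marker_effect
    }
  }
  dimnames(x) <- list(gene_ids, meta$sample_id)

  truth <- structure(list(
    module_membership = stats::setNames(module_membership, gene_ids),
    marker_sets = lapply(marker_sets, as.character),
    stage_map = stage_map,
    below_detection = gene_ids[below_idx],
    effects = list(gradient_slope = params$gradient_slope,
                   marker_effect = params$marker_effect)
  ), class = "PlantedTruth")

  list(matrix = expression_matrix(x, meta, scale = "log2"), truth = truth)
}

#' Write a simulated cohort to plain-text fixture files
#'
#' Emits the expression matrix, sample metadata and planted-truth tables
#' as tab-delimited text that round-trips losslessly through
#' [read_expression()] (values are serialized with 17 significant digits).
#'
#' @param matrix An [expression_matrix()].
#' @param truth A `PlantedTruth` object from [simulate_cohort()], or
#'   `NULL` to write only expression and metadata.
#' @param directory Output directory (created if needed).
#'
#' @return Named character vector of the file paths written.
#' @export
write_fixture <- function(matrix, truth = NULL, directory) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  paths <- c(expression = file.path(directory, "expression.tsv"),
             metadata = file.path(directory, "metadata.tsv"))
  write_expression_tsv(matrix$values, paths[["expression"]])
  utils::write.table(matrix$metadata, paths[["metadata"]],
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "PlantedTruth"))
    mm <- truth$module_membership
    modules <- data.frame(gene_id = names(mm)[!is.na(mm)],
                          module = mm[!is.na(mm)], stringsAsFactors = FALSE)
    markers <- data.frame(
      gene_id = unlist(truth$marker_sets, use.names = FALSE),
      subgroup = rep(names(truth$marker_sets),
                     lengths(truth$marker_sets)),
      stringsAsFactors = FALSE)
    stages <- data.frame(group = names(truth$stage_map),
                         stage_index = as.integer(truth$stage_map),
                         stringsAsFactors = FALSE)
    paths <- c(paths,
               truth_modules = file.path(directory, "truth_modules.tsv"),
               truth_markers = file.path(directory, "truth_markers.tsv"),
               truth_stage_map = file.path(directory, "truth_stage_map.tsv"))
    utils::write.table(modules, paths[["truth_modules"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(markers, paths[["truth_markers"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(stages, paths[["truth_stage_map"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  paths
}

# internal: full-precision TSV writer (first column gene id)
write_expression_tsv <- function(values, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(values)), collapse = "\t"), con)
  body <- matrix(sprintf("%.17g", values), nrow(values), ncol(values))
  writeLines(paste(rownames(values),
                   apply(body, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}
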