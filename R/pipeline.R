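pipeline_defaults <- function() {
  list(
    simulate = TRUE,
    expression_path = NULL,
    metadata_path = NULL,
    scale = "log2",
    seed = 1L,
    out_dir = "devalign_out",
    quantile_normalize = TRUE,
    detection_threshold = 200,
    variance_quantile = 0.75,
    suffix_list = "_x_at",
    alpha = 0.05,
    k_sigma = 2,
    t_variant = "student",
    direction = "up",
    components = c(1, 2, 4),
    n_components_classify = 4,
    panel_path = NULL,
    gmt_path = NULL,
    powers = 1:10,
    soft_power = NULL,
    scale_free_r2_target = 0.85,
    network_type = "unsigned",
    min_module_size = 20,
    module_cut_height = 0.7,
    family_cut_height = 0.5,
    trait_encoding = "stage_rank",
    top_n = 10
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config file (or takes an in-memory list), rejects unknown
#' keys, fills defaults, and range-checks every parameter. An empty file
#' yields the full default configuration. The effective values are
#' echoed in the run log by [run_pipeline()]; there are no hidden
#' defaults.
#'
#' @param path Path to a YAML config file, or `NULL`.
#' @param config Named list of settings overriding the file (and the
#'   defaults).
#' @return A validated `PipelineConfig` list.
#' @export
validate_config <- function(path = NULL, config = list()) {
  file_cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_cfg <- yaml::read_yaml(path)
    if (is.null(file_cfg)) file_cfg <- list()
  }
  defaults <- pipeline_defaults()
  merged <- defaults
  for (src in list(file_cfg, config)) {
    unknown <- setdiff(names(src), names(defaults))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    merged[names(src)] <- src
  }
  cfg <- merged
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cfg$k_sigma <= 0) stop("k_sigma must be positive")
  if (cfg$detection_threshold < 0) stop("detection_threshold must be non-negative")
  if (cfg$variance_quantile < 0 || cfg$variance_quantile >= 1)
    stop("variance_quantile must lie in [0, 1)")
  if (!cfg$t_variant %in% c("student", "welch")) stop("t_variant must be student or welch")
  if (!cfg$direction %in% c("up", "down")) stop("direction must be up or down")
  if (!cfg$network_type %in% c("unsigned", "signed"))
    stop("network_type must be unsigned or signed")
  if (!cfg$trait_encoding %in% c("stage_rank", "control_mean"))
    stop("trait_encoding must be stage_rank or control_mean")
  if (cfg$scale_free_r2_target <= 0 || cfg$scale_free_r2_target > 1)
    stop("scale_free_r2_target must lie in (0, 1]")
  if (cfg$module_cut_height <= 0 || cfg$module_cut_height > 1)
    stop("module_cut_height must lie in (0, 1]")
  if (any(cfg$powers < 1)) stop("powers must be >= 1")
  if (any(cfg$components < 1)) stop("components must be positive indices")
  cfg$seed <- as.integer(cfg$seed)
  if (!isTRUE(cfg$simulate)) {
    if (is.null(cfg$expression_path) || is.null(cfg$metadata_path))
      stop("expression_path and metadata_path are required when simulate is false")
    for (p in c(cfg$expression_path, cfg$metadata_path))
      if (!file.exists(p)) stop("input file not found: ", p)
  }
  if (!is.null(cfg$panel_path) && !file.exists(cfg$panel_path))
    stop("panel file not found: ", cfg$panel_path)
  if (!is.null(cfg$gmt_path) && !file.exists(cfg$gmt_path))
    stop("GMT file not found: ", cfg$gmt_path)
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

# internal: stable hash of the effective configuration. The output
# location is not an analysis parameter, so it is excluded: runs of the
# same configuration into different directories produce identical bytes.
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full developmental-alignment pipeline
#'
#' Executes, in order: data loading (or synthetic-cohort simulation),
#' quantile normalization, the detection-limit filter, subgroup
#' classification (when a panel and reference are available), PCA with
#' group centroids and nearest-control ranking, the developmental
#' intersect analysis, the co-expression network with alignment-order
#' scoring, and (when a GMT file is configured) over-representation of
#' the exclusivity sets. Every output is tab-delimited text (or Newick)
#' under `out_dir`, each carrying the configuration hash; the run is
#' fully determined by the configuration and seed. A stage failure
#' writes a `FAILED` marker naming the stage and re-raises the error;
#' outputs of completed stages are retained.
#'
#' @param config A `PipelineConfig` from [validate_config()] (or a named
#'   list, which will be validated).
#' @return Invisibly, a list with the main in-memory results
#'   (`matrix`, `truth`, `ordination`, `centroids`, `exclusivity`,
#'   `modules`, `eigengenes`, `alignment`, `summary`, `paths`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "PipelineConfig")) config else
    validate_config(config = config)
  hash <- config_hash(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  echo_cfg <- unclass(cfg)
  echo_cfg$out_dir <- NULL
  log_lines <- c("devalign run log",
                 paste0("package_version: ", as.character(utils::packageVersion("devalign"))),
                 paste0("config_hash: ", hash),
                 "effective_config:",
                 paste0("  ", strsplit(yaml::as.yaml(echo_cfg), "\n")[[1]]))
  stage <- "setup"
  fail <- function(e) {
    writeLines(c(paste0("FAILED at stage: ", stage),
                 paste0("error: ", conditionMessage(e))),
               file.path(cfg$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    con <- file(path, "wt")
    writeLines(paste0("# config_hash: ", hash), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }
  emit_newick <- function(txt, name) {
    path <- file.path(cfg$out_dir, name)
    writeLines(c(paste0("[config_hash=", hash, "]"), txt), path)
    path
  }
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  paths <- character(0)
  res <- list(config = cfg, hash = hash)

  tryCatch({
    set.seed(cfg$seed)

    stage <- "load"
    if (isTRUE(cfg$simulate)) {
      sim <- simulate_cohort(cohort_design(),
                             simulation_params(seed = cfg$seed))
      mat <- sim$matrix
      res$truth <- sim$truth
      note("simulated default cohort: %d genes x %d samples (seed %d)",
           nrow(mat$values), ncol(mat$values), cfg$seed)
    } else {
      mat <- read_expression(cfg$expression_path, cfg$metadata_path,
                             scale = cfg$scale)
      note("read %d genes x %d samples from %s", nrow(mat$values),
           ncol(mat$values), cfg$expression_path)
    }
    if (!length(group_labels(mat, "tumor")))
      stop("cohort contains no tumor subgroups; nothing to classify or align")

    stage <- "normalize"
    if (isTRUE(cfg$quantile_normalize)) {
      mat <- quantile_normalize(mat)
      note("quantile normalization applied")
    } else note("quantile normalization skipped by config")

    stage <- "detection_filter"
    det <- detection_filter(mat, cfg$detection_threshold)
    mat <- det$matrix
    paths <- c(paths, emit(data.frame(gene_id = names(det$report$flags),
                                      flag = det$report$flags),
                           "filter_report.tsv"))
    note("detection filter: %d of %d genes retained (threshold %g linear units)",
         det$report$n_retained, det$report$n_input, cfg$detection_threshold)

    stage <- "classify"
    panel <- NULL
    if (!is.null(cfg$panel_path)) {
      panel <- read_panel(cfg$panel_path)
    } else if (isTRUE(cfg$simulate)) {
      panel <- unlist(res$truth$marker_sets, use.names = FALSE)
      note("no panel configured; using planted marker genes as the panel")
    }
    if (!is.null(panel)) {
      tumor_ids <- mat$metadata$sample_id[mat$metadata$kind == "tumor"]
      ref <- em_subset(mat, samples = tumor_ids)
      assign <- withCallingHandlers(
        classify_by_reference(ref, ref, panel, cfg$n_components_classify),
        warning = function(w) {
          note("classification warning: %s", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      res$assignment <- assign
      acc <- mean(assign$label ==
                    mat$metadata$group[match(assign$sample_id,
                                             mat$metadata$sample_id)])
      note("classification (self-reference) agreement with labels: %.3f", acc)
      paths <- c(paths, emit(as.data.frame(assign), "subgroup_assignments.tsv"))
    } else note("classification skipped: no panel available")

    stage <- "ordination"
    ord <- pca_ordination(mat)
    cents <- group_centroids(ord, cfg$components)
    res$ordination <- ord
    res$centroids <- cents
    paths <- c(paths,
               emit(data.frame(sample_id = rownames(ord$scores),
                               ord$scores, check.names = FALSE),
                    "pca_scores.tsv"),
               emit(data.frame(component = seq_along(ord$variance_fraction),
                               variance_fraction = ord$variance_fraction),
                    "pca_variance.tsv"),
               emit(data.frame(group = rownames(cents$centroids),
                               cents$centroids, check.names = FALSE),
                    "centroids.tsv"),
               emit(data.frame(group = rownames(cents$distances),
                               cents$distances, check.names = FALSE),
                    "centroid_distances.tsv"))
    hc <- hierarchical_cluster(mat)
    paths <- c(paths, emit_newick(dendrogram_newick(hc), "sample_dendrogram.nwk"))
    nearest <- vapply(cents$control_ranking, `[`, "", 1)
    for (s in names(nearest))
      note("nearest control to %s (PC %s): %s", s,
           paste(cfg$components, collapse = ","), nearest[s])

    stage <- "intersect_de"
    comparisons <- dia_comparisons(mat, alpha = cfg$alpha, k = cfg$k_sigma,
                                   variant = cfg$t_variant)
    calls <- stepwise_exclusive(comparisons, direction = cfg$direction)
    res$exclusivity <- calls
    for (key in names(comparisons))
      paths <- c(paths, emit(as.data.frame(comparisons[[key]]),
                             paste0("de_", gsub("[^A-Za-z0-9]+", "_", key),
                                    ".tsv")))
    paths <- c(paths, emit(as.data.frame(calls), "exclusivity_calls.tsv"))
    excl_sizes <- vapply(attr(comparisons, "subgroups"),
                         function(s) length(exclusive_genes(calls, s)), 0L)
    for (s in names(excl_sizes))
      note("exclusive (%s) genes for %s: %d", cfg$direction, s, excl_sizes[s])
    tops <- list()
    for (key in names(comparisons)) {
      if (identical(attr(comparisons[[key]], "type"), "test")) {
        tops[[key]] <- top_table(comparisons[[key]], n = cfg$top_n,
                                 direction = cfg$direction)
        paths <- c(paths, emit(tops[[key]],
                               paste0("top_", gsub("[^A-Za-z0-9]+", "_", key),
                                      ".tsv")))
      }
    }
    res$top_tables <- tops

    stage <- "network"
    pre <- network_prefilter(mat, suffix = cfg$suffix_list,
                             variance_quantile = cfg$variance_quantile)
    note("network prefilter: %d genes retained", pre$report$n_retained)
    net_mat <- pre$matrix
    sp <- suppressWarnings(
      select_soft_power(net_mat, powers = cfg$powers,
                        r2_target = cfg$scale_free_r2_target,
                        type = cfg$network_type))
    paths <- c(paths, emit(sp$fit_table, "scale_free_fit.tsv"))
    power <- if (!is.null(cfg$soft_power)) {
      note("soft power fixed by config: %d", cfg$soft_power)
      cfg$soft_power
    } else if (!any(!is.na(sp$fit_table$r_squared) &
                    sp$fit_table$r_squared >= cfg$scale_free_r2_target)) {
      # no candidate reaches the scale-free target: fall back to the
      # conventional default for the network type rather than the argmax,
      # which is unstable when the fit is uniformly poor
      fallback <- if (cfg$network_type == "unsigned") 6L else 12L
      note("scale-free fit below target for every power; using conventional power %d",
           fallback)
      fallback
    } else {
      note("soft power selected by scale-free fit: %d", sp$power)
      sp$power
    }
    modules <- detect_modules(net_mat, power,
                              min_module_size = cfg$min_module_size,
                              cut_height = cfg$module_cut_height,
                              type = cfg$network_type)
    res$modules <- modules
    paths <- c(paths, emit(data.frame(gene_id = names(modules$labels),
                                      module = modules$labels),
                           "module_assignments.tsv"))
    note("modules detected: %d (unassigned genes: %d)",
         length(modules$sizes), sum(modules$labels == 0))
    if (length(modules$sizes) >= 1) {
      eg <- module_eigengenes(net_mat, modules)
      res$eigengenes <- eg
      paths <- c(paths, emit(data.frame(module = rownames(eg),
                                        unclass(eg), check.names = FALSE),
                             "eigengenes.tsv"))
      if (nrow(eg) >= 2) {
        fam <- cluster_families(eg, cfg$family_cut_height)
        res$families <- fam
        paths <- c(paths,
                   emit(data.frame(module = names(fam$families),
                                   family = fam$families),
                        "cluster_families.tsv"),
                   emit_newick(fam$newick, "family_dendrogram.nwk"))
      }
      ta <- trait_association(eg, subgroup_trait_matrix(net_mat))
      res$trait_association <- ta
      paths <- c(paths,
                 emit(data.frame(module = rownames(ta$r), ta$r,
                                 check.names = FALSE), "trait_r.tsv"),
                 emit(data.frame(module = rownames(ta$p), ta$p,
                                 check.names = FALSE), "trait_p.tsv"))
      stage <- "alignment"
      align <- score_alignment_orders(eg, net_mat,
                                      encoding = cfg$trait_encoding)
      res$alignment <- align
      paths <- c(paths, emit(align, "alignment_orders.tsv"))
      note("best alignment order: %s (score %.4f, module %s)",
           align$map[1], align$score[1], align$best_module[1])
    } else note("alignment skipped: no module detected")

    stage <- "enrichment"
    if (!is.null(cfg$gmt_path)) {
      sets <- read_gmt(cfg$gmt_path)
      universe <- rownames(mat$values)
      collection <- gene_set_collection(sets, universe)
      for (s in attr(comparisons, "subgroups")) {
        genes <- exclusive_genes(calls, s)
        if (length(intersect(genes, universe))) {
          enr <- overrepresentation(genes, collection)
          paths <- c(paths, emit(enr, paste0("enrichment_",
                                             gsub("[^A-Za-z0-9]+", "_", s),
                                             ".tsv")))
        } else note("enrichment skipped for %s: no exclusive gene in universe", s)
      }
    } else note("enrichment stage skipped: no GMT configured")

    stage <- "summary"
    summary_df <- data.frame(
      key = c(paste0("nearest_control.", names(nearest)),
              paste0("n_exclusive.", names(excl_sizes)),
              "n_modules", "soft_power", "best_alignment",
              "best_alignment_score"),
      value = c(unname(nearest), as.character(unname(excl_sizes)),
                as.character(length(modules$sizes)), as.character(power),
                if (!is.null(res$alignment)) res$alignment$map[1] else NA,
                if (!is.null(res$alignment))
                  format(res$alignment$score[1], digits = 15) else NA),
      stringsAsFactors = FALSE)
    res$summary <- summary_df
    paths <- c(paths, emit(summary_df, "summary.tsv"))
    writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
    paths <- c(paths, file.path(cfg$out_dir, "run_log.txt"))
    res$paths <- paths
  }, error = fail)

  invisible(res)
}
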