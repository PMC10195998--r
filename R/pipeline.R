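## Pipeline orchestration: simulate (or load) -> temporal DE -> TF targets ->
## networks -> enrichment -> knockdown ranking, from a single config, with a
## JSON run manifest recording parameters, seed and output checksums.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    simulate = list(),
    inputs = NULL,
    de = list(fpkm_min = 1, fc_cutoff = 2, min_timepoints = 2L, pseudocount = 1),
    promoter = list(upstream_bp = 2000L, downstream_bp = 500L),
    network = list(confidence_threshold = 0.9, min_component_size = 3L),
    gsea = list(n_perm = 1000L, weight_p = 1),
    kd = list(alpha = 0.05, fc_cutoff_kd = 1.3, final_day = "7d", top_k = 50L,
              use_q = FALSE, pseudocount = 1),
    tf = list(name = NULL, early_stage = "0h", late_stage = "120h")
  )
}

## merge user config over defaults; unknown keys (typos) are errors
merge_config <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) && !path %in% c("simulate", "inputs"))
    config_error("unknown config key(s)%s: %s",
                 if (nzchar(path)) paste0(" in '", path, "'") else "",
                 paste(unknown, collapse = ", "))
  out <- defaults
  for (nm in names(user)) {
    out[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
                     !nm %in% c("simulate", "inputs"))
      merge_config(user[[nm]], defaults[[nm]], nm)
    else user[[nm]]
  }
  out
}

#' Read and validate a pipeline configuration
#'
#' YAML with sections mirroring the analysis stages (`simulate` or `inputs`,
#' `de`, `promoter`, `network`, `gsea`, `kd`, `tf`) plus `seed` and
#' `outdir`. Unknown keys raise an error so that typos cannot silently fall
#' back to defaults.
#'
#' @param config a YAML file path or a list with the same structure.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) config_error("no such config file: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(config, default_pipeline_config())
  if (!is.null(cfg$inputs)) {
    paths <- unlist(cfg$inputs[setdiff(names(cfg$inputs), "peaks")])
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      config_error("input file(s) not found: %s", paste(missing, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

write_table_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header_comment(), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e),
             class = "neuroinduct_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: simulate (or load inputs),
#' expressed-gene filtering and temporal DE per series, DE unions, promoter
#' TF-target derivation with stage subtraction and DE intersection,
#' confidence-thresholded network module detection with cross-series module
#' conservation, preranked GSEA of the days-scale ranking, and the knockdown
#' effect ranking. With `outdir` set, analytic outputs are written as
#' tab-delimited/plain-text files plus a JSON manifest with per-stage
#' parameters and output checksums; reruns with the same config and seed
#' reproduce byte-identical analytic outputs.
#'
#' @param config a [pipeline_config()], a YAML path, or a list.
#' @return list of stage results: `study`, `de` (per series profiles and
#'   unions), `targets`, `network`, `enrichment`, `kd`, `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  t0 <- Sys.time()
  stages_run <- character()

  ## stage 1: data
  study <- run_stage("simulate", {
    if (!is.null(cfg$inputs)) load_study_inputs(cfg) else {
      sim_args <- cfg$simulate
      sim_args$seed <- cfg$seed
      do.call(sim_config, sim_args) |> simulate_study()
    }
  })
  stages_run <- c(stages_run, "simulate")

  ## stage 2: temporal DE per series
  dep <- do.call(de_params, cfg$de)
  de <- run_stage("temporal_de", {
    call_series <- function(m) {
      expressed <- filter_expressed(m, dep)
      call_temporal_de(log_fold_changes(expressed, dep))
    }
    profiles <- list(hours = call_series(study$series_h$matrix),
                     days = call_series(study$series_d$matrix))
    list(profiles = profiles, union = de_union(profiles))
  })
  stages_run <- c(stages_run, "temporal_de")

  ## stage 3: TF targets
  pp <- do.call(promoter_params, cfg$promoter)
  targets <- run_stage("tf_targets", {
    map <- derive_tf_targets(study$peaks, study$models, pp)
    tf_name <- cfg$tf$name
    if (is.null(tf_name)) tf_name <- names(study$peaks)[[1L]]
    gained <- stage_specific_targets(map, tf_name, cfg$tf$late_stage,
                                     cfg$tf$early_stage)
    list(map = map, tf = tf_name, stage_gained = gained,
         intersect_hours = intersect_with_de(gained, de_genes(de$profiles$hours)),
         intersect_days = intersect_with_de(gained, de_genes(de$profiles$days)))
  })
  stages_run <- c(stages_run, "tf_targets")

  ## stage 4: network modules per series + conservation
  np <- do.call(network_params, cfg$network)
  network <- run_stage("network_modules", {
    part <- lapply(de$profiles, function(p) {
      g <- build_network(study$edges, de_genes(p), np)
      if (igraph::ecount(g) == 0L) return(NULL)
      annotate_modules(detect_modules(g, seed = cfg$seed), p, study$gene_sets)
    })
    conservation <- if (!is.null(part$hours) && !is.null(part$days))
      module_conservation(part$hours, part$days) else NULL
    list(partitions = part, conservation = conservation)
  })
  stages_run <- c(stages_run, "network_modules")

  ## stage 5: enrichment (preranked GSEA of the days-scale ranking)
  enr <- run_stage("enrichment", {
    ranked <- ranked_list(de$profiles$days)
    gsea_preranked(ranked, study$gene_sets, n_perm = cfg$gsea$n_perm,
                   weight_p = cfg$gsea$weight_p, seed = cfg$seed)
  })
  stages_run <- c(stages_run, "enrichment")

  ## stage 6: knockdown contrast and effect ranking
  kdp <- do.call(kd_params, cfg$kd)
  kd <- run_stage("kd_contrast", {
    test <- kd_de_test(study$kd$control, study$kd$kd, kdp$final_day, kdp)
    ranking <- kd_effect_score(de$profiles$days, test, kdp)
    list(test = test, ranking = ranking, top = top_k_table(ranking, kdp))
  })
  stages_run <- c(stages_run, "kd_contrast")

  result <- list(study = study, de = de, targets = targets, network = network,
                 enrichment = enr, kd = kd)
  manifest <- list(stages = stages_run, seed = cfg$seed,
                   parameters = list(de = unclass(dep), promoter = unclass(pp),
                                     network = unclass(np), kd = unclass(kdp),
                                     gsea = cfg$gsea),
                   version = pkg_version_string(),
                   wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(cfg$outdir)) {
    manifest$outputs <- write_pipeline_outputs(result, cfg$outdir)
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result$manifest <- manifest
  result
}

load_study_inputs <- function(cfg) {
  ins <- cfg$inputs
  peaks <- lapply(ins$peaks, function(stages) lapply(stages, read_bed))
  list(models = read_tss(ins$tss),
       series_h = list(matrix = read_expression(ins$expression_hours)),
       series_d = list(matrix = read_expression(ins$expression_days)),
       peaks = peaks,
       edges = read_edges(ins$edges),
       kd = list(control = read_expression(ins$kd_control),
                 kd = read_expression(ins$kd_knockdown)),
       gene_sets = read_gmt(ins$gene_sets),
       truth = NULL)
}

## writes analytic outputs; returns named md5 checksums
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  add <- function(p) { paths[[basename(p)]] <<- p; invisible(p) }
  add(write_de_profile(result$de$profiles$hours, file.path(outdir, "de_hours.tsv")))
  add(write_de_profile(result$de$profiles$days, file.path(outdir, "de_days.tsv")))
  add(write_gene_list(result$de$union$combined, file.path(outdir, "de_union_combined.txt")))
  add(write_gene_list(result$targets$stage_gained,
                      file.path(outdir, "tf_stage_gained_targets.txt")))
  add(write_gene_list(result$targets$intersect_days$genes,
                      file.path(outdir, "tf_targets_de_intersect_days.txt")))
  add(write_gene_list(result$targets$intersect_hours$genes,
                      file.path(outdir, "tf_targets_de_intersect_hours.txt")))
  for (nm in names(result$network$partitions)) {
    part <- result$network$partitions[[nm]]
    if (!is.null(part))
      add(write_partition(part, file.path(outdir, sprintf("modules_%s.tsv", nm))))
  }
  if (!is.null(result$network$conservation))
    add(write_table_tsv(result$network$conservation,
                        file.path(outdir, "module_conservation.tsv")))
  add(write_table_tsv(result$enrichment, file.path(outdir, "gsea.tsv")))
  add(write_table_tsv(result$kd$test, file.path(outdir, "kd_de_test.tsv")))
  add(write_table_tsv(result$kd$ranking, file.path(outdir, "kd_ranking.tsv")))
  add(write_table_tsv(result$kd$top, file.path(outdir, "kd_top.tsv")))
  sums <- tools::md5sum(unlist(paths))
  names(sums) <- basename(names(sums))
  as.list(sums)
}
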