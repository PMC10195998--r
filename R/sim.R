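## Synthetic-data generator with known ground truth.
##
## Emulates the structure of a dual-SMAD-inhibition neural-induction study:
## FPKM time courses over an hours-scale and a days-scale series with
## planted step-trajectory DE genes, per-(TF, stage) ChIP-seq promoter peaks
## with stage-gained targets and decoys, a planted-partition interaction
## network with edge confidences, and a replicated knockdown experiment in
## which a TF's own expression and the trajectories of its targets are
## attenuated. Expression noise is log-normal (Gaussian on the log2 scale),
## matching the FPKM-scale quantity the pipeline consumes.

#' Simulation configuration
#'
#' Defaults emulate the study design: 2000 genes, hours-scale time grid
#' 0,2,4,8,18,24,30,48 h (the days-scale grid 0,1,2,3,4,6,8 d and the KD grid
#' 0,1,2,7 d are used by [simulate_study()] and [generate_kd_experiment()]),
#' 300 planted DE genes with |log2FC| in \[1.5, 3\] switching on at a random
#' onset time, log2-FPKM baselines N(3, 2), measurement noise 0.25 on the
#' log2 scale, 3 TFs with 50 stage-gained promoter targets each, a planted
#' 4-block interaction network, and a knockdown of the first TF at 90%
#' efficiency with 3 replicates.
#'
#' @param n_genes number of genes.
#' @param time_points ordered time labels (`<number>h` or `<number>d`); the
#'   first is the reference.
#' @param kd_time_points time labels of the knockdown experiment.
#' @param n_de_genes number of planted DE genes.
#' @param de_log2fc_range interval of planted |log2FC|.
#' @param de_up_fraction fraction of planted genes that go up.
#' @param baseline_log_fpkm_mean,baseline_log_fpkm_sd log2-FPKM baseline
#'   location/scale.
#' @param noise_sd log2-scale measurement noise SD.
#' @param n_tfs,targets_per_tf,tf_effect_log2fc TF-target structure: number
#'   of TFs, stage-gained targets per TF, and the planted trajectory
#'   magnitude of knockdown-affected targets.
#' @param n_modules,p_within,p_between planted-partition network: block
#'   count and within/between edge probabilities.
#' @param conf_range interval from which edge confidences are drawn.
#' @param kd_tf TF gene id to knock down (default: the first generated TF).
#' @param kd_efficiency fraction of the TF's activity removed, in \[0, 1\].
#' @param n_replicates_kd replicates per condition per time point.
#' @param min_spacing minimum TSS spacing in bp.
#' @param n_chroms number of chromosomes gene models are spread over.
#' @param decoy_peaks decoy peaks per (TF, stage), placed outside all
#'   promoter windows.
#' @param peak_width width of simulated peaks in bp.
#' @param early_stage,late_stage stage labels of the peak files.
#' @param seed integer seed; identical configs give identical outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L,
                       time_points = c("0h", "2h", "4h", "8h", "18h", "24h", "30h", "48h"),
                       kd_time_points = c("0d", "1d", "2d", "7d"),
                       n_de_genes = 300L,
                       de_log2fc_range = c(1.5, 3),
                       de_up_fraction = 0.5,
                       baseline_log_fpkm_mean = 3,
                       baseline_log_fpkm_sd = 2,
                       noise_sd = 0.25,
                       n_tfs = 3L,
                       targets_per_tf = 50L,
                       tf_effect_log2fc = 2,
                       n_modules = 4L,
                       p_within = 0.3,
                       p_between = 0.01,
                       conf_range = c(0.9, 1),
                       kd_tf = NULL,
                       kd_efficiency = 0.9,
                       n_replicates_kd = 3L,
                       min_spacing = 10000L,
                       n_chroms = 5L,
                       decoy_peaks = 500L,
                       peak_width = 200L,
                       early_stage = "0h",
                       late_stage = "120h",
                       seed = 1L) {
  if (!is_count(n_genes)) config_error("n_genes must be a positive count")
  ## unspecified structural counts scale down with small gene universes so
  ## that minimal configurations remain valid
  if (missing(n_de_genes)) n_de_genes <- min(300L, floor(0.15 * n_genes))
  if (missing(n_tfs)) n_tfs <- min(3L, n_genes)
  if (missing(targets_per_tf))
    targets_per_tf <- min(50L, n_genes %/% max(2L * n_tfs, 1L))
  if (!is_count(n_de_genes, 0L) || n_de_genes > n_genes)
    config_error("n_de_genes must satisfy 0 <= n_de_genes <= n_genes")
  if (!is_prob(p_within) || !is_prob(p_between) || p_between >= p_within)
    config_error("need 0 <= p_between < p_within <= 1")
  if (n_tfs * targets_per_tf > n_genes)
    config_error("targets_per_tf * n_tfs must not exceed n_genes")
  if (!is_prob(kd_efficiency)) config_error("kd_efficiency must lie in [0,1]")
  if (!(is.numeric(noise_sd) && noise_sd >= 0)) config_error("noise_sd must be >= 0")
  if (length(de_log2fc_range) != 2L || de_log2fc_range[1] > de_log2fc_range[2] ||
      any(de_log2fc_range <= 0))
    config_error("de_log2fc_range must be a positive interval [lo, hi]")
  structure(list(n_genes = as.integer(n_genes), time_points = time_points,
                 kd_time_points = kd_time_points,
                 n_de_genes = as.integer(n_de_genes),
                 de_log2fc_range = de_log2fc_range,
                 de_up_fraction = de_up_fraction,
                 baseline_log_fpkm_mean = baseline_log_fpkm_mean,
                 baseline_log_fpkm_sd = baseline_log_fpkm_sd,
                 noise_sd = noise_sd, n_tfs = as.integer(n_tfs),
                 targets_per_tf = as.integer(targets_per_tf),
                 tf_effect_log2fc = tf_effect_log2fc,
                 n_modules = as.integer(n_modules), p_within = p_within,
                 p_between = p_between, conf_range = conf_range,
                 kd_tf = kd_tf, kd_efficiency = kd_efficiency,
                 n_replicates_kd = as.integer(n_replicates_kd),
                 min_spacing = as.integer(min_spacing),
                 n_chroms = as.integer(n_chroms),
                 decoy_peaks = as.integer(decoy_peaks),
                 peak_width = as.integer(peak_width),
                 early_stage = early_stage, late_stage = late_stage,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("G%05d", seq_len(n))

## Baseline floors for planted genes. A planted DE gene must (a) survive the
## FPKM > 1 expressed-gene filter and (b) still clear |log2FC| >= 1 after the
## +1 pseudocount, which compresses apparent fold changes at low expression
## (most severely for down-regulation). Solving
## |log2((2^(b+L) + 1) / (2^b + 1))| >= 1 at the weakest planted effect L
## gives the minimum baseline per direction; baselines are drawn from the
## normal truncated there.
planted_baseline_floors <- function(config, de) {
  if (!nrow(de)) return(numeric())
  lmin <- config$de_log2fc_range[1]
  up_floor <- if (2^lmin > 2) log2(1 / (2^lmin - 2)) else 1
  down_floor <- if (2^(-lmin) < 0.5) log2(0.5 / (0.5 - 2^(-lmin))) else 1
  pmax(1, ifelse(de$direction == "up", up_floor, down_floor)) + 0.01
}

sim_baselines <- function(n, mu, sd, planted_idx = integer(), floors = 1) {
  b <- stats::rnorm(n, mu, sd)
  if (length(planted_idx)) {
    lo <- stats::pnorm(floors, mu, sd)
    b[planted_idx] <- stats::qnorm(stats::runif(length(planted_idx), lo, 1), mu, sd)
  }
  b
}

#' Generate gene models
#'
#' One record per gene: unique id, chromosome (round-robin over
#' `n_chroms`), strand (random, roughly balanced) and TSS. Within each
#' chromosome consecutive TSSs are spaced by `min_spacing` plus a uniform
#' jitter of up to the same amount, so small `min_spacing` lets promoter
#' windows overlap and large values keep them disjoint.
#'
#' @param config a [sim_config()].
#' @return a `gene_model_set` data.frame.
#' @export
generate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  with_seed(sub_seed(config$seed, 101L), {
    chrom <- sprintf("chr%d", rep_len(seq_len(config$n_chroms), n))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tss <- numeric(n)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      gaps <- config$min_spacing +
        floor(stats::runif(length(idx), 0, config$min_spacing))
      tss[idx] <- 5000 + cumsum(gaps)
    }
    gene_model_set(sim_gene_ids(n), chrom, strand, tss)
  })
}

## planted DE assignment shared by all series of one simulated study
plant_de <- function(config) {
  n_de <- config$n_de_genes
  ids <- sim_gene_ids(config$n_genes)
  with_seed(sub_seed(config$seed, 202L), {
    genes <- sort(sample(ids, n_de))
    sgn <- ifelse(stats::runif(n_de) < config$de_up_fraction, 1, -1)
    lfc <- sgn * stats::runif(n_de, config$de_log2fc_range[1],
                              config$de_log2fc_range[2])
    data.frame(gene_id = genes, lfc = lfc,
               direction = ifelse(sgn > 0, "up", "down"),
               stringsAsFactors = FALSE)
  })
}

## per-series onset indices (time-point index at which the step switches on);
## drawn from 2..(T-1) so every planted gene reaches its plateau at >= 2
## non-reference time points by construction
plant_onsets <- function(config, de, series_offset) {
  T <- length(config$time_points)
  with_seed(sub_seed(config$seed, 250L + series_offset), {
    stats::setNames(sample(2:(T - 1L), nrow(de), replace = TRUE), de$gene_id)
  })
}

#' Generate an FPKM time course with planted DE genes
#'
#' FPKM(g, t) = 2^(baseline_g + trajectory_g(t) + noise), where the
#' trajectory of a planted gene is a step of height log2FC switching on at
#' its onset time (never the last time point, so the plateau covers >= 2
#' non-reference points); non-planted genes have trajectory 0.
#'
#' @param config a [sim_config()] (needs >= 3 time points).
#' @param truth optional truth from a previous call (or [simulate_study()])
#'   whose planted genes/log2FCs are reused; onsets are redrawn per series.
#' @param series_offset integer distinguishing independently generated
#'   series of one study (affects onsets, baselines and noise).
#' @param condition condition label of the generated samples.
#' @return list with `matrix` (a [timecourse_matrix()]) and `truth` (list
#'   with `de` data.frame gene_id/lfc/direction and `onsets`).
#' @export
generate_timecourse <- function(config, truth = NULL, series_offset = 0L,
                                condition = "ctrl") {
  stopifnot(inherits(config, "sim_config"))
  tp <- config$time_points
  if (length(tp) < 3L)
    config_error("need >= 3 time points (the DE rule needs >= 2 non-reference points)")
  de <- if (!is.null(truth) && !is.null(truth$de)) truth$de else plant_de(config)
  onsets <- plant_onsets(config, de, series_offset)
  n <- config$n_genes
  ids <- sim_gene_ids(n)
  T <- length(tp)
  traj <- matrix(0, n, T, dimnames = list(ids, tp))
  if (nrow(de)) {
    for (i in seq_len(nrow(de)))
      traj[de$gene_id[i], onsets[i]:T] <- de$lfc[i]
  }
  with_seed(sub_seed(config$seed, 300L + series_offset), {
    baseline <- sim_baselines(n, config$baseline_log_fpkm_mean,
                              config$baseline_log_fpkm_sd,
                              match(de$gene_id, ids),
                              planted_baseline_floors(config, de))
    noise <- matrix(stats::rnorm(n * T, 0, config$noise_sd), n, T)
    vals <- 2^(baseline + traj + noise)
  })
  dimnames(vals) <- list(ids, tp)
  m <- timecourse_matrix(vals, time = tp, condition = condition,
                         replicate = 1L, time_levels = tp)
  list(matrix = m, truth = list(de = de, onsets = onsets))
}

## choose per-TF target gene sets; the knockdown TF's stage-gained targets
## are sampled from planted up-regulated genes (its dependents), other TFs
## from the whole universe
choose_tf_targets <- function(config, de) {
  ids <- sim_gene_ids(config$n_genes)
  with_seed(sub_seed(config$seed, 400L), {
    tfs <- sort(sample(ids, config$n_tfs))
    kd_tf <- if (!is.null(config$kd_tf)) config$kd_tf else tfs[1L]
    targets <- list()
    taken <- character()
    up <- if (!is.null(de)) de$gene_id[de$direction == "up"] else character()
    for (tf in tfs) {
      pool_g <- if (tf == kd_tf && length(up) >= config$targets_per_tf) up
                else setdiff(ids, taken)
      gained <- sort(sample(pool_g, config$targets_per_tf))
      pool_e <- setdiff(ids, c(gained, taken))
      early <- sort(sample(pool_e, min(config$targets_per_tf, length(pool_e))))
      targets[[tf]] <- list(early = early, gained = gained)
      taken <- union(taken, c(gained, early))
    }
    list(tfs = tfs, kd_tf = kd_tf, targets = targets)
  })
}

#' Generate per-(TF, stage) ChIP-seq peak files
#'
#' For each TF, the early stage gets peaks in the promoters of its early
#' targets; the late stage gets peaks for early plus stage-gained targets,
#' so the late-minus-early subtraction recovers exactly the gained set.
#' Decoy peaks are placed outside every promoter window at both stages.
#'
#' @param config a [sim_config()].
#' @param models a `gene_model_set` from [generate_gene_models()].
#' @param truth optional truth carrying planted DE (biases the knockdown
#'   TF's targets toward up-regulated genes) or an existing `tf` element.
#' @param params a [promoter_params()] used to place peaks inside windows.
#' @return list with `peaks` (`peaks[[tf]][[stage]]`, `peak_set` objects)
#'   and `truth` (`tfs`, `kd_tf`, `targets` with `early`/`gained` per TF).
#' @export
generate_peaks <- function(config, models, truth = NULL,
                           params = promoter_params()) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(models, "gene_model_set") || !nrow(models))
    config_error("empty or invalid gene model set")
  tf <- if (!is.null(truth) && !is.null(truth$tf)) truth$tf
        else choose_tf_targets(config, truth$de)
  win <- promoter_windows(models, params)
  rownames(win) <- win$gene_id
  chrom_max <- tapply(win$end, win$chrom, max)

  promoter_peak <- function(gene) {
    w <- win[gene, ]
    width <- min(config$peak_width, w$end - w$start)
    start <- floor((w$start + w$end - width) / 2)  # centered in the window
    c(chrom = w$chrom, start = start, end = start + width)
  }
  with_seed(sub_seed(config$seed, 450L), {
    out <- list()
    for (t in tf$tfs) {
      stage_targets <- list()
      stage_targets[[config$early_stage]] <- tf$targets[[t]]$early
      stage_targets[[config$late_stage]] <-
        sort(c(tf$targets[[t]]$early, tf$targets[[t]]$gained))
      out[[t]] <- lapply(stage_targets, function(genes) {
        rows <- lapply(genes, promoter_peak)
        decoys <- decoy_intervals(config, win, chrom_max)
        chrom <- c(vapply(rows, `[[`, "", "chrom"), decoys$chrom)
        start <- c(as.numeric(vapply(rows, `[[`, "", "start")), decoys$start)
        end <- c(as.numeric(vapply(rows, `[[`, "", "end")), decoys$end)
        peak_set(chrom, start, end)
      })
    }
    list(peaks = out, truth = tf)
  })
}

## decoy peaks guaranteed outside all promoter windows (rejection sampling)
decoy_intervals <- function(config, win, chrom_max) {
  n <- config$decoy_peaks
  if (n == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  chroms <- names(chrom_max)
  got <- 0L
  chrom <- character(n); start <- numeric(n)
  while (got < n) {
    m <- (n - got) * 2L
    ch <- sample(chroms, m, replace = TRUE)
    st <- floor(stats::runif(m, 0, as.numeric(chrom_max[ch]) + 50000))
    en <- st + config$peak_width
    ok <- vapply(seq_len(m), function(i) {
      ww <- win[win$chrom == ch[i], , drop = FALSE]
      !any(st[i] < ww$end & ww$start < en[i])
    }, logical(1))
    take <- min(sum(ok), n - got)
    if (take > 0) {
      sel <- which(ok)[seq_len(take)]
      chrom[got + seq_len(take)] <- ch[sel]
      start[got + seq_len(take)] <- st[sel]
      got <- got + take
    }
  }
  data.frame(chrom = chrom, start = start, end = start + config$peak_width,
             stringsAsFactors = FALSE)
}

#' Generate a planted-partition interaction edge table
#'
#' Nodes are split into `n_modules` equal blocks; node pairs within a block
#' are connected with probability `p_within`, pairs across blocks with
#' `p_between`. Each edge carries a confidence drawn uniformly from
#' `conf_range`, so thresholding retains a controllable fraction.
#'
#' @param config a [sim_config()].
#' @param nodes node ids; defaults to the planted DE genes of `truth`.
#' @param truth optional truth carrying planted DE genes.
#' @return list with `edges` (node_a, node_b, confidence) and `truth`
#'   (named block assignment).
#' @export
generate_ppi_edges <- function(config, nodes = NULL, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(nodes)) {
    if (is.null(truth) || is.null(truth$de) || !nrow(truth$de))
      config_error("supply nodes or a truth with planted DE genes")
    nodes <- truth$de$gene_id
  }
  n <- length(nodes)
  if (n < 2L * config$n_modules)
    config_error("too few nodes (%d) for %d modules", n, config$n_modules)
  with_seed(sub_seed(config$seed, 500L), {
    block <- stats::setNames(sample(rep_len(seq_len(config$n_modules), n)), nodes)
    pairs <- utils::combn(nodes, 2L)
    same <- block[pairs[1L, ]] == block[pairs[2L, ]]
    p <- ifelse(same, config$p_within, config$p_between)
    keep <- stats::runif(ncol(pairs)) < p
    conf <- stats::runif(sum(keep), config$conf_range[1], config$conf_range[2])
    edges <- edge_table(pairs[1L, keep], pairs[2L, keep], conf)
    list(edges = edges, truth = block)
  })
}

#' Generate a replicated knockdown experiment
#'
#' The control arm follows the time-course generator on the knockdown time
#' grid. In the KD arm the knocked-down TF's FPKM is multiplied by
#' `1 - kd_efficiency` and the planted trajectories of that TF's
#' (stage-gained) targets are attenuated by the same factor. Both arms get
#' `n_replicates_kd` replicates per time point with independent noise.
#'
#' @param config a [sim_config()].
#' @param truth truth carrying `de` and `tf` elements (from
#'   [generate_timecourse()] / [generate_peaks()] or [simulate_study()]).
#' @return list with `control` and `kd` ([timecourse_matrix()] objects) and
#'   `truth` (`kd_tf`, `affected` = targets with planted trajectories).
#' @export
generate_kd_experiment <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_gene_ids(config$n_genes)
  tf <- if (!is.null(truth$tf)) truth$tf else choose_tf_targets(config, truth$de)
  kd_tf <- if (!is.null(config$kd_tf)) config$kd_tf else tf$kd_tf
  if (!kd_tf %in% ids) config_error("kd_tf '%s' not in the gene universe", kd_tf)
  de <- truth$de
  tp <- config$kd_time_points
  if (length(tp) < 2L) config_error("knockdown design needs >= 2 time points")
  T <- length(tp); n <- config$n_genes; R <- config$n_replicates_kd
  targets <- tf$targets[[kd_tf]]$gained
  affected <- intersect(targets, de$gene_id)

  traj <- matrix(0, n, T, dimnames = list(ids, tp))
  with_seed(sub_seed(config$seed, 600L), {
    onset <- stats::setNames(sample(2:max(2L, T - 1L), nrow(de), replace = TRUE),
                             de$gene_id)
    for (i in seq_len(nrow(de))) traj[de$gene_id[i], onset[i]:T] <- de$lfc[i]
    traj_kd <- traj
    traj_kd[affected, ] <- traj[affected, , drop = FALSE] * (1 - config$kd_efficiency)
    baseline <- sim_baselines(n, config$baseline_log_fpkm_mean,
                              config$baseline_log_fpkm_sd,
                              match(de$gene_id, ids),
                              planted_baseline_floors(config, de))
    make_arm <- function(tr, condition) {
      vals <- matrix(0, n, T * R, dimnames = list(ids, NULL))
      time <- rep(tp, each = R)
      for (j in seq_len(T * R)) {
        noise <- stats::rnorm(n, 0, config$noise_sd)
        vals[, j] <- 2^(baseline + tr[, time[j]] + noise)
      }
      if (condition == "kd") vals[kd_tf, ] <- vals[kd_tf, ] * (1 - config$kd_efficiency)
      timecourse_matrix(vals, time = time, condition = condition,
                        replicate = rep(seq_len(R), T), time_levels = tp)
    }
    control <- make_arm(traj, "ctrl")
    kd <- make_arm(traj_kd, "kd")
  })
  list(control = control, kd = kd,
       truth = list(kd_tf = kd_tf, affected = affected, onsets = onset))
}

#' Simulate a full study with ground truth
#'
#' Generates every input the pipeline consumes: gene models, an hours-scale
#' and a days-scale induction time course sharing planted DE genes, per-(TF,
#' stage) peak sets, a planted-partition edge table over the DE genes, truth
#' derived gene sets (up/down/blocks plus random decoy sets), and a
#' replicated knockdown experiment. With `outdir` set, all files are written
#' (expression TSV, BED, TSS TSV, GMT, edge TSV, truth JSON).
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory.
#' @param days_time_points time grid of the days-scale series.
#' @return list: `models`, `series_h`, `series_d` (each `$matrix`), `peaks`,
#'   `edges`, `kd`, `gene_sets`, and `truth` with elements `de`, `tf`,
#'   `modules`, `kd`.
#' @export
simulate_study <- function(config = sim_config(), outdir = NULL,
                           days_time_points = c("0d", "1d", "2d", "3d", "4d", "6d", "8d")) {
  models <- generate_gene_models(config)
  de <- plant_de(config)
  truth <- list(de = de)
  series_h <- generate_timecourse(config, truth, series_offset = 0L)
  cfg_d <- config; cfg_d$time_points <- days_time_points
  series_d <- generate_timecourse(cfg_d, truth, series_offset = 1L)
  pk <- generate_peaks(config, models, truth)
  truth$tf <- pk$truth
  ppi <- generate_ppi_edges(config, truth = truth)
  truth$modules <- ppi$truth
  kd <- generate_kd_experiment(config, truth)
  truth$kd <- kd$truth
  gene_sets <- truth_gene_sets(config, truth)
  out <- list(models = models, series_h = series_h, series_d = series_d,
              peaks = pk$peaks, edges = ppi$edges, kd = kd,
              gene_sets = gene_sets, truth = truth, config = config)
  if (!is.null(outdir)) write_study(out, outdir)
  out
}

## truth-derived gene sets plus random decoys (for enrichment testing)
truth_gene_sets <- function(config, truth) {
  ids <- sim_gene_ids(config$n_genes)
  sets <- list()
  de <- truth$de
  if (!is.null(de) && nrow(de)) {
    sets[["planted_up"]] <- de$gene_id[de$direction == "up"]
    sets[["planted_down"]] <- de$gene_id[de$direction == "down"]
  }
  if (!is.null(truth$kd) && length(truth$kd$affected))
    sets[["kd_dependent"]] <- truth$kd$affected
  with_seed(sub_seed(config$seed, 700L), {
    for (i in 1:5)
      sets[[sprintf("random_set_%d", i)]] <- sort(sample(ids, 50L))
  })
  sets[lengths(sets) > 0]
}

write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tss(study$models, file.path(outdir, "gene_models.tsv"))
  write_expression(study$series_h$matrix, file.path(outdir, "expression_hours.tsv"))
  write_expression(study$series_d$matrix, file.path(outdir, "expression_days.tsv"))
  write_expression(study$kd$control, file.path(outdir, "kd_control.tsv"))
  write_expression(study$kd$kd, file.path(outdir, "kd_knockdown.tsv"))
  write_edges(study$edges, file.path(outdir, "ppi_edges.tsv"))
  write_gmt(study$gene_sets, file.path(outdir, "gene_sets.gmt"))
  for (tf in names(study$peaks))
    for (stage in names(study$peaks[[tf]]))
      write_bed(study$peaks[[tf]][[stage]],
                file.path(outdir, sprintf("peaks_%s_%s.bed", tf, stage)))
  truth <- study$truth
  truth_json <- list(
    de = truth$de,
    tf_targets = truth$tf$targets,
    kd_tf = truth$kd$kd_tf,
    kd_affected = truth$kd$affected,
    modules = as.list(truth$modules))
  jsonlite::write_json(truth_json, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
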