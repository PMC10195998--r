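test_that("config invariants are enforced", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(p_within = 0.1, p_between = 0.2), "p_between")
  expect_error(sim_config(n_de_genes = 100, n_genes = 50), "n_de_genes")
  expect_error(sim_config(n_tfs = 10, targets_per_tf = 50, n_genes = 100),
               "targets_per_tf")
  expect_error(sim_config(kd_efficiency = 1.5), "kd_efficiency")
})

test_that("gene models are deterministic, spaced, and minimal cases work", {
  one <- generate_gene_models(sim_config(n_genes = 1))
  expect_equal(nrow(one), 1)
  expect_true(one$strand %in% c("+", "-") && one$tss >= 0)

  cfg <- sim_config(n_genes = 200, seed = 7)
  expect_identical(generate_gene_models(cfg), generate_gene_models(cfg))

  # min_spacing 10000: no two same-strand promoter windows overlap
  models <- generate_gene_models(sim_config(n_genes = 200, min_spacing = 10000,
                                            seed = 7))
  w <- promoter_windows(models)
  for (st in c("+", "-")) {
    ws <- w[w$strand == st, ]
    for (i in seq_len(nrow(ws))) {
      same <- ws$chrom == ws$chrom[i] & seq_len(nrow(ws)) != i
      expect_false(any(ws$start[same] < ws$end[i] & ws$start[i] < ws$end[same]))
    }
  }
})

test_that("null and forced time courses behave exactly as planted", {
  # zero noise, no DE: every fold change is exactly 1
  cfg0 <- sim_config(n_genes = 50, n_de_genes = 0, noise_sd = 0, seed = 3)
  tc0 <- generate_timecourse(cfg0)
  prof0 <- log_fold_changes(tc0$matrix, de_params(pseudocount = 1))
  expect_true(all(abs(2^prof0$lfc - 1) < 1e-12))

  # zero noise, one planted gene: it and only it satisfies the DE rule
  cfg1 <- sim_config(n_genes = 50, n_de_genes = 1, de_log2fc_range = c(2, 2),
                     noise_sd = 0, seed = 3)
  tc1 <- generate_timecourse(cfg1)
  called <- de_genes(call_temporal_de(log_fold_changes(
    filter_expressed(tc1$matrix))))
  expect_identical(called, tc1$truth$de$gene_id)

  expect_error(generate_timecourse(sim_config(time_points = c("0h", "2h"))),
               "3 time points")
})

test_that("truth consistency: every planted gene is called at zero noise", {
  cfg <- sim_config(n_genes = 500, n_de_genes = 60, noise_sd = 0, seed = 29)
  tc <- generate_timecourse(cfg)
  called <- de_genes(call_temporal_de(log_fold_changes(
    filter_expressed(tc$matrix))))
  expect_setequal(called, tc$truth$de$gene_id)
})

test_that("null DE fraction shrinks with noise and vanishes at zero", {
  frac <- vapply(c(0, 0.25, 0.6), function(s) {
    cfg <- sim_config(n_genes = 800, n_de_genes = 0, noise_sd = s, seed = 31)
    tc <- generate_timecourse(cfg)
    prof <- call_temporal_de(log_fold_changes(filter_expressed(tc$matrix)))
    mean(prof$de)
  }, numeric(1))
  expect_equal(frac[1], 0)
  expect_true(all(diff(frac) >= 0))
})

test_that("stage-gained peak structure is recovered exactly by subtraction", {
  cfg <- sim_config(n_genes = 300, targets_per_tf = 10, n_tfs = 2,
                    decoy_peaks = 50, seed = 13)
  models <- generate_gene_models(cfg)
  pk <- generate_peaks(cfg, models)
  map <- derive_tf_targets(pk$peaks, models)
  for (tf in pk$truth$tfs) {
    gained <- stage_specific_targets(map, tf, "120h", "0h")
    expect_setequal(gained, pk$truth$targets[[tf]]$gained)
  }

  # zero targets: subtraction is empty even with decoys present
  cfg0 <- sim_config(n_genes = 300, targets_per_tf = 0, n_tfs = 1,
                     decoy_peaks = 50, seed = 13)
  pk0 <- generate_peaks(cfg0, models)
  map0 <- derive_tf_targets(pk0$peaks, models)
  expect_identical(stage_specific_targets(map0, pk0$truth$tfs[1], "120h", "0h"),
                   character())

  expect_error(generate_peaks(cfg, models[0, ]), "empty")
})

test_that("planted-partition edges respect probabilities and confidences", {
  # p_within = 1, p_between = 0, 2 blocks of 5: two disjoint 5-cliques
  cfg <- sim_config(n_genes = 100, n_de_genes = 0, n_modules = 2,
                    p_within = 1, p_between = 0, seed = 2)
  sim <- generate_ppi_edges(cfg, nodes = sprintf("n%02d", 1:10))
  g <- build_network(sim$edges, sprintf("n%02d", 1:10), network_params(0, 1))
  comp <- igraph::components(g)
  expect_equal(comp$no, 2)
  expect_equal(sort(unname(comp$csize)), c(5, 5))
  expect_equal(igraph::ecount(g), 2 * choose(5, 2))

  # all confidences at 0.5: thresholding at 0.7 empties the network
  cfg2 <- sim_config(n_genes = 100, n_de_genes = 0, n_modules = 2,
                     p_within = 0.5, p_between = 0.05,
                     conf_range = c(0.5, 0.5), seed = 2)
  sim2 <- generate_ppi_edges(cfg2, nodes = sprintf("n%02d", 1:20))
  g2 <- build_network(sim2$edges, sprintf("n%02d", 1:20), network_params(0.7, 1))
  expect_equal(igraph::ecount(g2), 0)
})

test_that("knockdown generator attenuates the TF and its targets", {
  # full knockdown without noise zeroes the TF's expression
  cfg <- sim_config(n_genes = 200, n_de_genes = 40, targets_per_tf = 10,
                    kd_efficiency = 1, noise_sd = 0, n_replicates_kd = 2,
                    seed = 21)
  st <- simulate_study(cfg)
  kd_tf <- st$truth$kd$kd_tf
  expect_true(all(st$kd$kd$values[kd_tf, ] == 0))
  expect_true(all(st$kd$control$values[kd_tf, ] > 0))

  # affected targets flatten: KD log2FC at day 7 is ~0 while control induces
  aff <- st$truth$kd$affected
  expect_gt(length(aff), 0)
  d7_ctrl <- condition_means_for_test(st$kd$control, "ctrl")
  d7_kd <- condition_means_for_test(st$kd$kd, "kd")
  ctrl_fc <- log2((d7_ctrl[aff, "7d"] + 1) / (d7_ctrl[aff, "0d"] + 1))
  kd_fc <- log2((d7_kd[aff, "7d"] + 1) / (d7_kd[aff, "0d"] + 1))
  expect_true(all(abs(ctrl_fc) > abs(kd_fc)))

  expect_error(generate_kd_experiment(
    sim_config(n_genes = 50, kd_tf = "NOPE", seed = 1),
    truth = st$truth), "gene universe")
})

test_that("identical configs reproduce byte-identical study files", {
  cfg <- sim_config(n_genes = 120, n_de_genes = 30, targets_per_tf = 5,
                    decoy_peaks = 20, seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(cfg, outdir = d1)
  simulate_study(cfg, outdir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})
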