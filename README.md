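# neuroinduct

Temporal transcriptional analysis of neural induction for R.

When pluripotent stem cells are pushed toward neuroectoderm (e.g. by dual
SMAD inhibition), the transcriptome reorganizes over hours to days. This
package implements, as reusable and tested components, the analysis chain
used to dissect such a time course from FPKM expression matrices:

- **Temporal differential expression.** After an expressed-gene filter
  (FPKM > 1 in at least one sample), a gene is called DE when its fold
  change versus the reference time point satisfies |log2FC| ≥ log2(2) at a
  minimum of 2 non-reference time points; per-series DE sets are combined
  into across-time unions.
- **TF-target derivation from ChIP-seq.** Peaks are assigned to genes
  through strand-aware promoter windows (−2000..+500 bp around the TSS,
  half-open coordinates); stage-specific targets are obtained by set
  subtraction (late-stage targets minus early-stage targets) and
  intersected with the DE unions.
- **Preranked GSEA and ORA.** A weighted Kolmogorov–Smirnov running sum
  (ES), gene-permutation null with exact enumeration for small universes,
  NES, nominal p and GSEA-style FDR; plus exact hypergeometric
  overrepresentation with Benjamini–Hochberg control.
- **Network modules.** Interaction edges (STRING-style confidences) are
  thresholded (0.9 for TF networks, 0.7 for TF-target networks), the
  subgraph over a DE union is partitioned by greedy modularity
  maximization (Newman–Girvan Q reported and recomputable), modules are
  annotated by enrichment, and module conservation between two series is
  quantified by greedy maximum-Jaccard matching.
- **Knockdown effect ranking.** Replicated knockdown-vs-control contrasts
  per time point (two-sample t on log2(FPKM+1), BH, p ≤ 0.05 and FC ≥ 1.3),
  and the effect score
  `score(g) = mean_t log2FC_timecourse(g, t) − log2FC_KD(g, final day)`,
  whose top-k table flags genes that rise during normal induction but fail
  to under knockdown.
- **Synthetic data with ground truth.** A generator that emulates the
  study design (two time grids: 0,2,4,8,18,24,30,48 h and 0–8 d; KD at
  0,1,2,7 d with replicates) with planted DE genes, planted stage-gained
  promoter targets, a planted-partition interaction network and a simulated
  knockdown — so every component can be validated by recovery against known
  truth, without external downloads.

## Worked example

```r
library(neuroinduct)

study <- simulate_study(sim_config(n_genes = 1000, n_de_genes = 150, seed = 42))

# temporal DE on the hours-scale series
de_h <- call_temporal_de(log_fold_changes(filter_expressed(study$series_h$matrix)))
de_h
#> de_profile: 962 genes x 7 time points (reference 0h)
#>   DE: 148 (up 71, down 76, mixed 1)

de_d <- call_temporal_de(log_fold_changes(filter_expressed(study$series_d$matrix)))
u <- de_union(hours = de_h, days = de_d)
length(u$combined)
#> [1] 151

# stage-specific TF targets and their DE intersection
map <- derive_tf_targets(study$peaks, study$models)
gained <- stage_specific_targets(map, names(study$peaks)[1], "120h", "0h")
intersect_with_de(gained, de_genes(de_d))$n_intersect
#> [1] 49

# network modules over the DE union
part <- detect_modules(build_network(study$edges, u$combined,
                                     network_params(0.9, 3)), seed = 42)
part
#> module_partition: 150 nodes in 4 modules, Q = 0.6571

# knockdown effect ranking
test <- kd_de_test(study$kd$control, study$kd$kd, "7d")
head(top_k_table(kd_effect_score(de_d, test), kd_params(top_k = 5)))
#>   gene_id mean_tc_lfc    kd_lfc    score rank
#> 1  G00700    3.046130 -2.293049 5.339179    1
#> 2  G00288    1.895468 -3.210907 5.106375    2
#> 3  G00156    2.312747 -2.473985 4.786732    3
#> 4  G00969    2.048955 -2.610199 4.659154    4
#> 5  G00968    2.354026 -2.301486 4.655512    5
```

The 148 called genes recover the planted DE set on expressed genes; the 50
stage-gained targets are recovered exactly from the peak files; and 92% of
the planted knockdown-dependent genes appear in the top-50 effect-score
table (`mean(study$truth$kd$affected %in% top_k_table(kd_effect_score(de_d,
test))$gene_id)`).

The whole chain can also be driven from a single YAML config with
`run_pipeline("config.yaml")`, which writes every analytic output plus a
JSON manifest with parameters and checksums; reruns with the same config
and seed are byte-identical.

## Documentation

The methods vignette (`vignettes/neural-induction-pipeline.Rmd`) describes
the models, parameter choices, what the synthetic generator does and does
not emulate, and known limitations. Every exported function carries
roxygen documentation.
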