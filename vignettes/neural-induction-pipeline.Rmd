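---
title: "Methods: temporal transcriptional analysis of neural induction"
author: "neuroinduct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal transcriptional analysis of neural induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroinduct)
```

# Scope

`neuroinduct` analyses bulk RNA-seq time courses of neural induction — the
transition of pluripotent stem cells to neuroectodermal identity, typically
triggered by dual SMAD inhibition — together with ChIP-seq-derived
transcription-factor target sets and a CRISPRi-style knockdown experiment.
The package consumes FPKM matrices, BED peak files, TSS tables (or GTF),
GMT gene sets and STRING-style edge tables; it does not perform read
alignment, quantification, or peak calling.

All genomic intervals are handled in 0-based half-open coordinates
internally. BED is native to this convention; GTF (1-based inclusive) is
converted on load: TSS = start − 1 on the plus strand, end − 1 on the minus
strand. Gene identity is a case-sensitive opaque string; no alias
resolution is attempted, because identifier mapping is data-dependent and
out of scope.

# Temporal differential expression

Time-series designs here have a single replicate per time point, so DE is
called by a fold-change rule rather than a variance model:

1. **Expressed-gene filter.** A gene is kept when its maximum FPKM over all
   samples is *strictly* greater than `fpkm_min` (default 1); ties at
   exactly 1.0 are excluded.
2. **Fold changes.** For each non-reference time point `t`,
   `log2FC(g, t) = log2((FPKM(g, t) + c) / (FPKM(g, t0) + c))` with
   pseudocount `c = 1` FPKM by default. The pseudocount is applied to both
   numerator and denominator: zeros occur in real FPKM data, and the offset
   bounds ratios. Multiplying all FPKM values and the pseudocount by the
   same positive constant leaves every log2FC unchanged.
3. **Calling rule.** A gene is DE when `|log2FC| >= log2(fc_cutoff)`
   (default cutoff 2, i.e. ≥ 1 in log2 units, up **or** down) at
   `min_timepoints` (default 2) or more non-reference time points. The
   qualifying points need not agree in direction; direction is reported as
   `up`, `down` or `mixed` rather than used to veto calls, so downstream
   steps can filter on it explicitly.

Per-series DE sets are unioned across time points, and series unions are
combined, mirroring how network analyses are run on "all genes DE at any
time". Lowering the cutoff or the minimum time-point count can only grow
the DE set (monotonicity), which the test suite asserts.

When replicates do exist (the knockdown control arm), their arithmetic mean
on FPKM scale is taken before fold changes.

The expressed-gene filter is applied per series; whether a joint filter
across series would be preferable is data-dependent, and the per-series
choice keeps each series self-contained.

# Promoter windows and TF targets

The promoter window spans `upstream_bp` = 2000 bp 5' of the TSS to
`downstream_bp` = 500 bp 3' of it. Windows are strand-reflected so that
"upstream" is always 5' of the gene; in genomic (0-based half-open)
coordinates a plus-strand gene at TSS `s` gets `[s − 2000, s + 500)` and a
minus-strand gene `[s − 500 + 1, s + 2000 + 1)`, clipped at zero. The
"−2000 – 500" notation is read as downstream-inclusive (the standard
promoter-annotation semantics); this is a deliberate, documented choice
since the notation alone does not fix which side the 500 falls on.

A gene is a target of a TF at a stage when at least one of that TF's peaks
overlaps the gene's promoter window by ≥ 1 bp; a peak may hit several
genes. Overlap is computed with `GenomicRanges::findOverlaps` and verified
in the tests against a brute-force nested-loop oracle. Peaks are intervals,
not summits — summit-containment semantics would need summit columns that
BED does not guarantee.

Stage-specific ("stage-gained") targets are the plain set difference
`targets(late) \ targets(early)` — e.g. targets present at 120 h of
induction but absent at 0 h — and are then intersected with DE unions. Both
operations report input and output sizes for audit.

# Enrichment

## Preranked GSEA

The time series has one replicate, which rules out phenotype-permutation
GSEA; the package therefore implements preranked GSEA with a
gene-permutation null. The ranking metric defaults to the mean log2FC
across non-reference time points; ties are broken by gene id so rankings
are deterministic.

The running sum increments by `|m|^p / sum_hits |m|^p` at set members and
decrements by `1/(N − Nh)` elsewhere; the enrichment score is the signed
extremum, with a magnitude tie resolved to the positive side. The weight
exponent defaults to `p = 1` (the weighted statistic); `p = 0` gives the
classic Kolmogorov–Smirnov form. If all hit weights are zero the hit
increments fall back to `1/Nh`, keeping the statistic defined.

The null permutes gene labels preserving set size. When the number of
distinct subsets `choose(N, k)` does not exceed `n_perm`, the null is
enumerated exhaustively and the p-value is exact; otherwise `n_perm`
random subsets are drawn (default 1000, values below 100 warn).
`NES = ES / mean(|null ES| of the same sign)`; the nominal p is the
fraction of same-sign null ES at least as extreme; FDR follows the GSEA
convention of pooling normalized null and observed NES separately for the
positive and negative sides, with monotonicity enforced within each side.
Calibration is checked in the tests: with exchangeable metrics and random
sets the nominal p passes a Kolmogorov–Smirnov uniformity test over 1000
sets at α = 0.01.

## Overrepresentation

Module labels and top-table annotation use the exact upper-tail
hypergeometric test with Benjamini–Hochberg correction across sets; this
replaces by-hand annotation with an automatable, exact computation. Set
sizes are counted within the stated universe, and the query must be a
subset of the universe.

# Network modules

Edges carry confidences in [0, 1]; STRING-style integer combined scores
(0–1000) are divided by 1000 on load, so the conventional "combined score ≥
900" becomes confidence ≥ 0.9. Networks are built by inducing the subgraph
on a DE union, keeping edges at or above the confidence threshold (0.9 for
TF networks, 0.7 for TF-target networks by convention), dropping isolated
nodes, and dropping components smaller than `min_component_size` (default
3 — singleton and pair components carry no module structure; the count of
dropped components is recorded on the graph). Confidences are used only
for thresholding, never as modularity weights, mirroring the binary use of
STRING cutoffs.

Modules are found by agglomerative greedy modularity maximization
(`igraph::cluster_fast_greedy`); the merge dendrogram is cut at the maximum
of the modularity sequence (rounded at 1e-12 to stabilize ties), which
matters for degenerate graphs — a complete graph correctly yields one
module with Q = 0. The achieved Newman–Girvan Q is reported and is
recomputable from the partition and graph by an independent direct formula
(`recompute_modularity`), to within 1e-12. The contract validated by the
tests is "a modularity-maximizing partition that recovers planted blocks"
(adjusted Rand index ≥ 0.9 on 60-node two-block graphs with within/between
edge probabilities 0.3/0.01), not any particular tool's exact boundaries.

Module conservation between two series is quantified by greedy
maximum-Jaccard matching on the shared gene universe: repeatedly pair the
remaining modules with the highest Jaccard index (ties broken by module
name), reporting shared, gained and lost genes per pair. This makes
"the same module, different membership" claims quantitative.

# Knockdown contrast and effect ranking

Knockdown experiments carry replicates, so a replicate-based test is used
per time point: log2FC of replicate-mean FPKM (pseudocounted) and a
two-sample t-test on `log2(FPKM + 1)` with BH correction; a gene is called
at p ≤ 0.05 (or q, configurable) **and** |FC| ≥ 1.3. This is a deliberate
stand-in for count-model DE: the scientific content here is the contrast
design and the ranking, and the engine is swappable behind the
`kd_de_test` contract.

The default is the **pooled-variance** (Student) t. At 2–3 replicates the
Welch–Satterthwaite approximation is systematically conservative (measured
size ≈ 0.032 at nominal 0.05 on exactly normal data with 3 + 3
replicates), whereas the pooled test is exact under the equal-variance
replicate model and measured at ≈ 0.049; Welch remains available via
`var_equal = FALSE` for designs with heteroscedastic arms. The +1
pseudocount additionally compresses fold changes (and hence calls) for
genes expressed near or below 1 FPKM — a conservative bias to keep in mind
for low-expression genes.

The knockdown effect score is
`score(g) = mean_t log2FC_timecourse(g, t) − log2FC_KD(g, final day)`,
with both terms on the log2 scale (consistent units are required for the
subtraction), the time-course term from the days-scale induction series
and the KD term against the same-day control. Large positive scores mark
genes that are induced normally but fail to come up under knockdown. The
score is exactly linear in its two terms: shifting them by δ1 and δ2
shifts the score by δ1 − δ2. The top-k table (default k = 50) sorts by
descending score with ties broken by gene id, so reruns are stable.

# The synthetic-data generator

The generator produces every input with known ground truth, emulating the
study design: an hours-scale grid (0, 2, 4, 8, 18, 24, 30, 48 h), a
days-scale grid (0–8 d), and a knockdown at 0, 1, 2, 7 d with 3 replicates
per arm. Defaults (chosen once, as the package's model of a realistic
experiment): 2000 genes; 300 planted DE genes with |log2FC| uniform in
[1.5, 3] and random sign; log2-FPKM baselines N(3, 2) (median ≈ 8 FPKM
with a wide dynamic range); measurement noise SD 0.25 on the log2 scale;
3 TFs with 50 stage-gained promoter targets each plus 500 decoy peaks per
file; a 4-block interaction network with within/between edge probabilities
0.3/0.01 and edge confidences uniform in [0.9, 1]; knockdown efficiency
0.9.

Design choices worth spelling out:

- **Log-normal expression, not counts.** The pipeline consumes FPKM, so
  noise is Gaussian on the log2 scale. Count overdispersion, library-size
  effects and batch structure are *not* emulated; passing recovery tests
  therefore demonstrates correctness of the analysis logic, not robustness
  to count noise or batches.
- **Step trajectories.** Planted DE genes switch on at a random onset time
  drawn from the non-reference time points excluding the last, so every
  planted gene reaches its plateau at ≥ 2 non-reference points — the
  sharpest possible exercise of the threshold-at-≥2-time-points rule.
- **Planted baselines are expressed.** A "differentially expressed" gene
  that is never expressed is a contradiction, so planted genes draw their
  baselines from the normal truncated at the level where the gene both
  survives the FPKM > 1 filter and still clears |log2FC| ≥ 1 after
  pseudocount compression (the binding case is down-regulation at the
  weakest planted effect; for |log2FC| ≥ 1.5 the floor works out to ≈ 1.78
  log2-FPKM). Without the truncation the generator would plant truth it
  then guarantees cannot be recovered.
- **Knockdown semantics.** The knocked-down TF's own FPKM is multiplied by
  `1 − kd_efficiency`; the planted trajectories of that TF's stage-gained
  targets are attenuated by the same factor. The TF's targets are sampled
  from the planted *up-regulated* genes: a target must have a trajectory
  for its attenuation to be observable. A consequence is that with
  `kd_efficiency = 0` the effect score reduces to the time-course mean
  log2FC plus replicate noise, so the top-50 table is populated by induced
  genes and chance-level recall of the (exchangeable) planted targets is
  `k / n_up` with respect to the up-regulated DE genes — not `k / n_genes`
  — which is what the recovery tests assert.
- **Stage-gained peak structure.** Early-stage files carry peaks for a
  disjoint "early" target set (present at both stages); late-stage files
  add peaks for the gained set; decoys are rejection-sampled outside every
  promoter window. Late-minus-early subtraction therefore recovers the
  gained set exactly at exact-overlap settings.
- **Determinism.** Every generator draws from a sub-seed derived from the
  config seed plus a fixed per-component offset, so components can be
  regenerated independently and still match a full run; identical configs
  yield byte-identical files.

Structural defaults (`n_de_genes`, `n_tfs`, `targets_per_tf`) scale down
automatically when a small `n_genes` is requested, so minimal
configurations remain valid; explicitly supplied values are always
validated strictly.

# Pipeline orchestration

`run_pipeline()` executes simulate/load → temporal DE → TF targets →
network modules → enrichment → knockdown ranking from a single YAML config
with sections mirroring the stages. Unknown keys are errors, so typos
cannot silently fall back to defaults. Any stage failure aborts with the
stage name and underlying message. With an output directory set, all
analytic outputs are written as tab-delimited or plain-text files plus a
JSON manifest recording parameters, seed, wall-clock and per-file MD5
checksums; reruns with the same config and seed are byte-identical in
every analytic output (the manifest itself records wall-clock and is
excluded from that comparison).

# Verification strategy and problem sizes

The test suite validates each operation against an independent oracle:
brute-force interval overlap for promoter assignment; an independently
coded running-sum loop and `fgsea::calcGseaStat` for the enrichment score;
exhaustive subset enumeration for small-universe GSEA p-values; closed-form
and Monte-Carlo tails for the hypergeometric test; hand-enumerated
modularity for two disjoint 5-cliques (Q = 1/2 exactly); per-gene
`stats::t.test` for the knockdown contrast; and the generator's own ground
truth for end-to-end recovery. Recovery checks run at 5000 genes / 300
planted DE genes for the temporal caller (sensitivity ≥ 0.95, false
discovery proportion ≤ 0.05 at noise SD 0.25), 60-node planted two-block
graphs over 10 seeds for community detection, and 2000 genes / 40 planted
targets / 3 replicates for the knockdown ranking — sizes chosen to give
stable statistics while keeping the full suite around a minute of
runtime.

# Known limitations

- The fold-change DE rule has no error control; its false-discovery
  behaviour depends entirely on the noise level and cutoffs. The
  simulation quantifies this for log-normal noise only.
- FPKM is accepted as given; no normalization, length-bias or
  library-composition correction is applied.
- One TSS per gene id; with multi-transcript GTFs the 5'-most transcript
  start represents the gene, and a gene is a target if any transcript
  promoter overlaps a peak.
- The greedy modularity optimizer has the usual resolution limit; very
  small modules inside large networks may be merged.
- Knockdown inference assumes same-day controls and equal-variance
  replicate arms by default.
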