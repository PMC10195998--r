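## TF-target derivation from ChIP-seq peaks: promoter-window annotation,
## stage-specific target subtraction, and intersection with DE unions.

#' Promoter window parameters
#'
#' The promoter window runs from `upstream_bp` 5' of the TSS to
#' `downstream_bp` 3' of it (defaults -2000..+500 relative to the TSS).
#'
#' @param upstream_bp bases upstream (5') of the TSS. Default 2000.
#' @param downstream_bp bases downstream (3') of the TSS. Default 500.
#' @return a `promoter_params` list.
#' @export
promoter_params <- function(upstream_bp = 2000L, downstream_bp = 500L) {
  if (!is_count(upstream_bp, 0L) || !is_count(downstream_bp, 0L))
    config_error("window extents must be non-negative counts")
  if (upstream_bp + downstream_bp <= 0)
    config_error("promoter window must have positive length")
  structure(list(upstream_bp = as.integer(upstream_bp),
                 downstream_bp = as.integer(downstream_bp)),
            class = "promoter_params")
}

#' Promoter windows for a gene model set
#'
#' Windows are strand-reflected about the TSS so that "upstream" is always 5'
#' of the gene, in 0-based half-open genomic coordinates:
#' plus strand `[TSS - upstream, TSS + downstream)`, minus strand
#' `[TSS - downstream + 1, TSS + upstream + 1)`. Windows are clipped at 0.
#'
#' @param models a `gene_model_set` (see [read_tss()]).
#' @param params a [promoter_params()].
#' @return data.frame gene_id, chrom, strand, start, end (0-based half-open).
#' @export
promoter_windows <- function(models, params = promoter_params()) {
  stopifnot(inherits(models, "gene_model_set"))
  up <- params$upstream_bp; down <- params$downstream_bp
  plus <- models$strand == "+"
  start <- ifelse(plus, models$tss - up, models$tss - down + 1)
  end <- ifelse(plus, models$tss + down, models$tss + up + 1)
  start <- pmax(start, 0)
  data.frame(gene_id = models$gene_id, chrom = models$chrom,
             strand = models$strand, start = start, end = end,
             stringsAsFactors = FALSE)
}

## 0-based half-open -> GRanges (1-based closed)
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
}

#' Assign ChIP-seq peaks to genes through promoter windows
#'
#' A gene is a target iff at least one peak overlaps its promoter window by
#' >= 1 bp (half-open overlap). One peak may hit several genes. Peaks on
#' chromosomes absent from the gene models are ignored with a warning.
#'
#' @param peaks a `peak_set` from [read_bed()].
#' @param windows promoter windows from [promoter_windows()].
#' @return sorted character vector of target gene ids.
#' @export
assign_peaks_to_genes <- function(peaks, windows) {
  if (!nrow(peaks) || !nrow(windows)) return(character())
  unknown <- !(peaks$chrom %in% windows$chrom)
  if (any(unknown)) {
    warning(sprintf("%d peak(s) on chromosome(s) absent from gene models ignored: %s",
                    sum(unknown),
                    paste(unique(peaks$chrom[unknown]), collapse = ", ")),
            call. = FALSE)
    peaks <- peaks[!unknown, , drop = FALSE]
    if (!nrow(peaks)) return(character())
  }
  pg <- as_granges0(peaks$chrom, peaks$start, peaks$end)
  wg <- as_granges0(windows$chrom, windows$start, windows$end)
  hits <- GenomicRanges::findOverlaps(pg, wg, minoverlap = 1L)
  sort(unique(windows$gene_id[S4Vectors::subjectHits(hits)]))
}

#' TF target map
#'
#' Container mapping TF id -> stage label -> target gene set, with provenance.
#'
#' @param assignments nested list: `assignments[[tf]][[stage]]` is a character
#'   vector of target gene ids.
#' @param provenance optional list recording peak files and parameters.
#' @return a `tf_target_map`.
#' @export
tf_target_map <- function(assignments, provenance = list()) {
  stopifnot(is.list(assignments))
  structure(list(assignments = assignments, provenance = provenance),
            class = "tf_target_map")
}

#' Derive a TF target map from per-stage peak sets
#'
#' @param peak_sets nested list `peak_sets[[tf]][[stage]]` of `peak_set`
#'   objects (or BED paths).
#' @param models a `gene_model_set`.
#' @param params a [promoter_params()].
#' @return a [tf_target_map()].
#' @export
derive_tf_targets <- function(peak_sets, models, params = promoter_params()) {
  win <- promoter_windows(models, params)
  assignments <- lapply(peak_sets, function(stages) {
    lapply(stages, function(p) {
      if (is.character(p)) p <- read_bed(p)
      assign_peaks_to_genes(p, win)
    })
  })
  tf_target_map(assignments, provenance = list(params = unclass(params)))
}

#' Stage-specific targets by set subtraction
#'
#' Targets gained at the late stage: `targets(late) \ targets(early)`
#' (e.g. OTX2 targets at 120 h minus targets at 0 h).
#'
#' @param map a [tf_target_map()].
#' @param tf TF identifier.
#' @param late_stage,early_stage stage labels present in the map for `tf`.
#' @return sorted character vector of stage-gained target gene ids.
#' @export
stage_specific_targets <- function(map, tf, late_stage, early_stage) {
  stopifnot(inherits(map, "tf_target_map"))
  if (!tf %in% names(map$assignments))
    config_error("TF '%s' not in map (have: %s)", tf,
                 paste(names(map$assignments), collapse = ", "))
  stages <- map$assignments[[tf]]
  for (st in c(late_stage, early_stage))
    if (!st %in% names(stages))
      config_error("stage '%s' absent for %s (available: %s)", st, tf,
                   paste(names(stages), collapse = ", "))
  sort(setdiff(stages[[late_stage]], stages[[early_stage]]))
}

#' Intersect TF targets with a DE union
#'
#' @param targets character vector of target gene ids.
#' @param de_union character vector of DE gene ids.
#' @return list with `genes` (sorted intersection), `n_targets`, `n_de`,
#'   `n_intersect`.
#' @export
intersect_with_de <- function(targets, de_union) {
  genes <- sort(intersect(targets, de_union))
  list(genes = genes, n_targets = length(unique(targets)),
       n_de = length(unique(de_union)), n_intersect = length(genes))
}
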