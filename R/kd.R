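## Knockdown contrast analysis: replicate-based KD-vs-control DE per time
## point and the knockdown effect ranking that contrasts time-course
## induction with the KD fold change at the final day.

#' Knockdown analysis parameters
#'
#' @param alpha significance level for KD-vs-control calls (default 0.05).
#' @param fc_cutoff_kd linear fold-change cutoff for KD calls (default 1.3).
#' @param final_day time label of the terminal KD contrast (default "7d").
#' @param top_k size of the top table (default 50).
#' @param use_q if TRUE, the BH-adjusted q-value is compared to `alpha`
#'   instead of the raw p-value (default FALSE, the raw-p convention).
#' @param pseudocount FPKM offset for fold changes and log transforms.
#' @return a `kd_params` list.
#' @export
kd_params <- function(alpha = 0.05, fc_cutoff_kd = 1.3, final_day = "7d",
                      top_k = 50L, use_q = FALSE, pseudocount = 1) {
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1))
    config_error("alpha must lie in (0,1)")
  if (!(is.numeric(fc_cutoff_kd) && fc_cutoff_kd > 1))
    config_error("fc_cutoff_kd must be > 1")
  if (!is_count(top_k)) config_error("top_k must be a count >= 1")
  structure(list(alpha = alpha, fc_cutoff_kd = fc_cutoff_kd,
                 final_day = final_day, top_k = as.integer(top_k),
                 use_q = isTRUE(use_q), pseudocount = pseudocount),
            class = "kd_params")
}

## group means and variances of log2(FPKM + pc) for one condition at one time
group_stats <- function(x, time, condition, pc) {
  cols <- which(x$samples$time == time & x$samples$condition == condition)
  if (length(cols) < 2L)
    config_error("need >= 2 replicates for %s/%s (found %d)",
                 condition, time, length(cols))
  v <- log2(x$values[, cols, drop = FALSE] + pc)
  list(mean = rowMeans(v),
       var = apply(v, 1L, stats::var),
       n = length(cols),
       fpkm_mean = rowMeans(x$values[, cols, drop = FALSE]))
}

#' KD-vs-control differential test at one time point
#'
#' Per gene: log2FC of replicate-mean FPKM (KD over control, pseudocounted)
#' and a two-sample t-test on log2(FPKM + pseudocount) with BH correction
#' across genes. The default is the pooled-variance (Student) t, which is
#' exactly calibrated under the replicate model at the small replicate
#' counts typical of knockdown designs; `var_equal = FALSE` switches to
#' Welch's t (conservative at 2-3 replicates because of the
#' Welch-Satterthwaite df estimate). A gene is called DE when its p (or q,
#' per `params$use_q`) is at most `alpha` and
#' `|log2FC| >= log2(fc_cutoff_kd)`.
#'
#' @param control,kd `timecourse_matrix` objects sharing a gene universe,
#'   with >= 2 replicates at `time`.
#' @param time time label at which to test.
#' @param params a [kd_params()].
#' @param var_equal pool the group variances (default TRUE).
#' @return data.frame: gene_id, log2fc, t, df, pval, qval, de.
#' @export
kd_de_test <- function(control, kd, time, params = kd_params(),
                       var_equal = TRUE) {
  stopifnot(inherits(control, "timecourse_matrix"),
            inherits(kd, "timecourse_matrix"))
  genes <- intersect(gene_ids(control), gene_ids(kd))
  if (!length(genes)) config_error("control and KD share no genes")
  control$values <- control$values[genes, , drop = FALSE]
  kd$values <- kd$values[genes, , drop = FALSE]
  pc <- params$pseudocount
  gc <- group_stats(control, time, unique(control$samples$condition)[1L], pc)
  gk <- group_stats(kd, time, unique(kd$samples$condition)[1L], pc)
  lfc <- log2((gk$fpkm_mean + pc) / (gc$fpkm_mean + pc))
  if (var_equal) {
    pooled <- ((gk$n - 1) * gk$var + (gc$n - 1) * gc$var) / (gk$n + gc$n - 2)
    se2 <- pooled * (1 / gk$n + 1 / gc$n)
    df <- rep(gk$n + gc$n - 2, length(se2))
  } else {
    se2 <- gk$var / gk$n + gc$var / gc$n
    df <- se2^2 / ((gk$var / gk$n)^2 / (gk$n - 1) + (gc$var / gc$n)^2 / (gc$n - 1))
  }
  tstat <- (gk$mean - gc$mean) / sqrt(se2)
  zero <- se2 == 0
  tstat[zero] <- 0; df[zero] <- gk$n + gc$n - 2
  p <- 2 * stats::pt(-abs(tstat), df)
  q <- stats::p.adjust(p, method = "BH")
  crit <- if (params$use_q) q else p
  de <- crit <= params$alpha & abs(lfc) >= log2(params$fc_cutoff_kd)
  data.frame(gene_id = genes, log2fc = lfc, t = tstat, df = df,
             pval = p, qval = q, de = de, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Knockdown effect ranking
#'
#' Per gene, the effect score is the mean time-course log2FC (over
#' non-reference time points of the induction series) minus the KD-vs-control
#' log2FC at the final day. Large positive scores mark genes that rise during
#' normal induction but fail to under knockdown. Computed on the
#' intersection of the two gene universes; ranked descending, ties broken by
#' gene id.
#'
#' @param timecourse_de a `de_profile` of the induction series (log2FC matrix
#'   required; flags optional).
#' @param kd_fc_final named numeric vector of KD log2FC at the final day
#'   (e.g. the `log2fc` column of [kd_de_test()] named by gene), or the
#'   data.frame returned by [kd_de_test()].
#' @param params a [kd_params()].
#' @return a `kd_ranking` data.frame: gene_id, mean_tc_lfc, kd_lfc, score,
#'   rank.
#' @export
kd_effect_score <- function(timecourse_de, kd_fc_final, params = kd_params()) {
  stopifnot(inherits(timecourse_de, "de_profile"))
  if (is.data.frame(kd_fc_final))
    kd_fc_final <- stats::setNames(kd_fc_final$log2fc, kd_fc_final$gene_id)
  tc <- rowMeans(timecourse_de$lfc)
  genes <- intersect(names(tc), names(kd_fc_final))
  if (!length(genes)) config_error("no genes shared between time course and KD")
  score <- tc[genes] - kd_fc_final[genes]
  ord <- order(-score, genes, method = "radix")
  out <- data.frame(gene_id = genes[ord], mean_tc_lfc = tc[genes][ord],
                    kd_lfc = kd_fc_final[genes][ord], score = score[ord],
                    rank = seq_along(genes), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("kd_ranking", "data.frame")
  out
}

#' Top-k table of a knockdown ranking
#'
#' @param ranking a `kd_ranking` from [kd_effect_score()].
#' @param params a [kd_params()] (`top_k`).
#' @return the first `top_k` rows (all rows with a warning if fewer exist).
#' @export
top_k_table <- function(ranking, params = kd_params()) {
  stopifnot(inherits(ranking, "kd_ranking"))
  k <- params$top_k
  if (nrow(ranking) < k) {
    warning(sprintf("ranking has %d genes, fewer than top_k = %d; returning all",
                    nrow(ranking), k), call. = FALSE)
    k <- nrow(ranking)
  }
  utils::head(ranking, k)
}
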