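## Temporal differential-expression calling.
##
## A gene in a time series (one replicate per time point) is called DE when
## its fold change versus the reference time point exceeds a cutoff, in
## either direction, at a minimum number of time points. An expression floor
## (FPKM > 1 in at least one sample) is applied first.

#' Parameters of the temporal DE rule
#'
#' @param fpkm_min expression floor: genes whose maximum FPKM over all samples
#'   is not strictly greater than this are dropped. Default 1.
#' @param fc_cutoff linear fold-change cutoff, applied as
#'   `|log2FC| >= log2(fc_cutoff)` (up or down). Default 2.
#' @param min_timepoints minimum number of non-reference time points at which
#'   the cutoff must be met. Default 2.
#' @param pseudocount FPKM offset added to numerator and denominator of every
#'   ratio; bounds fold changes when zeros occur. Default 1.
#' @return a `de_params` list.
#' @export
de_params <- function(fpkm_min = 1, fc_cutoff = 2, min_timepoints = 2L,
                      pseudocount = 1) {
  if (!(is.numeric(fc_cutoff) && fc_cutoff > 1))
    config_error("fc_cutoff must be > 1")
  if (!is_count(min_timepoints)) config_error("min_timepoints must be a count >= 1")
  if (!(is.numeric(pseudocount) && pseudocount > 0))
    config_error("pseudocount must be > 0")
  structure(list(fpkm_min = fpkm_min, fc_cutoff = fc_cutoff,
                 min_timepoints = as.integer(min_timepoints),
                 pseudocount = pseudocount),
            class = "de_params")
}

#' Filter to expressed genes
#'
#' Retains exactly the genes whose maximum FPKM over all samples is strictly
#' greater than `params$fpkm_min`; gene order is preserved.
#'
#' @param x a [timecourse_matrix()].
#' @param params a [de_params()].
#' @return a filtered `timecourse_matrix` (possibly with zero rows).
#' @export
filter_expressed <- function(x, params = de_params()) {
  stopifnot(inherits(x, "timecourse_matrix"))
  keep <- apply(x$values, 1L, max) > params$fpkm_min
  y <- x
  y$values <- x$values[keep, , drop = FALSE]
  y
}

## replicate means on FPKM scale per (time, condition); returns matrix
## genes x time for one condition
condition_means <- function(x, condition) {
  sel <- x$samples$condition == condition
  if (!any(sel)) config_error("condition '%s' not present", condition)
  times <- intersect(x$time_levels, unique(x$samples$time[sel]))
  out <- vapply(times, function(tt) {
    cols <- which(sel & x$samples$time == tt)
    rowMeans(x$values[, cols, drop = FALSE])
  }, numeric(nrow(x$values)))
  out <- matrix(out, nrow = nrow(x$values),
                dimnames = list(rownames(x$values), times))
  out
}

#' Per-time-point log2 fold changes against the reference time
#'
#' Computes `log2((FPKM(g, t) + pc) / (FPKM(g, t0) + pc))` for every
#' non-reference time point. When replicates exist their arithmetic mean on
#' FPKM scale is taken first.
#'
#' @param x a [timecourse_matrix()].
#' @param params a [de_params()] (supplies the pseudocount).
#' @param condition condition to evaluate (default first condition present).
#' @param reference reference time label; default the matrix's reference time.
#' @return a `de_profile` with element `lfc`: genes x non-reference-time
#'   matrix of log2 fold changes; DE flags are filled by [call_temporal_de()].
#' @export
log_fold_changes <- function(x, params = de_params(),
                             condition = NULL, reference = NULL) {
  stopifnot(inherits(x, "timecourse_matrix"))
  if (is.null(condition)) condition <- x$samples$condition[[1L]]
  if (is.null(reference)) reference <- reference_time(x)
  m <- condition_means(x, condition)
  if (!reference %in% colnames(m))
    config_error("reference time '%s' absent (have: %s)", reference,
                 paste(colnames(m), collapse = ", "))
  other <- setdiff(colnames(m), reference)
  if (!length(other)) config_error("no non-reference time points")
  pc <- params$pseudocount
  lfc <- log2((m[, other, drop = FALSE] + pc) / (m[, reference] + pc))
  structure(list(lfc = lfc, params = params, reference = reference,
                 condition = condition,
                 flags = NULL, de = NULL, direction = NULL),
            class = "de_profile")
}

#' Apply the temporal DE rule
#'
#' A gene is DE when `|log2FC| >= log2(fc_cutoff)` at `>= min_timepoints`
#' non-reference time points. The qualifying points need not agree in
#' direction; direction is reported as `up` (all qualifying log2FC > 0),
#' `down` (all < 0) or `mixed`.
#'
#' @param profile a `de_profile` from [log_fold_changes()].
#' @param params a [de_params()]; defaults to the profile's own.
#' @return the profile with `flags` (genes x time logical), `de` (overall
#'   logical), and `direction` filled in.
#' @export
call_temporal_de <- function(profile, params = NULL) {
  stopifnot(inherits(profile, "de_profile"))
  if (is.null(params)) params <- profile$params
  if (ncol(profile$lfc) < params$min_timepoints)
    config_error("profile has %d non-reference time points; min_timepoints is %d",
                 ncol(profile$lfc), params$min_timepoints)
  thr <- log2(params$fc_cutoff)
  flags <- abs(profile$lfc) >= thr
  nhit <- rowSums(flags)
  de <- nhit >= params$min_timepoints
  direction <- rep(NA_character_, nrow(flags))
  pos <- rowSums(flags & profile$lfc > 0)
  neg <- rowSums(flags & profile$lfc < 0)
  direction[de & neg == 0] <- "up"
  direction[de & pos == 0] <- "down"
  direction[de & pos > 0 & neg > 0] <- "mixed"
  profile$flags <- flags
  profile$de <- stats::setNames(de, rownames(flags))
  profile$direction <- stats::setNames(direction, rownames(flags))
  profile$params <- params
  profile
}

#' @export
print.de_profile <- function(x, ...) {
  cat(sprintf("de_profile: %d genes x %d time points (reference %s)\n",
              nrow(x$lfc), ncol(x$lfc), x$reference))
  if (!is.null(x$de))
    cat(sprintf("  DE: %d (up %d, down %d, mixed %d)\n", sum(x$de),
                sum(x$direction == "up", na.rm = TRUE),
                sum(x$direction == "down", na.rm = TRUE),
                sum(x$direction == "mixed", na.rm = TRUE)))
  invisible(x)
}

#' DE genes of a called profile
#' @param profile a called `de_profile`.
#' @param direction optionally restrict to `"up"`, `"down"` or `"mixed"`.
#' @return character vector of gene ids.
#' @export
de_genes <- function(profile, direction = NULL) {
  stopifnot(inherits(profile, "de_profile"), !is.null(profile$de))
  g <- names(profile$de)[profile$de]
  if (!is.null(direction)) g <- g[profile$direction[g] %in% direction]
  g
}

#' Union of DE genes across time points and series
#'
#' For each called profile, reports the per-time-point DE counts (genes
#' meeting the cutoff at that time point) and the across-time union (the
#' overall DE set); also returns the combined union over all series.
#'
#' @param ... called `de_profile` objects, optionally named.
#' @return list with `per_series` (per series: `per_time` counts, `union`
#'   gene vector, `n_union`) and `combined` (union over series).
#' @export
de_union <- function(...) {
  profiles <- list(...)
  if (length(profiles) == 1L && is.list(profiles[[1L]]) &&
      !inherits(profiles[[1L]], "de_profile"))
    profiles <- profiles[[1L]]
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    names(profiles) <- paste0("series", seq_along(profiles))
  per <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "de_profile"), !is.null(p$flags))
    u <- de_genes(p)
    list(per_time = colSums(p$flags), union = u, n_union = length(u))
  })
  combined <- sort(unique(unlist(lapply(per, `[[`, "union"), use.names = FALSE)))
  list(per_series = per, combined = combined)
}

#' Write a called DE profile to TSV
#'
#' @param profile a called `de_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_profile <- function(profile, path) {
  stopifnot(inherits(profile, "de_profile"), !is.null(profile$de))
  con <- file(path, "w")
  on.exit(close(con))
  p <- profile$params
  writeLines(tsv_header_comment(list(fc_cutoff = p$fc_cutoff,
                                     min_timepoints = p$min_timepoints,
                                     pseudocount = p$pseudocount,
                                     reference = profile$reference)), con)
  tp <- colnames(profile$lfc)
  writeLines(paste(c("gene_id", paste0("log2fc_", tp), paste0("de_", tp),
                     "de", "direction"), collapse = "\t"), con)
  body <- cbind(rownames(profile$lfc),
                apply(profile$lfc, 2L, function(v) format(v, digits = 10, trim = TRUE)),
                apply(profile$flags, 2L, as.integer),
                as.integer(profile$de),
                ifelse(is.na(profile$direction), ".", profile$direction))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
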