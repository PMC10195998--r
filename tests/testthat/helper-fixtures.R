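# Small fixtures built in code, shared across test files.

# genes x time matrix with exact fold changes, one replicate per time point
toy_matrix <- function(values, times = NULL, condition = "ctrl") {
  if (is.null(times)) times <- paste0(c(0, 2, 4, 8), "h")[seq_len(ncol(values))]
  timecourse_matrix(values, time = times, condition = condition,
                    replicate = 1L, time_levels = times)
}

# de_profile straight from a log2FC matrix (bypasses expression values)
profile_from_lfc <- function(lfc, params = de_params()) {
  structure(list(lfc = lfc, params = params, reference = "0h",
                 condition = "ctrl", flags = NULL, de = NULL, direction = NULL),
            class = "de_profile")
}

# brute-force half-open interval overlap oracle: O(peaks x windows)
overlap_oracle <- function(peaks, windows) {
  hits <- character()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(windows))) {
      if (peaks$chrom[i] == windows$chrom[j] &&
          peaks$start[i] < windows$end[j] &&
          windows$start[j] < peaks$end[i]) {
        hits <- c(hits, windows$gene_id[j])
      }
    }
  }
  sort(unique(hits))
}

# independently coded GSEA running-sum (direct loop, no shared code path)
es_oracle <- function(metric, members, weight_p) {
  ord <- order(-metric, names(metric), method = "radix")
  m <- metric[ord]
  hit <- names(m) %in% members
  nh <- sum(hit)
  w <- abs(m)^weight_p
  denom <- sum(w[hit])
  rs <- 0; hi <- -Inf; lo <- Inf
  for (i in seq_along(m)) {
    if (hit[i]) rs <- rs + (if (denom > 0) w[i] / denom else 1 / nh)
    else rs <- rs - 1 / (length(m) - nh)
    hi <- max(hi, rs); lo <- min(lo, rs)
  }
  # signed extremum; a magnitude tie resolves to the positive side
  if (hi >= -lo) hi else lo
}

# adjusted Rand index between two labelings over the same names
ari <- function(a, b) {
  shared <- intersect(names(a), names(b))
  mclust::adjustedRandIndex(a[shared], b[shared])
}

# replicate-mean FPKM per time point for one condition (independent of the
# package's own averaging path)
condition_means_for_test <- function(m, cond) {
  out <- sapply(m$time_levels, function(tt) {
    cols <- which(m$samples$time == tt & m$samples$condition == cond)
    rowMeans(m$values[, cols, drop = FALSE])
  })
  rownames(out) <- rownames(m$values)
  out
}

# two disjoint 5-cliques as an edge table
two_cliques_edges <- function() {
  nodes1 <- paste0("A", 1:5); nodes2 <- paste0("B", 1:5)
  p1 <- t(combn(nodes1, 2)); p2 <- t(combn(nodes2, 2))
  data.frame(node_a = c(p1[, 1], p2[, 1]), node_b = c(p1[, 2], p2[, 2]),
             confidence = 0.95, stringsAsFactors = FALSE)
}
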