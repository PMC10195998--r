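## Gene set enrichment: preranked GSEA (weighted Kolmogorov-Smirnov running
## sum with a gene-permutation null) and exact hypergeometric
## overrepresentation with Benjamini-Hochberg control.

#' Build a ranked gene list
#'
#' From a named metric vector or a called `de_profile` (metric = mean log2FC
#' across non-reference time points). Sorted by decreasing metric; ties are
#' broken by gene id so the ranking is deterministic.
#'
#' @param x named numeric vector, or a `de_profile`.
#' @return named numeric vector sorted descending (a `ranked_list`).
#' @export
ranked_list <- function(x) {
  if (inherits(x, "de_profile")) x <- rowMeans(x$lfc)
  if (is.null(names(x)) || anyDuplicated(names(x)))
    config_error("ranking metric must be named with unique gene ids")
  if (any(!is.finite(x))) config_error("ranking metrics must be finite")
  x[order(-x, names(x), method = "radix")]
}

## ES from sorted hit positions; absw = |metric|^p over the ranked list.
## Used for the permutation null (O(k) per permutation).
es_core <- function(pos, absw, n) {
  k <- length(pos)
  whit <- absw[pos]
  W <- sum(whit)
  if (W == 0) { whit <- rep(1 / k, k); W <- 1 }
  cumw <- cumsum(whit) / W
  miss <- (pos - seq_len(k)) / (n - k)
  after <- cumw - miss                 # running sum just after each hit
  before <- c(0, cumw[-k]) - miss      # just before each hit
  hi <- max(after)
  lo <- min(c(before, 0))
  if (hi >= -lo) hi else lo
}

#' GSEA enrichment score with running sum and leading edge
#'
#' The running sum increments by `|metric|^weight_p / sum(|metric|^weight_p)`
#' at genes in the set and decrements by `1 / (N - Nh)` otherwise; the
#' enrichment score is the signed extremum. The leading edge is the subset of
#' hits at or before the extremum (for ES > 0) or at or after it (ES < 0).
#'
#' @param ranked a [ranked_list()].
#' @param gene_set character vector of member gene ids.
#' @param weight_p weighting exponent (0 = classic KS, 1 = weighted; default 1).
#' @return list with `es`, `running_sum` (length N), `leading_edge`,
#'   `size` (overlap with the ranking), and `degenerate` (TRUE when the set
#'   covers the whole ranking). With no overlap, `es` is `NA`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  n <- length(ranked)
  hit <- names(ranked) %in% gene_set
  k <- sum(hit)
  if (k == 0L)
    return(list(es = NA_real_, running_sum = rep(NA_real_, n),
                leading_edge = character(), size = 0L, degenerate = FALSE))
  if (k == n) {
    w <- abs(ranked)^weight_p
    if (sum(w) == 0) w <- rep(1, n)
    return(list(es = 1, running_sum = cumsum(w / sum(w)),
                leading_edge = names(ranked), size = n, degenerate = TRUE))
  }
  w <- abs(ranked)^weight_p
  whit <- w * hit
  W <- sum(whit)
  step_hit <- if (W > 0) whit / W else hit / k
  step_miss <- (!hit) / (n - k)
  rs <- unname(cumsum(step_hit - step_miss))
  imax <- which.max(rs); imin <- which.min(rs)
  es <- if (rs[imax] >= -rs[imin]) rs[imax] else rs[imin]
  le <- if (es >= 0) names(ranked)[seq_len(imax)][hit[seq_len(imax)]]
        else names(ranked)[imin:n][hit[imin:n]]
  list(es = es, running_sum = rs, leading_edge = le, size = k,
       degenerate = FALSE)
}

## Null ES values for one set size by gene-label permutation. Enumerates all
## C(n, k) position subsets when that is no larger than n_perm (exact null);
## otherwise samples n_perm random subsets.
null_es <- function(k, absw, n, n_perm) {
  if (choose(n, k) <= n_perm) {
    combos <- utils::combn(n, k)
    apply(combos, 2L, es_core, absw = absw, n = n)
  } else {
    vapply(seq_len(n_perm),
           function(i) es_core(sort.int(sample.int(n, k)), absw, n),
           numeric(1))
  }
}

#' Preranked GSEA over a gene set collection
#'
#' Null distribution by gene-label permutation preserving set size (exact
#' enumeration when the number of subsets does not exceed `n_perm`).
#' `NES = ES / mean(|null ES| of the same sign)`; the nominal p-value is the
#' fraction of same-sign null ES at least as extreme as the observed; FDR q
#' follows the GSEA convention of pooling normalized null and observed NES
#' separately for the positive and negative sides.
#'
#' @param ranked a [ranked_list()].
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param n_perm permutations per set (>= 100 recommended; fewer warns).
#' @param weight_p running-sum weight exponent, default 1.
#' @param seed integer seed; results are deterministic given it.
#' @return data.frame with one row per set: set, size, es, nes, pval, fdr,
#'   leading_edge (comma-separated); attribute `"leading_edges"` holds the
#'   gene vectors.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000L, weight_p = 1, seed = 1L) {
  n <- length(ranked)
  if (!length(sets)) config_error("no gene sets supplied")
  over <- vapply(sets, function(s) sum(names(ranked) %in% s), integer(1))
  if (any(over > n)) config_error("gene set larger than the ranked universe")
  if (n_perm < 100L)
    warning("n_perm < 100: p-values and FDR will be coarse", call. = FALSE)
  absw <- abs(ranked)^weight_p

  res <- vector("list", length(sets))
  null_by_set <- vector("list", length(sets))
  with_seed(seed, {
    for (i in seq_along(sets)) {
      sc <- enrichment_score(ranked, sets[[i]], weight_p)
      if (sc$size == 0L || sc$degenerate) {
        res[[i]] <- data.frame(set = names(sets)[i], size = sc$size,
                               es = sc$es, nes = NA_real_, pval = NA_real_,
                               fdr = NA_real_,
                               leading_edge = paste(sc$leading_edge, collapse = ","),
                               stringsAsFactors = FALSE)
        null_by_set[[i]] <- numeric()
        next
      }
      nulls <- null_es(sc$size, absw, n, n_perm)
      pos_mean <- mean(nulls[nulls >= 0])
      neg_mean <- mean(abs(nulls[nulls < 0]))
      norm_null <- ifelse(nulls >= 0,
                          nulls / pos_mean,
                          nulls / neg_mean)
      norm_null[!is.finite(norm_null)] <- NA_real_
      if (sc$es >= 0) {
        den <- sum(nulls >= 0)
        p <- if (den > 0) sum(nulls >= sc$es) / den else 1 / length(nulls)
        nes <- if (is.finite(pos_mean) && pos_mean > 0) sc$es / pos_mean else NA_real_
      } else {
        den <- sum(nulls < 0)
        p <- if (den > 0) sum(nulls <= sc$es) / den else 1 / length(nulls)
        nes <- if (is.finite(neg_mean) && neg_mean > 0) sc$es / neg_mean else NA_real_
      }
      res[[i]] <- data.frame(set = names(sets)[i], size = sc$size, es = sc$es,
                             nes = nes, pval = p, fdr = NA_real_,
                             leading_edge = paste(sc$leading_edge, collapse = ","),
                             stringsAsFactors = FALSE)
      null_by_set[[i]] <- norm_null[is.finite(norm_null)]
    }
  })
  out <- do.call(rbind, res)
  out$fdr <- gsea_fdr(out$nes, null_by_set)
  le <- strsplit(out$leading_edge, ",", fixed = TRUE)
  names(le) <- out$set
  attr(out, "leading_edges") <- le
  rownames(out) <- NULL
  out
}

## GSEA-style FDR: pooled normalized null NES vs observed NES, per sign.
gsea_fdr <- function(nes, null_by_set) {
  pool <- unlist(null_by_set, use.names = FALSE)
  q <- rep(NA_real_, length(nes))
  ok <- is.finite(nes)
  for (i in which(ok)) {
    x <- nes[i]
    if (x >= 0) {
      null_frac <- if (any(pool >= 0)) sum(pool >= x) / sum(pool >= 0) else 1
      obs_frac <- sum(nes[ok] >= x & nes[ok] >= 0) / max(1, sum(nes[ok] >= 0))
    } else {
      null_frac <- if (any(pool < 0)) sum(pool <= x) / sum(pool < 0) else 1
      obs_frac <- sum(nes[ok] <= x & nes[ok] < 0) / max(1, sum(nes[ok] < 0))
    }
    q[i] <- min(1, null_frac / max(obs_frac, .Machine$double.eps))
  }
  ## enforce monotonicity within each sign by |NES|
  for (sgn in c(1, -1)) {
    idx <- which(ok & sign(nes) * sgn >= 0 & (sgn > 0 | nes < 0))
    if (sgn > 0) idx <- which(ok & nes >= 0)
    if (length(idx) > 1L) {
      o <- order(-abs(nes[idx]))
      q[idx[o]] <- cummax(q[idx[o]])
    }
  }
  q
}

#' Hypergeometric overrepresentation analysis
#'
#' Upper-tail hypergeometric test of a query gene set against each collection
#' member, within a stated universe, with Benjamini-Hochberg correction
#' across sets.
#'
#' @param query character vector of query gene ids (must lie in `universe`).
#' @param sets named list of gene sets.
#' @param universe character vector of background gene ids.
#' @return data.frame with set, k (overlap), K (set size in universe),
#'   n (query size), N (universe size), pval, qval, overlap_genes.
#' @export
hypergeom_ora <- function(query, sets, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0L) config_error("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside))
    config_error("query gene(s) outside universe: %s",
                 paste(utils::head(outside, 5L), collapse = ", "))
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    K <- length(intersect(sets[[nm]], universe))
    ov <- intersect(sets[[nm]], query)
    k <- length(ov)
    p <- if (K == 0L) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, pval = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qval <- stats::p.adjust(out$pval, method = "BH")
  out <- out[, c("set", "k", "K", "n", "N", "pval", "qval", "overlap_genes")]
  rownames(out) <- NULL
  out
}
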