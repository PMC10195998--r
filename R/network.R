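## Confidence-thresholded interaction networks over DE-gene unions:
## module detection by greedy modularity maximization and cross-series
## module conservation.

#' Network construction parameters
#'
#' @param confidence_threshold minimum edge confidence retained, in \[0, 1\]
#'   (0.9 for TF networks, 0.7 for TF-target networks by convention).
#' @param min_component_size connected components smaller than this are
#'   dropped (default 3).
#' @return a `network_params` list.
#' @export
network_params <- function(confidence_threshold = 0.9, min_component_size = 3L) {
  if (!is_prob(confidence_threshold))
    config_error("confidence_threshold must lie in [0,1]")
  if (!is_count(min_component_size, 1L))
    config_error("min_component_size must be a count >= 1")
  structure(list(confidence_threshold = confidence_threshold,
                 min_component_size = as.integer(min_component_size)),
            class = "network_params")
}

#' Build a confidence-thresholded network over a gene set
#'
#' Induces the subgraph on `nodes`, keeps edges with confidence >= threshold,
#' drops isolated nodes, and drops connected components smaller than
#' `min_component_size` (counts are recorded as graph attributes).
#'
#' @param edges edge table (node_a, node_b, confidence), see [read_edges()].
#' @param nodes character vector of gene ids (e.g. a DE union).
#' @param params a [network_params()].
#' @return an [igraph::graph] (possibly empty).
#' @export
build_network <- function(edges, nodes, params = network_params()) {
  if (!length(nodes)) config_error("empty node set")
  keep <- edges$confidence >= params$confidence_threshold &
    edges$node_a %in% nodes & edges$node_b %in% nodes
  el <- edges[keep, c("node_a", "node_b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = sort(unique(nodes))))
  deg <- igraph::degree(g)
  g <- igraph::delete_vertices(g, names(deg)[deg == 0])
  comp <- igraph::components(g)
  small <- which(comp$csize < params$min_component_size)
  n_small <- length(small)
  if (n_small) {
    drop <- names(comp$membership)[comp$membership %in% small]
    g <- igraph::delete_vertices(g, drop)
  }
  g <- igraph::set_graph_attr(g, "n_small_components_dropped", n_small)
  g <- igraph::set_graph_attr(g, "confidence_threshold", params$confidence_threshold)
  g
}

#' Detect network modules by greedy modularity maximization
#'
#' Agglomerative (fast-greedy) modularity maximization; the achieved
#' Newman-Girvan modularity Q is reported and recomputable from the
#' partition via [recompute_modularity()]. Edge confidences are used only
#' for thresholding, never as modularity weights.
#'
#' @param graph an [igraph::graph] with at least one edge.
#' @param seed integer seed (the greedy merge order is deterministic; the
#'   seed is fixed for reproducibility of any tie-broken order).
#' @return a `module_partition`: list with `membership` (named integer
#'   vector), `modularity`, `modules` (per-module gene lists), `graph`.
#' @export
detect_modules <- function(graph, seed = 1L) {
  if (igraph::ecount(graph) == 0L)
    config_error("graph has no edges; lower the confidence threshold")
  cl <- with_seed(seed, igraph::cluster_fast_greedy(graph))
  ## cut the merge dendrogram at the modularity maximum ourselves: the
  ## default membership can miss the final all-merged step (e.g. complete
  ## graphs, where the one-module partition with Q = 0 is optimal)
  mod_seq <- cl$modularity
  best <- which.max(round(mod_seq, 12L))
  n_comm <- igraph::vcount(graph) - (best - 1L)
  membership <- igraph::cut_at(cl, no = n_comm)
  names(membership) <- igraph::V(graph)$name
  q <- igraph::modularity(graph, membership)
  mods <- split(names(membership), membership)
  names(mods) <- paste0("M", names(mods))
  structure(list(membership = stats::setNames(as.integer(membership),
                                              names(membership)),
                 modularity = q, modules = mods, graph = graph),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d nodes in %d modules, Q = %.4f\n",
              length(x$membership), length(x$modules), x$modularity))
  invisible(x)
}

#' Recompute Newman-Girvan modularity of a partition
#'
#' Direct evaluation of `Q = sum_c (e_c / m - (d_c / 2m)^2)` where `e_c` is
#' the number of within-module edges, `d_c` the module degree sum and `m`
#' the edge count; independent of the detection path.
#'
#' @param graph an [igraph::graph].
#' @param membership named module assignment over the graph's vertices.
#' @return modularity Q.
#' @export
recompute_modularity <- function(graph, membership) {
  el <- igraph::as_edgelist(graph)
  m <- nrow(el)
  if (m == 0L) return(0)
  mem <- membership[igraph::V(graph)$name]
  ma <- membership[el[, 1L]]; mb <- membership[el[, 2L]]
  deg <- igraph::degree(graph)
  q <- 0
  for (c in unique(mem)) {
    e_c <- sum(ma == c & mb == c)
    d_c <- sum(deg[mem == c])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

#' Annotate modules with enrichment and mean fold change
#'
#' Labels each module with its top overrepresented gene set (hypergeometric,
#' BH-corrected within module, universe = all partition nodes unless given)
#' and attaches per-node mean log2 fold change across time from a called DE
#' profile.
#'
#' @param partition a `module_partition`.
#' @param de a called `de_profile` (optional; supplies mean fold changes).
#' @param gene_sets named list of gene sets (optional).
#' @param universe background genes for enrichment; default partition nodes.
#' @return the partition with `annotation` (per-module data.frame: module,
#'   size, label, pval, qval, mean_lfc) and `node_mean_lfc` added.
#' @export
annotate_modules <- function(partition, de = NULL, gene_sets = NULL,
                             universe = NULL) {
  stopifnot(inherits(partition, "module_partition"))
  nodes <- names(partition$membership)
  if (is.null(universe)) universe <- nodes
  mean_lfc <- if (!is.null(de)) {
    ml <- rowMeans(de$lfc)
    stats::setNames(ml[match(nodes, names(ml))], nodes)
  } else stats::setNames(rep(NA_real_, length(nodes)), nodes)
  rows <- lapply(names(partition$modules), function(mn) {
    members <- partition$modules[[mn]]
    label <- "unannotated"; p <- NA_real_; q <- NA_real_
    if (!is.null(gene_sets) && length(gene_sets)) {
      ora <- hypergeom_ora(intersect(members, universe), gene_sets, universe)
      ora <- ora[ora$k > 0, , drop = FALSE]
      if (nrow(ora)) {
        best <- ora[order(ora$pval, ora$set), ][1L, ]
        label <- best$set; p <- best$pval; q <- best$qval
      }
    }
    data.frame(module = mn, size = length(members), label = label,
               pval = p, qval = q,
               mean_lfc = mean(mean_lfc[members], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  partition$annotation <- do.call(rbind, rows)
  partition$node_mean_lfc <- mean_lfc
  partition
}

#' Module conservation between two partitions
#'
#' Greedy maximum-Jaccard matching between the modules of two partitions on
#' their shared gene universe: repeatedly pairs the remaining modules with
#' the highest Jaccard index (ties broken by module name), reporting shared,
#' gained and lost genes per matched pair.
#'
#' @param p1,p2 `module_partition` objects with overlapping gene universes.
#' @return data.frame: module_1, module_2, jaccard, n_shared, n_gained,
#'   n_lost (gained/lost relative to module_1), plus attribute
#'   `"unmatched"` listing modules left unpaired.
#' @export
module_conservation <- function(p1, p2) {
  stopifnot(inherits(p1, "module_partition"), inherits(p2, "module_partition"))
  shared <- intersect(names(p1$membership), names(p2$membership))
  if (!length(shared)) config_error("partitions have disjoint gene universes")
  m1 <- lapply(p1$modules, intersect, shared)
  m2 <- lapply(p2$modules, intersect, shared)
  m1 <- m1[lengths(m1) > 0]; m2 <- m2[lengths(m2) > 0]
  jac <- outer(seq_along(m1), seq_along(m2),
               Vectorize(function(i, j) {
                 length(intersect(m1[[i]], m2[[j]])) /
                   length(union(m1[[i]], m2[[j]]))
               }))
  dimnames(jac) <- list(names(m1), names(m2))
  rows <- list()
  while (nrow(jac) && ncol(jac) && max(jac) > 0) {
    idx <- which(jac == max(jac), arr.ind = TRUE)
    idx <- idx[order(rownames(jac)[idx[, 1]], colnames(jac)[idx[, 2]]), ,
               drop = FALSE][1L, ]
    a <- rownames(jac)[idx[1L]]; b <- colnames(jac)[idx[2L]]
    inter <- intersect(m1[[a]], m2[[b]])
    rows[[length(rows) + 1L]] <-
      data.frame(module_1 = a, module_2 = b, jaccard = jac[idx[1L], idx[2L]],
                 n_shared = length(inter),
                 n_gained = length(setdiff(m2[[b]], m1[[a]])),
                 n_lost = length(setdiff(m1[[a]], m2[[b]])),
                 stringsAsFactors = FALSE)
    jac <- jac[-idx[1L], -idx[2L], drop = FALSE]
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(module_1 = character(), module_2 = character(),
                         jaccard = numeric(), n_shared = integer(),
                         n_gained = integer(), n_lost = integer())
  attr(out, "unmatched") <- list(p1 = rownames(jac), p2 = colnames(jac))
  out
}

#' Write a module partition to TSV
#' @param partition a `module_partition` (optionally annotated).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header_comment(list(modularity = sprintf("%.6f", partition$modularity))),
             con)
  writeLines("gene_id\tmodule\tmean_lfc", con)
  genes <- names(partition$membership)
  ml <- partition$node_mean_lfc
  if (is.null(ml)) ml <- stats::setNames(rep(NA_real_, length(genes)), genes)
  writeLines(sprintf("%s\tM%d\t%s", genes, partition$membership[genes],
                     ifelse(is.na(ml[genes]), "NA",
                            format(ml[genes], digits = 8, trim = TRUE))), con)
  invisible(path)
}
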