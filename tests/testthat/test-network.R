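test_that("build_network filters by confidence and component size", {
  edges <- data.frame(node_a = c("a", "b", "x"), node_b = c("b", "c", "y"),
                      confidence = c(0.95, 0.8, 0.95))
  nodes <- c("a", "b", "c", "x", "y", "lonely")
  # threshold 1.0 with all confidences below it: empty graph
  g0 <- build_network(edges, nodes, network_params(1.0, 1))
  expect_equal(igraph::vcount(g0), 0)
  # threshold 0: every edge among the nodes survives
  g1 <- build_network(edges, nodes, network_params(0, 1))
  expect_equal(igraph::ecount(g1), 3)
  # min_component_size drops the 2-node x-y component
  g2 <- build_network(edges, nodes, network_params(0.7, 3))
  expect_setequal(igraph::V(g2)$name, c("a", "b", "c"))
  expect_equal(igraph::graph_attr(g2, "n_small_components_dropped"), 1)
})

test_that("retained edges equal a brute-force confidence filter", {
  set.seed(17)
  nodes <- sprintf("n%02d", 1:30)
  pairs <- t(combn(nodes, 2))
  sel <- sample(nrow(pairs), 150)
  edges <- data.frame(node_a = pairs[sel, 1], node_b = pairs[sel, 2],
                      confidence = runif(150))
  thr <- 0.6
  g <- build_network(edges, nodes, network_params(thr, 1))
  got <- igraph::as_edgelist(g)
  got_keys <- sort(paste(pmin(got[, 1], got[, 2]), pmax(got[, 1], got[, 2])))
  want <- edges[edges$confidence >= thr, ]
  want_keys <- sort(paste(pmin(want$node_a, want$node_b),
                          pmax(want$node_a, want$node_b)))
  expect_identical(got_keys, want_keys)

  # raising the threshold never adds edges
  g_hi <- build_network(edges, nodes, network_params(0.8, 1))
  hi <- igraph::as_edgelist(g_hi)
  hi_keys <- paste(pmin(hi[, 1], hi[, 2]), pmax(hi[, 1], hi[, 2]))
  expect_true(all(hi_keys %in% got_keys))
})

test_that("two disjoint 5-cliques give two modules with Q exactly 0.5", {
  g <- build_network(two_cliques_edges(), c(paste0("A", 1:5), paste0("B", 1:5)),
                     network_params(0.9, 3))
  part <- detect_modules(g, seed = 1)
  expect_equal(length(part$modules), 2)
  expect_setequal(part$modules[[1]], paste0(substr(part$modules[[1]][1], 1, 1), 1:5))
  expect_equal(part$modularity, 0.5)
  # hand enumeration: 2 equal cliques, within-fraction 1/2 each, degree
  # fraction 1/2 each -> Q = 2 * (1/2 - 1/4) = 1/2
  expect_equal(recompute_modularity(g, part$membership), 0.5)
})

test_that("complete graphs carry no community structure", {
  nodes <- paste0("k", 1:6)
  pairs <- t(combn(nodes, 2))
  edges <- data.frame(node_a = pairs[, 1], node_b = pairs[, 2], confidence = 1)
  part <- detect_modules(build_network(edges, nodes, network_params(0.5, 3)))
  expect_equal(length(part$modules), 1)
  expect_equal(part$modularity, 0)
})

test_that("reported Q is recomputable and invariant to node relabeling", {
  cfg <- sim_config(n_genes = 100, n_de_genes = 0, n_modules = 3,
                    p_within = 0.4, p_between = 0.05, seed = 19)
  sim <- generate_ppi_edges(cfg, nodes = sprintf("n%02d", 1:60))
  g <- build_network(sim$edges, sprintf("n%02d", 1:60), network_params(0.7, 3))
  part <- detect_modules(g, seed = 4)
  expect_equal(recompute_modularity(g, part$membership), part$modularity,
               tolerance = 1e-12)

  # relabel nodes: same partition structure up to module id permutation
  relabel <- setNames(sprintf("m%02d", 60:1), sprintf("n%02d", 1:60))
  edges2 <- data.frame(node_a = relabel[sim$edges$node_a],
                       node_b = relabel[sim$edges$node_b],
                       confidence = sim$edges$confidence)
  g2 <- build_network(edges2, unname(relabel), network_params(0.7, 3))
  part2 <- detect_modules(g2, seed = 4)
  m1 <- part$membership
  m2 <- setNames(part2$membership[relabel[names(m1)]], names(m1))
  expect_equal(ari(m1, m2), 1)

  expect_error(detect_modules(build_network(sim$edges, c("zz1", "zz2"),
                                            network_params(0.7, 1))),
               "threshold")
})

test_that("planted two-block graphs are recovered with ARI >= 0.9 over seeds", {
  aris <- vapply(1:10, function(s) {
    cfg <- sim_config(n_genes = 100, n_de_genes = 0, n_modules = 2,
                      p_within = 0.3, p_between = 0.01, seed = s)
    nodes <- sprintf("v%02d", 1:60)
    sim <- generate_ppi_edges(cfg, nodes = nodes)
    g <- build_network(sim$edges, nodes, network_params(0.7, 3))
    part <- detect_modules(g, seed = s)
    ari(part$membership, sim$truth)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("module annotation picks the uniquely matching set and flags orphans", {
  edges <- two_cliques_edges()
  g <- build_network(edges, unique(c(edges$node_a, edges$node_b)),
                     network_params(0.9, 3))
  part <- detect_modules(g)
  sets <- list(cliqueA = paste0("A", 1:5), unrelated = c("z1", "z2", "z3"))
  ann <- annotate_modules(part, gene_sets = sets,
                          universe = c(names(part$membership), "z1", "z2", "z3"))
  lab <- setNames(ann$annotation$label, ann$annotation$module)
  a_mod <- names(which(vapply(part$modules, function(m) "A1" %in% m, logical(1))))
  b_mod <- setdiff(names(part$modules), a_mod)
  expect_equal(unname(lab[a_mod]), "cliqueA")
  expect_equal(unname(lab[b_mod]), "unannotated")
  # enrichment p agrees with the exact hypergeometric tail sum
  K <- 5; N <- 13; n <- 5; k <- 5
  exact <- sum(vapply(k:min(K, n), function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
  expect_equal(ann$annotation$pval[ann$annotation$module == a_mod], exact)
})

test_that("module conservation reports Jaccard-matched pairs", {
  edges <- two_cliques_edges()
  g <- build_network(edges, unique(c(edges$node_a, edges$node_b)),
                     network_params(0.9, 3))
  p1 <- detect_modules(g)
  cons <- module_conservation(p1, p1)
  expect_equal(cons$jaccard, c(1, 1))
  expect_equal(cons$n_gained, c(0, 0))

  # 20% membership turnover: Jaccard of matched pair = |A int B| / |A un B|
  p2 <- p1
  p2$modules <- list(M1 = c(paste0("A", 1:4), "B5"),
                     M2 = c(paste0("B", 1:4), "A5"))
  p2$membership <- setNames(c(rep(1L, 4), 2L, rep(2L, 4), 1L),
                            c(paste0("A", 1:5), paste0("B", 1:5)))
  cons2 <- module_conservation(p1, p2)
  expect_equal(sort(cons2$jaccard), c(4 / 6, 4 / 6))

  p3 <- p1; p3$membership <- setNames(1:2, c("q1", "q2"))
  p3$modules <- list(M1 = "q1", M2 = "q2")
  expect_error(module_conservation(p1, p3), "disjoint")
})
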