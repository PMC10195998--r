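test_that("enrichment score matches hand-forced cases", {
  # set occupying the top 2 of 4 ranks, unweighted: running sum reaches 1
  ranked <- ranked_list(c(a = 4, b = 3, c = 2, d = 1))
  sc <- enrichment_score(ranked, c("a", "b"), weight_p = 0)
  expect_equal(sc$es, 1)
  expect_equal(sc$leading_edge, c("a", "b"))

  # the whole universe as a set is degenerate with ES 1
  all_ <- enrichment_score(ranked, letters[1:4], weight_p = 1)
  expect_equal(all_$es, 1)
  expect_true(all_$degenerate)

  # no overlap gives a defined-empty result
  none <- enrichment_score(ranked, c("zz"), weight_p = 1)
  expect_true(is.na(none$es))
})

test_that("enrichment score equals independent implementations", {
  set.seed(21)
  metric <- setNames(rnorm(20), sprintf("g%02d", 1:20))
  ranked <- ranked_list(metric)
  for (i in 1:10) {
    members <- sample(names(metric), 5)
    for (p in c(0, 1)) {
      got <- enrichment_score(ranked, members, weight_p = p)$es
      expect_equal(got, es_oracle(metric, members, p))
    }
    # fgsea's gseaParam = 1 corresponds to weight_p = 1
    fes <- fgsea::calcGseaStat(unname(ranked),
                               which(names(ranked) %in% members),
                               gseaParam = 1)
    expect_equal(enrichment_score(ranked, members, 1)$es, fes,
                 tolerance = 1e-10)
  }
})

test_that("ES is scale invariant at weight 0/1 and negates under list reversal", {
  set.seed(31)
  metric <- setNames(rnorm(30), sprintf("g%02d", 1:30))
  members <- sample(names(metric), 6)
  for (p in c(0, 1)) {
    a <- enrichment_score(ranked_list(metric), members, p)$es
    b <- enrichment_score(ranked_list(metric * 3.7), members, p)$es
    expect_equal(a, b)
  }
  # a strictly reversed ranking flips the extremum
  rev_metric <- -metric
  a <- enrichment_score(ranked_list(metric), members, 0)$es
  b <- enrichment_score(ranked_list(rev_metric), members, 0)$es
  expect_equal(a, -b, tolerance = 1e-12)
})

test_that("exhaustive permutation p equals the enumeration fraction on C(6,2)", {
  metric <- setNames(c(3.1, 2.5, 1.1, 0.4, -0.9, -2.2), letters[1:6])
  ranked <- ranked_list(metric)
  members <- c("a", "c")
  res <- gsea_preranked(ranked, list(s = members), n_perm = 100, weight_p = 1,
                        seed = 1)
  combos <- combn(names(metric), 2)
  null_es <- apply(combos, 2, function(g) es_oracle(metric, g, 1))
  obs <- es_oracle(metric, members, 1)
  expected_p <- if (obs >= 0) sum(null_es[null_es >= 0] >= obs) / sum(null_es >= 0)
                else sum(null_es[null_es < 0] <= obs) / sum(null_es < 0)
  expect_equal(res$pval, expected_p)
  expect_equal(sign(res$nes), sign(res$es))
  expect_lte(abs(res$es), 1)
})

test_that("nominal p is uniform under exchangeable metrics (KS, alpha 0.01)", {
  set.seed(77)
  metric <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  ranked <- ranked_list(metric)
  sets <- lapply(1:1000, function(i) sample(names(metric), 10))
  names(sets) <- sprintf("rs%04d", 1:1000)
  res <- gsea_preranked(ranked, sets, n_perm = 200, weight_p = 1, seed = 3)
  ks <- suppressWarnings(stats::ks.test(res$pval, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a set planted at the top of a large ranking is significant", {
  set.seed(55)
  n <- 5000
  metric <- sort(rnorm(n), decreasing = TRUE)
  names(metric) <- sprintf("g%04d", 1:n)
  planted <- sample(names(metric)[1:250], 40)  # concentrated in top 5%
  sets <- c(list(planted = planted),
            lapply(setNames(1:5, paste0("rand", 1:5)),
                   function(i) sample(names(metric), 40)))
  res <- gsea_preranked(ranked_list(metric), sets, n_perm = 1000, weight_p = 1,
                        seed = 9)
  expect_lt(res$fdr[res$set == "planted"], 0.05)
})

test_that("hypergeometric ORA matches the closed form and Monte-Carlo tails", {
  sets <- list(s = letters[1:5])
  # N=10, K=5, n=5, k=5 -> 1 / C(10,5) = 1/252
  r <- hypergeom_ora(letters[1:5], sets, letters[1:10])
  expect_equal(r$pval, 1 / 252)
  # query = set = universe -> p = 1
  r2 <- hypergeom_ora(letters[1:5], sets, letters[1:5])
  expect_equal(r2$pval, 1)
  expect_error(hypergeom_ora("a", sets, character()), "universe")
  expect_error(hypergeom_ora("zz", sets, letters[1:10]), "outside")

  # empirical tail frequency of overlap >= k matches the reported p
  set.seed(12)
  universe <- sprintf("u%03d", 1:60)
  K_set <- list(s = universe[1:12])
  k_obs <- 5; n_q <- 15
  p <- hypergeom_ora(c(universe[1:k_obs], universe[13:(13 + n_q - k_obs - 1)]),
                     K_set, universe)$pval
  sim <- mean(replicate(4000, {
    length(intersect(sample(universe, n_q), K_set$s)) >= k_obs
  }))
  expect_lt(abs(sim - p), 4 * sqrt(p * (1 - p) / 4000))
})

test_that("BH q-values are monotone in p after sorting", {
  set.seed(8)
  universe <- sprintf("u%03d", 1:100)
  sets <- lapply(setNames(1:20, paste0("s", 1:20)),
                 function(i) sample(universe, sample(5:20, 1)))
  r <- hypergeom_ora(sample(universe, 25), sets, universe)
  o <- order(r$pval)
  expect_true(all(diff(r$qval[o]) >= -1e-12))
})
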