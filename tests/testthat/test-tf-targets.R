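make_models <- function(gene_id, chrom, strand, tss) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("gene_id\tchrom\tstrand\ttss",
               sprintf("%s\t%s\t%s\t%d", gene_id, chrom, strand, tss)), f)
  read_tss(f)
}

test_that("promoter windows are strand-reflected and clipped at zero", {
  models <- make_models(c("plus", "minus", "edge"), "chr1", c("+", "-", "+"),
                        c(10000L, 10000L, 100L))
  w <- promoter_windows(models, promoter_params(2000, 500))
  expect_equal(unlist(w[w$gene_id == "plus", c("start", "end")], use.names = FALSE),
               c(8000, 10500))
  expect_equal(unlist(w[w$gene_id == "minus", c("start", "end")], use.names = FALSE),
               c(9501, 12001))
  expect_equal(unlist(w[w$gene_id == "edge", c("start", "end")], use.names = FALSE),
               c(0, 600))
})

test_that("peak-to-gene assignment honours half-open overlap boundaries", {
  models <- make_models("g", "chr1", "+", 10000L)
  w <- promoter_windows(models)
  inside <- peak_set("chr1", 9990, 10010)
  expect_identical(assign_peaks_to_genes(inside, w), "g")
  # window is [8000, 10500): a peak starting at 10500 does not touch it
  boundary <- peak_set("chr1", 10500, 10600)
  expect_identical(assign_peaks_to_genes(boundary, w), character())
  # ...but a peak ending at 8001 overlaps by 1 bp
  onebp <- peak_set("chr1", 7900, 8001)
  expect_identical(assign_peaks_to_genes(onebp, w), "g")
})

test_that("interval-index assignment equals the nested-loop oracle", {
  set.seed(23)
  n_genes <- 200
  models <- make_models(sprintf("g%03d", 1:n_genes),
                        sample(paste0("chr", 1:3), n_genes, replace = TRUE),
                        sample(c("+", "-"), n_genes, replace = TRUE),
                        sample.int(2e6, n_genes))
  w <- promoter_windows(models)
  start <- sample.int(2e6, 1000)
  peaks <- peak_set(sample(paste0("chr", 1:3), 1000, replace = TRUE),
                    start, start + sample(50:2000, 1000, replace = TRUE))
  expect_identical(assign_peaks_to_genes(peaks, w), overlap_oracle(peaks, w))
})

test_that("assignment is permutation-invariant and warns on unknown chromosomes", {
  set.seed(5)
  models <- make_models(sprintf("g%02d", 1:20), "chr1", "+",
                        as.integer(seq(10000, 400000, length.out = 20)))
  w <- promoter_windows(models)
  start <- sample.int(4e5, 100)
  peaks <- peak_set("chr1", start, start + 300)
  shuffled <- peaks[sample(nrow(peaks)), ]
  expect_identical(assign_peaks_to_genes(peaks, w),
                   assign_peaks_to_genes(peak_set(shuffled$chrom, shuffled$start,
                                                  shuffled$end), w))
  stray <- peak_set(c("chr1", "chrUn"), c(9000, 100), c(9500, 400))
  expect_warning(got <- assign_peaks_to_genes(stray, w), "chrUn")
  expect_identical(got, "g01")
})

test_that("mirror-image coordinates with flipped strands give the same targets", {
  set.seed(11)
  n <- 50; L <- 1e6
  tss <- sample.int(L - 20000, n) + 10000
  strand <- sample(c("+", "-"), n, replace = TRUE)
  models <- make_models(sprintf("g%02d", 1:n), "chr1", strand, tss)
  flip <- c("+" = "-", "-" = "+")
  mirror_models <- make_models(sprintf("g%02d", 1:n), "chr1", flip[strand],
                               as.integer(L - tss))
  start <- sample.int(L, 300)
  peaks <- peak_set("chr1", start, start + 200)
  mirror_peaks <- peak_set("chr1", L - (start + 200), L - start)
  expect_identical(
    assign_peaks_to_genes(peaks, promoter_windows(models)),
    assign_peaks_to_genes(mirror_peaks, promoter_windows(mirror_models)))
})

test_that("widening the promoter window never loses targets", {
  set.seed(3)
  models <- make_models(sprintf("g%02d", 1:30), "chr1",
                        sample(c("+", "-"), 30, replace = TRUE),
                        sample.int(1e6, 30))
  start <- sample.int(1e6, 200)
  peaks <- peak_set("chr1", start, start + 150)
  narrow <- assign_peaks_to_genes(peaks, promoter_windows(models, promoter_params(500, 100)))
  wide <- assign_peaks_to_genes(peaks, promoter_windows(models, promoter_params(5000, 1000)))
  expect_true(all(narrow %in% wide))
})

test_that("stage subtraction and DE intersection are exact set algebra", {
  map <- tf_target_map(list(OTX2 = list(`0h` = c("b"), `120h` = c("a", "b", "c"))))
  expect_identical(stage_specific_targets(map, "OTX2", "120h", "0h"), c("a", "c"))
  map2 <- tf_target_map(list(OTX2 = list(`0h` = c("a", "b"), `120h` = c("a", "b"))))
  expect_identical(stage_specific_targets(map2, "OTX2", "120h", "0h"), character())
  expect_error(stage_specific_targets(map, "OTX2", "120h", "48h"), "0h")

  expect_identical(intersect_with_de(c("a", "b"), c("c", "d"))$genes, character())
  r <- intersect_with_de(c("a", "b"), c("a", "b", "z"))
  expect_identical(r$genes, c("a", "b"))
  expect_equal(r$n_intersect, 2)
})

test_that("random-set DE intersections match the hypergeometric expectation", {
  set.seed(99)
  universe <- sprintf("u%05d", 1:20000)
  sizes <- replicate(40, {
    t_ <- sample(universe, 1623); d_ <- sample(universe, 3893)
    intersect_with_de(t_, d_)$n_intersect
  })
  expected <- 1623 * 3893 / 20000
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - expected), 4 * se + 1)
})
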