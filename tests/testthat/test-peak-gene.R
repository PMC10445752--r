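# Peak-to-gene association, peak-count summaries and ORA.

test_that("nearest gene: containment, gaps, ties", {
  genes <- gene_table(c("gA", "gB"), "chr1", "+", c(150, 300), c(250, 400))
  pk <- peak_set("chr1", 100, 200, "p1")
  ln <- nearest_gene(pk, genes)
  expect_equal(ln$gene_id, "gA")          # tss 150 inside the peak
  expect_equal(ln$distance, 0L)

  genes2 <- gene_table(c("gA", "gB"), "chr1", "+", c(300, 350), c(400, 450))
  ln2 <- nearest_gene(pk, genes2)
  expect_equal(ln2$gene_id, "gA")
  expect_equal(abs(ln2$distance), 100L)   # gap from the end coordinate

  # equidistant TSSs at start-100 and end+100: lexicographic, flagged
  genes3 <- gene_table(c("gZ", "gA"), "chr1", "+", c(0, 300), c(120, 400))
  ln3 <- nearest_gene(pk, genes3)
  expect_equal(ln3$gene_id, "gA")
  expect_true(ln3$tie)

  # peaks on chromosomes without genes are unassigned
  pk2 <- peak_set(c("chr1", "chrX"), c(100, 100), c(200, 200), c("a", "b"))
  expect_equal(nearest_gene(pk2, genes)$peak_id, "a")
})

test_that("signed distances are strand-aware (upstream negative)", {
  pk <- peak_set("chr1", 100, 200, "p1")
  plus_down <- gene_table("g", "chr1", "+", 500, 800)    # peak upstream
  expect_lt(nearest_gene(pk, plus_down)$distance, 0)
  minus_down <- gene_table("g", "chr1", "-", 500, 800)   # tss 799, peak downstream side
  expect_gt(nearest_gene(pk, minus_down)$distance, 0)
})

test_that("capped association drops far peaks", {
  pk <- peak_set("chr1", 100, 200, "p1")
  far <- gene_table("g", "chr1", "+", 200 + 999999L, 200 + 1100000L)
  expect_equal(nrow(great_nearest_gene(pk, far)), 1L)
  far2 <- gene_table("g", "chr1", "+", 200 + 1000001L, 200 + 1100000L)
  expect_equal(nrow(great_nearest_gene(pk, far2)), 0L)
  none <- gene_table(character(0), character(0), character(0),
                     integer(0), integer(0))
  expect_equal(nrow(great_nearest_gene(pk, none)), 0L)
})

test_that("nearest gene agrees with the brute-force scan", {
  set.seed(12)
  for (rep in 1:100) {
    pk <- random_peak_set(sample(1:8, 1), "p", max_pos = 400)
    ng <- sample(1:6, 1)
    st <- sample.int(400, ng, replace = TRUE)
    genes <- gene_table(paste0("g", sample(ng)), sample(c("c1", "c2"), ng,
                                                        replace = TRUE),
                        sample(c("+", "-"), ng, replace = TRUE),
                        st, st + sample.int(50, ng, replace = TRUE))
    got <- nearest_gene(pk, genes)
    want <- oracle_nearest_gene(pk, genes)
    expect_equal(nrow(got), length(want))
    for (i in seq_len(nrow(got))) {
      w <- want[[got$peak_id[i]]]
      expect_equal(got$gene_id[i], w$gene)
      expect_equal(abs(got$distance[i]), w$mag)
    }
  }
})

test_that("uncapped association equals the capped one at infinity", {
  set.seed(13)
  pk <- random_peak_set(20, "p", max_pos = 400)
  st <- sample.int(400, 10)
  genes <- gene_table(paste0("g", 1:10), sample(c("c1", "c2"), 10, TRUE),
                      sample(c("+", "-"), 10, TRUE), st, st + 30L)
  a <- nearest_gene(pk, genes)
  b <- great_nearest_gene(pk, genes, max_dist = Inf)
  expect_equal(a[, c("peak_id", "gene_id", "distance")],
               b[, c("peak_id", "gene_id", "distance")])
})

test_that("distal fraction uses a strict cutoff", {
  links <- data.frame(peak_id = paste0("p", 1:4), gene_id = "g",
                      distance = c(0, 6000, -10000, 1000))
  expect_equal(distal_fraction(links), 0.5)
  expect_equal(distal_fraction(data.frame(distance = 5000)), 0)
  expect_equal(distal_fraction(data.frame(distance = c(0, 0))), 0)
  expect_error(distal_fraction(data.frame(distance = numeric(0))),
               class = "itb_validation_error")
})

test_that("peaks per gene collapses duplicates", {
  links <- data.frame(peak_id = c("p1", "p2", "p3", "p3"),
                      gene_id = c("g1", "g1", "g1", "g1"))
  pg <- peaks_per_gene(links)
  expect_equal(pg$counts, c(g1 = 3L))
  expect_equal(peaks_per_gene(links[0, ])$counts, integer(0))
})

test_that("expression comparison between peak-count groups", {
  counts <- c(gA = 3, gB = 4, gC = 5, gD = 1, gE = 0, gF = 2)
  expr <- c(gA = 10, gB = 11, gC = 12, gD = 1, gE = 2, gF = 3)
  res <- expression_by_peakcount(counts, expr, k = 3)
  expect_equal(res$test$p_value, 0.1, tolerance = 1e-12)
  expect_equal(res$n_high, 3)
  expect_gt(res$median_log10_high, res$median_log10_low)

  same <- expression_by_peakcount(counts, setNames(rep(5, 6), names(expr)))
  expect_equal(same$test$p_value, 1)

  expect_error(expression_by_peakcount(counts, expr, k = 100),
               class = "itb_validation_error")
  expect_error(expression_by_peakcount(c(gA = 1), c(gA = 2), k = 1),
               class = "itb_validation_error")
})

test_that("marker overlap delegates to the hypergeometric oracle", {
  uni <- paste0("g", 1:10)
  r <- marker_overlap(uni[1:4], uni[1:5], uni)
  expect_equal(r$p_value, oracle_hypergeom(4, 4, 5, 10), tolerance = 1e-12)
  expect_equal(marker_overlap(uni[1:3], uni, uni)$p_value, 1)
  expect_gt(marker_overlap(uni[1:2], uni[9:10], uni)$p_value, 0.9)
  expect_error(marker_overlap(c("zzz"), uni[1:2], uni),
               class = "itb_validation_error")
})

test_that("ORA computes rates, applies filters and controls the null", {
  uni <- paste0("g", 1:20)
  lst <- uni[1:10]
  gmt <- list(hit = uni[1:10], small = uni[1:4], null = uni[11:16])
  res <- ora(lst, gmt, uni, min_rate = 1.5, min_observed = 5)
  hit <- res[res$term_id == "hit", ]
  expect_equal(hit$enrichment_rate, 2.0)
  expect_equal(hit$observed, 10)
  expect_true(hit$enriched)
  expect_false(res$enriched[res$term_id == "small"])   # observed 4 < 5
  expect_false(res$enriched[res$term_id == "null"])

  # enrichment rate is invariant to gene relabeling
  set.seed(21)
  perm <- setNames(sample(uni), uni)
  res_p <- ora(unname(perm[lst]),
               lapply(gmt, function(g) unname(perm[g])), uni,
               min_rate = 1.5)
  expect_equal(res_p$enrichment_rate[match(res$term_id, res_p$term_id)],
               res$enrichment_rate)

  # random term under the null is not enriched
  set.seed(22)
  for (rep in 1:10) {
    g_rand <- sample(uni, 8)
    rr <- ora(sample(uni, 8), list(t = g_rand), uni)
    expect_false(any(rr$enriched & rr$fdr < 0.001))
  }
  expect_error(ora(lst, gmt, character(0)), class = "itb_validation_error")
  expect_error(ora("nope", gmt, uni), class = "itb_validation_error")
})
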