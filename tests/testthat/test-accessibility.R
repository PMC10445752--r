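# QC, normalization, gene activity and the depth-adjusted LR test.

test_that("QC boundary semantics: inclusive depth range, strict frip/tss", {
  counts <- matrix(c(500, 1500, 1000, 3000), nrow = 1)
  pk <- peak_set("chr1", 0, 100, "p1")
  cm <- count_matrix(counts, pk, paste0("bc", 1:4), rep("T", 4))
  total <- c(1000, 7500, 1000 / 0.15, 10000)
  tss <- c(2, 2, 2, 2)
  res <- qc_filter(cm, total, tss)
  # bc1: depth 500 below floor; bc3: depth exactly 1000 kept by depth but
  # frip exactly 0.15 fails the strict bound; bc2, bc4 retained
  expect_equal(res$matrix$barcodes, c("bc2", "bc4"))
  expect_equal(unname(res$removed["too_few_fragments"]), 1)
  expect_equal(unname(res$removed["low_frip"]), 1)

  res2 <- qc_filter(cm, total, c(2, 2, 2, 1.5))
  expect_false("bc4" %in% res2$matrix$barcodes)   # tss exactly 1.5 fails

  expect_error(qc_filter(cm, total[1:2], tss), class = "itb_validation_error")
})

test_that("TF-IDF: zeros stay zero, closed form, IDF ordering", {
  pk1 <- peak_set("chr1", 0, 100, "p1")
  cm1 <- count_matrix(matrix(1, 1, 1), pk1, "bc1", "T")
  v <- tfidf_normalize(cm1)
  expect_equal(v[1, 1], log(1 + 1e4) * log(2), tolerance = 1e-12)

  counts <- matrix(c(1, 1, 1,
                     2, 0, 0), nrow = 2, byrow = TRUE)
  pk <- peak_set("chr1", c(0, 200), c(100, 300), c("ubiq", "rare"))
  cm <- count_matrix(counts, pk, paste0("bc", 1:3), rep("T", 3))
  tv <- tfidf_normalize(cm)
  expect_true(all(tv[counts == 0] == 0))
  # same term frequency would give the rare peak a strictly larger IDF
  idf_ubiq <- tv["ubiq", 1] / log1p(1e4 * 1 / cm$depth[1])
  idf_rare <- tv["rare", 1] / log1p(1e4 * 2 / cm$depth[1])
  expect_lt(idf_ubiq, idf_rare)

  cm_zero <- count_matrix(matrix(c(1, 0), 1), pk1, c("a", "b"),
                          c("T", "T"))
  expect_error(tfidf_normalize(cm_zero), class = "itb_validation_error")
})

test_that("gene activity sums the TSS window and normalizes by depth", {
  pk <- peak_set("chr1", c(1000, 9000), c(1400, 9400), c("near", "far"))
  cm <- count_matrix(matrix(c(4, 0, 0, 4), 2), pk, c("bc1", "bc2"),
                     c("T1", "T2"))
  genes <- gene_table("g1", "chr1", "+", 1200, 2200)   # tss 1200 in "near"
  act <- gene_activity(cm, genes)
  expect_equal(act["g1", "T1"], 4 / 4 * 1e4)
  expect_equal(act["g1", "T2"], 0)

  # peak overlapping the window edge by one base is included:
  # window [tss - 2000, tss + 2000) = [0, 4000); peak [3999, 4400)
  pk2 <- peak_set("chr1", 3999, 4400, "edge")
  cm2 <- count_matrix(matrix(2, 1, 1), pk2, "bc1", "T1")
  g2 <- gene_table("g2", "chr1", "+", 2000, 2500)
  expect_equal(gene_activity(cm2, g2)["g2", "T1"], 1e4)
  # one base farther and it is out
  pk3 <- peak_set("chr1", 4000, 4400, "out")
  cm3 <- count_matrix(matrix(2, 1, 1), pk3, "bc1", "T1")
  expect_equal(gene_activity(cm3, g2)["g2", "T1"], 0)
})

test_that("gene activity is invariant to peak and nucleus order", {
  b <- default_bundle()
  cm <- b$data$counts$gd_a
  small <- subset_count_matrix(cm, nuclei = 1:40, peaks = 1:100)
  genes <- b$data$genes[b$data$genes$chrom %in% small$peaks$chrom, ]
  act <- gene_activity(small, genes)
  set.seed(4)
  perm <- subset_count_matrix(small, nuclei = sample(40), peaks = sample(100))
  expect_equal(gene_activity(perm, genes), act)
})

test_that("LR test: degenerate peaks and validation", {
  counts <- matrix(0, 2, 8)
  counts[2, ] <- c(5, 6, 4, 5, 1, 3, 2, 1)  # keeps every depth nonzero
  pk <- peak_set("chr1", c(0, 200), c(100, 300), c("zero", "real"))
  cm <- count_matrix(counts, pk, paste0("bc", 1:8),
                     rep(c("A", "B"), each = 4))
  da <- lr_differential_test(cm, "A")
  expect_equal(da$p_value[da$peak_id == "zero"], 1)
  expect_equal(da$log2fc[da$peak_id == "zero"], 0)
  expect_true(all(da$adj_p >= da$p_value))

  expect_error(lr_differential_test(cm, "missing_type"),
               class = "itb_validation_error")
})

test_that("LR p-values match an independent IRLS oracle", {
  set.seed(9)
  for (rep in 1:10) {
    n <- 80
    y <- rbinom(n, 1, 0.5)
    if (sum(y) < 2 || sum(1 - y) < 2) next
    depth <- round(exp(rnorm(n, 7.5, 0.3)))
    counts <- matrix(rpois(2 * n, lambda = depth / 500), nrow = 2)
    pk <- peak_set("chr1", c(0, 200), c(100, 300), c("p1", "p2"))
    cm <- count_matrix(counts, pk, paste0("bc", seq_len(n)),
                       ifelse(y == 1, "A", "B"))
    da <- lr_differential_test(cm, "A")
    for (i in 1:2) {
      a <- log1p(1e4 * counts[i, ] / cm$depth)
      if (max(a) == min(a)) next
      p_or <- oracle_lr_pvalue(a, y, log(cm$depth))
      expect_equal(da$p_value[i], p_or, tolerance = 1e-6)
    }
  }
})

test_that("planted peaks are called specific; stage test finds stage shifts", {
  b <- default_bundle()
  da <- lr_differential_test(b$data$counts$gd_a, "iTB")
  truth <- b$truth$specific$gd_a$iTB
  called <- specific_peaks(da)
  expect_gte(length(intersect(called, truth)) / length(truth), 0.9)

  # identical matrices relabeled as two stages: nothing is specific
  cm <- subset_count_matrix(b$data$counts$gd_a, nuclei = 1:160)
  st <- stage_specific_test(cm, cm, "iTB")
  expect_equal(sum(st$specific), 0)

  # stage-A-only planted peaks are specific to stage A (noiseless effect)
  nb <- noiseless_bundle()
  sa <- setdiff(nb$truth$specific$gd_a$iTB, nb$truth$specific$gd_b$iTB)
  st2 <- stage_specific_test(nb$data$counts$gd_a, nb$data$counts$gd_b, "iTB")
  expect_true(all(sa %in% specific_peaks(st2)))

  cm_b <- subset_count_matrix(cm, peaks = 1:10)
  cm_c <- subset_count_matrix(cm, peaks = 11:20)
  expect_error(stage_specific_test(cm_b, cm_c, "iTB"),
               class = "itb_validation_error")
})
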