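# Common-peak derivation and conservation statistics.

test_that("overlap rule validation", {
  expect_error(overlap_rule(), class = "itb_validation_error")
  expect_error(overlap_rule(min_fraction = 0.5, min_bp = 1),
               class = "itb_validation_error")
  expect_error(overlap_rule(min_fraction = 1.5),
               class = "itb_validation_error")
  expect_error(overlap_rule(min_bp = 0), class = "itb_validation_error")
})

test_that("common peaks apply the query-frame 50% rule inclusively", {
  a <- peak_set("chr1", c(100, 0), c(200, 100), c("a1", "a2"))
  b <- peak_set("chr1", c(150, 95), c(250, 200), c("b1", "b2"))
  # a1: overlap 50/100 = 0.5 vs b1 (inclusive, retained) and 100/100 vs b2
  # (the best partner); a2: 5/100, dropped
  cp <- common_peaks(a, b)
  expect_equal(cp$id, "a1")
  expect_equal(cp$partner, "b2")

  expect_equal(common_peaks(a, a)$id, a$id)

  # reciprocal mode requires the fraction both ways
  wide <- peak_set("chr1", 100, 600, "w")
  small <- peak_set("chr1", 100, 200, "s")
  expect_equal(nrow(common_peaks(small, wide)), 1L)
  expect_equal(nrow(common_peaks(
    small, wide, overlap_rule(min_fraction = 0.5, reference_frame = "reciprocal"))),
    0L)
})

test_that("common peaks match the all-pairs brute force", {
  set.seed(31)
  for (rep in 1:50) {
    a <- random_peak_set(sample(1:12, 1), "a")
    b <- random_peak_set(sample(1:12, 1), "b")
    expect_equal(common_peaks(a, b)$id, oracle_common_peaks(a, b))
  }
})

test_that("conservation requires >= 1 shared base (half-open)", {
  m <- peak_set("chr1", c(0, 100), c(100, 200), c("m1", "m2"))
  ref <- peak_set("chr1", 99, 150, "r1")
  co <- conserved_overlap(m, ref)
  expect_equal(co$conserved$id, c("m1", "m2"))

  adj <- peak_set("chr1", 100, 200, "r2")   # touches m1 at the boundary
  co2 <- conserved_overlap(peak_set("chr1", 0, 100, "m1"), adj)
  expect_equal(co2$n_conserved, 0L)

  co3 <- conserved_overlap(m, peak_set(character(0), integer(0),
                                       integer(0), character(0)))
  expect_equal(co3$n_conserved, 0L)
  expect_equal(co3$n_total, 2L)
})

test_that("conserved count is monotone in the reference set", {
  set.seed(32)
  m <- random_peak_set(30, "m")
  ref <- random_peak_set(20, "r")
  n1 <- conserved_overlap(m, ref)$n_conserved
  bigger <- rbind(as.data.frame(ref),
                  as.data.frame(random_peak_set(10, "x")))
  class(bigger) <- c("peak_set", "data.frame")
  expect_gte(conserved_overlap(m, bigger)$n_conserved, n1)
})

test_that("conservation proportion comparison", {
  expect_gt(conservation_proportion_compare(5, 10, 5, 10)$p_value, 0.4)
  r <- conservation_proportion_compare(90, 100, 10, 100)
  expect_lt(r$p_value, 0.05)
  expect_equal(r$p_value, oracle_prop_greater(90, 100, 10, 100),
               tolerance = 1e-12)
  expect_gte(conservation_proportion_compare(0, 10, 0, 10)$p_value, 0.5)
})

test_that("chromatin mark overlap builds the right table", {
  uni <- peak_set("chr1", c(0, 100, 200, 300), c(50, 150, 250, 350),
                  paste0("u", 1:4))
  query <- filter_peaks(uni, c("u1", "u2"))
  marks <- peak_set("chr1", c(10, 110), c(20, 120), c("k1", "k2"))
  res <- chromatin_mark_overlap(query, marks, uni)
  expect_equal(unname(res$table["query", ]), c(2, 0))
  expect_equal(res$test$p_value, 1 / 6, tolerance = 1e-12)

  empty <- peak_set(character(0), integer(0), integer(0), character(0))
  expect_equal(chromatin_mark_overlap(query, empty, uni)$test$p_value, 1)
  expect_equal(chromatin_mark_overlap(uni, marks, uni)$test$p_value, 1)
  other <- peak_set("chr9", 0, 10, "z")
  expect_error(chromatin_mark_overlap(other, marks, uni),
               class = "itb_validation_error")
})

test_that("cross-species peak-count comparison joins one-to-one orthologs", {
  qc <- c(gA = 3, gB = 4, gC = 5, gD = 0, gE = 1, gF = 2)
  rc <- c(hA = 10, hB = 11, hC = 12, hD = 1, hE = 2, hF = 3)
  orth <- data.frame(gene = names(qc), ortholog = names(rc))
  res <- peaks_with_min_count_comparison(qc, rc, orth, k = 3)
  expect_equal(res$test$p_value, 0.1, tolerance = 1e-12)

  same <- peaks_with_min_count_comparison(
    qc, setNames(rep(7, 6), names(rc)), orth, k = 3)
  expect_equal(same$test$p_value, 1)

  orth_m <- rbind(orth, data.frame(gene = "gA", ortholog = "hZ"))
  expect_warning(peaks_with_min_count_comparison(qc, rc, orth_m, k = 3),
                 "one-to-many")

  bad <- data.frame(gene = "nope", ortholog = "hZ")
  expect_error(
    suppressWarnings(peaks_with_min_count_comparison(qc, rc, bad)),
    class = "itb_validation_error")
})

test_that("overlap percentage is a guarded ratio", {
  expect_equal(overlap_percent(1, 2), 50)
  expect_equal(overlap_percent(1, 3, digits = 4), 33.3333)
  expect_error(overlap_percent(3, 2), class = "itb_validation_error")
  expect_error(overlap_percent(1, 0), class = "itb_validation_error")
})
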