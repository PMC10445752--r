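# PWM scanning, matched backgrounds, enrichment and family statistics.

near_det_pwm <- function(id, consensus) {
  bases <- strsplit(consensus, "")[[1]]
  probs <- matrix(0.001, 4, length(bases))
  for (j in seq_along(bases)) {
    probs[match(bases[j], c("A", "C", "G", "T")), j] <- 0.997
  }
  pwm(id, id, probs)
}

test_that("DP threshold equals exhaustive enumeration for short motifs", {
  set.seed(41)
  for (rep in 1:10) {
    L <- sample(3:8, 1)
    p <- random_pwm(paste0("m", rep), L)
    cutoff <- sample(c(1e-2, 1e-3, 5e-5), 1)
    bg <- rep(0.25, 4)
    expect_equal(pwm_score_threshold(p, cutoff, bg)$threshold_int,
                 as.integer(oracle_pwm_threshold(p, cutoff, bg)))
  }
  # non-uniform background too
  bg2 <- c(0.3, 0.2, 0.2, 0.3)
  p <- random_pwm("mbg", 5)
  expect_equal(pwm_score_threshold(p, 1e-3, bg2)$threshold_int,
               as.integer(oracle_pwm_threshold(p, 1e-3, bg2)))
})

test_that("consensus matching, strand symmetry and N handling", {
  p <- near_det_pwm("ACGT4", "ACGT")
  hits <- scan_motifs(c(s1 = "ACGT", s2 = "AAAA", s3 = "TTACGTTT"),
                      list(p), p_cutoff = 1e-2)
  expect_true(hits$hits["s1", 1])
  expect_false(hits$hits["s2", 1])
  expect_true(hits$hits["s3", 1])

  # reverse complement of the consensus only
  rc <- scan_motifs(c(s = "TTTTACGTTTT"), list(near_det_pwm("m", "ACGT")),
                    p_cutoff = 1e-2)
  expect_true(rc$hits[1, 1])

  # N never matches; too-short sequences are no-hit, not an error
  nn <- scan_motifs(c(s1 = "ACNT", s2 = "AC"), list(p), p_cutoff = 1e-2)
  expect_false(any(nn$hits))
})

test_that("scanning is strand-symmetric on whole sequence sets", {
  set.seed(42)
  seqs <- setNames(vapply(1:30, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  }, character(1)), paste0("s", 1:30))
  pwms <- lapply(1:4, function(k) random_pwm(paste0("m", k), 7))
  fwd <- scan_motifs(seqs, pwms, p_cutoff = 1e-2)
  rc_seqs <- vapply(seqs, function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }, character(1))
  rev <- scan_motifs(rc_seqs, pwms, p_cutoff = 1e-2)
  expect_equal(unname(fwd$hits), unname(rev$hits))
})

test_that("matched background reproduces the foreground GC/length profile", {
  # homogeneous pool: every draw has the foreground's GC and length
  fg <- c(a = "GGCCGGCCGG", b = "CCGGCCGGCC")
  pool <- setNames(rep(c("GGCCGGCCGG", "CCGGCCGGCC"), 5), paste0("p", 1:10))
  res <- sample_matched_background(fg, pool, n = 50)
  expect_true(all(gc_content(pool[res$ids]) == 1))
  expect_true(all(nchar(pool[res$ids]) == 10))

  expect_equal(length(sample_matched_background(fg, pool, n = 0)$ids), 0)

  # heterogeneous foreground: joint decile histogram within 0.02 TV
  b <- default_bundle()
  fgs <- b$data$sequences[b$truth$common_target]
  set.seed(43)
  bgres <- sample_matched_background(fgs, b$data$sequences, n = 50000)
  expect_lte(bgres$bin_deviation, 0.02)

  # a pool missing foreground bins falls back with a warning
  poor <- b$data$sequences[1:3]
  expect_warning(sample_matched_background(fgs, poor, n = 100),
                 "nearest populated")
})

test_that("per-motif enrichment: fold change and hypergeometric tail", {
  mk <- function(v) matrix(v, ncol = 2,
                           dimnames = list(NULL, c("m1", "m2")))
  fg <- mk(c(rep(TRUE, 4), rep(FALSE, 6), rep(TRUE, 8), rep(FALSE, 2)))
  bg <- mk(c(rep(TRUE, 2), rep(FALSE, 8), rep(TRUE, 2), rep(FALSE, 8)))
  res <- motif_enrichment_test(fg, bg)
  expect_equal(res$fold_change[res$motif_id == "m1"], 2.0)
  expect_equal(res$p_value[res$motif_id == "m2"],
               oracle_hypergeom(8, 10, 10, 20), tolerance = 1e-12)

  same <- motif_enrichment_test(fg, fg)
  expect_true(all(same$fold_change == 1))
  expect_true(all(same$p_value >= 0.5))

  zero_bg <- mk(c(rep(TRUE, 3), rep(FALSE, 7), rep(FALSE, 10)))
  none <- mk(rep(FALSE, 20))
  res0 <- motif_enrichment_test(zero_bg, none)
  expect_equal(res0$fold_change[res0$motif_id == "m1"], Inf)
  expect_true(is.finite(res0$p_value[res0$motif_id == "m1"]))

  expect_error(motif_enrichment_test(fg, mk(rep(FALSE, 10))[, 1, drop = FALSE]),
               class = "itb_validation_error")
})

test_that("TF expression filter keeps dual-stage expressed TFs", {
  pwms <- list(pwm("m1", "TFa", matrix(0.25, 4, 2)),
               pwm("m2", "TFb", matrix(0.25, 4, 2)),
               pwm("m3", "TFc::TFd", matrix(0.25, 4, 2)))
  enrich <- data.frame(motif_id = c("m1", "m2", "m3"),
                       fold_change = c(2, 3, 4),
                       stringsAsFactors = FALSE)
  expr <- data.frame(tf = c("TFa", "TFb", "TFc", "TFd"),
                     expr_a = c(0.5, 0.6, 0.1, 0.9),
                     expr_b = c(0.5, 0.4, 0.2, 0.9))
  out <- filter_expressed_tfs(enrich, pwms, expr)
  expect_equal(out$motif_id, c("m1", "m3"))   # m2 fails stage b
  expect_equal(out$tfs[out$motif_id == "m3"], "TFd")   # dimer, one passes

  pwms2 <- c(pwms, list(structure(list(motif_id = "m4", name = "x",
                                       probs = matrix(0.25, 4, 2),
                                       tf_names = character(0),
                                       family = NA, class = NA),
                                  class = "pwm")))
  enrich2 <- rbind(enrich, data.frame(motif_id = "m4", fold_change = 9))
  expect_warning(filter_expressed_tfs(enrich2, pwms2, expr),
                 "without TF mapping")
})

test_that("family grouping: union hits and representative choice", {
  pwms <- list(
    pwm("m1", "TFa", matrix(0.25, 4, 2), family = "F1"),
    pwm("m2", "TFb", matrix(0.25, 4, 2), family = "F1"),
    pwm("m3", "TFc", matrix(0.25, 4, 2), family = "F2")
  )
  fg <- matrix(c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE,
                 FALSE, FALSE, TRUE),
               nrow = 3, dimnames = list(paste0("p", 1:3),
                                         c("m1", "m2", "m3")))
  bg <- matrix(FALSE, 3, 3, dimnames = list(paste0("b", 1:3),
                                            c("m1", "m2", "m3")))
  enrich <- data.frame(motif_id = c("m1", "m2", "m3"),
                       fold_change = c(2, 3, 5), stringsAsFactors = FALSE)
  expr <- data.frame(tf = c("TFa", "TFb", "TFc"),
                     expr_a = c(1, 1, 1), expr_b = c(1, 1, 1))
  gf <- group_families(enrich, pwms, fg, bg, expr)
  f1 <- gf$table[gf$table$family == "F1", ]
  expect_equal(f1$representative, "m2")       # equal expression, higher FC
  expect_equal(unname(gf$fg_family_hits[, "F1"]), c(TRUE, TRUE, FALSE))
  f2 <- gf$table[gf$table$family == "F2", ]
  expect_equal(f2$representative, "m3")       # single-motif family

  # union property: family fraction >= any member fraction
  set.seed(44)
  for (rep in 1:10) {
    h <- matrix(runif(40) < 0.3, 10, 4,
                dimnames = list(paste0("p", 1:10), paste0("m", 1:4)))
    pw <- lapply(1:4, function(k) pwm(paste0("m", k), paste0("TF", k),
                                      matrix(0.25, 4, 2), family = "F"))
    en <- data.frame(motif_id = paste0("m", 1:4), fold_change = 1:4)
    ex <- data.frame(tf = paste0("TF", 1:4), expr_a = 1, expr_b = 1)
    g <- group_families(en, pw, h, h, ex)
    expect_gte(g$table$fg_fraction[1], max(colMeans(h)))
  }
})

test_that("pairwise family tests are symmetric and oracle-consistent", {
  sets <- list(A = paste0("g", 1:4), B = paste0("g", 1:5))
  m <- pairwise_family_tests(sets, universe = 10)
  expect_equal(m["A", "B"], m["B", "A"])
  expect_equal(m["A", "B"], oracle_hypergeom(4, 4, 5, 10),
               tolerance = 1e-12)   # single pair: adjusted = raw
  expect_true(is.na(m["A", "A"]))

  sets3 <- list(A = paste0("g", 1:5), B = paste0("g", 1:5),
                C = paste0("g", 6:9))
  m3 <- pairwise_family_tests(sets3, universe = 20)
  expect_lt(m3["A", "B"], m3["A", "C"])    # identical beats disjoint
  expect_gt(m3["A", "C"], 0.5)

  expect_error(pairwise_family_tests(sets["A"], 10),
               class = "itb_validation_error")
  expect_error(pairwise_family_tests(list(A = paste0("g", 1:5),
                                          B = paste0("g", 1:2)), 3),
               class = "itb_validation_error")
})

test_that("families-per-peak histogram conserves the peak count", {
  h <- matrix(c(TRUE, FALSE, FALSE,
                TRUE, FALSE, FALSE,
                TRUE, FALSE, FALSE),
              nrow = 3, dimnames = list(paste0("p", 1:3), paste0("F", 1:3)))
  fp <- families_per_peak(h)
  expect_equal(unname(fp$per_peak), c(3, 0, 0))
  expect_equal(sum(fp$histogram), 3)
  expect_equal(unname(fp$histogram["0"]), 2L)

  none <- families_per_peak(matrix(FALSE, 4, 2,
                                   dimnames = list(paste0("p", 1:4),
                                                   c("a", "b"))))
  expect_equal(unname(none$histogram["0"]), 4L)
})
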