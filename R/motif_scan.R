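# PWM scanning with exact p-value score thresholds. Log-odds scores are
# discretized to a fixed granularity; the null score distribution under the
# background base frequencies is computed exactly by dynamic programming
# (position-wise convolution), and the hit threshold is the smallest
# discretized score whose null tail probability is at most the requested
# p-value cutoff. Scanning then uses the same discretized scores, so the
# threshold semantics are exact rather than approximate.

SCORE_GRANULARITY <- 1e-3

# Internal: discretized integer log2-odds matrix for a PWM.
pwm_int_scores <- function(p, bg, granularity = SCORE_GRANULARITY) {
  probs <- pmax(p$probs, 1e-10)   # guard hand-built PWMs with exact zeros
  lo <- log2(probs / bg)
  storage.mode(lo) <- "double"
  m <- round(lo / granularity)
  storage.mode(m) <- "integer"
  m
}

# Internal: reverse-complement score matrix (complement rows, reverse cols).
rc_int_scores <- function(m) {
  m[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(m))), drop = FALSE]
}

# Internal: exact distribution of the window score under iid background.
# Returns P(S = min_score + k - 1) for k = 1..length(probs).
score_distribution <- function(int_scores, bg) {
  dist <- 1
  offset <- 0L
  for (j in seq_len(ncol(int_scores))) {
    col <- int_scores[, j]
    mn <- min(col)
    nd <- numeric(length(dist) + (max(col) - mn))
    for (b in 1:4) {
      sh <- col[b] - mn
      idx <- (sh + 1L):(sh + length(dist))
      nd[idx] <- nd[idx] + bg[b] * dist
    }
    dist <- nd
    offset <- offset + mn
  }
  list(probs = dist, min_score = offset)
}

#' Exact PWM score threshold for a p-value cutoff
#'
#' Smallest discretized log-odds score whose null tail probability under the
#' background is at most `p_cutoff`. When even the maximal score has tail
#' probability above the cutoff, the threshold is one unit above the maximum
#' (no window can ever match).
#'
#' @param p A [pwm].
#' @param p_cutoff Null tail probability cutoff.
#' @param bg Background base frequencies (A, C, G, T).
#' @return A list with `threshold_int` (integer units of the granularity),
#'   `granularity`, and `tail_prob` (the exact tail at the threshold).
#' @export
pwm_score_threshold <- function(p, p_cutoff = 5e-5, bg = rep(0.25, 4)) {
  m <- pwm_int_scores(p, bg)
  sd <- score_distribution(m, bg)
  tail <- rev(cumsum(rev(sd$probs)))
  # canonical threshold: the smallest achievable window score whose tail
  # qualifies (scores in the gaps between achievable values give the same
  # hit set)
  ok <- which(tail <= p_cutoff & sd$probs > 0)
  if (length(ok) == 0) {
    thr <- sd$min_score + length(sd$probs)   # max score + 1: unreachable
    tp <- 0
  } else {
    thr <- sd$min_score + ok[1] - 1L
    tp <- tail[ok[1]]
  }
  list(threshold_int = as.integer(thr), granularity = SCORE_GRANULARITY,
       tail_prob = tp)
}

# Internal: encode a DNA string as integers (A=0,C=1,G=2,T=3, N/other=-1).
encode_dna <- function(s) {
  v <- utf8ToInt(toupper(s))
  out <- rep(-1L, length(v))
  out[v == 65L] <- 0L   # A
  out[v == 67L] <- 1L   # C
  out[v == 71L] <- 2L   # G
  out[v == 84L] <- 3L   # T
  out
}

#' Scan sequences for motif occurrences
#'
#' A sequence is called a hit for a motif if any window, on either strand,
#' reaches the motif's exact p-value score threshold (see
#' [pwm_score_threshold]). `N` bases never match; sequences shorter than a
#' motif are simply not hit.
#'
#' @param sequences Named character vector of DNA sequences over
#'   `A, C, G, T, N`.
#' @param pwms List of [pwm] records.
#' @param p_cutoff Null tail probability cutoff (default `5e-5`).
#' @param bg Background base frequencies.
#' @return A list of class `motif_hits` with `hits` (logical sequence x
#'   motif matrix), `p_cutoff`, `bg`.
#' @export
scan_motifs <- function(sequences, pwms, p_cutoff = 5e-5, bg = rep(0.25, 4)) {
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq_", seq_along(sequences))
  }
  mats <- lapply(pwms, pwm_int_scores, bg = bg)
  rcmats <- lapply(mats, rc_int_scores)
  thresholds <- vapply(pwms, function(p) {
    pwm_score_threshold(p, p_cutoff, bg)$threshold_int
  }, integer(1))
  enc <- lapply(unname(sequences), encode_dna)
  hits <- scan_hits_cpp(enc, mats, rcmats, thresholds)
  dimnames(hits) <- list(names(sequences),
                         vapply(pwms, `[[`, "", "motif_id"))
  structure(list(hits = hits, p_cutoff = p_cutoff, bg = bg),
            class = "motif_hits")
}

#' @export
print.motif_hits <- function(x, ...) {
  cat(sprintf("motif_hits: %d sequences x %d motifs (p_cutoff = %g)\n",
              nrow(x$hits), ncol(x$hits), x$p_cutoff))
  invisible(x)
}
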