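# Motif enrichment in foreground peaks against a GC/length-matched
# background, TF expression filtering, family grouping and pairwise
# family co-occurrence statistics.

#' GC content of sequences
#' @param sequences Character vector of DNA sequences.
#' @return Fraction of G/C among non-N bases per sequence.
#' @export
gc_content <- function(sequences) {
  vapply(sequences, function(s) {
    v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    acgt <- v %in% c("A", "C", "G", "T")
    if (!any(acgt)) return(NA_real_)
    mean(v[acgt] %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

# Internal: decile bin index (1..10) using foreground-derived breaks.
decile_bins <- function(values, ref) {
  br <- unique(stats::quantile(ref, probs = seq(0, 1, 0.1), names = FALSE))
  findInterval(values, br, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Sample a GC/length-matched background
#'
#' Samples `n` pool sequences with replacement, weighted so the joint
#' (GC decile x length decile) distribution (deciles taken from the
#' foreground) matches the foreground's. Foreground bins with no pool
#' members fall back to the nearest populated bin with a warning.
#'
#' @param fg_seqs Named character vector of foreground sequences.
#' @param pool_seqs Named character vector of candidate background
#'   sequences.
#' @param n Number of background draws (default 50,000).
#' @return A list with `ids` (length-`n` character vector of sampled pool
#'   names, with replacement) and `bin_deviation` (maximum absolute
#'   difference between the sampled and foreground joint bin proportions).
#' @export
sample_matched_background <- function(fg_seqs, pool_seqs, n = 50000) {
  if (length(pool_seqs) == 0) validation_error("empty background pool")
  if (n == 0) return(list(ids = character(0), bin_deviation = 0))
  fg_gc <- gc_content(fg_seqs)
  fg_len <- nchar(fg_seqs)
  pool_gc <- gc_content(pool_seqs)
  pool_len <- nchar(pool_seqs)

  fg_bin <- cbind(decile_bins(fg_gc, fg_gc), decile_bins(fg_len, fg_len))
  pool_bin <- cbind(decile_bins(pool_gc, fg_gc),
                    decile_bins(pool_len, fg_len))
  fg_key <- paste(fg_bin[, 1], fg_bin[, 2])
  pool_key <- paste(pool_bin[, 1], pool_bin[, 2])
  pool_by_bin <- split(seq_along(pool_seqs), pool_key)

  fg_tab <- table(fg_key) / length(fg_key)
  target_keys <- names(fg_tab)
  missing <- setdiff(target_keys, names(pool_by_bin))
  remap <- stats::setNames(target_keys, target_keys)
  if (length(missing) > 0) {
    warning("background pool missing ", length(missing),
            " foreground bins; using nearest populated bins")
    have <- do.call(rbind, strsplit(names(pool_by_bin), " "))
    have_num <- matrix(as.numeric(have), ncol = 2)
    for (k in missing) {
      kv <- as.numeric(strsplit(k, " ")[[1]])
      d <- abs(have_num[, 1] - kv[1]) + abs(have_num[, 2] - kv[2])
      remap[k] <- names(pool_by_bin)[which.min(d)]
    }
  }
  drawn_keys <- sample(target_keys, n, replace = TRUE,
                       prob = as.numeric(fg_tab))
  ids <- character(n)
  for (k in unique(drawn_keys)) {
    sel <- drawn_keys == k
    cand <- pool_by_bin[[remap[k]]]
    ids[sel] <- names(pool_seqs)[cand[sample.int(length(cand), sum(sel),
                                                 replace = TRUE)]]
  }
  drawn_tab <- table(factor(drawn_keys, levels = target_keys)) / n
  list(ids = ids,
       bin_deviation = max(abs(as.numeric(drawn_tab) - as.numeric(fg_tab))))
}

#' Per-motif enrichment of foreground vs background hits
#'
#' For each motif, compares the fraction of foreground peaks hit with the
#' fraction of background sequences hit: fold change is the ratio of the
#' two fractions, the p-value is a hypergeometric tail (greater) on the
#' pooled counts, and p-values are BH-adjusted across motifs. A motif with
#' foreground hits but an empty background fraction reports `Inf` fold
#' change (the p-value is still computed).
#'
#' @param fg_hits,bg_hits `motif_hits` (or logical matrices) over the same
#'   motif set.
#' @return A data.frame with `motif_id`, `fg_fraction`, `bg_fraction`,
#'   `fold_change`, `p_value`, `adj_p`.
#' @export
motif_enrichment_test <- function(fg_hits, bg_hits) {
  fg <- if (inherits(fg_hits, "motif_hits")) fg_hits$hits else fg_hits
  bg <- if (inherits(bg_hits, "motif_hits")) bg_hits$hits else bg_hits
  if (ncol(fg) != ncol(bg) ||
      !identical(colnames(fg), colnames(bg))) {
    validation_error("foreground and background must share the motif set")
  }
  n_fg <- nrow(fg)
  n_bg <- nrow(bg)
  k_fg <- colSums(fg)
  k_bg <- colSums(bg)
  fg_frac <- k_fg / n_fg
  bg_frac <- k_bg / n_bg
  fold <- ifelse(bg_frac > 0, fg_frac / bg_frac,
                 ifelse(fg_frac > 0, Inf, NA_real_))
  p <- vapply(seq_along(k_fg), function(i) {
    hypergeom_overlap(k_fg[i], n_fg, k_fg[i] + k_bg[i], n_fg + n_bg,
                      "greater")$p_value
  }, numeric(1))
  data.frame(
    motif_id = colnames(fg),
    fg_fraction = unname(fg_frac),
    bg_fraction = unname(bg_frac),
    fold_change = unname(fold),
    p_value = p,
    adj_p = bh_adjust(p),
    stringsAsFactors = FALSE
  )
}

#' Filter motifs by TF expression at both stages
#'
#' Keeps motifs with at least one mapped TF whose expression is at least
#' `min_expr` at both stages (inclusive); motifs with no TF mapping are
#' dropped with a warning.
#'
#' @param enrich Data frame from [motif_enrichment_test].
#' @param pwms List of [pwm] records providing `tf_names`.
#' @param expression Data frame with columns `tf`, `expr_a`, `expr_b`.
#' @param min_expr Minimum expression at both stages (default 0.5).
#' @return The filtered `enrich` with an added `tfs` column listing the
#'   surviving TFs per motif (comma-separated).
#' @export
filter_expressed_tfs <- function(enrich, pwms, expression, min_expr = 0.5) {
  by_id <- stats::setNames(pwms, vapply(pwms, `[[`, "", "motif_id"))
  passing <- expression$tf[expression$expr_a >= min_expr &
                             expression$expr_b >= min_expr]
  keep <- logical(nrow(enrich))
  tfs <- character(nrow(enrich))
  unmapped <- 0L
  for (i in seq_len(nrow(enrich))) {
    p <- by_id[[enrich$motif_id[i]]]
    if (is.null(p) || length(p$tf_names) == 0) {
      unmapped <- unmapped + 1L
      next
    }
    ok <- intersect(p$tf_names, passing)
    if (length(ok) > 0) {
      keep[i] <- TRUE
      tfs[i] <- paste(ok, collapse = ",")
    }
  }
  if (unmapped > 0) {
    warning(unmapped, " motifs without TF mapping dropped")
  }
  out <- enrich[keep, , drop = FALSE]
  out$tfs <- tfs[keep]
  rownames(out) <- NULL
  out
}

#' Group enriched motifs into TF families
#'
#' A peak is hit by a family iff it is hit by any member motif (union).
#' The representative motif is the member with the highest fold change
#' among motifs of the family's two most highly expressed TFs. Family-level
#' fold change is the ratio of union hit fractions, and the family p-value
#' is the hypergeometric tail on the union counts, BH-adjusted across
#' families.
#'
#' @param enrich Per-motif results after [filter_expressed_tfs] (only these
#'   motifs are grouped).
#' @param pwms List of [pwm] records with `family` labels.
#' @param fg_hits,bg_hits `motif_hits` (or logical matrices) used for the
#'   union aggregation.
#' @param expression Data frame with `tf`, `expr_a`, `expr_b` used to rank
#'   TFs within a family (by mean of the two stages).
#' @return A list with `table` (one row per family: `family`,
#'   `representative`, `members`, `fg_fraction`, `bg_fraction`,
#'   `fold_change`, `p_value`, `adj_p`) and `fg_family_hits` /
#'   `bg_family_hits` (logical sequence x family matrices).
#' @export
group_families <- function(enrich, pwms, fg_hits, bg_hits, expression) {
  fg <- if (inherits(fg_hits, "motif_hits")) fg_hits$hits else fg_hits
  bg <- if (inherits(bg_hits, "motif_hits")) bg_hits$hits else bg_hits
  by_id <- stats::setNames(pwms, vapply(pwms, `[[`, "", "motif_id"))
  fam_of <- vapply(enrich$motif_id, function(id) {
    f <- by_id[[id]]$family
    if (is.null(f) || is.na(f)) "unassigned" else f
  }, character(1))
  fams <- sort(unique(fam_of))
  expr_mean <- stats::setNames((expression$expr_a + expression$expr_b) / 2,
                               expression$tf)

  fg_fam <- matrix(FALSE, nrow(fg), length(fams),
                   dimnames = list(rownames(fg), fams))
  bg_fam <- matrix(FALSE, nrow(bg), length(fams),
                   dimnames = list(rownames(bg), fams))
  rows <- vector("list", length(fams))
  for (k in seq_along(fams)) {
    members <- enrich$motif_id[fam_of == fams[k]]
    fg_fam[, k] <- rowSums(fg[, members, drop = FALSE]) > 0
    bg_fam[, k] <- rowSums(bg[, members, drop = FALSE]) > 0
    fam_tfs <- unique(unlist(lapply(members,
                                    function(id) by_id[[id]]$tf_names)))
    top2 <- fam_tfs[order(-replace(expr_mean[fam_tfs],
                                   is.na(expr_mean[fam_tfs]), -Inf))]
    top2 <- top2[seq_len(min(2, length(top2)))]
    cand <- members[vapply(members, function(id) {
      length(intersect(by_id[[id]]$tf_names, top2)) > 0
    }, logical(1))]
    if (length(cand) == 0) cand <- members
    fc <- enrich$fold_change[match(cand, enrich$motif_id)]
    rep_motif <- cand[which.max(fc)]

    k_fg <- sum(fg_fam[, k]); k_bg <- sum(bg_fam[, k])
    fgf <- k_fg / nrow(fg); bgf <- k_bg / nrow(bg)
    p <- hypergeom_overlap(k_fg, nrow(fg), k_fg + k_bg, nrow(fg) + nrow(bg),
                           "greater")$p_value
    rows[[k]] <- data.frame(
      family = fams[k], representative = rep_motif,
      members = paste(members, collapse = ","),
      fg_fraction = fgf, bg_fraction = bgf,
      fold_change = ifelse(bgf > 0, fgf / bgf, ifelse(fgf > 0, Inf, NA)),
      p_value = p, stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  tab$adj_p <- bh_adjust(tab$p_value)
  list(table = tab, fg_family_hits = fg_fam, bg_family_hits = bg_fam)
}

#' Pairwise TF-family co-occurrence tests
#'
#' For each unordered family pair, a hypergeometric (greater) test of the
#' overlap between the two families' sets, BH-adjusted across all pairs.
#' Used twice: on target-gene sets and on hit-peak sets.
#'
#' @param sets Named list of character sets (one per family).
#' @param universe Universe size the sets are drawn from.
#' @return A symmetric matrix of adjusted p-values (diagonal `NA`).
#' @export
pairwise_family_tests <- function(sets, universe) {
  fams <- names(sets)
  if (length(fams) < 2) validation_error("need at least 2 families")
  if (any(vapply(sets, length, 1L) > universe)) {
    validation_error("family set exceeds the universe")
  }
  pairs <- utils::combn(length(fams), 2)
  raw <- apply(pairs, 2, function(ix) {
    a <- sets[[ix[1]]]
    b <- sets[[ix[2]]]
    hypergeom_overlap(length(intersect(a, b)), length(a), length(b),
                      universe, "greater")$p_value
  })
  adj <- bh_adjust(raw)
  out <- matrix(NA_real_, length(fams), length(fams),
                dimnames = list(fams, fams))
  for (j in seq_len(ncol(pairs))) {
    out[pairs[1, j], pairs[2, j]] <- adj[j]
    out[pairs[2, j], pairs[1, j]] <- adj[j]
  }
  out
}

#' Histogram of TF families per peak
#'
#' @param family_hits Logical peak x family matrix (union hits, see
#'   [group_families]).
#' @return A list with `per_peak` (named integer vector) and `histogram`
#'   (table over counts, including the zero class).
#' @export
families_per_peak <- function(family_hits) {
  counts <- rowSums(family_hits)
  hist <- table(factor(counts, levels = 0:max(c(counts, 0))))
  list(per_peak = stats::setNames(as.integer(counts), rownames(family_hits)),
       histogram = hist)
}
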