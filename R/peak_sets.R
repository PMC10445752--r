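# Common and stage-specific peak sets and cross-species conservation.

#' Overlap rule
#'
#' Exactly one of `min_fraction` (fraction of the query peak's bases that
#' must be covered, bedtools `-f` semantics) or `min_bp` (absolute overlap
#' in bp) must be set.
#'
#' @param min_fraction Fraction in (0, 1\], or `NULL`.
#' @param min_bp Minimum overlap in bp (>= 1), or `NULL`.
#' @param reference_frame `"query"` (fraction of the query peak) or
#'   `"reciprocal"` (required both ways).
#' @return A list of class `overlap_rule`.
#' @export
overlap_rule <- function(min_fraction = NULL, min_bp = NULL,
                         reference_frame = c("query", "reciprocal")) {
  reference_frame <- match.arg(reference_frame)
  if (is.null(min_fraction) == is.null(min_bp)) {
    validation_error("exactly one of min_fraction / min_bp must be set")
  }
  if (!is.null(min_fraction) &&
      (min_fraction <= 0 || min_fraction > 1)) {
    validation_error("min_fraction must lie in (0, 1]")
  }
  if (!is.null(min_bp) && (!is_count(min_bp) || min_bp < 1)) {
    validation_error("min_bp must be a count >= 1")
  }
  structure(list(min_fraction = min_fraction, min_bp = min_bp,
                 reference_frame = reference_frame),
            class = "overlap_rule")
}

# Internal: for each peak of `a`, the best overlap against `b` under the
# rule; returns logical keep vector plus the id of the matched partner.
rule_overlap <- function(a, b, rule) {
  keep <- logical(nrow(a))
  partner <- rep(NA_character_, nrow(a))
  if (nrow(a) == 0 || nrow(b) == 0) return(list(keep = keep, partner = partner))
  # disjoint chromosome sets legitimately mean "no overlap", not a problem
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(peaks_to_granges(a), peaks_to_granges(b))
  )
  if (length(hits) == 0) return(list(keep = keep, partner = partner))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ovl <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  pass <- if (!is.null(rule$min_bp)) {
    ovl >= rule$min_bp
  } else {
    frac_q <- ovl / (a$end[qi] - a$start[qi])
    if (rule$reference_frame == "reciprocal") {
      frac_s <- ovl / (b$end[si] - b$start[si])
      frac_q >= rule$min_fraction & frac_s >= rule$min_fraction
    } else {
      frac_q >= rule$min_fraction
    }
  }
  qi <- qi[pass]; si <- si[pass]; ovl <- ovl[pass]
  if (length(qi) > 0) {
    best <- tapply(seq_along(qi), qi, function(ix) ix[which.max(ovl[ix])])
    keep[as.integer(names(best))] <- TRUE
    partner[as.integer(names(best))] <- b$id[si[unlist(best)]]
  }
  list(keep = keep, partner = partner)
}

#' Common peaks between two peak sets
#'
#' Returns the peaks of `set_a` for which some peak of `set_b` overlaps at
#' least the rule's fraction of the `set_a` peak (default: at least 50% of
#' the query peak's base pairs; `reciprocal` requires the fraction both
#' ways). Each retained peak appears once, carrying the id of its best-
#' overlapping partner in the `partner` attribute column.
#'
#' @param set_a,set_b [peak_set] objects on the same chromosome namespace.
#' @param rule An [overlap_rule] (default 50% query-frame).
#' @return A [peak_set] (subset of `set_a`) with an extra `partner` column.
#' @export
common_peaks <- function(set_a, set_b,
                         rule = overlap_rule(min_fraction = 0.5)) {
  ro <- rule_overlap(set_a, set_b, rule)
  out <- peaks_subset(set_a, ro$keep)
  out$partner <- ro$partner[ro$keep]
  out
}

#' Conserved peaks by overlap with a reference set
#'
#' Subset of `mapped` (already in reference coordinates, see
#' [map_intervals]) overlapping any reference peak by at least `min_bp`
#' (default 1 bp).
#'
#' @param mapped A [peak_set] in reference coordinates.
#' @param reference A reference [peak_set] (e.g. EVT ATAC-seq peaks).
#' @param rule An [overlap_rule] (default 1 bp).
#' @return A list with `conserved` (a [peak_set]), `n_conserved`, `n_total`.
#' @export
conserved_overlap <- function(mapped, reference,
                              rule = overlap_rule(min_bp = 1)) {
  ro <- rule_overlap(mapped, reference, rule)
  list(conserved = peaks_subset(mapped, ro$keep),
       n_conserved = sum(ro$keep),
       n_total = nrow(mapped))
}

#' Compare conservation proportions between two peak sets
#'
#' One-sided test that the first set's conserved proportion exceeds the
#' second's; delegates to [two_proportion_greater].
#'
#' @param conserved_a,total_a Conserved and total counts for set A.
#' @param conserved_b,total_b Conserved and total counts for set B.
#' @return A `test_result`.
#' @export
conservation_proportion_compare <- function(conserved_a, total_a,
                                            conserved_b, total_b) {
  two_proportion_greater(conserved_a, total_a, conserved_b, total_b)
}

#' Chromatin-mark overlap enrichment
#'
#' Tests whether peaks of a query set overlap a mark set (e.g. H3K27ac, by
#' at least 1 bp) more often than the rest of a peak universe, with a
#' one-sided Fisher's exact test on the 2x2 table
#' (in/out of query) x (overlapping/not overlapping marks).
#'
#' @param peaks Query [peak_set]; ids must be a subset of `universe` ids.
#' @param marks Mark [peak_set].
#' @param universe Universe [peak_set].
#' @return A list with `test` (a `test_result`) and `table` (the 2x2 table).
#' @export
chromatin_mark_overlap <- function(peaks, marks, universe) {
  if (!all(peaks$id %in% universe$id)) {
    validation_error("query peaks must be a subset of the universe")
  }
  ro <- rule_overlap(universe, marks, overlap_rule(min_bp = 1))
  in_query <- universe$id %in% peaks$id
  tab <- matrix(
    c(sum(in_query & ro$keep), sum(in_query & !ro$keep),
      sum(!in_query & ro$keep), sum(!in_query & !ro$keep)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("query", "other"), c("overlap", "no_overlap"))
  )
  list(test = fisher_greater(tab), table = tab)
}

#' Compare reference peak counts between genes with many vs few query peaks
#'
#' Joins the two per-gene peak-count maps through a one-to-one orthology
#' table (rows whose source or target gene appears more than once are
#' dropped with a warning), then runs a Wilcoxon two-sided test of the
#' reference counts between genes with `>= k` and `< k` query peaks.
#'
#' @param query_counts Named vector: query-species gene -> peak count.
#' @param ref_counts Named vector: reference-species gene -> peak count.
#' @param orthology Data frame with columns `gene` (query species) and
#'   `ortholog` (reference species).
#' @param k Peak-count threshold (default 3).
#' @return A list with `test` (a `test_result`), `n_high`, `n_low`.
#' @export
peaks_with_min_count_comparison <- function(query_counts, ref_counts,
                                            orthology, k = 3) {
  dup <- duplicated(orthology$gene) | duplicated(orthology$gene, fromLast = TRUE) |
    duplicated(orthology$ortholog) | duplicated(orthology$ortholog, fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " one-to-many orthology rows dropped")
    orthology <- orthology[!dup, , drop = FALSE]
  }
  orthology <- orthology[orthology$gene %in% names(query_counts) &
                           orthology$ortholog %in% names(ref_counts), ,
                         drop = FALSE]
  if (nrow(orthology) == 0) validation_error("no shared orthologous genes")
  qc <- query_counts[orthology$gene]
  rc <- ref_counts[orthology$ortholog]
  hi <- rc[qc >= k]
  lo <- rc[qc < k]
  if (length(hi) == 0 || length(lo) == 0) {
    validation_error("one of the peak-count groups is empty")
  }
  list(test = wilcoxon_rank_sum(as.numeric(hi), as.numeric(lo)),
       n_high = length(hi), n_low = length(lo))
}

#' Overlap percentage
#'
#' Percentage of a peak set overlapping a reference, as reported for the
#' TFAP2C motif-peak vs ChIP-seq comparison.
#'
#' @param n_overlap Number of overlapping peaks.
#' @param n_total Total number of peaks.
#' @param digits Decimal places to round to (default 2).
#' @return Percentage in \[0, 100\].
#' @export
overlap_percent <- function(n_overlap, n_total, digits = 2) {
  if (!is_count(n_overlap) || !is_count(n_total) || n_total == 0 ||
      n_overlap > n_total) {
    validation_error("need 0 <= n_overlap <= n_total with n_total > 0")
  }
  round(100 * n_overlap / n_total, digits)
}
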