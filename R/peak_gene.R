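# Peak-to-gene association and downstream summaries. Distances are measured
# from the nearest peak edge to the gene's strand-aware TSS; magnitudes drive
# all thresholds, while the stored sign is strand-aware (upstream negative).

# Internal: edge-to-TSS distance magnitude and strand-aware sign for one
# peak against vectors of TSS/strand. The gap is measured against the
# half-open interval boundaries: a TSS at `start - d` or `end + d` is at
# distance d (a TSS exactly at `end` touches the peak, distance 0).
tss_distances <- function(p_start, p_end, tss, strand) {
  inside <- tss >= p_start & tss <= p_end
  left <- tss < p_start       # peak lies right of the TSS
  mag <- ifelse(inside, 0L,
                ifelse(left, p_start - tss, tss - p_end))
  # relative position of the peak w.r.t. the TSS on the plus strand:
  # negative when the peak is left of (before) the TSS
  relpos <- ifelse(inside, 0L, ifelse(left, mag, -mag))
  signed <- ifelse(strand == "+", relpos, -relpos)
  list(mag = mag, signed = as.integer(signed))
}

# Internal: core nearest-TSS scan shared by the two association rules.
nearest_gene_impl <- function(peaks, genes, max_dist, use_plus_start) {
  tss <- if (use_plus_start) genes$start else genes$tss
  n <- nrow(peaks)
  gene_id <- character(n)
  distance <- integer(n)
  tie <- logical(n)
  ok <- logical(n)
  by_chr <- split(seq_len(nrow(genes)), genes$chrom)
  for (i in seq_len(n)) {
    gi <- by_chr[[peaks$chrom[i]]]
    if (is.null(gi)) next
    d <- tss_distances(peaks$start[i], peaks$end[i], tss[gi], genes$strand[gi])
    best <- min(d$mag)
    if (best > max_dist) next
    cand <- gi[d$mag == best]
    pick <- cand[order(genes$gene_id[cand])][1]
    ok[i] <- TRUE
    gene_id[i] <- genes$gene_id[pick]
    distance[i] <- d$signed[which(gi == pick)]
    tie[i] <- length(cand) > 1
  }
  data.frame(
    peak_id = peaks$id[ok], gene_id = gene_id[ok], distance = distance[ok],
    tie = tie[ok], stringsAsFactors = FALSE
  )
}

#' Nearest-gene association
#'
#' Associates each peak with the same-chromosome gene whose TSS is closest
#' to the peak interval (distance 0 when the TSS falls inside the peak).
#' Ties are broken by the lexicographically smaller `gene_id` and flagged in
#' the `tie` column. Peaks on chromosomes without genes are unassigned
#' (absent from the output).
#'
#' @param peaks A [peak_set].
#' @param genes A [gene_table].
#' @param use_plus_start Use the plus-strand start literally instead of the
#'   strand-aware TSS.
#' @return A data.frame with columns `peak_id`, `gene_id`, `distance`
#'   (signed, strand-aware, upstream negative), `tie`, `rule`.
#' @export
nearest_gene <- function(peaks, genes, use_plus_start = FALSE) {
  out <- nearest_gene_impl(peaks, genes, Inf, use_plus_start)
  out$rule <- rep("nearest_start", nrow(out))
  out
}

#' Nearest-gene association with a distance cap
#'
#' As [nearest_gene] but peaks whose nearest TSS is farther than `max_dist`
#' are unassigned, the single-nearest-gene association used for reference-
#' species peak sets.
#'
#' @inheritParams nearest_gene
#' @param max_dist Maximum TSS distance in bp (default 1 Mb).
#' @return A data.frame as in [nearest_gene] with `rule = "great_1mb"`.
#' @export
great_nearest_gene <- function(peaks, genes, max_dist = 1e6,
                               use_plus_start = FALSE) {
  out <- nearest_gene_impl(peaks, genes, max_dist, use_plus_start)
  out$rule <- rep("great_1mb", nrow(out))
  out
}

#' Fraction of peak-gene links distal to the TSS
#'
#' @param links Data frame from [nearest_gene] (non-empty).
#' @param cutoff Distance cutoff in bp; links with `|distance| > cutoff`
#'   count as distal (strict inequality).
#' @return Fraction in \[0, 1\].
#' @export
distal_fraction <- function(links, cutoff = 5000) {
  if (nrow(links) == 0) validation_error("no links supplied")
  mean(abs(links$distance) > cutoff)
}

#' Peaks-per-gene counts and histogram
#'
#' @param links Data frame with `peak_id`, `gene_id`; duplicate pairs are
#'   collapsed before counting.
#' @return A list with `counts` (named integer vector, genes to distinct
#'   peak counts) and `histogram` (table over the counts).
#' @export
peaks_per_gene <- function(links) {
  if (nrow(links) == 0) {
    return(list(counts = integer(0), histogram = table(integer(0))))
  }
  uniq <- unique(links[, c("peak_id", "gene_id")])
  counts <- table(uniq$gene_id)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts, histogram = table(counts))
}

#' Expression comparison between genes with many vs few peaks
#'
#' Wilcoxon two-sided test of expression between genes with `>= k` and
#' `< k` associated peaks, with group medians reported on the
#' `log10(expression + 1e-5)` scale.
#'
#' @param counts Named vector of peaks-per-gene counts (genes absent from
#'   the vector are treated as 0 if present in `expression`).
#' @param expression Named numeric vector of average expression per gene.
#' @param k Peak-count threshold (default 3).
#' @return A list with `test` (a `test_result`), `n_high`, `n_low`,
#'   `median_log10_high`, `median_log10_low`.
#' @export
expression_by_peakcount <- function(counts, expression, k = 3) {
  genes <- names(expression)
  pc <- counts[genes]
  pc[is.na(pc)] <- 0L
  hi <- expression[pc >= k]
  lo <- expression[pc < k]
  if (length(hi) == 0) validation_error("no genes with >= ", k, " peaks")
  if (length(lo) == 0) validation_error("no genes with < ", k, " peaks")
  list(
    test = wilcoxon_rank_sum(hi, lo),
    n_high = length(hi),
    n_low = length(lo),
    median_log10_high = stats::median(log10(hi + 1e-5)),
    median_log10_low = stats::median(log10(lo + 1e-5))
  )
}

#' Overlap of a gene group with a marker list
#'
#' Hypergeometric test of the overlap between a gene set (e.g. genes with at
#' least three specific peaks) and a marker list within a gene universe.
#'
#' @param genes Character gene set.
#' @param markers Character marker set.
#' @param universe Character gene universe; both sets must be subsets.
#' @param tail `"greater"` (over-representation, default) or `"less"`.
#' @return A `test_result`.
#' @export
marker_overlap <- function(genes, markers, universe, tail = "greater") {
  genes <- unique(genes)
  markers <- unique(markers)
  universe <- unique(universe)
  if (!all(genes %in% universe) || !all(markers %in% universe)) {
    validation_error("gene and marker sets must be subsets of the universe")
  }
  hypergeom_overlap(length(intersect(genes, markers)), length(genes),
                    length(markers), length(universe), tail)
}

#' Over-representation analysis against a gene-set collection
#'
#' Per-term hypergeometric (greater) test of a gene list against each set in
#' a GMT-style collection, BH-adjusted across tested terms and filtered on
#' FDR, enrichment rate and minimum observed genes.
#'
#' @param gene_list Character gene list (subset of `universe`).
#' @param gmt Named list of character gene sets.
#' @param universe Character gene universe.
#' @param min_rate Minimum enrichment rate (`observed / expected`) to call a
#'   term enriched (1.5 for peak-derived gene lists, 2 for TF-target lists).
#' @param min_observed Minimum observed genes in the term (default 5).
#' @param fdr_cut FDR threshold (default 0.05).
#' @return A data.frame with one row per term: `term_id`, `observed`,
#'   `expected`, `enrichment_rate`, `p_value`, `fdr`, `enriched`.
#' @export
ora <- function(gene_list, gmt, universe, min_rate = 1.5, min_observed = 5,
                fdr_cut = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) validation_error("empty universe")
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe)) {
    validation_error("gene_list must be a subset of the universe")
  }
  terms <- names(gmt)
  res <- lapply(terms, function(tt) {
    term_genes <- intersect(gmt[[tt]], universe)
    obs <- length(intersect(gene_list, term_genes))
    expd <- length(gene_list) * length(term_genes) / length(universe)
    p <- if (length(term_genes) == 0) 1 else {
      hypergeom_overlap(obs, length(gene_list), length(term_genes),
                        length(universe), "greater")$p_value
    }
    data.frame(term_id = tt, observed = obs, expected = expd,
               enrichment_rate = if (expd > 0) obs / expd else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p_value)
  out$enriched <- out$fdr < fdr_cut &
    !is.na(out$enrichment_rate) & out$enrichment_rate >= min_rate &
    out$observed >= min_observed
  out[order(out$fdr, out$p_value), , drop = FALSE]
}
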