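# Nucleus QC, TF-IDF normalization and accessibility-derived gene activity.

#' QC thresholds for nucleus filtering
#'
#' Defaults follow standard snATAC practice: 1000-20,000 fragments in peaks
#' (inclusive), fraction of reads in peaks strictly greater than 0.15, and
#' TSS enrichment strictly greater than 1.5.
#'
#' @param min_fragments,max_fragments Inclusive bounds on fragments in peaks.
#' @param min_frip Strict lower bound on the fraction of reads in peaks.
#' @param min_tss_enrichment Strict lower bound on TSS enrichment.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_fragments = 1000, max_fragments = 20000,
                          min_frip = 0.15, min_tss_enrichment = 1.5) {
  if (min_fragments >= max_fragments) {
    validation_error("min_fragments must be < max_fragments")
  }
  if (min_frip <= 0 || min_frip >= 1) {
    validation_error("min_frip must lie in (0, 1)")
  }
  structure(
    list(min_fragments = min_fragments, max_fragments = max_fragments,
         min_frip = min_frip, min_tss_enrichment = min_tss_enrichment),
    class = "qc_thresholds"
  )
}

#' Filter nuclei on QC criteria
#'
#' Retains nuclei with `min_fragments <= depth <= max_fragments` (inclusive),
#' `depth / total_reads > min_frip` (strict) and
#' `tss_enrichment > min_tss_enrichment` (strict).
#'
#' @param x A [count_matrix].
#' @param total_reads Per-nucleus total read counts, aligned to nuclei.
#' @param tss_enrichment Per-nucleus TSS enrichment ratios, aligned to nuclei.
#' @param thresholds A [qc_thresholds].
#' @return A list with `matrix` (the filtered [count_matrix]) and `removed`,
#'   a named count of nuclei failing each criterion (a nucleus can fail
#'   several).
#' @export
qc_filter <- function(x, total_reads, tss_enrichment,
                      thresholds = qc_thresholds()) {
  n <- n_nuclei(x)
  if (length(total_reads) != n || length(tss_enrichment) != n) {
    validation_error("total_reads and tss_enrichment must align to nuclei")
  }
  d <- x$depth
  fail_low <- d < thresholds$min_fragments
  fail_high <- d > thresholds$max_fragments
  fail_frip <- (d / total_reads) <= thresholds$min_frip
  fail_tss <- tss_enrichment <= thresholds$min_tss_enrichment
  keep <- !(fail_low | fail_high | fail_frip | fail_tss)
  list(
    matrix = subset_count_matrix(x, nuclei = keep),
    removed = c(
      too_few_fragments = sum(fail_low),
      too_many_fragments = sum(fail_high),
      low_frip = sum(fail_frip),
      low_tss_enrichment = sum(fail_tss),
      total_removed = sum(!keep)
    )
  )
}

#' TF-IDF normalization (log-TF x log-IDF)
#'
#' Computes `log1p(scale * count / depth) * log1p(n_nuclei / n_with_peak)`
#' per entry: the log term frequency times log inverse document frequency
#' variant suited to sparse matrices with strong count outliers. Zero counts
#' map exactly to zero; peaks observed in no nucleus stay zero.
#'
#' @param x A [count_matrix]; all nuclei must have depth > 0.
#' @param scale Scale factor for the term frequency (default `1e4`).
#' @return A sparse peak x nucleus `Matrix` of normalized values.
#' @export
tfidf_normalize <- function(x, scale = 1e4) {
  if (any(x$depth == 0)) {
    validation_error("zero-depth nucleus; run qc_filter first")
  }
  m <- x$counts
  ncell <- ncol(m)
  # column index per stored entry of the CsparseMatrix
  colidx <- rep(seq_len(ncell), diff(m@p))
  m@x <- log1p(scale * m@x / x$depth[colidx])
  df <- Matrix::rowSums(x$counts > 0)
  idf <- ifelse(df > 0, log1p(ncell / pmax(df, 1)), 0)
  out <- Matrix::Diagonal(x = idf) %*% m
  dimnames(out) <- dimnames(x$counts)
  out
}

#' Accessibility-derived gene activity
#'
#' For each gene, sums fragment counts of peaks overlapping the window
#' `[tss - window, tss + window)`, then aggregates per cell type as the mean
#' over nuclei of `1e4 * gene_count / depth`.
#'
#' @param x A [count_matrix].
#' @param genes A [gene_table].
#' @param window Half-width of the TSS window in bp.
#' @return A gene x cell-type numeric matrix.
#' @export
gene_activity <- function(x, genes, window = 2000) {
  win_start <- pmax(genes$tss - window, 0L)
  win_end <- genes$tss + window
  gr_win <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = win_start + 1L, end = win_end)
  )
  hits <- GenomicRanges::findOverlaps(gr_win, peaks_to_granges(x$peaks))
  ind <- Matrix::sparseMatrix(
    i = S4Vectors::queryHits(hits), j = S4Vectors::subjectHits(hits),
    x = 1, dims = c(nrow(genes), n_peaks(x))
  )
  gene_counts <- ind %*% x$counts
  norm <- Matrix::t(Matrix::t(gene_counts) / x$depth) * 1e4
  types <- sort(unique(x$labels))
  out <- vapply(types, function(tt) {
    Matrix::rowMeans(norm[, x$labels == tt, drop = FALSE])
  }, numeric(nrow(genes)))
  out <- matrix(out, nrow = nrow(genes),
                dimnames = list(genes$gene_id, types))
  out
}
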