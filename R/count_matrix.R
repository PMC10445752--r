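# Peak x nucleus fragment-count matrix with per-nucleus cell-type labels.
# Counts are stored sparse (dgCMatrix); per-nucleus depth (total fragments in
# peaks) is the column sum and is derived once at construction.

#' Construct a count matrix
#'
#' @param counts Peak x nucleus matrix of non-negative integer fragment
#'   counts (dense or `Matrix` sparse).
#' @param peaks A [peak_set] with one row per matrix row.
#' @param barcodes Character nucleus barcodes, one per column.
#' @param labels Cell-type label per nucleus, either a vector aligned to
#'   `barcodes` or a named vector covering all barcodes.
#' @return A list of class `count_matrix` with elements `counts`, `peaks`,
#'   `barcodes`, `labels`, `depth`.
#' @export
count_matrix <- function(counts, peaks, barcodes, labels) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != nrow(peaks)) {
    validation_error("count rows (", nrow(counts), ") != peaks (",
                     nrow(peaks), ")")
  }
  if (ncol(counts) != length(barcodes)) {
    validation_error("count columns (", ncol(counts), ") != barcodes (",
                     length(barcodes), ")")
  }
  if (any(counts@x < 0)) validation_error("negative counts")
  barcodes <- as.character(barcodes)
  if (anyDuplicated(barcodes)) validation_error("duplicate barcodes")
  if (!is.null(names(labels))) {
    missing <- setdiff(barcodes, names(labels))
    if (length(missing) > 0) {
      validation_error("unlabeled barcode: ", missing[1])
    }
    labels <- unname(labels[barcodes])
  } else if (length(labels) != length(barcodes)) {
    validation_error("labels must cover all barcodes")
  }
  labels <- as.character(labels)
  if (any(is.na(labels))) validation_error("unlabeled barcode")
  rownames(counts) <- peaks$id
  colnames(counts) <- barcodes
  structure(
    list(counts = counts, peaks = peaks, barcodes = barcodes,
         labels = labels, depth = unname(Matrix::colSums(counts))),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d peaks x %d nuclei; %d cell types\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$labels))))
  invisible(x)
}

#' Number of peaks / nuclei
#' @param x A `count_matrix`.
#' @name count_matrix-dims
#' @export
n_peaks <- function(x) nrow(x$counts)

#' @rdname count_matrix-dims
#' @export
n_nuclei <- function(x) ncol(x$counts)

#' Subset a count matrix by nuclei and/or peaks
#'
#' @param x A `count_matrix`.
#' @param nuclei Logical/integer index or barcode names of columns to keep.
#' @param peaks Logical/integer index or peak ids of rows to keep.
#' @return A `count_matrix` (depth recomputed).
#' @export
subset_count_matrix <- function(x, nuclei = NULL, peaks = NULL) {
  ri <- seq_len(nrow(x$counts))
  ci <- seq_len(ncol(x$counts))
  if (!is.null(peaks)) {
    ri <- if (is.character(peaks)) match(peaks, x$peaks$id) else ri[peaks]
    if (any(is.na(ri))) validation_error("unknown peak id in subset")
  }
  if (!is.null(nuclei)) {
    ci <- if (is.character(nuclei)) match(nuclei, x$barcodes) else ci[nuclei]
    if (any(is.na(ci))) validation_error("unknown barcode in subset")
  }
  count_matrix(x$counts[ri, ci, drop = FALSE], peaks_subset(x$peaks, ri),
               x$barcodes[ci], x$labels[ci])
}

#' Read a count matrix from MatrixMarket triplets plus side files
#'
#' @param mtx Path to a MatrixMarket coordinate file (peaks x nuclei).
#' @param peaks_bed Path to the peak BED file (rows of the matrix, in order).
#' @param barcodes_tsv Path to a headerless one-column barcode file
#'   (columns of the matrix, in order).
#' @param labels_tsv Path to a TSV with header columns `barcode`, `label`.
#' @return A [count_matrix].
#' @export
read_count_matrix <- function(mtx, peaks_bed, barcodes_tsv, labels_tsv) {
  m <- Matrix::readMM(mtx)
  peaks <- read_bed(peaks_bed)
  barcodes <- readLines(barcodes_tsv)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != nrow(peaks) || ncol(m) != length(barcodes)) {
    validation_error("MTX dimensions ", nrow(m), "x", ncol(m),
                     " do not match peaks (", nrow(peaks),
                     ") and barcodes (", length(barcodes), ")")
  }
  lab <- utils::read.delim(labels_tsv, stringsAsFactors = FALSE)
  if (!all(c("barcode", "label") %in% names(lab))) {
    parse_error("labels TSV must have columns barcode, label")
  }
  labels <- stats::setNames(lab$label, lab$barcode)
  count_matrix(m, peaks, barcodes, labels)
}

#' Write a count matrix bundle (MTX + BED + barcodes + labels)
#'
#' @param x A `count_matrix`.
#' @param mtx,peaks_bed,barcodes_tsv,labels_tsv Output paths.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_count_matrix <- function(x, mtx, peaks_bed, barcodes_tsv, labels_tsv) {
  Matrix::writeMM(x$counts, mtx)
  write_bed(x$peaks, peaks_bed)
  writeLines(x$barcodes, barcodes_tsv)
  utils::write.table(
    data.frame(barcode = x$barcodes, label = x$labels),
    labels_tsv, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(mtx = mtx, peaks_bed = peaks_bed, barcodes_tsv = barcodes_tsv,
              labels_tsv = labels_tsv))
}
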