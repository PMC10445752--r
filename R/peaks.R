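# Peak sets: the atomic unit of every overlap/association computation.
# Internally a data.frame (chrom, start, end, id) in 0-based half-open (BED)
# coordinates; GTF input is shifted on read so only one convention exists
# inside the package.

#' Construct a peak set
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer 0-based half-open coordinates (`start < end`).
#' @param id Peak identifiers, unique; generated as `peak_<n>` when missing.
#' @return A data.frame of class `peak_set` with columns
#'   `chrom`, `start`, `end`, `id`.
#' @export
peak_set <- function(chrom, start, end, id = NULL) {
  n <- length(start)
  if (length(chrom) == 1L && n > 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n) {
    validation_error("chrom, start, end must have equal length")
  }
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) {
    validation_error("non-integer coordinates")
  }
  if (any(start < 0)) validation_error("negative start coordinate")
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    validation_error("empty or inverted interval at row ", bad,
                     ": start ", start[bad], " >= end ", end[bad])
  }
  if (is.null(id)) id <- paste0("peak_", seq_len(n))
  id <- as.character(id)
  if (anyDuplicated(id)) {
    validation_error("duplicate peak id: ", id[duplicated(id)][1])
  }
  structure(
    data.frame(chrom = as.character(chrom), start = start, end = end,
               id = id, stringsAsFactors = FALSE),
    class = c("peak_set", "data.frame")
  )
}

#' Read a BED3/BED4 file as a peak set
#'
#' Tab-separated, 0-based half-open. Ids are taken from column 4 when
#' present, otherwise generated as `peak_<n>` in file order.
#'
#' @param path Path to a BED file.
#' @return A [peak_set].
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(peak_set(character(0), integer(0), integer(0), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    parse_error("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (any(is.na(start)) || any(is.na(end))) {
    parse_error("malformed BED line ",
                which(is.na(start) | is.na(end))[1],
                ": non-integer coordinates")
  }
  id <- if (all(nf >= 4)) {
    vapply(fields, `[[`, "", 4L)
  } else {
    NULL
  }
  peak_set(chrom, start, end, id)
}

#' Write a peak set as BED4
#'
#' @param peaks A [peak_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  lines <- sprintf("%s\t%d\t%d\t%s", peaks$chrom, peaks$start, peaks$end,
                   peaks$id)
  writeLines(lines, path)
  invisible(path)
}

# Internal: GRanges view of a peak set (1-based closed, as GRanges requires).
peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    id = peaks$id
  )
}

# Internal: subset rows of a peak set, keeping the class.
peaks_subset <- function(peaks, idx) {
  out <- peaks[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Subset a peak set by id
#'
#' @param peaks A [peak_set].
#' @param ids Peak ids to keep (order of `peaks` preserved).
#' @return A [peak_set].
#' @export
filter_peaks <- function(peaks, ids) {
  peaks_subset(peaks, peaks$id %in% ids)
}

#' Peak widths in base pairs
#' @param peaks A [peak_set].
#' @return Integer vector of widths.
#' @export
peak_widths <- function(peaks) peaks$end - peaks$start
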