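# Simplified cross-species interval mapping: a 7-column TSV of equal-length
# source/target blocks standing in for a liftover chain. A peak maps iff it
# lies entirely inside one source block; the mapped interval keeps the same
# offset within the target block (mirrored for minus-strand records).

#' Read an interval mapping table
#'
#' Tab-separated with header columns `src_chrom`, `src_start`, `src_end`,
#' `tgt_chrom`, `tgt_start`, `tgt_end`, `strand`. Coordinates are 0-based
#' half-open; within a record the source and target lengths must be equal
#' and source records must not overlap one another.
#'
#' @param path Path to the mapping TSV.
#' @return A data.frame of class `interval_mapping`.
#' @export
read_interval_mapping <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("src_chrom", "src_start", "src_end", "tgt_chrom", "tgt_start",
            "tgt_end", "strand")
  if (!all(need %in% names(df))) {
    parse_error("mapping TSV must have columns: ", paste(need, collapse = ", "))
  }
  interval_mapping(df)
}

#' Construct an interval mapping
#'
#' @param df Data frame with the seven mapping columns (see
#'   [read_interval_mapping]).
#' @return A data.frame of class `interval_mapping`.
#' @export
interval_mapping <- function(df) {
  df$src_start <- as.integer(df$src_start)
  df$src_end <- as.integer(df$src_end)
  df$tgt_start <- as.integer(df$tgt_start)
  df$tgt_end <- as.integer(df$tgt_end)
  if (any((df$src_end - df$src_start) != (df$tgt_end - df$tgt_start))) {
    validation_error("mapping record with source length != target length")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    validation_error("mapping strand must be + or -")
  }
  if (nrow(df) > 1) {
    o <- order(df$src_chrom, df$src_start)
    s <- df[o, ]
    same <- s$src_chrom[-1] == s$src_chrom[-nrow(s)]
    ovl <- s$src_start[-1] < s$src_end[-nrow(s)]
    if (any(same & ovl)) validation_error("overlapping source records")
  }
  structure(df, class = c("interval_mapping", "data.frame"))
}

#' Map peaks through an interval mapping
#'
#' A peak maps iff it lies entirely within a single source record; the
#' output interval has the same offset within the target record (reversed
#' for minus-strand records). Peaks spanning record boundaries or hitting no
#' record are reported as unmapped, not as errors.
#'
#' @param peaks A [peak_set].
#' @param mapping An [interval_mapping].
#' @return A list with `mapped` (a [peak_set] in target coordinates, ids
#'   preserved) and `unmapped` (character vector of peak ids).
#' @export
map_intervals <- function(peaks, mapping) {
  n <- nrow(peaks)
  chrom <- character(n)
  start <- integer(n)
  end <- integer(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    hit <- which(mapping$src_chrom == peaks$chrom[i] &
                   mapping$src_start <= peaks$start[i] &
                   mapping$src_end >= peaks$end[i])
    if (length(hit) == 0) next
    r <- mapping[hit[1], ]
    ok[i] <- TRUE
    chrom[i] <- r$tgt_chrom
    if (r$strand == "+") {
      start[i] <- r$tgt_start + (peaks$start[i] - r$src_start)
    } else {
      start[i] <- r$tgt_start + (r$src_end - peaks$end[i])
    }
    end[i] <- start[i] + (peaks$end[i] - peaks$start[i])
  }
  mapped <- if (any(ok)) {
    peak_set(chrom[ok], start[ok], end[ok], peaks$id[ok])
  } else {
    peak_set(character(0), integer(0), integer(0), character(0))
  }
  list(mapped = mapped, unmapped = peaks$id[!ok])
}

#' Write an interval mapping table
#' @param mapping An [interval_mapping].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_mapping <- function(mapping, path) {
  utils::write.table(as.data.frame(mapping), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
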