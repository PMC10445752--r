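# Gene annotation input. Two dialects: GTF (1-based inclusive, gene_id pulled
# from the attribute column) and a plain TSV (0-based half-open). Both are
# normalized to the package-wide 0-based half-open convention on read, with a
# strand-aware TSS derived per record.

#' Construct gene records
#'
#' Coordinates are 0-based half-open; `tss` is derived strand-aware:
#' `start` for `+` genes and `end - 1` for `-` genes.
#'
#' @param gene_id Character gene identifiers.
#' @param chrom Chromosome names.
#' @param strand `"+"` or `"-"` per gene.
#' @param start,end Integer 0-based half-open coordinates.
#' @return A data.frame of class `gene_table` with a derived `tss` column.
#' @export
gene_table <- function(gene_id, chrom, strand, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start >= end)) validation_error("gene with start >= end")
  if (any(start < 0)) validation_error("negative gene start")
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-"))) {
    validation_error("unknown strand symbol: ",
                     setdiff(unique(strand), c("+", "-"))[1])
  }
  tss <- ifelse(strand == "+", start, end - 1L)
  structure(
    data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
               strand = strand, start = start, end = end,
               tss = as.integer(tss), stringsAsFactors = FALSE),
    class = c("gene_table", "data.frame")
  )
}

#' Read gene annotation
#'
#' @param path Path to the annotation file.
#' @param dialect `"gtf"` (1-based inclusive; only `gene` feature lines are
#'   used and `gene_id` is parsed from the attributes) or `"tsv"` (columns
#'   `gene_id`, `chrom`, `strand`, `start`, `end`; 0-based half-open, with a
#'   header).
#' @return A [gene_table].
#' @export
read_gene_annotation <- function(path, dialect = c("tsv", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "start", "end")
    if (!all(need %in% names(df))) {
      parse_error("annotation TSV must have columns: ",
                  paste(need, collapse = ", "))
    }
    return(gene_table(df$gene_id, df$chrom, df$strand, df$start, df$end))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    parse_error("malformed GTF line ", which(nf < 9)[1], ": fewer than 9 fields")
  }
  feat <- vapply(fields, `[[`, "", 3L)
  fields <- fields[feat == "gene"]
  if (length(fields) == 0) {
    return(gene_table(character(0), character(0), character(0),
                      integer(0), integer(0)))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start1 <- as.integer(vapply(fields, `[[`, "", 4L))
  end1 <- as.integer(vapply(fields, `[[`, "", 5L))
  strand <- vapply(fields, `[[`, "", 7L)
  attrs <- vapply(fields, `[[`, "", 9L)
  m <- regmatches(attrs, regexpr('gene_id "[^"]+"', attrs))
  if (length(m) != length(attrs)) {
    parse_error("GTF gene line without gene_id attribute")
  }
  gene_id <- sub('gene_id "([^"]+)"', "\\1", m)
  # GTF is 1-based inclusive: shift start down by one for half-open 0-based.
  gene_table(gene_id, chrom, strand, start1 - 1L, end1)
}
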