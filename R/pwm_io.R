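# PWM input. JASPAR-style count matrices are converted to probability
# matrices with a total pseudocount of 0.8 distributed by the background
# base frequencies (the TFBSTools/JASPAR convention), so columns of all
# zeros become uniform and log-odds scores stay finite.

#' Construct a PWM record
#'
#' @param motif_id Motif identifier (e.g. `"MA0001.1"`).
#' @param name Motif name; `"::"`-separated names denote dimers.
#' @param probs 4 x L probability matrix, rows A, C, G, T; columns must sum
#'   to one.
#' @param tf_names Transcription factors the motif maps to (defaults to the
#'   name split on `"::"`).
#' @param family TF family label (may be `NA` until attached).
#' @param class TF structural class label.
#' @return A list of class `pwm`.
#' @export
pwm <- function(motif_id, name, probs, tf_names = NULL, family = NA_character_,
                class = NA_character_) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L || ncol(probs) < 1L) {
    validation_error("PWM must be a 4 x L matrix with L >= 1")
  }
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    validation_error("PWM columns must sum to 1")
  }
  rownames(probs) <- c("A", "C", "G", "T")
  if (is.null(tf_names)) tf_names <- strsplit(name, "::", fixed = TRUE)[[1]]
  structure(
    list(motif_id = motif_id, name = name, probs = probs,
         tf_names = tf_names, family = family, class = class),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), length %d, family %s\n", x$motif_id, x$name,
              ncol(x$probs), x$family))
  invisible(x)
}

# Internal: counts -> probabilities with total pseudocount split by bg.
counts_to_probs <- function(counts, pseudocount = 0.8,
                            bg = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  sweep(counts + pseudocount * bg, 2, tot + pseudocount, "/")
}

#' Read JASPAR-style matrix text
#'
#' Parses records of the form
#' ```
#' >MA0001.1 NAME
#' A [ 9 0 ... ]
#' C [ 0 9 ... ]
#' G [ ... ]
#' T [ ... ]
#' ```
#' (brackets optional). Counts are converted to probabilities with a total
#' pseudocount of 0.8 distributed by `bg`.
#'
#' @param path Path to the matrix file.
#' @param pseudocount Total pseudocount added per column before
#'   normalization.
#' @param bg Background base frequencies (A, C, G, T) used to distribute the
#'   pseudocount.
#' @return A list of [pwm] records.
#' @export
read_matrix_pwm <- function(path, pseudocount = 0.8, bg = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0) parse_error("no motif records found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[k]])
    parts <- strsplit(header, "\\s+")[[1]]
    motif_id <- parts[1]
    name <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else parts[1]
    body <- lines[(starts[k] + 1L):ends[k]]
    if (length(body) != 4L) {
      parse_error("motif ", motif_id, ": expected 4 base rows, got ",
                  length(body))
    }
    rows <- lapply(body, function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1L) {
      parse_error("motif ", motif_id, ": row-length mismatch among A/C/G/T")
    }
    counts <- do.call(rbind, rows)
    out[[k]] <- pwm(motif_id, name,
                    counts_to_probs(counts, pseudocount, bg))
  }
  out
}

#' Attach TF and family maps to PWMs
#'
#' @param pwms List of [pwm] records.
#' @param motif_to_tfs Data frame with columns `motif_id`, `tf` (one row per
#'   mapping); motifs absent from the map keep their name-derived TFs.
#' @param tf_to_family Data frame with columns `tf`, `family`, and optionally
#'   `class`.
#' @return The list of PWMs with `tf_names`, `family`, `class` filled in.
#' @export
attach_tf_maps <- function(pwms, motif_to_tfs = NULL, tf_to_family = NULL) {
  lapply(pwms, function(p) {
    if (!is.null(motif_to_tfs)) {
      tfs <- motif_to_tfs$tf[motif_to_tfs$motif_id == p$motif_id]
      if (length(tfs) > 0) p$tf_names <- unique(tfs)
    }
    if (!is.null(tf_to_family)) {
      i <- match(p$tf_names, tf_to_family$tf)
      fams <- unique(stats::na.omit(tf_to_family$family[i]))
      if (length(fams) > 0) p$family <- paste(sort(fams), collapse = "+")
      if ("class" %in% names(tf_to_family)) {
        cls <- unique(stats::na.omit(tf_to_family$class[i]))
        if (length(cls) > 0) p$class <- paste(sort(cls), collapse = "+")
      }
    }
    p
  })
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file (term, description, genes...).
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    parse_error("malformed GMT line ", bad[1], ": fewer than 3 fields")
  }
  stats::setNames(
    lapply(fields, function(f) unique(f[-c(1, 2)])),
    vapply(fields, `[[`, "", 1L)
  )
}

#' Read sequences from FASTA
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}
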