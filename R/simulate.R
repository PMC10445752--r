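# Synthetic study generator. Emulates the design of a two-stage ("gestational
# day") single-nucleus ATAC study over a multi-cell-type tissue: planted
# cell-type-specific peaks partially shared between stages, lognormal
# sequencing-depth heterogeneity, Poisson fragment counts, peak sequences
# with controlled GC and planted motif occurrences, expression monotonically
# coupled to promoter-proximal accessibility, a partial cross-species
# mapping, reference-species peak sets, and the implied ground-truth
# TF-family -> gene network.

#' Built-in synthetic motif set
#'
#' Five high-information 12-bp PWMs (dominant base probability 0.97), one
#' per synthetic TF family, used as the default planted motif set.
#'
#' @return A list of [pwm] records with `tf_names` and `family` set.
#' @export
default_motif_set <- function() {
  consensi <- c(
    SM01 = "GCCTCAGGCTAA",
    SM02 = "TTACGCATCGTG",
    SM03 = "AGGATGTCCAAT",
    SM04 = "CACGATTGGACA",
    SM05 = "GTTCCGGAACTT"
  )
  base_idx <- stats::setNames(1:4, c("A", "C", "G", "T"))
  out <- vector("list", length(consensi))
  for (k in seq_along(consensi)) {
    bases <- strsplit(consensi[[k]], "")[[1]]
    probs <- matrix(0.01, 4, length(bases))
    for (j in seq_along(bases)) probs[base_idx[bases[j]], j] <- 0.97
    out[[k]] <- pwm(names(consensi)[k], paste0("TF", k), probs,
                    tf_names = paste0("TF", k),
                    family = paste0("FAM", k),
                    class = paste0("CLASS", k))
  }
  out
}

#' Simulation configuration
#'
#' Defaults describe the study the generator emulates: five labeled cell
#' types with the invasive population first, 80 nuclei per type per stage,
#' 1000 peaks of 300-500 bp on a 2 x 2 Mb genome, 50 planted specific
#' peaks per type of which 80% are shared between the two stages, a
#' threefold accessibility effect, lognormal depths inside the usual QC
#' range, each motif planted into 30% of the shared invasive-specific
#' peaks, 60% of peaks covered by the cross-species mapping.
#'
#' @param n_celltypes Number of cell types.
#' @param celltypes Cell-type labels; the first is the invasive target.
#' @param n_nuclei_per_type Nuclei per cell type per stage.
#' @param n_peaks Total peaks.
#' @param n_specific_per_type Planted specific peaks per type per stage.
#' @param shared_specific_fraction Fraction of a type's specific peaks
#'   shared between the two stages.
#' @param effect_size Fold increase of the planted peak's fragment rate in
#'   its own cell type; values <= 1 disable the effect (null data).
#' @param depth_lognormal Named numeric `c(meanlog, sdlog)` for per-nucleus
#'   depth.
#' @param genome Data frame `chrom`, `length` in bp.
#' @param peak_width_range Integer min/max peak widths in bp.
#' @param gc_mean,gc_sd Mean and sd of per-peak GC content (clamped to
#'   \[0.25, 0.65\]).
#' @param n_genes Number of genes (TSSs anchored near random peaks).
#' @param motif_set List of [pwm] records to plant.
#' @param planted_fraction Fraction of shared invasive-specific peaks that
#'   each motif is planted into.
#' @param conserved_fraction Fraction of peaks covered by the mapping.
#' @param expr_noise_sd SD of the additive expression noise.
#' @param scan_p_cutoff Motif-scan p-value cutoff used downstream (recorded
#'   in the config so analyses and ground truth agree).
#' @param seed Integer RNG seed; a fixed seed yields a byte-identical
#'   bundle.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_celltypes = 5,
                       celltypes = c("iTB", "NK", "Mac", "Endo",
                                     "SMC")[seq_len(n_celltypes)],
                       n_nuclei_per_type = 80,
                       n_peaks = 1000,
                       n_specific_per_type = 50,
                       shared_specific_fraction = 0.8,
                       effect_size = 3,
                       depth_lognormal = c(meanlog = 8, sdlog = 0.35),
                       genome = data.frame(chrom = c("chr1", "chr2"),
                                           length = c(2e6, 2e6)),
                       peak_width_range = c(300L, 500L),
                       gc_mean = 0.45, gc_sd = 0.08,
                       n_genes = 300,
                       motif_set = default_motif_set(),
                       planted_fraction = 0.3,
                       conserved_fraction = 0.6,
                       expr_noise_sd = 1.0,
                       scan_p_cutoff = 5e-5,
                       seed = 1L) {
  for (v in list(n_celltypes, n_nuclei_per_type, n_peaks,
                 n_specific_per_type, n_genes)) {
    if (!is_count(v) || v <= 0) validation_error("counts must be positive")
  }
  for (f in list(shared_specific_fraction, planted_fraction,
                 conserved_fraction)) {
    if (f < 0 || f > 1) validation_error("fractions must lie in [0, 1]")
  }
  if (n_specific_per_type * n_celltypes * 2 > n_peaks) {
    validation_error("too many specific peaks for the peak universe")
  }
  structure(
    list(n_celltypes = n_celltypes, celltypes = celltypes,
         target_type = celltypes[1],
         n_nuclei_per_type = n_nuclei_per_type, n_peaks = n_peaks,
         n_specific_per_type = n_specific_per_type,
         shared_specific_fraction = shared_specific_fraction,
         effect_size = effect_size, depth_lognormal = depth_lognormal,
         genome = genome, peak_width_range = as.integer(peak_width_range),
         gc_mean = gc_mean, gc_sd = gc_sd, n_genes = n_genes,
         motif_set = motif_set, planted_fraction = planted_fraction,
         conserved_fraction = conserved_fraction,
         expr_noise_sd = expr_noise_sd, scan_p_cutoff = scan_p_cutoff,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Noiseless configuration for end-to-end recovery checks
#'
#' A configuration in which every planted signal is recoverable with
#' certainty for practical purposes: a tenfold accessibility effect, more
#' nuclei, tight depth spread, zero expression noise and a strict motif-scan
#' cutoff (1e-7) under which random false motif hits are vanishingly rare.
#'
#' @param seed Integer RNG seed.
#' @return A `sim_config`.
#' @export
noiseless_config <- function(seed = 1L) {
  sim_config(effect_size = 10, n_nuclei_per_type = 100,
             depth_lognormal = c(meanlog = 8, sdlog = 0.2),
             expr_noise_sd = 0, scan_p_cutoff = 1e-7, seed = seed)
}

# Internal: sample a DNA string of given length and GC content.
random_dna <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

reverse_complement <- function(s) {
  paste(rev(DNA_COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
}

# Internal: consensus string of a PWM.
pwm_consensus <- function(p) {
  paste(c("A", "C", "G", "T")[apply(p$probs, 2, which.max)], collapse = "")
}

#' Generate a synthetic two-stage study bundle
#'
#' Writes every input the pipeline consumes into `dir` and returns the
#' written paths, in-memory objects and the planted ground truth. See
#' [sim_config] for the knobs and the vignette for what the generator does
#' and does not emulate.
#'
#' @param config A [sim_config].
#' @param dir Output directory (created if needed).
#' @param write_genome Also write the full genome FASTA (the peak sequences
#'   FASTA is always written).
#' @return A list with `files` (named paths), `data` (count matrices, peak
#'   set, sequences, genes, expression tables, mapping, reference sets) and
#'   `truth` (planted ground truth, also written as JSON).
#' @export
generate_dataset <- function(config = sim_config(), dir = tempfile("simdata"),
                             write_genome = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  cc <- config
  stages <- c("gd_a", "gd_b")
  types <- cc$celltypes
  effect <- if (cc$effect_size > 1) cc$effect_size else 1

  ## ---- peak placement ---------------------------------------------------
  n_chrom <- nrow(cc$genome)
  per_chrom <- diff(round(seq(0, cc$n_peaks, length.out = n_chrom + 1)))
  chrom <- rep(cc$genome$chrom, per_chrom)
  widths <- sample(seq(cc$peak_width_range[1], cc$peak_width_range[2]),
                   cc$n_peaks, replace = TRUE)
  starts <- integer(cc$n_peaks)
  off <- 0L
  for (ci in seq_len(n_chrom)) {
    nk <- per_chrom[ci]
    if (nk == 0) next
    slot <- floor(cc$genome$length[ci] / nk)
    if (slot < cc$peak_width_range[2] + 200L) {
      validation_error("genome too small for ", cc$n_peaks,
                       " peaks with spacing")
    }
    starts[off + seq_len(nk)] <- (seq_len(nk) - 1L) * slot + 100L
    off <- off + nk
  }
  peaks <- peak_set(chrom, starts, starts + widths,
                    sprintf("peak_%04d", seq_len(cc$n_peaks)))

  ## ---- specific peak assignment -----------------------------------------
  n_shared <- round(cc$shared_specific_fraction * cc$n_specific_per_type)
  n_extra <- cc$n_specific_per_type - n_shared
  pool <- sample(peaks$id)   # random order, drawn from the front
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  specific <- list(gd_a = list(), gd_b = list())
  shared_sets <- list()
  if (effect > 1) {
    for (tt in types) {
      sh <- take(n_shared)
      shared_sets[[tt]] <- sh
      specific$gd_a[[tt]] <- sort(c(sh, if (n_extra > 0) take(n_extra)))
      specific$gd_b[[tt]] <- sort(c(sh, if (n_extra > 0) take(n_extra)))
    }
  } else {
    for (tt in types) {
      shared_sets[[tt]] <- character(0)
      specific$gd_a[[tt]] <- character(0)
      specific$gd_b[[tt]] <- character(0)
    }
  }
  common_target <- sort(shared_sets[[cc$target_type]])

  ## ---- sequences and motif planting -------------------------------------
  gc_peak <- pmin(pmax(stats::rnorm(cc$n_peaks, cc$gc_mean, cc$gc_sd),
                       0.25), 0.65)
  seqs <- vapply(seq_len(cc$n_peaks), function(i) {
    random_dna(widths[i], gc_peak[i])
  }, character(1))
  names(seqs) <- peaks$id

  planted <- list()
  if (cc$planted_fraction > 0 && length(common_target) > 0 &&
      length(cc$motif_set) > 0) {
    slots_used <- stats::setNames(
      vector("list", length(common_target)), common_target)
    for (m in cc$motif_set) {
      ids <- sort(sample(common_target,
                         ceiling(cc$planted_fraction *
                                   length(common_target))))
      planted[[m$motif_id]] <- ids
      cons <- pwm_consensus(m)
      L <- nchar(cons)
      for (id in ids) {
        w <- nchar(seqs[[id]])
        # place without clobbering previously planted occurrences
        occupied <- slots_used[[id]]
        repeat {
          pos <- sample.int(w - L + 1L, 1)
          if (is.null(occupied) ||
              all(pos + L - 1L < occupied[, 1] | pos > occupied[, 2])) break
        }
        slots_used[[id]] <- rbind(occupied, c(pos, pos + L - 1L))
        ins <- if (stats::runif(1) < 0.5) cons else reverse_complement(cons)
        substr(seqs[[id]], pos, pos + L - 1L) <- ins
      }
    }
  }

  ## ---- counts per stage ---------------------------------------------------
  w <- stats::rgamma(cc$n_peaks, shape = 2, rate = 2) + 0.05
  make_stage <- function(stage) {
    depth <- round(stats::rlnorm(length(types) * cc$n_nuclei_per_type,
                                 cc$depth_lognormal[["meanlog"]],
                                 cc$depth_lognormal[["sdlog"]]))
    labels <- rep(types, each = cc$n_nuclei_per_type)
    counts <- matrix(0L, cc$n_peaks, length(depth))
    for (tt in types) {
      mult <- rep(1, cc$n_peaks)
      mult[match(specific[[stage]][[tt]], peaks$id)] <- effect
      rate <- w * mult
      rate <- rate / sum(rate)
      jj <- which(labels == tt)
      lam <- rate %o% depth[jj]
      counts[, jj] <- stats::rpois(length(lam), lam)
    }
    barcodes <- sprintf("%s_%s_%03d", stage, labels,
                        stats::ave(seq_along(labels), labels,
                                   FUN = seq_along))
    count_matrix(counts, peaks, barcodes, labels)
  }
  cm <- list(gd_a = make_stage("gd_a"), gd_b = make_stage("gd_b"))

  ## ---- genes and expression ----------------------------------------------
  anchor <- sample.int(cc$n_peaks, cc$n_genes)
  strand <- sample(c("+", "-"), cc$n_genes, replace = TRUE)
  tss <- pmax(peaks$start[anchor] + sample(-500:500, cc$n_genes,
                                           replace = TRUE), 1000L)
  glen <- sample(1000:3000, cc$n_genes, replace = TRUE)
  gstart <- ifelse(strand == "+", tss, tss + 1L - glen)
  gend <- ifelse(strand == "+", tss + glen, tss + 1L)
  genes <- gene_table(sprintf("gene_%04d", seq_len(cc$n_genes)),
                      peaks$chrom[anchor], strand, pmax(gstart, 0L), gend)
  # TF genes live away from all peaks (no accessibility signal of their own)
  tf_names <- unique(unlist(lapply(cc$motif_set, `[[`, "tf_names")))
  if (length(tf_names) > 0) {
    tf_start <- cc$genome$length[n_chrom] - 20000L -
      seq_along(tf_names) * 5000L
    genes <- gene_table(
      c(genes$gene_id, tf_names),
      c(genes$chrom, rep(cc$genome$chrom[n_chrom], length(tf_names))),
      c(genes$strand, rep("+", length(tf_names))),
      c(genes$start, tf_start),
      c(genes$end, tf_start + 2000L)
    )
  }

  activity <- lapply(cm, gene_activity, genes = genes)
  expr_rows <- list()
  for (stage in stages) {
    act <- activity[[stage]]
    for (tt in types) {
      e <- pmax(0.2 + act[, tt] / 10 +
                  stats::rnorm(nrow(act), 0, cc$expr_noise_sd), 0)
      e[rownames(act) %in% tf_names] <- 2.0
      expr_rows[[paste(stage, tt)]] <- data.frame(
        gene_id = rownames(act), celltype = tt, stage = stage,
        expression = round(e, 6), stringsAsFactors = FALSE
      )
    }
  }
  expression <- do.call(rbind, expr_rows)
  rownames(expression) <- NULL
  tf_expression <- data.frame(
    tf = tf_names,
    expr_a = 2.0, expr_b = 2.0,
    stringsAsFactors = FALSE
  )

  ## ---- cross-species mapping and reference peak sets ----------------------
  conserved_ids <- sort(sample(peaks$id,
                               round(cc$conserved_fraction * cc$n_peaks)))
  ci <- match(conserved_ids, peaks$id)
  mapping <- interval_mapping(data.frame(
    src_chrom = peaks$chrom[ci],
    src_start = peaks$start[ci] - 50L,
    src_end = peaks$end[ci] + 50L,
    tgt_chrom = paste0("h", peaks$chrom[ci]),
    tgt_start = peaks$start[ci] - 50L + 1000000L,
    tgt_end = peaks$end[ci] + 50L + 1000000L,
    strand = "+", stringsAsFactors = FALSE
  ))

  target_union <- sort(unique(c(specific$gd_a[[cc$target_type]],
                                specific$gd_b[[cc$target_type]])))
  conserved_target <- intersect(target_union, conserved_ids)
  image_of <- function(ids) {
    i <- match(ids, peaks$id)
    peak_set(paste0("h", peaks$chrom[i]), peaks$start[i] + 1000000L,
             peaks$end[i] + 1000000L, paste0("ref_", ids))
  }
  decoy_peaks <- function(n, prefix) {
    ch <- sample(paste0("h", cc$genome$chrom), n, replace = TRUE)
    st <- sample(seq(3200000L, 3900000L), n)
    peak_set(ch, st, st + 400L, sprintf("%s_%03d", prefix, seq_len(n)))
  }
  ref_atac <- if (length(conserved_target) > 0) {
    rbind(image_of(conserved_target), decoy_peaks(200, "atac_decoy"))
  } else {
    decoy_peaks(200, "atac_decoy")
  }
  class(ref_atac) <- c("peak_set", "data.frame")
  conserved_common <- intersect(common_target, conserved_ids)
  h3k_src <- if (length(conserved_common) > 0) {
    sample(conserved_common, max(1, round(0.8 * length(conserved_common))))
  } else {
    character(0)
  }
  ref_h3k27ac <- if (length(h3k_src) > 0) {
    rbind(image_of(sort(h3k_src)), decoy_peaks(100, "h3k_decoy"))
  } else {
    decoy_peaks(100, "h3k_decoy")
  }
  class(ref_h3k27ac) <- c("peak_set", "data.frame")
  chip_src <- if (length(planted) > 0) {
    intersect(planted[[1]], conserved_ids)
  } else {
    character(0)
  }
  ref_chip <- if (length(chip_src) > 0) {
    rbind(image_of(sort(chip_src)), decoy_peaks(100, "chip_decoy"))
  } else {
    decoy_peaks(100, "chip_decoy")
  }
  class(ref_chip) <- c("peak_set", "data.frame")

  ## ---- markers, orthology, gene sets --------------------------------------
  links_all <- nearest_gene(peaks, genes)
  gene_of <- stats::setNames(links_all$gene_id, links_all$peak_id)
  marker_genes <- sort(unique(stats::na.omit(gene_of[conserved_common])))
  decoy_markers <- setdiff(genes$gene_id, c(marker_genes, tf_names))
  markers <- sort(c(marker_genes,
                    decoy_markers[seq_len(min(5, length(decoy_markers)))]))
  orth <- data.frame(gene = genes$gene_id,
                     ortholog = paste0("h", genes$gene_id),
                     stringsAsFactors = FALSE)
  # a couple of one-to-many rows exercise the drop-with-warning path
  extra <- setdiff(genes$gene_id, markers)[1:2]
  orth <- rbind(orth, data.frame(gene = extra,
                                 ortholog = paste0("h", extra, "_alt"),
                                 stringsAsFactors = FALSE))
  other_genes <- setdiff(genes$gene_id, markers)
  gmt <- list(
    marker_module = markers,
    random_module_1 = sort(sample(other_genes, min(40, length(other_genes)))),
    random_module_2 = sort(sample(genes$gene_id,
                                  min(40, length(genes$gene_id))))
  )

  ## ---- ground truth --------------------------------------------------------
  edges <- list()
  for (mid in names(planted)) {
    fam <- cc$motif_set[[match(mid, vapply(cc$motif_set, `[[`, "",
                                           "motif_id"))]]$family
    pk <- intersect(planted[[mid]], conserved_common)
    g <- stats::na.omit(gene_of[pk])
    g <- unique(g[g %in% markers])
    if (length(g) > 0) {
      edges[[mid]] <- data.frame(family = fam, gene = sort(unname(g)),
                                 stringsAsFactors = FALSE)
    }
  }
  truth_network <- if (length(edges) > 0) {
    out <- unique(do.call(rbind, edges))
    out <- out[order(out$family, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(family = character(0), gene = character(0))
  }
  truth <- list(
    specific = specific,
    common_target = common_target,
    conserved_ids = conserved_ids,
    conserved_common = sort(conserved_common),
    planted_motifs = planted,
    markers = markers,
    network = truth_network
  )

  ## ---- write the bundle ----------------------------------------------------
  fp <- function(...) file.path(dir, paste0(...))
  files <- c(
    peaks_bed = fp("peaks.bed"),
    counts_gd_a = fp("counts_gd_a.mtx"),
    barcodes_gd_a = fp("barcodes_gd_a.tsv"),
    labels_gd_a = fp("labels_gd_a.tsv"),
    counts_gd_b = fp("counts_gd_b.mtx"),
    barcodes_gd_b = fp("barcodes_gd_b.tsv"),
    labels_gd_b = fp("labels_gd_b.tsv"),
    genes = fp("genes.tsv"),
    expression = fp("expression.tsv"),
    tf_expression = fp("tf_expression.tsv"),
    mapping = fp("mapping.tsv"),
    ref_atac = fp("ref_atac.bed"),
    ref_h3k27ac = fp("ref_h3k27ac.bed"),
    ref_chip = fp("ref_chip.bed"),
    markers = fp("markers.tsv"),
    orthology = fp("orthology.tsv"),
    genesets = fp("genesets.gmt"),
    peak_sequences = fp("peak_sequences.fa"),
    ground_truth = fp("ground_truth.json")
  )
  write_count_matrix(cm$gd_a, files["counts_gd_a"], files["peaks_bed"],
                     files["barcodes_gd_a"], files["labels_gd_a"])
  write_count_matrix(cm$gd_b, files["counts_gd_b"], fp("peaks.bed"),
                     files["barcodes_gd_b"], files["labels_gd_b"])
  utils::write.table(as.data.frame(genes)[, c("gene_id", "chrom", "strand",
                                              "start", "end")],
                     files["genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(expression, files["expression"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tf_expression, files["tf_expression"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_interval_mapping(mapping, files["mapping"])
  write_bed(ref_atac, files["ref_atac"])
  write_bed(ref_h3k27ac, files["ref_h3k27ac"])
  write_bed(ref_chip, files["ref_chip"])
  utils::write.table(data.frame(gene_id = markers), files["markers"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(orth, files["orthology"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(vapply(names(gmt), function(tt) {
    paste(c(tt, "synthetic", gmt[[tt]]), collapse = "\t")
  }, character(1)), files["genesets"])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), files["peak_sequences"]
  )
  jsonlite::write_json(truth, files["ground_truth"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  if (write_genome) {
    files <- c(files, genome_fasta = fp("genome.fa"))
    gseq <- vapply(seq_len(n_chrom), function(ci) {
      s <- random_dna(cc$genome$length[ci], 0.40)
      on_chr <- which(peaks$chrom == cc$genome$chrom[ci])
      for (i in on_chr) {
        substr(s, peaks$start[i] + 1L, peaks$end[i]) <- seqs[[peaks$id[i]]]
      }
      s
    }, character(1))
    names(gseq) <- cc$genome$chrom
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(gseq),
                                files["genome_fasta"])
  }

  list(
    files = files,
    data = list(counts = cm, peaks = peaks, sequences = seqs, genes = genes,
                expression = expression, tf_expression = tf_expression,
                mapping = mapping, ref_atac = ref_atac,
                ref_h3k27ac = ref_h3k27ac, ref_chip = ref_chip,
                markers = markers, orthology = orth, gmt = gmt),
    truth = truth,
    config = cc
  )
}

#' Generate a null bundle (no planted effects)
#'
#' As [generate_dataset] with the accessibility effect forced off and no
#' motif planting; used for calibration checks.
#'
#' @inheritParams generate_dataset
#' @return As [generate_dataset]; the ground truth lists no planted
#'   entities.
#' @export
generate_null <- function(config = sim_config(), dir = tempfile("simnull"),
                          write_genome = FALSE) {
  config$effect_size <- 0
  config$planted_fraction <- 0
  generate_dataset(config, dir, write_genome)
}
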