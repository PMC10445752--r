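#!/usr/bin/env Rscript

# Motif analysis in the common (both-stage) invasive-specific peaks:
# GC/length-matched background, PWM scanning with exact thresholds,
# per-motif enrichment, TF-expression filtering, family grouping, pairwise
# family co-occurrence, and the families-per-peak histogram.

suppressPackageStartupMessages(library(itbregnet))

sim <- "results/sim"
out_dir <- "results/motifs"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

peaks <- read_bed(file.path(sim, "peaks.bed"))
genes <- read_gene_annotation(file.path(sim, "genes.tsv"), "tsv")
seqs <- read_fasta_sequences(file.path(sim, "peak_sequences.fa"))
tf_expr <- read.delim(file.path(sim, "tf_expression.tsv"))
pwms <- sim_config()$motif_set

da_a <- read.delim("results/da/da_gd_a_iTB.tsv")
da_b <- read.delim("results/da/da_gd_b_iTB.tsv")
cmn <- common_peaks(filter_peaks(peaks, da_a$peak_id[da_a$specific]),
                    filter_peaks(peaks, da_b$peak_id[da_b$specific]))
write_bed(cmn[, c("chrom", "start", "end", "id")],
          file.path(out_dir, "common_peaks.bed"))
cat(sprintf("%d common invasive-specific peaks\n", nrow(cmn)))

set.seed(7)
bg <- sample_matched_background(seqs[cmn$id], seqs, n = 50000)
cat(sprintf("background: 50,000 draws, max bin deviation %.4f\n",
            bg$bin_deviation))

scan_all <- scan_motifs(seqs, pwms, p_cutoff = 5e-5)
fg_hits <- scan_all$hits[cmn$id, , drop = FALSE]
bg_hits <- scan_all$hits[bg$ids, , drop = FALSE]

enr <- motif_enrichment_test(fg_hits, bg_hits)
write.table(enr, file.path(out_dir, "motif_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(enr)

expr_tab <- data.frame(tf = tf_expr$tf, expr_a = tf_expr$expr_a,
                       expr_b = tf_expr$expr_b)
kept <- filter_expressed_tfs(enr, pwms, expr_tab, min_expr = 0.5)
kept <- kept[kept$adj_p <= 0.05 & kept$fold_change >= 1.5, ]
cat(sprintf("%d motifs enriched and expressed at both stages\n", nrow(kept)))

fam <- group_families(kept, pwms, fg_hits, bg_hits, expr_tab)
write.table(fam$table, file.path(out_dir, "family_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(fam$table[, c("family", "representative", "fold_change", "adj_p")])

# pairwise co-occurrence over shared target genes and shared peaks
links <- nearest_gene(cmn, genes)
gene_of <- setNames(links$gene_id, links$peak_id)
fams <- colnames(fam$fg_family_hits)
peak_sets <- lapply(fams, function(f) {
  rownames(fam$fg_family_hits)[fam$fg_family_hits[, f]]
})
names(peak_sets) <- fams
gene_sets <- lapply(peak_sets, function(p) unique(na.omit(gene_of[p])))
shared_genes <- pairwise_family_tests(gene_sets, nrow(genes))
shared_peaks <- pairwise_family_tests(peak_sets, nrow(cmn))
write.table(shared_genes, file.path(out_dir, "family_shared_genes_adjp.tsv"),
            sep = "\t", quote = FALSE)
write.table(shared_peaks, file.path(out_dir, "family_shared_peaks_adjp.tsv"),
            sep = "\t", quote = FALSE)
cat("smallest shared-gene adjusted p:",
    format(min(shared_genes, na.rm = TRUE), digits = 3), "\n")

fpp <- families_per_peak(fam$fg_family_hits)
write.table(data.frame(families = names(fpp$histogram),
                       peaks = as.integer(fpp$histogram)),
            file.path(out_dir, "families_per_peak_hist.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("families-per-peak histogram:\n")
print(fpp$histogram)
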