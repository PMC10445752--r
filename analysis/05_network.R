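#!/usr/bin/env Rscript

# Cross-species conservation of the common peaks and assembly of the
# conserved TF-family -> target-gene network, with in-degree centrality and
# a comparison against the planted ground truth.

suppressPackageStartupMessages(library(itbregnet))

sim <- "results/sim"
out_dir <- "results/network"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

peaks <- read_bed(file.path(sim, "peaks.bed"))
genes <- read_gene_annotation(file.path(sim, "genes.tsv"), "tsv")
seqs <- read_fasta_sequences(file.path(sim, "peak_sequences.fa"))
mapping <- read_interval_mapping(file.path(sim, "mapping.tsv"))
ref_atac <- read_bed(file.path(sim, "ref_atac.bed"))
ref_h3k <- read_bed(file.path(sim, "ref_h3k27ac.bed"))
markers <- read.delim(file.path(sim, "markers.tsv"))$gene_id
truth <- jsonlite::read_json(file.path(sim, "ground_truth.json"),
                             simplifyVector = TRUE)
pwms <- sim_config()$motif_set

cmn <- read_bed("results/motifs/common_peaks.bed")
da_b <- read.delim("results/da/da_gd_b_iTB.tsv")
stage_b_only <- filter_peaks(peaks,
                             setdiff(da_b$peak_id[da_b$specific], cmn$id))

## conservation of common vs stage-specific peaks; denominators are the
## full peak sets (peaks without a mapping record count as not conserved)
mp_c <- map_intervals(cmn, mapping)
cons_c <- conserved_overlap(mp_c$mapped, ref_atac)
mp_s <- map_intervals(stage_b_only, mapping)
cons_s <- conserved_overlap(mp_s$mapped, ref_atac)
cat(sprintf("conserved: %d/%d common, %d/%d stage-B-specific\n",
            cons_c$n_conserved, nrow(cmn),
            cons_s$n_conserved, nrow(stage_b_only)))
pc <- conservation_proportion_compare(cons_c$n_conserved, nrow(cmn),
                                      cons_s$n_conserved,
                                      nrow(stage_b_only))
cat(sprintf(paste0(
  "one-sided proportion test (common > stage-specific): p = %.3g\n",
  "  (the generator plants conservation uniformly, so no difference is\n",
  "   expected here, unlike in real data)\n"), pc$p_value))

## active-enhancer support: conserved common peaks against the mapped
## images of the whole peak universe
mp_all <- map_intervals(peaks, mapping)
mk <- chromatin_mark_overlap(
  filter_peaks(mp_all$mapped, cons_c$conserved$id), ref_h3k, mp_all$mapped)
cat(sprintf("H3K27ac overlap of conserved common peaks: p = %.3g\n",
            mk$test$p_value))

## the conserved network
cons_src <- filter_peaks(cmn, cons_c$conserved$id)
sc <- scan_motifs(seqs[cons_src$id], pwms, p_cutoff = 5e-5)
hits <- sc$hits
colnames(hits) <- vapply(pwms, `[[`, "", "family")
links <- nearest_gene(cons_src, genes)
net <- build_network(cons_src, hits, links, markers)
cat(sprintf("network: %d families -> %d genes, %d edges\n",
            length(net$families), length(net$genes), nrow(net$edges)))

export_network(net, file.path(out_dir, "network_edges.tsv"), "edge_tsv")
export_network(net, file.path(out_dir, "network.sif"), "sif")
export_network(net, file.path(out_dir, "network.graphml"), "graphml")

deg <- in_degree(net)
write.table(data.frame(gene = names(deg), in_degree = as.integer(deg)),
            file.path(out_dir, "in_degree.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("highest in-degree targets:\n")
print(head(deg))

got <- paste(net$edges$family, net$edges$gene)
want <- paste(truth$network$family, truth$network$gene)
cat(sprintf("planted-edge recovery: %d/%d (precision %.2f)\n",
            length(intersect(got, want)), length(want),
            length(intersect(got, want)) / max(length(got), 1)))
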