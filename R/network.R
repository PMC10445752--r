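# Bipartite TF-family -> target-gene network over conserved common peaks.
# An edge (family, gene) exists iff some conserved common peak carries the
# family's motif and has the gene as its nearest gene, and the gene is a
# conserved invasive-population marker. The mediating peaks are recorded on
# the edge.

#' Build the conserved regulatory network
#'
#' @param conserved_common A [peak_set] of conserved common peaks.
#' @param family_hits Logical peak x family matrix (rows named by peak id,
#'   see [group_families]) or a named list of per-family peak-id vectors.
#' @param links Peak-gene links (from [nearest_gene]) computed on
#'   `conserved_common`; links referencing unknown peaks are an error.
#' @param conserved_markers Character vector of eligible target genes
#'   (markers at both stages and conserved).
#' @return A list of class `regulatory_network` with `edges` (data.frame
#'   `family`, `gene`, `peaks` semicolon-joined), `families`, `genes`.
#' @export
build_network <- function(conserved_common, family_hits, links,
                          conserved_markers) {
  if (!all(links$peak_id %in% conserved_common$id)) {
    validation_error("links reference peaks outside the conserved common set")
  }
  if (is.matrix(family_hits)) {
    fams <- colnames(family_hits)
    hit_list <- lapply(fams, function(f) {
      rownames(family_hits)[family_hits[, f]]
    })
    names(hit_list) <- fams
  } else {
    hit_list <- family_hits
  }
  gene_of <- stats::setNames(links$gene_id, links$peak_id)
  edges <- list()
  for (f in names(hit_list)) {
    pk <- intersect(hit_list[[f]], conserved_common$id)
    pk <- pk[!is.na(gene_of[pk])]
    if (length(pk) == 0) next
    g <- gene_of[pk]
    ok <- g %in% conserved_markers
    pk <- pk[ok]; g <- g[ok]
    if (length(pk) == 0) next
    by_gene <- split(pk, g)
    edges[[f]] <- data.frame(
      family = f,
      gene = names(by_gene),
      peaks = vapply(by_gene, function(p) paste(sort(p), collapse = ";"), ""),
      stringsAsFactors = FALSE
    )
  }
  edges <- if (length(edges) > 0) {
    out <- do.call(rbind, edges)
    rownames(out) <- NULL
    out[order(out$family, out$gene), , drop = FALSE]
  } else {
    data.frame(family = character(0), gene = character(0),
               peaks = character(0), stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(
    list(edges = edges, families = unique(edges$family),
         genes = unique(edges$gene)),
    class = "regulatory_network"
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d families -> %d genes, %d edges\n",
              length(x$families), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' In-degree centrality of target genes
#'
#' Number of distinct source families with an edge to each gene.
#'
#' @param network A `regulatory_network`.
#' @return Named integer vector (gene -> in-degree), decreasing.
#' @export
in_degree <- function(network) {
  if (nrow(network$edges) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(network$edges$gene)
  sort(stats::setNames(as.integer(tab), names(tab)), decreasing = TRUE)
}

#' Export a regulatory network
#'
#' Formats: `edge_tsv` (lossless: family, gene, mediating peak ids),
#' `sif` (`family\tregulates\tgene`), `graphml` (via igraph).
#'
#' @param network A `regulatory_network`.
#' @param path Output path.
#' @param format One of `"edge_tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("edge_tsv", "sif", "graphml")) {
  format <- match.arg(format)
  e <- network$edges
  if (format == "edge_tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    writeLines(sprintf("%s\tregulates\t%s", e$family, e$gene), path)
  } else {
    g <- igraph::graph_from_data_frame(
      e[, c("family", "gene"), drop = FALSE], directed = TRUE,
      vertices = data.frame(
        name = c(network$families, network$genes),
        type = rep(c("family", "gene"),
                   c(length(network$families), length(network$genes))))
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge TSV back into a regulatory network
#'
#' Round-trip counterpart of `export_network(..., format = "edge_tsv")`.
#'
#' @param path Path to the edge TSV.
#' @return A `regulatory_network`.
#' @export
read_network_edges <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("family", "gene", "peaks") %in% names(e))) {
    parse_error("edge TSV must have columns family, gene, peaks")
  }
  structure(
    list(edges = e, families = unique(e$family), genes = unique(e$gene)),
    class = "regulatory_network"
  )
}
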