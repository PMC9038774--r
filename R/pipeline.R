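#' Run the full virome-mining pipeline on a dataset
#'
#' Executes every stage in order on an in-memory dataset (as produced by
#' [simulate_community()] or [read_dataset()]): viral screening, greedy vOTU
#' clustering of retained contigs, majority-rules taxonomy with VC
#' propagation, tRNA and CRISPR host linkage with topology classes, gene
#' classification with positional AMG validation, TPM normalization, AMG
#' group comparisons, alpha/beta diversity, UPGMA trees and the gene
#' co-occurrence network.
#'
#' Gene-level counts are inherited from the gene's contig (one short-read
#' count profile per contig), then length-normalized to TPM per gene.
#'
#' @param dataset A `viro_dataset`.
#' @param params A [viro_params()] object.
#' @param amg_families AMG family table; defaults to the shipped list.
#' @return A list of class `viro_result` with components `screen`, `votus`,
#'   `taxonomy`, `links`, `topology`, `gene_classes`, `amg_validation`,
#'   `amg`, `viral_tpm`, `gene_tpm`, `alpha_viral`, `alpha_bacterial`,
#'   `bray_curtis`, `upgma`, `network_edges`, `network_stats`.
#' @export
run_pipeline <- function(dataset, params = viro_params(),
                         amg_families = default_amg_families()) {
  stopifnot(inherits(dataset, "viro_dataset"))
  profiles <- build_screen_profiles(dataset$contigs, dataset$genes,
                                    dataset$hits)
  screen <- screen_contigs(dataset$contigs, profiles, params)
  retained <- dataset$contigs[dataset$contigs$contig_id %in%
                                screen$contig_id[screen$retained], ]
  votus <- greedy_cluster(retained, params)
  taxonomy <- vote_family(votus, dataset$genes, dataset$hits, params)
  taxonomy <- propagate_by_vc(taxonomy, votus, dataset$vc_membership, params)

  links <- rbind(
    match_trna(dataset$trnas, dataset$bacterial_contigs,
               dataset$host_taxonomy, params),
    match_spacers(dataset$crispr_arrays, retained,
                  dataset$bacterial_contigs, dataset$host_taxonomy, params)
  )
  topology <- classify_topology(links)

  gene_classes <- classify_genes(dataset$genes, dataset$hits, amg_families)

  hall <- hallmark_gene_ids(dataset)
  amg_ids <- gene_classes$gene_id[gene_classes$klass == "AMG"]
  amg_validation <- if (length(amg_ids))
    validate_context(amg_ids, dataset$genes, hall, dataset$hits, params)
    else data.frame()

  # abundance: contig-level TPM for community stats, gene-level for AMGs
  vc_counts <- dataset$viral_counts
  contig_len <- stats::setNames(dataset$contigs$length_bp,
                                dataset$contigs$contig_id)
  viral_tpm <- tpm_normalize(vc_counts, contig_len[rownames(vc_counts)])
  g <- dataset$genes[dataset$genes$contig_id %in% rownames(vc_counts), ]
  gene_counts <- vc_counts[g$contig_id, , drop = FALSE]
  rownames(gene_counts) <- g$gene_id
  gene_tpm <- tpm_normalize(gene_counts, g$end - g$start + 1L)

  amg <- amg_abundance(gene_classes, gene_tpm, dataset$samples)

  alpha_viral <- alpha_diversity(vc_counts, params)
  alpha_bacterial <- alpha_diversity(dataset$bacterial_counts, params)
  bc <- bray_curtis(viral_tpm)
  tree <- upgma_tree(bc)
  edges <- cooccurrence_network(gene_tpm, params)
  nstats <- if (nrow(edges)) network_stats(edges, params = params) else NULL

  out <- list(screen = screen, votus = votus, taxonomy = taxonomy,
              links = links, topology = topology,
              gene_classes = gene_classes,
              amg_validation = amg_validation, amg = amg,
              viral_tpm = viral_tpm, gene_tpm = gene_tpm,
              alpha_viral = alpha_viral, alpha_bacterial = alpha_bacterial,
              bray_curtis = bc, upgma = tree,
              network_edges = edges, network_stats = nstats,
              samples = dataset$samples)
  class(out) <- "viro_result"
  out
}

#' @export
print.viro_result <- function(x, ...) {
  cat("virome pipeline result\n")
  cat("  retained contigs :", sum(x$screen$retained), "of",
      nrow(x$screen), "\n")
  cat("  vOTUs            :", length(unique(x$votus$votu_id)), "\n")
  assigned <- mean(x$taxonomy$family != "Unassigned")
  cat("  family-assigned  :", sprintf("%.0f%%", 100 * assigned), "\n")
  cat("  host links       :", nrow(unique(x$links[c("virus_contig_id",
                                                    "host_taxon")])), "\n")
  cat("  AMG genes        :", sum(x$gene_classes$klass == "AMG"), "\n")
  invisible(x)
}
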