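#' Partition viral genes into core functional genes, AMGs and other
#'
#' Core functional genes are those whose VOG functional category contains
#' `Xr` (viral replication) or `Xs` (viral structure). Auxiliary metabolic
#' genes (AMGs) are genes whose Pfam family appears in a curated AMG family
#' list (nutrient transformation and pollutant degradation families). When a
#' gene matches both, core wins: structural/replication genes must not inflate
#' AMG counts. Everything else is `other`.
#'
#' @param genes Gene table (`gene_id`, `protein_id`, `contig_id`).
#' @param hits Annotation hit table (`VOG` rows carry the functional category
#'   in `label`; `PFAM` rows carry the family in `label`).
#' @param amg_families AMG family table (`pfam_family`, `amg_category`);
#'   defaults to the curated list shipped with the package.
#' @return Data.frame: `gene_id`, `contig_id`, `klass` (`core`/`AMG`/`other`),
#'   `basis` (the VOG category or Pfam family that decided), `amg_category`.
#' @export
classify_genes <- function(genes, hits, amg_families = default_amg_families()) {
  vog <- hits[hits$database == "VOG", , drop = FALSE]
  core_prot <- unique(vog$protein_id[grepl("Xr|Xs", vog$label)])
  pf <- hits[hits$database == "PFAM" &
               hits$label %in% amg_families$pfam_family, , drop = FALSE]
  cat_of <- stats::setNames(amg_families$amg_category,
                            amg_families$pfam_family)
  klass <- rep("other", nrow(genes))
  basis <- rep(NA_character_, nrow(genes))
  amg_cat <- rep(NA_character_, nrow(genes))
  is_amg <- genes$protein_id %in% pf$protein_id
  first_pf <- pf[!duplicated(pf$protein_id), ]
  idx <- match(genes$protein_id, first_pf$protein_id)
  klass[is_amg] <- "AMG"
  basis[is_amg] <- first_pf$label[idx[is_amg]]
  amg_cat[is_amg] <- unname(cat_of[first_pf$label[idx[is_amg]]])
  is_core <- genes$protein_id %in% core_prot
  both <- is_core & is_amg
  if (any(both))
    message(sum(both), " gene(s) matched both core and AMG labels; ",
            "classified core")
  first_vog <- vog[grepl("Xr|Xs", vog$label), ]
  first_vog <- first_vog[!duplicated(first_vog$protein_id), ]
  vidx <- match(genes$protein_id, first_vog$protein_id)
  klass[is_core] <- "core"
  basis[is_core] <- first_vog$label[vidx[is_core]]
  amg_cat[is_core] <- NA_character_
  data.frame(gene_id = genes$gene_id, contig_id = genes$contig_id,
             klass = klass, basis = basis, amg_category = amg_cat,
             stringsAsFactors = FALSE)
}

#' Validate the viral context of genes positionally
#'
#' For each gene of interest: `flanked_both_sides` is true when at least one
#' viral hallmark gene lies at a lower index and at least one at a higher
#' index on the same contig. Positional flags follow the DRAM-v convention:
#' `F` when the gene's rank is within `end_flag_window_genes` of either contig
#' end, `B` when the gene belongs to a run of at least `consecutive_M_for_B`
#' consecutive genes carrying the metabolism flag `M`. Any other flags
#' (`V`, `M`, `K`, `E`, `A`, `P`) are copied from `AMG_FLAG` annotation hits.
#'
#' @param gene_ids Genes to validate.
#' @param genes Full gene table for their contigs (`gene_id`, `contig_id`,
#'   `index`, `protein_id`).
#' @param hallmark_ids Gene ids annotated as viral hallmark genes.
#' @param hits Annotation table; `AMG_FLAG` rows carry single-letter flags in
#'   `label`.
#' @param params A [viro_params()] object.
#' @return Data.frame: `gene_id`, `contig_id`, `index`, `flanked_both_sides`,
#'   `flags` (comma-free string, e.g. `"MF"`).
#' @export
validate_context <- function(gene_ids, genes, hallmark_ids,
                             hits = NULL, params = viro_params()) {
  miss <- setdiff(gene_ids, genes$gene_id)
  if (length(miss))
    stop("gene(s) absent from gene table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  flag_hits <- if (is.null(hits)) NULL else
    hits[hits$database == "AMG_FLAG", , drop = FALSE]
  m_flagged <- function(g) {
    if (is.null(flag_hits)) rep(FALSE, nrow(g)) else
      g$protein_id %in% flag_hits$protein_id[flag_hits$label == "M"]
  }
  out <- lapply(gene_ids, function(gid) {
    row <- genes[genes$gene_id == gid, ]
    g <- genes[genes$contig_id == row$contig_id, ]
    g <- g[order(g$index), ]
    n <- nrow(g)
    i <- row$index
    hall_idx <- g$index[g$gene_id %in% hallmark_ids & g$gene_id != gid]
    flanked <- any(hall_idx < i) && any(hall_idx > i)
    flags <- character()
    if (!is.null(flag_hits)) {
      own <- flag_hits$label[flag_hits$protein_id == row$protein_id]
      flags <- sort(unique(own[own %in% c("V", "M", "K", "E", "A", "P")]))
    }
    # F: rank within the end window of either contig end
    if (min(i, n - 1L - i) < params$end_flag_window_genes)
      flags <- c(flags, "F")
    # B: member of a run of >= consecutive_M_for_B genes flagged M
    m <- m_flagged(g)
    if (m[match(gid, g$gene_id)]) {
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      pos <- match(gid, g$gene_id)
      in_run <- which(starts <= pos & ends >= pos)
      if (r$values[in_run] && r$lengths[in_run] >= params$consecutive_M_for_B)
        flags <- c(flags, "B")
    }
    data.frame(gene_id = gid, contig_id = row$contig_id, index = i,
               flanked_both_sides = flanked,
               flags = paste(flags, collapse = ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-sample AMG diversity and abundance with group comparisons
#'
#' For every sample: the number of distinct AMG categories present (TPM > 0)
#' and the summed TPM over AMG genes. Clean and contaminated (light + heavy)
#' groups are compared with a Wilcoxon rank-sum test on summed TPM and on
#' category diversity, and the count of AMG categories detected in each
#' condition with Fisher's exact test.
#'
#' @param gene_classes Output of [classify_genes()].
#' @param tpm_matrix Gene-level TPM matrix (genes in rows, samples in
#'   columns), e.g. from [tpm_normalize()].
#' @param samples Sample table (`sample_id`, `group`).
#' @param pseudocount Added before the log10 display column.
#' @return List with `per_sample` (data.frame: `sample_id`, `group`,
#'   `amg_diversity`, `amg_tpm`, `log10_amg_tpm`) and `tests` (data.frame of
#'   statistic/p-value rows; empty with a warning when a condition has fewer
#'   than two samples).
#' @export
amg_abundance <- function(gene_classes, tpm_matrix, samples,
                          pseudocount = 1) {
  amg <- gene_classes[gene_classes$klass == "AMG", , drop = FALSE]
  amg <- amg[amg$gene_id %in% rownames(tpm_matrix), , drop = FALSE]
  per_sample <- data.frame(
    sample_id = colnames(tpm_matrix),
    group = samples$group[match(colnames(tpm_matrix), samples$sample_id)],
    stringsAsFactors = FALSE
  )
  sub <- tpm_matrix[amg$gene_id, , drop = FALSE]
  per_sample$amg_diversity <- vapply(seq_len(ncol(sub)), function(j) {
    length(unique(amg$amg_category[sub[, j] > 0]))
  }, integer(1))
  per_sample$amg_tpm <- colSums(sub)
  per_sample$log10_amg_tpm <- log10(per_sample$amg_tpm + pseudocount)
  contaminated <- per_sample$group %in% c("light", "heavy")
  clean <- per_sample$group == "clean"
  if (sum(clean) < 2L || sum(contaminated) < 2L) {
    warning("fewer than 2 samples in a condition; group tests skipped")
    return(list(per_sample = per_sample, tests = data.frame()))
  }
  w_tpm <- stats::wilcox.test(per_sample$amg_tpm[contaminated],
                              per_sample$amg_tpm[clean], exact = FALSE)
  w_div <- stats::wilcox.test(per_sample$amg_diversity[contaminated],
                              per_sample$amg_diversity[clean], exact = FALSE)
  # categories detected vs not, clean vs contaminated
  cats <- sort(unique(stats::na.omit(amg$amg_category)))
  det <- function(mask) vapply(cats, function(cc) {
    any(sub[amg$amg_category %in% cc, mask, drop = FALSE] > 0)
  }, logical(1))
  tab <- rbind(clean = c(sum(det(clean)), length(cats) - sum(det(clean))),
               contaminated = c(sum(det(contaminated)),
                                length(cats) - sum(det(contaminated))))
  f <- stats::fisher.test(tab)
  tests <- data.frame(
    test = c("amg_tpm_ranksum", "amg_diversity_ranksum",
             "amg_category_fisher"),
    statistic = c(unname(w_tpm$statistic), unname(w_div$statistic),
                  unname(f$estimate)),
    p_value = c(w_tpm$p.value, w_div$p.value, f$p.value),
    stringsAsFactors = FALSE
  )
  list(per_sample = per_sample, tests = tests)
}

#' Pearson co-occurrence network over abundance profiles
#'
#' An edge joins two features when the Pearson correlation of their abundance
#' profiles across samples satisfies `|r| > pearson_r_threshold` and the
#' two-sided p-value (t distribution, `n - 2` degrees of freedom) is below
#' `pearson_p_threshold` (both strict). Constant rows are excluded: their
#' correlation is undefined. P-values are uncorrected by default, matching
#' common practice for display networks; set `network_p_adjust = "BH"` in the
#' parameters for Benjamini-Hochberg correction.
#'
#' @param abundance Feature-by-sample numeric matrix (at least 3 samples).
#' @param params A [viro_params()] object.
#' @return Data.frame of edges: `feature_a`, `feature_b`, `r`, `p_value`.
#' @export
cooccurrence_network <- function(abundance, params = viro_params()) {
  n <- ncol(abundance)
  if (n < 3L)
    stop("co-occurrence p-values require at least 3 samples", call. = FALSE)
  keep <- apply(abundance, 1L, function(x) stats::sd(x) > 0)
  m <- abundance[keep, , drop = FALSE]
  if (nrow(m) < 2L)
    return(data.frame(feature_a = character(), feature_b = character(),
                      r = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  r <- stats::cor(t(m), method = "pearson")
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  ut <- upper.tri(r)
  edges <- data.frame(
    feature_a = rownames(r)[row(r)[ut]],
    feature_b = rownames(r)[col(r)[ut]],
    r = r[ut], p_value = p[ut],
    stringsAsFactors = FALSE
  )
  if (params$network_p_adjust == "BH")
    edges$p_value <- stats::p.adjust(edges$p_value, method = "BH")
  edges <- edges[abs(edges$r) > params$pearson_r_threshold &
                   edges$p_value < params$pearson_p_threshold, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}
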