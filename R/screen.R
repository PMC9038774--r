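#' Build per-contig screening profiles from gene and annotation tables
#'
#' A profile counts, per contig, the genes covered by at least one hit in each
#' annotation database. All screening criteria are phrased in gene-covered
#' counts, so multiple hits to one gene count once.
#'
#' @param contigs Contig data.frame (`contig_id`, `length_bp`).
#' @param genes Gene table (`gene_id`, `contig_id`, `protein_id`, ...).
#' @param hits Annotation hit table (`protein_id`, `database`, ...).
#' @return Data.frame with columns `contig_id`, `n_genes`, `n_genes_vpf`,
#'   `n_genes_ko`, `n_genes_pfam`, `length_bp`.
#' @export
build_screen_profiles <- function(contigs, genes, hits) {
  count_db <- function(db) {
    prot <- unique(hits$protein_id[hits$database == db])
    g <- genes[genes$protein_id %in% prot, ]
    tab <- table(g$contig_id)
    out <- as.integer(tab[contigs$contig_id])
    ifelse(is.na(out), 0L, out)
  }
  tab <- table(genes$contig_id)
  n_genes <- as.integer(tab[contigs$contig_id])
  data.frame(
    contig_id = contigs$contig_id,
    n_genes = ifelse(is.na(n_genes), 0L, n_genes),
    n_genes_vpf = count_db("VPF"),
    n_genes_ko = count_db("KO"),
    n_genes_pfam = count_db("PFAM"),
    length_bp = contigs$length_bp,
    stringsAsFactors = FALSE
  )
}

#' Evaluate the three viral-screening criteria
#'
#' For each profile:
#' * `c1`: at least `min_vpf_hits` genes with a viral-protein-family hit,
#'   KO-covered gene fraction strictly below `max_ko_fraction`, and
#'   Pfam-covered gene fraction at most `max_pfam_fraction`;
#' * `c2`: at least as many VPF-covered genes as Pfam-covered genes;
#' * `c3`: VPF-covered genes reach `vpf_total_fraction` of all genes.
#'
#' Fractions on a contig with zero genes are defined as 0.
#'
#' @param profiles Data.frame from [build_screen_profiles()].
#' @param params A [viro_params()] object.
#' @return `profiles` with logical columns `c1`, `c2`, `c3` appended.
#' @export
evaluate_criteria <- function(profiles, params = viro_params()) {
  n <- profiles$n_genes
  frac <- function(x) ifelse(n == 0L, 0, x / n)
  ko_f <- frac(profiles$n_genes_ko)
  pf_f <- frac(profiles$n_genes_pfam)
  profiles$c1 <- profiles$n_genes_vpf >= params$min_vpf_hits &
    ko_f < params$max_ko_fraction &
    pf_f <= params$max_pfam_fraction
  profiles$c2 <- profiles$n_genes_vpf >= profiles$n_genes_pfam
  profiles$c3 <- profiles$n_genes_vpf >= params$vpf_total_fraction * n
  profiles
}

#' Screen contigs for viral retention
#'
#' Contigs first pass a VirSorter category gate (category in
#' `params$kept_categories`). Contigs at or below `screen_len_gate_bp` are
#' retained on the category gate alone; longer contigs are additionally
#' filtered by the three annotation criteria. Under the default
#' `retain_if_any` polarity a long contig is kept if it meets at least one
#' criterion; `discard_if_any` inverts this (the literal protocol reading —
#' see the methods vignette).
#'
#' @param contigs Contig data.frame with `contig_id`, `length_bp`,
#'   `virsorter_category` (NA allowed, never passes the gate).
#' @param profiles Screening profiles covering every contig.
#' @param params A [viro_params()] object.
#' @return Data.frame with one row per input contig: `contig_id`, `category`,
#'   `category_pass`, `c1`, `c2`, `c3`, `retained`, `reason`.
#' @export
screen_contigs <- function(contigs, profiles, params = viro_params()) {
  stopifnot(all(contigs$contig_id %in% profiles$contig_id))
  prof <- evaluate_criteria(profiles, params)
  prof <- prof[match(contigs$contig_id, prof$contig_id), ]
  cat_pass <- !is.na(contigs$virsorter_category) &
    contigs$virsorter_category %in% params$kept_categories
  too_short <- contigs$length_bp < params$min_contig_len_bp
  long <- contigs$length_bp > params$screen_len_gate_bp
  any_crit <- prof$c1 | prof$c2 | prof$c3
  crit_keep <- if (params$screen_polarity == "retain_if_any") any_crit
               else !any_crit
  retained <- !too_short & cat_pass & (!long | crit_keep)
  reason <- character(nrow(contigs))
  reason[retained] <- "retained"
  reason[!retained] <- "criteria_fail"
  reason[!cat_pass] <- "category_fail"
  reason[too_short] <- "below_min_length"
  data.frame(
    contig_id = contigs$contig_id,
    category = contigs$virsorter_category,
    category_pass = cat_pass,
    c1 = prof$c1, c2 = prof$c2, c3 = prof$c3,
    retained = retained,
    reason = reason,
    stringsAsFactors = FALSE
  )
}
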