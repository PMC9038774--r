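#' Majority-rules family assignment for vOTUs
#'
#' Each protein on a vOTU's member contigs casts at most one vote: its best
#' family among reference-family hits with bitscore at or above
#' `taxonomy_min_bitscore`; a bitscore tie between different families discards
#' the vote. A family is adopted only if its votes exceed
#' `taxonomy_vote_fraction` (default 50%, strict) of the vote denominator —
#' by default all proteins on the vOTU, including unannotated ones.
#'
#' @param votus A `viro_votus` object from [greedy_cluster()].
#' @param genes Gene table (`contig_id`, `protein_id`).
#' @param hits Annotation hit table; only `REFSEQ_FAMILY` rows are used, with
#'   the family name in `label`.
#' @param params A [viro_params()] object.
#' @return Data.frame with one row per vOTU: `votu_id`, `family`
#'   (`"Unassigned"` when no majority), `support` (vote fraction), `n_proteins`,
#'   `tier` (`"direct"` or `"unassigned"`).
#' @export
vote_family <- function(votus, genes, hits, params = viro_params()) {
  fam_hits <- hits[hits$database == "REFSEQ_FAMILY" &
                     !is.na(hits$bitscore) &
                     hits$bitscore >= params$taxonomy_min_bitscore, ,
                   drop = FALSE]
  # protein -> single vote (best family by bitscore; ties across families void)
  votes <- protein_votes(fam_hits)
  ids <- unique(votus$votu_id)
  out <- lapply(ids, function(v) {
    members <- votus$member_id[votus$votu_id == v]
    prot <- genes$protein_id[genes$contig_id %in% members]
    n_prot <- length(prot)
    pv <- votes[names(votes) %in% prot]
    denom <- if (params$taxonomy_count_unannotated) n_prot else length(pv)
    if (denom == 0L || length(pv) == 0L)
      return(data.frame(votu_id = v, family = "Unassigned", support = 0,
                        n_proteins = n_prot, tier = "unassigned",
                        stringsAsFactors = FALSE))
    tab <- sort(table(pv), decreasing = TRUE)
    support <- as.numeric(tab[1]) / denom
    if (support > params$taxonomy_vote_fraction)
      data.frame(votu_id = v, family = names(tab)[1], support = support,
                 n_proteins = n_prot, tier = "direct",
                 stringsAsFactors = FALSE)
    else
      data.frame(votu_id = v, family = "Unassigned", support = support,
                 n_proteins = n_prot, tier = "unassigned",
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# One vote per protein: the family with the highest bitscore; a tie between
# two or more distinct families discards the protein's vote.
protein_votes <- function(fam_hits) {
  if (nrow(fam_hits) == 0L) return(stats::setNames(character(), character()))
  sp <- split(fam_hits, fam_hits$protein_id)
  v <- vapply(sp, function(h) {
    best <- h$label[h$bitscore == max(h$bitscore)]
    if (length(unique(best)) == 1L) best[1] else NA_character_
  }, character(1))
  v[!is.na(v)]
}

#' Propagate family calls through viral clusters (VCs)
#'
#' An unassigned vOTU that belongs to a VC adopts family F when strictly more
#' than `taxonomy_vote_fraction` of the VC's directly assigned members carry
#' F. Direct calls never change, so propagation cannot feed back on itself.
#' vOTUs outside any VC stay unassigned.
#'
#' @param calls Output of [vote_family()].
#' @param votus The `viro_votus` object the calls were made on.
#' @param vc_membership Data.frame (`contig_id`, `vc_id`); vOTUs are mapped to
#'   a VC through their representative contig.
#' @param params A [viro_params()] object.
#' @return `calls` with propagated rows updated (`tier = "propagated"`).
#' @export
propagate_by_vc <- function(calls, votus, vc_membership,
                            params = viro_params()) {
  rep_of <- unique(votus[c("votu_id", "representative_id")])
  vc_of <- stats::setNames(vc_membership$vc_id, vc_membership$contig_id)
  calls$vc_id <- unname(vc_of[rep_of$representative_id[
    match(calls$votu_id, rep_of$votu_id)]])
  for (vc in unique(stats::na.omit(calls$vc_id))) {
    in_vc <- !is.na(calls$vc_id) & calls$vc_id == vc
    direct <- in_vc & calls$tier == "direct"
    if (!any(direct)) next
    tab <- sort(table(calls$family[direct]), decreasing = TRUE)
    if (as.numeric(tab[1]) <= params$taxonomy_vote_fraction * sum(direct))
      next
    adopt <- in_vc & calls$tier == "unassigned"
    calls$family[adopt] <- names(tab)[1]
    calls$support[adopt] <- as.numeric(tab[1]) / sum(direct)
    calls$tier[adopt] <- "propagated"
  }
  calls$vc_id <- NULL
  calls
}
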