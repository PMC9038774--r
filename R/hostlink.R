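# Full-length occurrences of `pattern` in `subject` on either strand with at
# most `max_mm` mismatches. `N` never matches (fixed = TRUE keeps every letter
# literal). Returns a data.frame of hits with the realized mismatch count.
find_occurrences <- function(pattern, subject, max_mm = 0L) {
  pat <- Biostrings::DNAString(pattern)
  subj <- Biostrings::DNAString(subject)
  out <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
    m <- Biostrings::matchPattern(p, subj, max.mismatch = max_mm,
                                  with.indels = FALSE, fixed = TRUE)
    if (length(m) == 0L) next
    mm <- Biostrings::neditStartingAt(p, subj, starting.at = BiocGenerics::start(m),
                                      with.indels = FALSE, fixed = TRUE)
    out[[strand]] <- data.frame(position = BiocGenerics::start(m),
                                strand = strand,
                                mismatches = as.integer(mm),
                                stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(position = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

empty_links <- function() {
  data.frame(virus_contig_id = character(), host_taxon = character(),
             host_contig_id = character(), evidence = character(),
             position = integer(), strand = character(),
             mismatches = integer(), stringsAsFactors = FALSE)
}

#' Link viruses to hosts through shared tRNAs
#'
#' A link is made when the full tRNA sequence recovered from a viral contig
#' occurs exactly (100% identity over 100% of its length, either strand) in a
#' bacterial contig. Self-hits (the tRNA's own source contig) are removed and
#' duplicate (virus, host contig) pairs collapsed to the first occurrence.
#'
#' @param trnas Data.frame (`virus_contig_id`, `trna_seq`).
#' @param host_contigs Data.frame (`contig_id`, `sequence`).
#' @param host_taxonomy Data.frame (`host_contig_id`, `host_taxon`).
#' @param params A [viro_params()] object.
#' @return A link data.frame (`virus_contig_id`, `host_taxon`,
#'   `host_contig_id`, `evidence`, `position`, `strand`, `mismatches`).
#' @export
match_trna <- function(trnas, host_contigs, host_taxonomy,
                       params = viro_params()) {
  taxon_of <- stats::setNames(host_taxonomy$host_taxon,
                              host_taxonomy$host_contig_id)
  links <- list()
  for (i in seq_len(nrow(trnas))) {
    seq <- toupper(trnas$trna_seq[i])
    if (nchar(seq) < params$trna_min_len_nt) next
    for (j in seq_len(nrow(host_contigs))) {
      hid <- host_contigs$contig_id[j]
      if (identical(hid, trnas$virus_contig_id[i])) next  # self-hit
      occ <- find_occurrences(seq, host_contigs$sequence[j], max_mm = 0L)
      if (nrow(occ) == 0L) next
      links[[length(links) + 1L]] <- data.frame(
        virus_contig_id = trnas$virus_contig_id[i],
        host_taxon = unname(taxon_of[hid]),
        host_contig_id = hid,
        evidence = "tRNA",
        position = occ$position[1], strand = occ$strand[1],
        mismatches = 0L, stringsAsFactors = FALSE)
    }
  }
  if (!length(links)) return(empty_links())
  links <- do.call(rbind, links)
  links[!duplicated(links[c("virus_contig_id", "host_contig_id")]), ,
        drop = FALSE]
}

#' Link viruses to hosts through CRISPR spacer/repeat evidence
#'
#' Two-step logic: (1) a spacer matches a protospacer in a viral contig over
#' its full length with at most `spacer_max_mismatch` mismatches (default 1,
#' either strand); (2) the same array's repeat must occur exactly in a
#' bacterial contig, which supplies the host taxon. Spacer matches whose
#' array repeat anchors to no bacterial contig are returned as orphan records
#' in the `"orphans"` attribute, not as links. Spacers shorter than
#' `spacer_min_len_nt` are ignored: for full-length exact or one-mismatch
#' matches, spacer length is the statistical control on chance hits.
#'
#' @param arrays CRISPR array table (`host_contig_id`, `array_id`,
#'   `repeat_seq`, `spacer_rank`, `spacer_seq`).
#' @param virus_contigs Data.frame (`contig_id`, `sequence`).
#' @param host_contigs Data.frame (`contig_id`, `sequence`).
#' @param host_taxonomy Data.frame (`host_contig_id`, `host_taxon`).
#' @param params A [viro_params()] object.
#' @return A link data.frame as in [match_trna()] (evidence `"CRISPR"`),
#'   minimal-mismatch detail per (virus, host contig) pair; orphan spacer
#'   matches in `attr(, "orphans")`.
#' @export
match_spacers <- function(arrays, virus_contigs, host_contigs, host_taxonomy,
                          params = viro_params()) {
  taxon_of <- stats::setNames(host_taxonomy$host_taxon,
                              host_taxonomy$host_contig_id)
  links <- list()
  orphans <- list()
  for (aid in unique(arrays$array_id)) {
    arr <- arrays[arrays$array_id == aid, , drop = FALSE]
    rep_seq <- toupper(arr$repeat_seq[1])
    if (nchar(rep_seq) < params$min_repeat_len_nt) next
    # step 2 anchor: bacterial contigs carrying the repeat exactly
    anchored <- host_contigs$contig_id[vapply(host_contigs$sequence,
      function(s) nrow(find_occurrences(rep_seq, s, 0L)) > 0L, logical(1))]
    for (k in seq_len(nrow(arr))) {
      spacer <- toupper(arr$spacer_seq[k])
      if (nchar(spacer) < params$spacer_min_len_nt) next
      for (j in seq_len(nrow(virus_contigs))) {
        occ <- find_occurrences(spacer, virus_contigs$sequence[j],
                                max_mm = params$spacer_max_mismatch)
        if (nrow(occ) == 0L) next
        best <- occ[which.min(occ$mismatches), , drop = FALSE]
        rec <- data.frame(
          virus_contig_id = virus_contigs$contig_id[j],
          array_id = aid, spacer_rank = arr$spacer_rank[k],
          position = best$position, strand = best$strand,
          mismatches = best$mismatches, stringsAsFactors = FALSE)
        if (length(anchored) == 0L) {
          orphans[[length(orphans) + 1L]] <- rec
        } else {
          for (hid in anchored) {
            links[[length(links) + 1L]] <- data.frame(
              virus_contig_id = rec$virus_contig_id,
              host_taxon = unname(taxon_of[hid]),
              host_contig_id = hid,
              evidence = "CRISPR",
              position = rec$position, strand = rec$strand,
              mismatches = rec$mismatches, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (length(links)) do.call(rbind, links) else empty_links()
  # minimal-mismatch detail per (virus, host contig) pair
  if (nrow(out)) {
    out <- out[order(out$virus_contig_id, out$host_contig_id,
                     out$mismatches), ]
    out <- out[!duplicated(out[c("virus_contig_id", "host_contig_id")]), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "orphans") <- if (length(orphans)) do.call(rbind, orphans) else
    data.frame()
  out
}

#' Classify virus-host link topology
#'
#' Links are deduplicated to (virus, host taxon) pairs and classified from
#' the bipartite degree pattern: an edge whose virus has one host and whose
#' host has one virus is a specialist pair; edges of a host with two or more
#' viruses are generalist on the host side; edges of a virus with two or more
#' host taxa are polyvalent on the virus side. One edge can carry both a
#' host-side and a virus-side class.
#'
#' @param links A link data.frame from the matchers (or their rbind).
#' @return Data.frame of unique (virus, host taxon) edges with logical
#'   columns `specialist`, `generalist_host`, `polyvalent_virus`.
#' @export
classify_topology <- function(links) {
  edges <- unique(links[c("virus_contig_id", "host_taxon")])
  if (nrow(edges) == 0L)
    return(cbind(edges, specialist = logical(), generalist_host = logical(),
                 polyvalent_virus = logical()))
  deg_v <- table(edges$virus_contig_id)
  deg_h <- table(edges$host_taxon)
  dv <- as.integer(deg_v[edges$virus_contig_id])
  dh <- as.integer(deg_h[edges$host_taxon])
  edges$specialist <- dv == 1L & dh == 1L
  edges$generalist_host <- dh >= 2L
  edges$polyvalent_virus <- dv >= 2L
  rownames(edges) <- NULL
  edges
}
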