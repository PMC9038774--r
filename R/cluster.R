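# Substitution matrix over {A,C,G,T,N}: N never scores as a match, not even
# against another N.
align_submat <- function(match, mismatch) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- match
  m
}

#' Summarize a pairwise nucleotide alignment
#'
#' End-gap-free (overlap) alignment of two contig sequences, scored with the
#' match/mismatch/gap scheme in `params`. Both the forward and the
#' reverse-complement orientation of `b` are evaluated and the higher-scoring
#' one reported. `N` counts as a mismatch against everything. Identity is
#' matched bases over aligned columns; coverage is aligned columns over the
#' length of the shorter sequence.
#'
#' @param seq_a,seq_b Nucleotide sequences (character scalars).
#' @param params A [viro_params()] object.
#' @return A one-row data.frame: `identity`, `coverage`, `aligned_len_bp`,
#'   `orientation` (`"+"` or `"-"`), `score`.
#' @export
align_pair <- function(seq_a, seq_b, params = viro_params()) {
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  if (max(nchar(seq_a), nchar(seq_b)) > params$align_max_len)
    stop("sequence exceeds align_max_len (", params$align_max_len,
         " bp); use the k-mer prefilter mode for long inputs", call. = FALSE)
  sm <- align_submat(params$align_match, params$align_mismatch)
  a <- Biostrings::DNAString(seq_a)
  b_f <- Biostrings::DNAString(seq_b)
  b_r <- Biostrings::reverseComplement(b_f)
  one <- function(b) {
    Biostrings::pairwiseAlignment(
      a, b, type = "overlap", substitutionMatrix = sm,
      gapOpening = params$align_gap_open,
      gapExtension = params$align_gap_extend
    )
  }
  al_f <- one(b_f)
  al_r <- one(b_r)
  fwd <- Biostrings::score(al_f) >= Biostrings::score(al_r)
  al <- if (fwd) al_f else al_r
  cols <- Biostrings::nchar(al)
  # matched bases counted by hand so that N never matches, not even N vs N
  pa <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  nmatch <- sum(pa == sa & pa != "-" & pa != "N")
  ident <- if (cols == 0L) 0 else nmatch / cols
  cov <- min(1, cols / min(nchar(seq_a), nchar(seq_b)))
  data.frame(identity = ident, coverage = cov,
             aligned_len_bp = as.integer(cols),
             orientation = if (fwd) "+" else "-",
             score = Biostrings::score(al),
             stringsAsFactors = FALSE)
}

# Canonical k-mer set of a sequence (k-mers containing N are dropped; each
# k-mer is represented by the lexicographic min of itself and its reverse
# complement so orientation does not matter).
canonical_kmers <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character())
  km <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (!length(km)) return(character())
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  unique(pmin(km, rc))
}

#' Greedy centroid clustering of viral contigs into vOTUs
#'
#' Contigs are sorted by length (descending, ties broken lexicographically by
#' id) and processed in order: each contig joins the first existing cluster
#' whose representative it matches at `votu_min_identity` identity and
#' `votu_min_coverage` coverage, otherwise it founds a new cluster. Because
#' assignment is always against representatives in founding order and sorting
#' is internal, the partition is invariant to input order, and every
#' representative is the longest member of its cluster.
#'
#' An optional shared-k-mer prefilter (on by default) skips the alignment of
#' pairs that share no canonical 21-mer; such pairs cannot approach the 95%
#' identity gate.
#'
#' @param contigs Data.frame with `contig_id`, `sequence`, `length_bp`.
#' @param params A [viro_params()] object.
#' @return An object of class `viro_votus`: a data.frame with one row per
#'   contig (`votu_id`, `representative_id`, `member_id`, `member_len`,
#'   `representative_len`).
#' @export
greedy_cluster <- function(contigs, params = viro_params()) {
  stopifnot(nrow(contigs) >= 1L, !anyDuplicated(contigs$contig_id))
  ord <- order(-contigs$length_bp, contigs$contig_id)
  contigs <- contigs[ord, ]
  n <- nrow(contigs)
  rep_idx <- integer(0)       # indices (into contigs) of representatives
  assign_rep <- integer(n)    # for each contig, index of its representative
  kmers <- if (params$kmer_prefilter) vector("list", n) else NULL
  get_kmers <- function(i) {
    if (is.null(kmers[[i]]))
      kmers[[i]] <<- canonical_kmers(contigs$sequence[i], params$kmer_k)
    kmers[[i]]
  }
  for (i in seq_len(n)) {
    hit <- 0L
    for (r in rep_idx) {
      if (params$kmer_prefilter &&
          !any(get_kmers(i) %in% get_kmers(r))) next
      al <- align_pair(contigs$sequence[r], contigs$sequence[i], params)
      if (al$identity >= params$votu_min_identity &&
          al$coverage >= params$votu_min_coverage) {
        hit <- r
        break
      }
    }
    if (hit == 0L) {
      rep_idx <- c(rep_idx, i)
      assign_rep[i] <- i
    } else {
      assign_rep[i] <- hit
    }
  }
  votu_id <- sprintf("vOTU_%04d", match(assign_rep, rep_idx))
  out <- data.frame(
    votu_id = votu_id,
    representative_id = contigs$contig_id[assign_rep],
    member_id = contigs$contig_id,
    member_len = contigs$length_bp,
    representative_len = contigs$length_bp[assign_rep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$votu_id, out$member_id), ]
  rownames(out) <- NULL
  class(out) <- c("viro_votus", "data.frame")
  out
}

#' @export
print.viro_votus <- function(x, ...) {
  cat("vOTU clustering: ", length(unique(x$votu_id)), " clusters over ",
      nrow(x), " contigs\n", sep = "")
  NextMethod()
}

#' Select vOTUs with long representatives
#'
#' Keeps clusters whose representative is strictly longer than
#' `votu_long_len_bp` (default 10 kb), the subset conventionally taken forward
#' to protein-sharing analyses.
#'
#' @param votus A `viro_votus` object from [greedy_cluster()].
#' @param params A [viro_params()] object.
#' @return The filtered `viro_votus` subset.
#' @export
select_long <- function(votus, params = viro_params()) {
  out <- votus[votus$representative_len > params$votu_long_len_bp, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}
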