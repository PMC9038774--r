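#' Pipeline parameter set
#'
#' All numeric thresholds used across the pipeline live in one object so that
#' nothing is hard-coded in stage functions and every gate can be audited or
#' switched from a single config file.
#'
#' @param min_contig_len_bp Minimum contig length considered at all (bp).
#' @param screen_len_gate_bp Contigs longer than this are subject to the three
#'   annotation-fraction screening criteria; shorter contigs pass or fail on
#'   their VirSorter category alone.
#' @param kept_categories VirSorter categories accepted as viral.
#' @param min_vpf_hits Minimum genes with a viral-protein-family hit
#'   (criterion 1).
#' @param max_ko_fraction Maximum fraction of genes with a KEGG KO hit,
#'   strict `<` (criterion 1).
#' @param max_pfam_fraction Maximum fraction of genes with a Pfam hit,
#'   inclusive `<=` (criterion 1).
#' @param vpf_total_fraction VPF genes must reach this fraction of all genes
#'   (criterion 3).
#' @param screen_polarity `"retain_if_any"` keeps long contigs meeting at
#'   least one criterion (protocol reading); `"discard_if_any"` removes them
#'   (the literal reading). See the methods vignette.
#' @param votu_min_identity,votu_min_coverage Greedy vOTU clustering gates.
#' @param votu_long_len_bp Representative length gate (strict `>`) for the
#'   "long vOTU" subset used in protein-sharing analyses.
#' @param align_match,align_mismatch,align_gap_open,align_gap_extend Scoring
#'   for the end-gap-free pairwise alignment.
#' @param align_max_len Hard cap on sequence length for full dynamic
#'   programming alignment.
#' @param kmer_prefilter Use a shared 21-mer screen to skip alignment of
#'   pairs that cannot reach the identity gate.
#' @param kmer_k k-mer size of the prefilter.
#' @param taxonomy_min_bitscore Minimum BLASTp-style bitscore for a protein
#'   family vote.
#' @param taxonomy_vote_fraction Majority needed to adopt a family,
#'   strict `>`.
#' @param taxonomy_count_unannotated Count proteins without any qualifying hit
#'   in the vote denominator.
#' @param spacer_max_mismatch Maximum mismatches for a spacer-protospacer
#'   match (`0` gives the strict-exact mode).
#' @param spacer_min_len_nt Minimum spacer length considered; for full-length
#'   matches this is the statistical control that replaces a BLAST E-value
#'   cutoff.
#' @param trna_min_len_nt Minimum tRNA length considered.
#' @param min_repeat_len_nt Minimum CRISPR repeat length.
#' @param pearson_r_threshold,pearson_p_threshold Co-occurrence network gates
#'   (`|r| >` and `p <`, both strict).
#' @param network_p_adjust Multiple-testing correction for network p-values
#'   (`"none"` mirrors the original analysis; `"BH"` available).
#' @param end_flag_window_genes A gene within this many positions of either
#'   contig end receives flag `F`.
#' @param consecutive_M_for_B Minimum run length of metabolism-flagged genes
#'   for flag `B`.
#' @param shannon_base Logarithm base for Shannon diversity (natural log by
#'   default).
#' @param clustering_include_low_degree Count degree < 2 nodes as clustering
#'   coefficient 0 (NetworkAnalyzer convention) rather than dropping them.
#' @param rng_seed Seed recorded with the parameter set.
#'
#' @return An object of class `viro_params` (a validated named list).
#' @examples
#' p <- viro_params()
#' p$votu_min_identity
#' @export
viro_params <- function(min_contig_len_bp = 1000,
                        screen_len_gate_bp = 5000,
                        kept_categories = c(1L, 2L, 4L, 5L),
                        min_vpf_hits = 5,
                        max_ko_fraction = 0.20,
                        max_pfam_fraction = 0.40,
                        vpf_total_fraction = 0.60,
                        screen_polarity = c("retain_if_any", "discard_if_any"),
                        votu_min_identity = 0.95,
                        votu_min_coverage = 0.80,
                        votu_long_len_bp = 10000,
                        align_match = 1,
                        align_mismatch = -1,
                        align_gap_open = 5,
                        align_gap_extend = 1,
                        align_max_len = 100000,
                        kmer_prefilter = TRUE,
                        kmer_k = 21L,
                        taxonomy_min_bitscore = 50,
                        taxonomy_vote_fraction = 0.50,
                        taxonomy_count_unannotated = TRUE,
                        spacer_max_mismatch = 1L,
                        spacer_min_len_nt = 20L,
                        trna_min_len_nt = 50L,
                        min_repeat_len_nt = 18L,
                        pearson_r_threshold = 0.6,
                        pearson_p_threshold = 0.05,
                        network_p_adjust = c("none", "BH"),
                        end_flag_window_genes = 2L,
                        consecutive_M_for_B = 3L,
                        shannon_base = exp(1),
                        clustering_include_low_degree = TRUE,
                        rng_seed = 1L) {
  p <- list(
    min_contig_len_bp = as.numeric(min_contig_len_bp),
    screen_len_gate_bp = as.numeric(screen_len_gate_bp),
    kept_categories = as.integer(kept_categories),
    min_vpf_hits = as.numeric(min_vpf_hits),
    max_ko_fraction = as.numeric(max_ko_fraction),
    max_pfam_fraction = as.numeric(max_pfam_fraction),
    vpf_total_fraction = as.numeric(vpf_total_fraction),
    screen_polarity = match.arg(screen_polarity),
    votu_min_identity = as.numeric(votu_min_identity),
    votu_min_coverage = as.numeric(votu_min_coverage),
    votu_long_len_bp = as.numeric(votu_long_len_bp),
    align_match = as.numeric(align_match),
    align_mismatch = as.numeric(align_mismatch),
    align_gap_open = as.numeric(align_gap_open),
    align_gap_extend = as.numeric(align_gap_extend),
    align_max_len = as.numeric(align_max_len),
    kmer_prefilter = isTRUE(kmer_prefilter),
    kmer_k = as.integer(kmer_k),
    taxonomy_min_bitscore = as.numeric(taxonomy_min_bitscore),
    taxonomy_vote_fraction = as.numeric(taxonomy_vote_fraction),
    taxonomy_count_unannotated = isTRUE(taxonomy_count_unannotated),
    spacer_max_mismatch = as.integer(spacer_max_mismatch),
    spacer_min_len_nt = as.integer(spacer_min_len_nt),
    trna_min_len_nt = as.integer(trna_min_len_nt),
    min_repeat_len_nt = as.integer(min_repeat_len_nt),
    pearson_r_threshold = as.numeric(pearson_r_threshold),
    pearson_p_threshold = as.numeric(pearson_p_threshold),
    network_p_adjust = match.arg(network_p_adjust),
    end_flag_window_genes = as.integer(end_flag_window_genes),
    consecutive_M_for_B = as.integer(consecutive_M_for_B),
    shannon_base = as.numeric(shannon_base),
    clustering_include_low_degree = isTRUE(clustering_include_low_degree),
    rng_seed = as.integer(rng_seed)
  )
  validate_params(p)
  class(p) <- "viro_params"
  p
}

validate_params <- function(p) {
  fracs <- c("max_ko_fraction", "max_pfam_fraction", "vpf_total_fraction",
             "votu_min_identity", "votu_min_coverage",
             "taxonomy_vote_fraction")
  for (f in fracs) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("parameter '", f, "' must be a fraction in [0, 1]", call. = FALSE)
  }
  pos <- c("min_contig_len_bp", "screen_len_gate_bp", "min_vpf_hits",
           "votu_long_len_bp", "align_max_len", "taxonomy_min_bitscore",
           "spacer_min_len_nt", "trna_min_len_nt", "min_repeat_len_nt",
           "pearson_r_threshold", "pearson_p_threshold",
           "end_flag_window_genes", "consecutive_M_for_B")
  for (f in pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("parameter '", f, "' must be a positive number", call. = FALSE)
  }
  if (p$spacer_max_mismatch < 0L)
    stop("'spacer_max_mismatch' must be >= 0", call. = FALSE)
  if (!all(p$kept_categories %in% 1:6))
    stop("'kept_categories' must be VirSorter categories in 1..6",
         call. = FALSE)
  invisible(p)
}

#' @export
print.viro_params <- function(x, ...) {
  cat("viromine parameter set\n")
  cat("  screening : categories {", paste(x$kept_categories, collapse = ","),
      "}, length gate ", x$screen_len_gate_bp, " bp, polarity ",
      x$screen_polarity, "\n", sep = "")
  cat("  criteria  : >=", x$min_vpf_hits, " VPF genes, KO < ",
      x$max_ko_fraction * 100, "%, Pfam <= ", x$max_pfam_fraction * 100,
      "%, VPF >= ", x$vpf_total_fraction * 100, "% of genes\n", sep = "")
  cat("  vOTUs     : identity >= ", x$votu_min_identity, ", coverage >= ",
      x$votu_min_coverage, ", long > ", x$votu_long_len_bp, " bp\n", sep = "")
  cat("  taxonomy  : bitscore >= ", x$taxonomy_min_bitscore,
      ", majority > ", x$taxonomy_vote_fraction * 100, "%\n", sep = "")
  cat("  host link : spacer mismatch <= ", x$spacer_max_mismatch,
      ", spacer >= ", x$spacer_min_len_nt, " nt, repeat exact\n", sep = "")
  cat("  AMG flags : F within ", x$end_flag_window_genes,
      " genes of an end, B run >= ", x$consecutive_M_for_B, " M genes\n",
      sep = "")
  cat("  network   : |r| > ", x$pearson_r_threshold, ", p < ",
      x$pearson_p_threshold, " (", x$network_p_adjust, ")\n", sep = "")
  invisible(x)
}

#' Read or write a parameter set as YAML
#'
#' Round-trips every threshold exactly: values are written as plain YAML
#' scalars and re-validated on read.
#'
#' @param path File path.
#' @param params A `viro_params` object.
#' @return `read_params()` returns a `viro_params`; `write_params()` returns
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  do.call(viro_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "viro_params"))
  yaml::write_yaml(unclass(params), path, precision = 15L)
  invisible(path)
}
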