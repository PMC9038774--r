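#' Read contig sequences from FASTA
#'
#' Sequences are uppercased (ambiguity code `N` preserved) and ids are taken
#' from the header up to the first whitespace. Record order is preserved.
#'
#' @param path FASTA file.
#' @return A data.frame with columns `contig_id`, `sequence`, `length_bp`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(contig_id = character(), sequence = character(),
                      length_bp = integer(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  seq <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("non-ACGTN characters in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  data.frame(contig_id = ids, sequence = unname(seq),
             length_bp = nchar(seq), stringsAsFactors = FALSE)
}

#' Write contig sequences to FASTA
#'
#' @param contigs Data.frame with `contig_id` and `sequence` columns.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  stopifnot(is.data.frame(contigs),
            all(c("contig_id", "sequence") %in% names(contigs)))
  x <- Biostrings::DNAStringSet(contigs$sequence)
  names(x) <- contigs$contig_id
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}

# Column schemas for every tabular interchange format the pipeline touches.
viro_schemas <- list(
  contig_meta = c("contig_id", "sample_id", "group", "virsorter_category"),
  genes = c("gene_id", "contig_id", "index", "start", "end", "strand",
            "protein_id"),
  hits = c("protein_id", "database", "accession", "label", "bitscore"),
  crispr = c("host_contig_id", "array_id", "repeat_seq", "spacer_rank",
             "spacer_seq"),
  trna = c("virus_contig_id", "trna_seq"),
  vc = c("contig_id", "vc_id"),
  samples = c("sample_id", "group"),
  host_taxonomy = c("host_contig_id", "host_taxon"),
  amg_families = c("pfam_family", "amg_category")
)

viro_databases <- c("VPF", "KO", "PFAM", "VOG", "REFSEQ_FAMILY", "AMG_FLAG")
viro_groups <- c("clean", "light", "heavy")

#' Read a typed pipeline table
#'
#' All tabular interchange formats are tab-separated with a header row. The
#' table is validated against its schema and type invariants before return.
#'
#' @param path TSV file.
#' @param schema One of `"contig_meta"`, `"genes"`, `"hits"`, `"crispr"`,
#'   `"trna"`, `"vc"`, `"samples"`, `"host_taxonomy"`, `"amg_families"`.
#' @param contigs Optional contig data.frame (with `length_bp`) used to check
#'   gene coordinates against contig bounds.
#' @return A validated data.frame.
#' @export
read_table <- function(path, schema, contigs = NULL) {
  schema <- match.arg(schema, names(viro_schemas))
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  missing <- setdiff(viro_schemas[[schema]], names(df))
  if (length(missing))
    stop("table '", basename(path), "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[viro_schemas[[schema]]]
  validate_viro_table(df, schema, contigs = contigs)
}

#' @rdname read_table
#' @param df A data.frame conforming to `schema`.
#' @export
write_table <- function(df, path, schema = NULL) {
  if (!is.null(schema)) {
    schema <- match.arg(schema, names(viro_schemas))
    df <- validate_viro_table(df[viro_schemas[[schema]]], schema)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a pipeline table against its type invariants
#'
#' @inheritParams read_table
#' @param df Data.frame to validate.
#' @return `df`, with typed columns.
#' @export
validate_viro_table <- function(df, schema, contigs = NULL) {
  schema <- match.arg(schema, names(viro_schemas))
  switch(schema,
    contig_meta = {
      if (anyDuplicated(df$contig_id))
        stop("duplicate contig_id in contig metadata", call. = FALSE)
      if (!all(is.na(df$group) | df$group %in% viro_groups))
        stop("group must be one of: ", paste(viro_groups, collapse = ", "),
             call. = FALSE)
      df$virsorter_category <- as.integer(df$virsorter_category)
      ok <- is.na(df$virsorter_category) | df$virsorter_category %in% 1:6
      if (!all(ok))
        stop("virsorter_category out of 1..6 for contig(s): ",
             paste(df$contig_id[!ok], collapse = ", "), call. = FALSE)
      grp <- unique(df[!is.na(df$group), c("sample_id", "group")])
      if (anyDuplicated(grp$sample_id))
        stop("a sample_id maps to more than one group", call. = FALSE)
    },
    genes = {
      df$index <- as.integer(df$index)
      df$start <- as.integer(df$start)
      df$end <- as.integer(df$end)
      if (anyDuplicated(df$gene_id))
        stop("duplicate gene_id", call. = FALSE)
      bad <- df$index < 0L | df$start < 1L | df$start > df$end |
        !(df$strand %in% c("+", "-"))
      if (any(bad))
        stop("invalid coordinates/strand for gene(s): ",
             paste(df$gene_id[bad], collapse = ", "), call. = FALSE)
      for (cid in unique(df$contig_id)) {
        g <- df[df$contig_id == cid, ]
        g <- g[order(g$start), ]
        if (!identical(g$index, seq_len(nrow(g)) - 1L))
          stop("gene index on contig '", cid,
               "' is not gap-free 0..n-1 in start order", call. = FALSE)
      }
      if (!is.null(contigs)) {
        len <- stats::setNames(contigs$length_bp, contigs$contig_id)
        over <- !is.na(len[df$contig_id]) & df$end > len[df$contig_id]
        if (any(over))
          stop("gene end beyond contig length for gene(s): ",
               paste(df$gene_id[over], collapse = ", "), call. = FALSE)
      }
    },
    hits = {
      if (!all(df$database %in% viro_databases))
        stop("unknown annotation database; expected one of: ",
             paste(viro_databases, collapse = ", "), call. = FALSE)
      df$bitscore <- as.numeric(df$bitscore)
      if (anyDuplicated(df[c("protein_id", "database", "accession")]))
        stop("duplicate (protein_id, database, accession) hit", call. = FALSE)
      bad <- df$database == "REFSEQ_FAMILY" & is.na(df$bitscore)
      if (any(bad))
        stop("REFSEQ_FAMILY hits require a bitscore", call. = FALSE)
      if (any(!is.na(df$bitscore) & df$bitscore < 0))
        stop("negative bitscore", call. = FALSE)
    },
    crispr = {
      df$spacer_rank <- as.integer(df$spacer_rank)
      if (any(nchar(df$repeat_seq) < 18L))
        stop("CRISPR repeat shorter than 18 nt in array(s): ",
             paste(unique(df$array_id[nchar(df$repeat_seq) < 18L]),
                   collapse = ", "), call. = FALSE)
    },
    trna = {
      df$trna_seq <- toupper(df$trna_seq)
    },
    vc = NULL,
    samples = {
      if (!all(df$group %in% viro_groups))
        stop("group must be one of: ", paste(viro_groups, collapse = ", "),
             call. = FALSE)
      if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id", call. = FALSE)
    },
    host_taxonomy = {
      if (anyDuplicated(df$host_contig_id))
        stop("a host contig maps to more than one taxon", call. = FALSE)
    },
    amg_families = {
      if (anyDuplicated(df$pfam_family))
        stop("duplicate pfam_family in AMG list", call. = FALSE)
    }
  )
  df
}

#' Read or write an abundance matrix
#'
#' Wide TSV: first column `feature_id`, one column per sample, non-negative
#' numeric values.
#'
#' @param path TSV file.
#' @return A numeric matrix, features in rows, samples in columns.
#' @export
read_abundance <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "feature_id")
    stop("abundance table must start with a 'feature_id' column",
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$feature_id
  if (any(m < 0, na.rm = TRUE)) stop("negative abundance value", call. = FALSE)
  m
}

#' @rdname read_abundance
#' @param m Numeric matrix with feature rownames and sample colnames.
#' @export
write_abundance <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default auxiliary-metabolic-gene family list
#'
#' A curated table mapping protein-family labels to AMG categories (carbon,
#' nitrogen, phosphorus, sulfur, pesticide degradation). Covers denitrification
#' (norD/norQ), sulfate assimilation (cysD/cysH), carbohydrate-active enzyme
#' families (GH/GT/CBM), phosphorus cycling, aldehyde dehydrogenase and the
#' haloacid dehalogenase (L-DEX) families implicated in organochlorine
#' pesticide degradation. The list is data, not code: pass your own table with
#' the same columns to widen or narrow the AMG definition.
#'
#' @return Data.frame with columns `pfam_family`, `amg_category`.
#' @export
default_amg_families <- function() {
  path <- system.file("extdata", "amg_families.tsv", package = "viromine",
                      mustWork = TRUE)
  read_table(path, "amg_families")
}
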