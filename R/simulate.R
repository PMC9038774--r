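random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute `m` bases at distinct positions drawn from [from, to], always to
# a different base, so pairwise identity is exactly 1 - m/length.
mutate_seq <- function(seq, m, from, to) {
  if (m == 0L) return(seq)
  pos <- sample(seq.int(from, to), m)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Synthetic community design
#'
#' Describes a complete synthetic soil-virome study: viral lineages with
#' point-mutation variants (clustering truth), screening plants, bacterial
#' host contigs with CRISPR arrays and shared tRNAs (linkage truth), planted
#' AMGs in hallmark-flanked context, and a clean / light / heavy sample
#' layout with multiplicative contamination effects on richness and AMG
#' abundance. Defaults mirror a nine-sample design (3 clean, 3 lightly and 3
#' heavily contaminated samples).
#'
#' @param n_samples_per_group Named vector of sample counts for groups
#'   `clean`, `light`, `heavy`.
#' @param n_viral_lineages Number of viral lineages (each one true vOTU).
#' @param variants_per_lineage Contigs per lineage: the ancestor plus
#'   `variants_per_lineage - 1` variants.
#' @param variant_identity_levels Identity of each non-ancestor variant to
#'   its lineage ancestor (recycled). Levels at or above 0.95 co-cluster with
#'   the ancestor in the planted partition; lower levels are their own truth
#'   clusters.
#' @param n_decoys Extra singleton contigs derived from random lineages at
#'   `decoy_identity` — below the clustering gate, so each is its own vOTU.
#' @param decoy_identity Identity of decoys to their source ancestor.
#' @param viral_contig_len_bp Variant length; ancestors are 10 bp longer so
#'   the ancestor is always the longest member (and hence the greedy
#'   representative) of its lineage.
#' @param genes_per_contig Genes laid out per contig.
#' @param n_bacterial_taxa Bacterial taxa (one 3 kb contig each).
#' @param bacterial_contig_len_bp Bacterial contig length.
#' @param n_long_pass,n_long_fail Long viral contigs planted to pass (12 kb)
#'   or fail (6 kb) the three screening criteria.
#' @param n_nonviral VirSorter category 3 contigs planted to fail the
#'   category gate.
#' @param planted_links Data.frame (`lineage`, `taxon`, `evidence`,
#'   `mismatches`) of virus-host plants; `NULL` builds a default set
#'   alternating tRNA and CRISPR evidence with 0/1 spacer mismatches.
#' @param amg_insertion_rate Fraction of lineages carrying one planted AMG.
#' @param abundance_meanlog,abundance_sdlog Lognormal base-abundance model.
#' @param gained_taxa_abundance Relative base abundance of
#'   contamination-exclusive viral features (lineages invisible to clean
#'   samples, and decoys). Richness gained under contamination enters at the
#'   rare tail of the community, as newly detected taxa do in real
#'   rarefaction data; this also keeps the planted AMG relative-abundance
#'   ordering from being washed out by the extra features.
#' @param contamination_effects Multiplicative effects:
#'   `bacterial_richness_drop` (fraction of the rarest bacterial taxa absent
#'   from contaminated samples), `viral_richness_gain` (contaminated samples
#'   see this factor more viral lineages; decoy contigs are
#'   contamination-exclusive), `amg_tpm_multiplier` (AMG-carrier abundance
#'   multiplier: light gets its square root, heavy the full factor).
#' @param rng_seed Seed; the same seed yields a byte-identical dataset.
#' @return A `synth_design` list.
#' @export
synth_design <- function(n_samples_per_group = c(clean = 3, light = 3,
                                                 heavy = 3),
                         n_viral_lineages = 8,
                         variants_per_lineage = 2,
                         variant_identity_levels = 0.97,
                         n_decoys = 3,
                         decoy_identity = 0.90,
                         viral_contig_len_bp = 2000,
                         genes_per_contig = 10,
                         n_bacterial_taxa = 15,
                         bacterial_contig_len_bp = 3000,
                         n_long_pass = 1,
                         n_long_fail = 1,
                         n_nonviral = 3,
                         planted_links = NULL,
                         amg_insertion_rate = 0.5,
                         abundance_meanlog = log(50),
                         abundance_sdlog = 0.6,
                         gained_taxa_abundance = 0.3,
                         contamination_effects = list(
                           bacterial_richness_drop = 0.4,
                           viral_richness_gain = 1.6,
                           amg_tpm_multiplier = 4),
                         rng_seed = 1L) {
  d <- as.list(environment())
  ids <- c(d$variant_identity_levels, d$decoy_identity)
  if (any(ids <= 0 | ids > 1))
    stop("identity levels must be in (0, 1]", call. = FALSE)
  eff <- d$contamination_effects
  if (any(unlist(eff) <= 0)) stop("effects must be > 0", call. = FALSE)
  # mutation budget: substitutions live in [26, L-25]
  L <- d$viral_contig_len_bp
  m_max <- ceiling((1 - min(ids)) * L)
  if (m_max > L - 50L)
    stop("infeasible design: identity level requires more substitutions ",
         "than the mutable region holds", call. = FALSE)
  if (L < 1000L)
    stop("viral contigs must be at least 1 kb", call. = FALSE)
  if (d$genes_per_contig < 8L)
    stop("gene layout needs at least 8 genes per contig", call. = FALSE)
  class(d) <- "synth_design"
  d
}

# Default virus-host plants: alternate tRNA and CRISPR evidence across the
# first few lineages; CRISPR plants alternate 0 and 1 spacer mismatches, and
# one extra 2-mismatch plant is recorded as unrecoverable.
default_planted_links <- function(design) {
  k <- min(4L, design$n_viral_lineages, design$n_bacterial_taxa)
  out <- data.frame(
    lineage = seq_len(k),
    taxon = seq_len(k),
    evidence = rep(c("tRNA", "CRISPR"), length.out = k),
    mismatches = 0L,
    stringsAsFactors = FALSE
  )
  cr <- which(out$evidence == "CRISPR")
  out$mismatches[cr] <- rep(c(0L, 1L), length.out = length(cr))
  if (design$n_viral_lineages > k && design$n_bacterial_taxa > k)
    out <- rbind(out, data.frame(lineage = k + 1L, taxon = k + 1L,
                                 evidence = "CRISPR", mismatches = 2L))
  out
}

gene_layout <- function(contig_id, len, n_genes) {
  w <- len %/% n_genes
  idx <- seq_len(n_genes) - 1L
  data.frame(
    gene_id = sprintf("%s_g%02d", contig_id, idx),
    contig_id = contig_id,
    index = idx,
    start = idx * w + 1L,
    end = pmin((idx + 1L) * w, len),
    strand = rep(c("+", "-"), length.out = n_genes),
    protein_id = sprintf("%s_p%02d", contig_id, idx),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete synthetic dataset with planted ground truth
#'
#' Generates, deterministically from `design$rng_seed`, every input the
#' pipeline consumes — contigs, gene calls, annotation hits, CRISPR arrays,
#' tRNA records, VC membership, sample table and count matrices — together
#' with a ground-truth object recording the planted vOTU partition, taxonomy,
#' host links, AMGs and screening decisions.
#'
#' @param design A [synth_design()].
#' @return A list of class `viro_dataset`; planted truth under `$truth`.
#' @export
simulate_community <- function(design = synth_design()) {
  stopifnot(inherits(design, "synth_design"))
  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv()) else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(design$rng_seed)

  L <- design$viral_contig_len_bp
  nG <- design$genes_per_contig
  nlin <- design$n_viral_lineages
  fam_pool <- c("Siphoviridae", "Podoviridae", "Myoviridae",
                "Microviridae", "Schitoviridae")
  amg_palette <- data.frame(
    family = c("GH13", "norD", "PhoD", "cysD", "HAD_2"),
    category = c("C", "N", "P", "S", "pesticide"),
    stringsAsFactors = FALSE
  )
  links_plan <- design$planted_links
  if (is.null(links_plan)) links_plan <- default_planted_links(design)

  samples <- data.frame(
    sample_id = c(sprintf("C%d", seq_len(design$n_samples_per_group["clean"])),
                  sprintf("S%d", seq_len(design$n_samples_per_group["light"] +
                                           design$n_samples_per_group["heavy"]))),
    group = rep(c("clean", "light", "heavy"), design$n_samples_per_group),
    stringsAsFactors = FALSE
  )

  contigs <- list(); genes <- list(); hits <- list()
  truth_partition <- list(); truth_amg <- list()

  # -- ancestor and bacterial sequences, with links planted FIRST ---------
  # tRNA insertions rewrite the ancestor, so they must precede variant
  # generation or the planted identity levels would drift.
  ancestors <- vapply(seq_len(nlin), function(i) random_dna(L + 10L),
                      character(1))
  nb <- design$n_bacterial_taxa
  bact <- data.frame(
    contig_id = sprintf("BACT%02d", seq_len(nb)),
    sequence = vapply(seq_len(nb), function(i)
      random_dna(design$bacterial_contig_len_bp), character(1)),
    stringsAsFactors = FALSE)
  host_taxonomy <- data.frame(host_contig_id = bact$contig_id,
                              host_taxon = sprintf("Taxon_%02d", seq_len(nb)),
                              stringsAsFactors = FALSE)

  trnas <- list(); arrays <- list(); truth_links <- list()
  overwrite <- function(seq, sub, pos)
    paste0(substr(seq, 1L, pos - 1L), sub,
           substr(seq, pos + nchar(sub), nchar(seq)))
  for (r in seq_len(NROW(links_plan))) {
    li <- links_plan$lineage[r]; ti <- links_plan$taxon[r]
    anc_id <- sprintf("VIR_L%02d_anc", li)
    taxon <- host_taxonomy$host_taxon[ti]
    if (links_plan$evidence[r] == "tRNA") {
      tr <- random_dna(75L)
      ancestors[li] <- overwrite(ancestors[li], tr, 30L)
      bact$sequence[ti] <- overwrite(bact$sequence[ti], tr, 100L)
      trnas[[r]] <- data.frame(virus_contig_id = anc_id, trna_seq = tr,
                               stringsAsFactors = FALSE)
      truth_links[[r]] <- data.frame(virus_contig_id = anc_id,
                                     host_taxon = taxon, evidence = "tRNA",
                                     mismatches = 0L, recoverable = TRUE,
                                     stringsAsFactors = FALSE)
    } else {
      mm <- links_plan$mismatches[r]
      proto <- substr(ancestors[li], 501L, 532L)    # 32 nt protospacer
      spacer <- mutate_seq(proto, mm, 1L, 32L)
      rep_seq <- random_dna(28L)
      spacer2 <- random_dna(32L)
      cassette <- paste0(rep_seq, spacer, rep_seq, spacer2, rep_seq)
      bact$sequence[ti] <- overwrite(bact$sequence[ti], cassette, 200L)
      arrays[[r]] <- data.frame(
        host_contig_id = bact$contig_id[ti],
        array_id = sprintf("array_%02d", r),
        repeat_seq = rep_seq, spacer_rank = c(1L, 2L),
        spacer_seq = c(spacer, spacer2),
        stringsAsFactors = FALSE)
      truth_links[[r]] <- data.frame(virus_contig_id = anc_id,
                                     host_taxon = taxon, evidence = "CRISPR",
                                     mismatches = mm,
                                     recoverable = mm <= 1L,
                                     stringsAsFactors = FALSE)
    }
  }
  bact$length_bp <- nchar(bact$sequence)
  trnas <- if (length(trnas)) do.call(rbind, trnas) else
    data.frame(virus_contig_id = character(), trna_seq = character())
  arrays <- if (length(arrays)) do.call(rbind, arrays) else
    data.frame(host_contig_id = character(), array_id = character(),
               repeat_seq = character(), spacer_rank = integer(),
               spacer_seq = character())
  truth_links <- do.call(rbind, truth_links)

  # -- annotation painter for a viral contig ------------------------------
  # VPF on 7 genes, KO on 1, hallmark (VOG Xr/Xs) around the AMG slot and at
  # interior anchors, optional planted AMG with a Pfam family + M flag.
  amg_slot <- nG %/% 2L
  hall_idx <- sort(unique(c(1L, amg_slot - 1L, amg_slot + 1L, nG - 2L)))
  paint_viral <- function(g, family, annotated, amg_row = NULL) {
    h <- list()
    vpf_idx <- sort(unique(c(hall_idx, amg_slot, 0L, nG - 1L)))[1:7]
    h$vpf <- data.frame(protein_id = g$protein_id[g$index %in% vpf_idx],
                        database = "VPF",
                        accession = sprintf("VPF%05d", sample.int(99999, 7)),
                        label = "viral protein family", bitscore = NA_real_)
    ko_idx <- setdiff(seq_len(nG) - 1L, vpf_idx)[1]
    h$ko <- data.frame(protein_id = g$protein_id[g$index == ko_idx],
                       database = "KO", accession = "K00001",
                       label = "ko", bitscore = NA_real_)
    h$vog <- data.frame(protein_id = g$protein_id[g$index %in% hall_idx],
                        database = "VOG",
                        accession = sprintf("VOG%05d", sample.int(99999,
                                              length(hall_idx))),
                        label = rep(c("Xr", "Xs"),
                                    length.out = length(hall_idx)),
                        bitscore = NA_real_)
    if (!is.null(amg_row)) {
      pid <- g$protein_id[g$index == amg_slot]
      h$amg <- data.frame(protein_id = pid, database = "PFAM",
                          accession = amg_row$family, label = amg_row$family,
                          bitscore = NA_real_)
      h$flag <- data.frame(protein_id = pid, database = "AMG_FLAG",
                           accession = "M", label = "M", bitscore = NA_real_)
    }
    if (annotated) {
      vote_idx <- (seq_len(nG) - 1L)[1:ceiling(0.6 * nG)]
      pid <- g$protein_id[g$index %in% vote_idx]
      h$fam <- data.frame(protein_id = pid, database = "REFSEQ_FAMILY",
                          accession = sprintf("ref_%s", family),
                          label = family,
                          bitscore = round(stats::runif(length(pid), 60, 120),
                                           1))
      # a weaker competing family on two proteins exercises best-hit voting
      decoy <- setdiff(fam_pool, family)[1]
      h$fam2 <- data.frame(protein_id = pid[1:2], database = "REFSEQ_FAMILY",
                           accession = sprintf("ref_%s", decoy),
                           label = decoy, bitscore = c(52, 55))
    }
    do.call(rbind, h)
  }

  # -- lineages -----------------------------------------------------------
  amg_carriers <- unique(round(seq(1, nlin,
                                   length.out = max(1L, ceiling(
                                     design$amg_insertion_rate * nlin)))))
  lineage_family <- fam_pool[(seq_len(nlin) - 1L) %% length(fam_pool) + 1L]
  lineage_annotated <- (seq_len(nlin) %% 4L) != 0L
  lvl <- rep(design$variant_identity_levels,
             length.out = max(0L, design$variants_per_lineage - 1L))
  for (i in seq_len(nlin)) {
    anc_id <- sprintf("VIR_L%02d_anc", i)
    anc <- ancestors[i]
    amg_row <- if (i %in% amg_carriers)
      amg_palette[(match(i, amg_carriers) - 1L) %% nrow(amg_palette) + 1L, ]
      else NULL
    g <- gene_layout(anc_id, L + 10L, nG)
    contigs[[anc_id]] <- data.frame(contig_id = anc_id, sequence = anc,
                                    length_bp = L + 10L,
                                    virsorter_category = sample(c(1L, 2L), 1),
                                    lineage = i, stringsAsFactors = FALSE)
    genes[[anc_id]] <- g
    hits[[anc_id]] <- paint_viral(g, lineage_family[i],
                                  lineage_annotated[i], amg_row)
    truth_partition[[anc_id]] <- data.frame(contig_id = anc_id,
                                            truth_cluster = sprintf("L%02d", i))
    if (!is.null(amg_row))
      truth_amg[[anc_id]] <- data.frame(
        gene_id = g$gene_id[g$index == amg_slot], contig_id = anc_id,
        family = amg_row$family, category = amg_row$category,
        stringsAsFactors = FALSE)
    for (v in seq_along(lvl)) {
      vid <- sprintf("VIR_L%02d_v%02d", i, v)
      m <- round((1 - lvl[v]) * L)
      vs <- mutate_seq(substr(anc, 1L, L), m, 26L, L - 25L)
      gv <- gene_layout(vid, L, nG)
      contigs[[vid]] <- data.frame(contig_id = vid, sequence = vs,
                                   length_bp = L,
                                   virsorter_category = sample(c(1L, 2L), 1),
                                   lineage = i, stringsAsFactors = FALSE)
      genes[[vid]] <- gv
      hits[[vid]] <- paint_viral(gv, lineage_family[i], lineage_annotated[i],
                                 amg_row)
      if (!is.null(amg_row))
        truth_amg[[vid]] <- data.frame(
          gene_id = gv$gene_id[gv$index == amg_slot], contig_id = vid,
          family = amg_row$family, category = amg_row$category,
          stringsAsFactors = FALSE)
      truth_partition[[vid]] <- data.frame(
        contig_id = vid,
        truth_cluster = if (lvl[v] >= 0.95) sprintf("L%02d", i) else vid)
    }
  }

  # -- decoys: below-threshold relatives, singleton truth clusters --------
  for (dk in seq_len(design$n_decoys)) {
    src <- (dk - 1L) %% nlin + 1L
    did <- sprintf("VIR_D%02d", dk)
    m <- round((1 - design$decoy_identity) * L)
    ds <- mutate_seq(substr(ancestors[src], 1L, L), m, 26L, L - 25L)
    gd <- gene_layout(did, L, nG)
    contigs[[did]] <- data.frame(contig_id = did, sequence = ds,
                                 length_bp = L,
                                 virsorter_category = sample(c(1L, 2L), 1),
                                 lineage = NA_integer_,
                                 stringsAsFactors = FALSE)
    genes[[did]] <- gd
    hits[[did]] <- paint_viral(gd, lineage_family[src], FALSE)
    truth_partition[[did]] <- data.frame(contig_id = did, truth_cluster = did)
  }

  # -- long contigs exercising the >5 kb criteria gate --------------------
  long_plan <- rbind(
    if (design$n_long_pass > 0)
      data.frame(id = sprintf("VIR_LONGP%02d", seq_len(design$n_long_pass)),
                 len = 12000L, pass = TRUE),
    if (design$n_long_fail > 0)
      data.frame(id = sprintf("VIR_LONGF%02d", seq_len(design$n_long_fail)),
                 len = 6000L, pass = FALSE)
  )
  for (r in seq_len(NROW(long_plan))) {
    lid <- long_plan$id[r]
    seq <- random_dna(long_plan$len[r])
    g <- gene_layout(lid, long_plan$len[r], nG)
    contigs[[lid]] <- data.frame(contig_id = lid, sequence = seq,
                                 length_bp = long_plan$len[r],
                                 virsorter_category = 1L,
                                 lineage = NA_integer_,
                                 stringsAsFactors = FALSE)
    genes[[lid]] <- g
    if (long_plan$pass[r]) {
      hits[[lid]] <- paint_viral(g, fam_pool[1], FALSE)
    } else {
      # no VPF, half KO, half Pfam: every criterion fails
      hits[[lid]] <- rbind(
        data.frame(protein_id = g$protein_id[1:5], database = "KO",
                   accession = "K00002", label = "ko", bitscore = NA_real_),
        data.frame(protein_id = g$protein_id[6:10], database = "PFAM",
                   accession = "PF99999", label = "NotAMG",
                   bitscore = NA_real_))
    }
    truth_partition[[lid]] <- data.frame(contig_id = lid, truth_cluster = lid)
  }

  # -- non-viral decoys: category 3, never retained -----------------------
  for (k in seq_len(design$n_nonviral)) {
    nid <- sprintf("NONVIR%02d", k)
    contigs[[nid]] <- data.frame(contig_id = nid, sequence = random_dna(L),
                                 length_bp = L, virsorter_category = 3L,
                                 lineage = NA_integer_,
                                 stringsAsFactors = FALSE)
    genes[[nid]] <- gene_layout(nid, L, nG)
    truth_partition[[nid]] <- data.frame(contig_id = nid, truth_cluster = nid)
  }

  contigs <- do.call(rbind, contigs)
  rownames(contigs) <- NULL
  genes <- do.call(rbind, genes); rownames(genes) <- NULL
  hits <- do.call(rbind, hits); rownames(hits) <- NULL
  hits$accession <- make.unique(paste(hits$database, hits$accession,
                                      hits$protein_id, sep = ":"))

  # -- VC membership: one VC per family over its lineage ancestors --------
  vc <- data.frame(contig_id = sprintf("VIR_L%02d_anc", seq_len(nlin)),
                   vc_id = paste0("VC_", lineage_family),
                   stringsAsFactors = FALSE)

  # -- abundance ----------------------------------------------------------
  eff <- design$contamination_effects
  viral_feats <- contigs$contig_id[!startsWith(contigs$contig_id, "NONVIR")]
  base <- stats::setNames(
    stats::rlnorm(length(viral_feats), design$abundance_meanlog,
                  design$abundance_sdlog), viral_feats)
  n_clean_lin <- max(1L, round(nlin / eff$viral_richness_gain))
  feat_lineage <- contigs$lineage[match(viral_feats, contigs$contig_id)]
  present_clean <- is.na(feat_lineage) & !startsWith(viral_feats, "VIR_D") |
    (!is.na(feat_lineage) & feat_lineage <= n_clean_lin)
  carrier <- !is.na(feat_lineage) & feat_lineage %in% amg_carriers
  # contamination-exclusive features sit in the rare tail
  base[!present_clean] <- base[!present_clean] * design$gained_taxa_abundance
  viral_counts <- matrix(0, length(viral_feats), nrow(samples),
                         dimnames = list(viral_feats, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    grp <- samples$group[j]
    pres <- if (grp == "clean") present_clean else TRUE
    mult <- rep(1, length(viral_feats))
    if (grp == "light") mult[carrier] <- sqrt(eff$amg_tpm_multiplier)
    if (grp == "heavy") mult[carrier] <- eff$amg_tpm_multiplier
    lam <- base * mult * as.numeric(pres)
    viral_counts[, j] <- stats::rpois(length(lam), lam)
  }

  bact_base <- 200 * 0.75^(seq_len(nb) - 1L)       # geometric rank-abundance
  n_bact_cont <- max(2L, round(nb * (1 - eff$bacterial_richness_drop)))
  bact_counts <- matrix(0, nb, nrow(samples),
                        dimnames = list(host_taxonomy$host_taxon,
                                        samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    pres <- if (samples$group[j] == "clean") rep(TRUE, nb)
            else seq_len(nb) <= n_bact_cont     # contaminated drop the rarest
    bact_counts[, j] <- stats::rpois(nb, bact_base * as.numeric(pres))
  }

  # -- ground truth -------------------------------------------------------
  truth_partition <- do.call(rbind, truth_partition)
  rownames(truth_partition) <- NULL
  expect_retained <- !startsWith(contigs$contig_id, "NONVIR") &
    !startsWith(contigs$contig_id, "VIR_LONGF")
  prop_expected <- lineage_family
  tier_expected <- ifelse(lineage_annotated, "direct",
    ifelse(lineage_family %in% lineage_family[lineage_annotated],
           "propagated", "unassigned"))
  truth <- list(
    votu_partition = truth_partition,
    screen = data.frame(contig_id = contigs$contig_id,
                        expect_retained = expect_retained,
                        stringsAsFactors = FALSE),
    taxonomy = data.frame(lineage = seq_len(nlin),
                          ancestor_id = sprintf("VIR_L%02d_anc", seq_len(nlin)),
                          family = prop_expected,
                          expect_tier = tier_expected,
                          stringsAsFactors = FALSE),
    links = truth_links,
    amg_genes = if (length(truth_amg)) do.call(rbind, truth_amg) else
      data.frame(),
    abundance_expectations = list(
      viral_richness = "contaminated > clean",
      bacterial_richness = "clean > contaminated",
      bacterial_pielou = "contaminated > clean",
      amg_tpm = "heavy > light > clean"),
    amg_carrier_lineages = amg_carriers
  )
  rownames(truth$amg_genes) <- NULL

  ds <- list(
    design = design,
    contigs = contigs[c("contig_id", "sequence", "length_bp",
                        "virsorter_category")],
    bacterial_contigs = bact,
    genes = genes, hits = hits,
    trnas = trnas, crispr_arrays = arrays,
    host_taxonomy = host_taxonomy,
    vc_membership = vc,
    samples = samples,
    viral_counts = viral_counts,
    bacterial_counts = bact_counts,
    truth = truth
  )
  class(ds) <- "viro_dataset"
  ds
}

#' @export
print.viro_dataset <- function(x, ...) {
  cat("synthetic virome dataset: ", nrow(x$contigs), " viral-side contigs, ",
      nrow(x$bacterial_contigs), " bacterial contigs, ",
      nrow(x$samples), " samples\n", sep = "")
  cat("  planted: ", length(unique(x$truth$votu_partition$truth_cluster)),
      " truth clusters, ", nrow(x$truth$links), " host links, ",
      nrow(x$truth$amg_genes), " AMG genes\n", sep = "")
  invisible(x)
}

#' Targeted negative-control perturbations
#'
#' Destroys one planted structure while leaving everything else unchanged,
#' so downstream recovery tests can show the corresponding signal vanish:
#' `shuffle_labels` permutes sample group labels; `scramble_spacers` replaces
#' every CRISPR spacer with a random sequence of the same length;
#' `strip_hallmarks` deletes all hallmark (VOG Xr/Xs) annotations.
#'
#' @param dataset A `viro_dataset`.
#' @param op One of `"shuffle_labels"`, `"scramble_spacers"`,
#'   `"strip_hallmarks"`.
#' @param seed Seed for the randomized perturbations.
#' @return The perturbed dataset.
#' @export
perturb <- function(dataset, op = c("shuffle_labels", "scramble_spacers",
                                    "strip_hallmarks"), seed = 1L) {
  stopifnot(inherits(dataset, "viro_dataset"))
  op <- match.arg(op)
  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv()) else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  switch(op,
    shuffle_labels = {
      dataset$samples$group <- sample(dataset$samples$group)
    },
    scramble_spacers = {
      # shuffle each spacer's own letters: same length and composition but
      # the protospacer correspondence is destroyed
      dataset$crispr_arrays$spacer_seq <- vapply(
        strsplit(dataset$crispr_arrays$spacer_seq, ""),
        function(ch) paste(sample(ch), collapse = ""), character(1))
    },
    strip_hallmarks = {
      h <- dataset$hits
      dataset$hits <- h[!(h$database == "VOG" & grepl("Xr|Xs", h$label)), ]
    }
  )
  dataset
}

#' Gene ids annotated as viral hallmark genes
#'
#' Hallmark genes here are genes carrying a VOG replication (`Xr`) or
#' structure (`Xs`) category — confidently viral genes usable to anchor the
#' positional validation of AMGs.
#'
#' @param dataset A `viro_dataset` (or any list with `$genes` and `$hits`).
#' @return Character vector of gene ids.
#' @export
hallmark_gene_ids <- function(dataset) {
  vog <- dataset$hits[dataset$hits$database == "VOG" &
                        grepl("Xr|Xs", dataset$hits$label), ]
  dataset$genes$gene_id[dataset$genes$protein_id %in% vog$protein_id]
}

#' Write or read a dataset as plain-text files
#'
#' The on-disk layout is the pipeline's external interface: FASTA for
#' sequences, TSV for every table, JSON for the ground truth.
#'
#' @param dataset A `viro_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir` (write) or a reconstructed `viro_dataset` (read).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_fasta(dataset$contigs, fp("viral_contigs.fasta"))
  write_fasta(dataset$bacterial_contigs, fp("bacterial_contigs.fasta"))
  meta <- dataset$contigs[c("contig_id", "virsorter_category")]
  meta$sample_id <- NA; meta$group <- NA
  write_table(meta[c("contig_id", "sample_id", "group",
                     "virsorter_category")], fp("contig_meta.tsv"))
  write_table(dataset$genes, fp("genes.tsv"), "genes")
  write_table(dataset$hits, fp("hits.tsv"), "hits")
  write_table(dataset$trnas, fp("trnas.tsv"))
  write_table(dataset$crispr_arrays, fp("crispr_arrays.tsv"))
  write_table(dataset$host_taxonomy, fp("host_taxonomy.tsv"),
              "host_taxonomy")
  write_table(dataset$vc_membership, fp("vc_membership.tsv"), "vc")
  write_table(dataset$samples, fp("samples.tsv"), "samples")
  write_abundance(dataset$viral_counts, fp("abundance_viral.tsv"))
  write_abundance(dataset$bacterial_counts, fp("abundance_bacteria.tsv"))
  jsonlite::write_json(dataset$truth, fp("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  fp <- function(x) file.path(dir, x)
  viral <- read_fasta(fp("viral_contigs.fasta"))
  meta <- read_table(fp("contig_meta.tsv"), "contig_meta")
  viral$virsorter_category <-
    meta$virsorter_category[match(viral$contig_id, meta$contig_id)]
  ds <- list(
    contigs = viral,
    bacterial_contigs = read_fasta(fp("bacterial_contigs.fasta")),
    genes = read_table(fp("genes.tsv"), "genes", contigs = viral),
    hits = read_table(fp("hits.tsv"), "hits"),
    trnas = read_table(fp("trnas.tsv"), "trna"),
    crispr_arrays = read_table(fp("crispr_arrays.tsv"), "crispr"),
    host_taxonomy = read_table(fp("host_taxonomy.tsv"), "host_taxonomy"),
    vc_membership = read_table(fp("vc_membership.tsv"), "vc"),
    samples = read_table(fp("samples.tsv"), "samples"),
    viral_counts = read_abundance(fp("abundance_viral.tsv")),
    bacterial_counts = read_abundance(fp("abundance_bacteria.tsv"))
  )
  if (file.exists(fp("ground_truth.json")))
    ds$truth <- jsonlite::read_json(fp("ground_truth.json"),
                                    simplifyVector = TRUE)
  class(ds) <- "viro_dataset"
  ds
}
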