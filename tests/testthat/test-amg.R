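mk_genes <- function(n, contig = "c1") {
  data.frame(gene_id = sprintf("%s_g%02d", contig, seq_len(n) - 1),
             contig_id = contig, index = seq_len(n) - 1L,
             start = (seq_len(n) - 1L) * 100L + 1L,
             end = seq_len(n) * 100L, strand = "+",
             protein_id = sprintf("%s_p%02d", contig, seq_len(n) - 1),
             stringsAsFactors = FALSE)
}

hit_row <- function(protein_id, database, label) {
  data.frame(protein_id = protein_id, database = database,
             accession = paste(database, label, protein_id, sep = ":"),
             label = label, bitscore = NA_real_, stringsAsFactors = FALSE)
}

test_that("core / AMG / other partition with core precedence", {
  genes <- mk_genes(5)
  hits <- rbind(
    hit_row("c1_p00", "VOG", "Xr"),                 # core
    hit_row("c1_p01", "PFAM", "HAD_2"),             # AMG (pesticide)
    hit_row("c1_p02", "VOG", "Xs"),                 # core
    hit_row("c1_p02", "PFAM", "GH13"),              # conflict -> core wins
    hit_row("c1_p03", "PFAM", "NotInList")          # other
  )
  suppressMessages(cls <- classify_genes(genes, hits))
  expect_equal(cls$klass, c("core", "AMG", "core", "other", "other"))
  expect_equal(cls$amg_category[2], "pesticide")
  expect_true(all(table(cls$gene_id) == 1))  # exactly one class per gene
  # gene with no hits at all is 'other'
  expect_equal(cls$klass[5], "other")
})

test_that("flank validation needs hallmarks on both sides", {
  genes <- mk_genes(10)
  hall <- genes$gene_id[c(3, 10)]   # indices 2 and 9
  v <- validate_context(genes$gene_id[6], genes, hall)  # index 5
  expect_true(v$flanked_both_sides)
  # first gene on the contig: no lower-index hallmark, and flag F
  v0 <- validate_context(genes$gene_id[1], genes, hall)
  expect_false(v0$flanked_both_sides)
  expect_match(v0$flags, "F")
  # hallmark only on one side
  v1 <- validate_context(genes$gene_id[6], genes, genes$gene_id[3])
  expect_false(v1$flanked_both_sides)
  expect_error(validate_context("missing_gene", genes, hall), "missing_gene")
})

test_that("F and B flags equal a brute-force layout oracle on random contigs", {
  set.seed(501)
  p <- viro_params()
  for (rep in 1:300) {
    n <- sample(3:15, 1)
    genes <- mk_genes(n, contig = sprintf("c%03d", rep))
    m_flags <- runif(n) < 0.4
    hits <- do.call(rbind, lapply(which(m_flags), function(i)
      hit_row(genes$protein_id[i], "AMG_FLAG", "M")))
    v <- validate_context(genes$gene_id, genes, character(), hits, p)
    o <- oracle_fb_flags(m_flags, p$end_flag_window_genes,
                         p$consecutive_M_for_B)
    expect_identical(grepl("F", v$flags), o$f)
    expect_identical(grepl("B", v$flags), o$b)
  }
})

test_that("three consecutive M genes get B, two do not", {
  genes <- mk_genes(8)
  mk_flags <- function(idx) do.call(rbind, lapply(idx, function(i)
    hit_row(genes$protein_id[i], "AMG_FLAG", "M")))
  v3 <- validate_context(genes$gene_id, genes, character(), mk_flags(4:6))
  expect_identical(grepl("B", v3$flags), seq_len(8) %in% 4:6)
  v2 <- validate_context(genes$gene_id, genes, character(), mk_flags(4:5))
  expect_false(any(grepl("B", v2$flags)))
})

test_that("planted AMGs classify, validate, and fail after hallmark stripping", {
  ds <- simulate_community(tiny_design(seed = 6L))
  suppressMessages(cls <- classify_genes(ds$genes, ds$hits))
  truth <- ds$truth$amg_genes
  expect_true(all(truth$gene_id %in% cls$gene_id[cls$klass == "AMG"]))
  got_cat <- cls$amg_category[match(truth$gene_id, cls$gene_id)]
  expect_equal(got_cat, truth$category)

  hall <- hallmark_gene_ids(ds)
  v <- validate_context(truth$gene_id, ds$genes, hall, ds$hits)
  expect_true(all(v$flanked_both_sides))

  stripped <- perturb(ds, "strip_hallmarks")
  v2 <- validate_context(truth$gene_id, stripped$genes,
                         hallmark_gene_ids(stripped), stripped$hits)
  expect_false(any(v2$flanked_both_sides))
})

test_that("AMG abundance summaries handle planted effects and edge cases", {
  ds <- simulate_community(tiny_design(seed = 10L))
  res <- run_pipeline(ds)
  per <- res$amg$per_sample
  clean <- per$amg_tpm[per$group == "clean"]
  cont <- per$amg_tpm[per$group != "clean"]
  expect_gt(mean(cont), mean(clean))
  expect_true(all(c("amg_tpm_ranksum", "amg_diversity_ranksum",
                    "amg_category_fisher") %in% res$amg$tests$test))

  # all-zero AMG rows -> diversity 0, sum 0
  cls <- data.frame(gene_id = c("gA", "gB"), contig_id = "c",
                    klass = "AMG", basis = "GH13", amg_category = "C")
  tpm <- matrix(0, 2, 4, dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        group = c("clean", "clean", "heavy", "heavy"))
  z <- amg_abundance(cls, tpm, samples)
  expect_true(all(z$per_sample$amg_diversity == 0))
  expect_true(all(z$per_sample$amg_tpm == 0))

  # under-replicated group skips tests with a warning
  samples1 <- data.frame(sample_id = paste0("s", 1:4),
                         group = c("clean", "heavy", "heavy", "heavy"))
  expect_warning(w <- amg_abundance(cls, tpm, samples1), "skipped")
  expect_equal(nrow(w$tests), 0L)
})

test_that("co-occurrence network applies strict |r| and p gates", {
  set.seed(77)
  n <- 9
  base <- rnorm(n)
  m <- rbind(
    perfect_a = base,
    perfect_b = 2 * base + 5,
    anti = -base,
    const = rep(3, n),
    noise1 = rnorm(n),
    noise2 = rnorm(n)
  )
  colnames(m) <- paste0("s", 1:n)
  edges <- cooccurrence_network(m, viro_params())
  pair <- edges[edges$feature_a == "perfect_a" & edges$feature_b == "perfect_b", ]
  expect_equal(pair$r, 1.0)
  expect_false("const" %in% c(edges$feature_a, edges$feature_b))
  # negative correlation passes through |r|
  expect_true(any(edges$feature_a == "perfect_a" & edges$feature_b == "anti" |
                    edges$feature_a == "anti" & edges$feature_b == "perfect_a"))
  expect_error(cooccurrence_network(m[, 1:2], viro_params()), "3 samples")

  # r exactly at the threshold is excluded; p-values match the t formula
  x <- c(1, 2, 3, 4, 5, 6)
  # build y with cor(x, y) very close to 0.6 and check the strict gate logic
  r_all <- abs(cor(t(m[c(1, 2, 3, 5, 6), ])))
  p_all <- 2 * pt(abs(r_all * sqrt((n - 2) / (1 - r_all^2))), df = n - 2,
                  lower.tail = FALSE)
  want <- sum(r_all[upper.tri(r_all)] > 0.6 &
                p_all[upper.tri(p_all)] < 0.05)
  expect_equal(nrow(edges), want)
})

test_that("edge rate on independent rows matches a brute-force check", {
  set.seed(88)
  m <- matrix(rnorm(40 * 9), 40, 9,
              dimnames = list(paste0("f", 1:40), paste0("s", 1:9)))
  edges <- cooccurrence_network(m, viro_params())
  r <- cor(t(m))
  p <- 2 * pt(abs(r * sqrt(7 / (1 - r^2))), df = 7, lower.tail = FALSE)
  ut <- upper.tri(r)
  expect_equal(nrow(edges), sum(abs(r[ut]) > 0.6 & p[ut] < 0.05))
})
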