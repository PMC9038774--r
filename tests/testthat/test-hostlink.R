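revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

test_that("tRNA links require a perfect full-length match and drop self-hits", {
  set.seed(301)
  tr <- rand_dna(75)
  host_ok <- paste0(rand_dna(400), tr, rand_dna(400))
  host_rc <- paste0(rand_dna(300), revcomp(tr), rand_dna(300))
  host_mm <- paste0(rand_dna(400), mutate_at_hl(tr, 30), rand_dna(400))
  hosts <- data.frame(contig_id = c("h1", "h2", "h3", "vir1"),
                      sequence = c(host_ok, host_rc, host_mm,
                                   paste0(rand_dna(100), tr, rand_dna(100))),
                      stringsAsFactors = FALSE)
  tax <- data.frame(host_contig_id = c("h1", "h2", "h3", "vir1"),
                    host_taxon = c("T1", "T2", "T3", "TV"))
  trnas <- data.frame(virus_contig_id = "vir1", trna_seq = tr)
  links <- match_trna(trnas, hosts, tax, viro_params())
  expect_setequal(links$host_contig_id, c("h1", "h2"))  # mismatch + self out
  expect_equal(links$position[links$host_contig_id == "h1"], 401)
  expect_equal(links$strand[links$host_contig_id == "h2"], "-")
  expect_true(all(links$mismatches == 0))
  # idempotent under repetition
  expect_identical(match_trna(trnas, hosts, tax, viro_params()), links)
})

test_that("spacer links allow one mismatch, not two, and need the repeat anchor", {
  set.seed(302)
  virus <- rand_dna(2000)
  proto <- substr(virus, 601, 632)
  rep_seq <- rand_dna(28)
  mk_arrays <- function(spacers, host = "h1")
    data.frame(host_contig_id = host, array_id = "a1", repeat_seq = rep_seq,
               spacer_rank = seq_along(spacers), spacer_seq = spacers,
               stringsAsFactors = FALSE)
  host_seq <- paste0(rand_dna(200), rep_seq, rand_dna(500))
  hosts <- data.frame(contig_id = "h1", sequence = host_seq)
  tax <- data.frame(host_contig_id = "h1", host_taxon = "T1")
  viruses <- data.frame(contig_id = "v1", sequence = virus)
  p <- viro_params()

  for (mm in 0:2) {
    sp <- if (mm == 0) proto else mutate_at_hl(proto, seq_len(mm))
    links <- match_spacers(mk_arrays(sp), viruses, hosts, tax, p)
    if (mm <= 1) {
      expect_equal(nrow(links), 1L)
      expect_equal(links$mismatches, mm)
      expect_equal(links$host_taxon, "T1")
    } else {
      expect_equal(nrow(links), 0L)
    }
  }

  # strict-exact mode rejects the 1-mismatch plant
  strict <- viro_params(spacer_max_mismatch = 0L)
  one_mm <- match_spacers(mk_arrays(mutate_at_hl(proto, 5)), viruses, hosts,
                          tax, strict)
  expect_equal(nrow(one_mm), 0L)

  # without the repeat anchored in any host the match is an orphan, not a link
  hosts_no <- data.frame(contig_id = "h1", sequence = rand_dna(700))
  orphaned <- match_spacers(mk_arrays(proto), viruses, hosts_no, tax, p)
  expect_equal(nrow(orphaned), 0L)
  expect_equal(nrow(attr(orphaned, "orphans")), 1L)

  # spacers below the minimum length are ignored entirely
  short <- match_spacers(mk_arrays(substr(proto, 1, 15)), viruses, hosts,
                         tax, p)
  expect_equal(nrow(short), 0L)
  expect_equal(NROW(attr(short, "orphans")), 0L)
})

test_that("reverse-complementing every host contig preserves the link set", {
  ds <- simulate_community(tiny_design(seed = 33L))
  p <- viro_params()
  l1 <- match_trna(ds$trnas, ds$bacterial_contigs, ds$host_taxonomy, p)
  ds$bacterial_contigs$sequence <-
    vapply(ds$bacterial_contigs$sequence, revcomp, character(1),
           USE.NAMES = FALSE)
  l2 <- match_trna(ds$trnas, ds$bacterial_contigs, ds$host_taxonomy, p)
  keep <- c("virus_contig_id", "host_taxon", "host_contig_id", "mismatches")
  expect_identical(l1[keep], l2[keep])
})

test_that("planted links are recovered with exact evidence and mismatch detail", {
  for (seed in c(1L, 2L)) {
    ds <- simulate_community(tiny_design(seed = seed))
    p <- viro_params()
    links <- rbind(
      match_trna(ds$trnas, ds$bacterial_contigs, ds$host_taxonomy, p),
      match_spacers(ds$crispr_arrays, ds$contigs, ds$bacterial_contigs,
                    ds$host_taxonomy, p))
    truth <- ds$truth$links
    for (i in seq_len(nrow(truth))) {
      hit <- links[links$virus_contig_id == truth$virus_contig_id[i] &
                     links$host_taxon == truth$host_taxon[i] &
                     links$evidence == truth$evidence[i], ]
      if (truth$recoverable[i]) {
        expect_equal(nrow(hit), 1L)
        expect_equal(hit$mismatches, truth$mismatches[i])
      } else {
        expect_equal(nrow(hit), 0L)
      }
    }
    # negative control: scrambled spacers yield no CRISPR links at all
    scr <- perturb(ds, "scramble_spacers", seed = seed)
    none <- match_spacers(scr$crispr_arrays, scr$contigs,
                          scr$bacterial_contigs, scr$host_taxonomy, p)
    expect_equal(nrow(none), 0L)
  }
})

test_that("topology classes match brute-force degree counting", {
  edges <- data.frame(
    virus_contig_id = c("v1", "v2", "v3", "v4", "v4", "v5"),
    host_taxon = c("tA", "tB", "tB", "tC", "tD", "tE"),
    stringsAsFactors = FALSE
  )
  topo <- classify_topology(edges)
  o <- oracle_topology(edges)
  m <- merge(topo, o, by = c("virus_contig_id", "host_taxon"))
  expect_equal(m$specialist.x, m$specialist.y)
  expect_equal(m$generalist_host.x, m$generalist_host.y)
  expect_equal(m$polyvalent_virus.x, m$polyvalent_virus.y)
  expect_true(topo$specialist[topo$virus_contig_id == "v1"])
  expect_true(all(topo$generalist_host[topo$host_taxon == "tB"]))
  expect_true(all(topo$polyvalent_virus[topo$virus_contig_id == "v4"]))

  set.seed(404)
  for (i in 1:20) {
    e <- unique(data.frame(
      virus_contig_id = sample(paste0("v", 1:6), 12, TRUE),
      host_taxon = sample(paste0("t", 1:5), 12, TRUE)))
    got <- classify_topology(e)
    want <- oracle_topology(e)
    m <- merge(got, want, by = c("virus_contig_id", "host_taxon"))
    expect_equal(m$specialist.x, unname(m$specialist.y))
    expect_equal(m$generalist_host.x, unname(m$generalist_host.y))
    expect_equal(m$polyvalent_virus.x, unname(m$polyvalent_virus.y))
  }
})
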