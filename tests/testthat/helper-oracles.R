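# Independent brute-force oracles and small utilities. Everything here is
# deliberately written from the definitions, not by calling package internals.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# substitute a different base at each given position
mutate_at_hl <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  paste(chars, collapse = "")
}

# --- screening -------------------------------------------------------------

# Boolean oracle for the three screening criteria, written longhand.
oracle_criteria <- function(n, vpf, ko, pfam) {
  ko_f <- if (n == 0) 0 else ko / n
  pf_f <- if (n == 0) 0 else pfam / n
  c(c1 = (vpf >= 5) && (ko_f < 0.20) && (pf_f <= 0.40),
    c2 = vpf >= pfam,
    c3 = vpf >= 0.60 * n)
}

oracle_retained <- function(n, vpf, ko, pfam, category, length_bp) {
  cat_ok <- !is.na(category) && category %in% c(1, 2, 4, 5)
  if (length_bp < 1000) return(FALSE)
  if (!cat_ok) return(FALSE)
  if (length_bp <= 5000) return(TRUE)
  any(oracle_criteria(n, vpf, ko, pfam))
}

random_profiles <- function(n_profiles) {
  n <- sample(0:30, n_profiles, TRUE)
  data.frame(
    contig_id = sprintf("c%04d", seq_len(n_profiles)),
    n_genes = n,
    n_genes_vpf = vapply(n, function(k) sample(0:max(k, 1), 1) * (k > 0),
                         integer(1)),
    n_genes_ko = vapply(n, function(k) sample(0:max(k, 1), 1) * (k > 0),
                        integer(1)),
    n_genes_pfam = vapply(n, function(k) sample(0:max(k, 1), 1) * (k > 0),
                          integer(1)),
    length_bp = sample(c(1200, 4000, 8000, 20000), n_profiles, TRUE),
    stringsAsFactors = FALSE
  )
}

# --- clustering ------------------------------------------------------------

# Adjusted Rand index from the contingency-table formula.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Greedy first-match clustering re-coded independently on a precomputed
# all-pairs alignment table (list keyed "a|b" -> c(identity, coverage)).
oracle_greedy <- function(ids, lens, pair_fun, min_id = 0.95, min_cov = 0.80) {
  ord <- order(-lens, ids)
  ids <- ids[ord]
  reps <- character()
  assign <- character(length(ids))
  names(assign) <- ids
  for (id in ids) {
    placed <- FALSE
    for (r in reps) {
      al <- pair_fun(r, id)
      if (al[1] >= min_id && al[2] >= min_cov) {
        assign[id] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      assign[id] <- id
    }
  }
  assign
}

# --- taxonomy --------------------------------------------------------------

# Counting oracle for the majority vote: per protein, best family among
# hits with bitscore >= 50 (tie -> abstain); family wins with > 50% of all
# proteins.
oracle_vote <- function(protein_ids, hit_tab) {
  votes <- character()
  for (p in protein_ids) {
    h <- hit_tab[hit_tab$protein_id == p & hit_tab$bitscore >= 50, ]
    if (nrow(h) == 0) next
    best <- h$label[h$bitscore == max(h$bitscore)]
    if (length(unique(best)) == 1) votes <- c(votes, best[1])
  }
  if (!length(votes)) return("Unassigned")
  tab <- sort(table(votes), decreasing = TRUE)
  if (tab[1] > 0.5 * length(protein_ids)) names(tab)[1] else "Unassigned"
}

# --- host linkage ----------------------------------------------------------

oracle_topology <- function(edges) {
  edges <- unique(edges)
  dv <- table(edges$virus_contig_id)
  dh <- table(edges$host_taxon)
  data.frame(
    virus_contig_id = edges$virus_contig_id,
    host_taxon = edges$host_taxon,
    specialist = dv[edges$virus_contig_id] == 1 & dh[edges$host_taxon] == 1,
    generalist_host = dh[edges$host_taxon] >= 2,
    polyvalent_virus = dv[edges$virus_contig_id] >= 2,
    row.names = NULL
  )
}

# --- AMG flags -------------------------------------------------------------

# F/B flags recomputed from first principles on a contig layout given as a
# logical vector of M flags (genes in index order).
oracle_fb_flags <- function(m_flags, window = 2, run_min = 3) {
  n <- length(m_flags)
  f <- (seq_len(n) - 1 < window) | (seq_len(n) - 1 > n - 1 - window)
  b <- rep(FALSE, n)
  i <- 1
  while (i <= n) {
    if (m_flags[i]) {
      j <- i
      while (j < n && m_flags[j + 1]) j <- j + 1
      if (j - i + 1 >= run_min) b[i:j] <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  list(f = f, b = b)
}

# --- diversity -------------------------------------------------------------

oracle_alpha <- function(x) {
  x <- x[x > 0]
  s <- length(x)
  p <- x / sum(x)
  h <- -sum(p * log(p))
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  chao1 <- s + f1 * (f1 - 1) / (2 * (f2 + 1))
  # ACE, rare cutoff 10, gamma^2 floored at 0
  rare <- x[x <= 10]
  abund <- x[x > 10]
  if (length(rare) == 0) {
    ace <- s
  } else {
    n_rare <- sum(rare)
    c_ace <- 1 - f1 / n_rare
    if (c_ace == 0) {
      ace <- NA_real_
    } else {
      ks <- vapply(1:10, function(k) sum(rare == k), numeric(1))
      g2 <- max(length(rare) / c_ace * sum((1:10) * (0:9) * ks) /
                  (n_rare * (n_rare - 1)) - 1, 0)
      ace <- length(abund) + length(rare) / c_ace + f1 / c_ace * g2
    }
  }
  c(richness = s, chao1 = chao1, ace = ace, shannon = h,
    simpson = 1 - sum(p^2),
    pielou = if (s > 1) h / log(s) else NA_real_)
}

oracle_bray <- function(x, y) {
  if (sum(x) + sum(y) == 0) return(0)
  sum(abs(x - y)) / sum(x + y)
}

# Average-linkage cophenetic distances by direct agglomeration.
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, length(clusters))
  dist_cl <- function(a, b) mean(d[clusters[[a]], clusters[[b]]])
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); bd <- Inf
    for (i in idx) for (j in idx) if (i < j) {
      dd <- dist_cl(i, j)
      if (dd < bd) { bd <- dd; best <- c(i, j) }
    }
    a <- best[1]; b <- best[2]
    coph[clusters[[a]], clusters[[b]]] <- bd
    coph[clusters[[b]], clusters[[a]]] <- bd
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    active[b] <- FALSE
  }
  coph
}

oracle_network <- function(edge_df, nodes = NULL) {
  el <- unique(t(apply(as.matrix(edge_df[, 1:2]), 1, sort)))
  el <- el[el[, 1] != el[, 2], , drop = FALSE]
  if (is.null(nodes)) nodes <- unique(as.vector(el))
  n <- length(nodes)
  e <- nrow(el)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(e)) {
    adj[el[k, 1], el[k, 2]] <- TRUE
    adj[el[k, 2], el[k, 1]] <- TRUE
  }
  cc <- vapply(nodes, function(v) {
    nb <- nodes[adj[v, ]]
    k <- length(nb)
    if (k < 2) return(0)
    t_v <- sum(adj[nb, nb]) / 2
    2 * t_v / (k * (k - 1))
  }, numeric(1))
  list(density = if (n >= 2) 2 * e / (n * (n - 1)) else NA_real_,
       avg_neighbors = 2 * e / n,
       avg_clustering = mean(cc))
}

# --- shared fixtures -------------------------------------------------------

# One small cached dataset for tests that only need a representative input.
tiny_design <- function(seed = 42L) {
  synth_design(n_viral_lineages = 4, variants_per_lineage = 2,
               n_decoys = 1, n_bacterial_taxa = 6,
               viral_contig_len_bp = 1000, n_nonviral = 1,
               rng_seed = seed)
}
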