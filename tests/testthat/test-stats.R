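test_that("TPM matches hand-evaluated values and its row-sum identity", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- tpm_normalize(counts, c(a = 1000, b = 2000))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-12)

  eq <- tpm_normalize(matrix(c(7, 7), 2, 1,
                             dimnames = list(c("a", "b"), "s")),
                      c(a = 500, b = 500))
  expect_equal(unname(eq[, 1]), c(5e5, 5e5))

  set.seed(601)
  m <- matrix(rpois(60, 20), 10, 6,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  tpm <- tpm_normalize(m, setNames(sample(500:3000, 10), paste0("f", 1:10)))
  expect_equal(unname(colSums(tpm)), rep(1e6, 6), tolerance = 1e-6)

  expect_error(tpm_normalize(matrix(-1), 100), "negative")
  zero <- matrix(c(0, 0, 3, 1), 2, 2,
                 dimnames = list(c("a", "b"), c("z", "s")))
  expect_warning(tz <- tpm_normalize(zero, c(a = 100, b = 100)), "all-zero")
  expect_equal(unname(tz[, "z"]), c(0, 0))
})

test_that("alpha diversity matches closed forms and the formula oracle", {
  uniform <- matrix(c(5, 5, 5, 5), 4, 1,
                    dimnames = list(paste0("t", 1:4), "s"))
  a <- alpha_diversity(uniform)
  expect_equal(a$shannon, log(4), tolerance = 1e-10)
  expect_equal(a$pielou, 1.0, tolerance = 1e-10)
  expect_equal(a$simpson, 0.75, tolerance = 1e-10)

  # worked bias-corrected Chao1 example: F1 = 2, F2 = 1
  x <- matrix(c(5, 1, 1, 2), 4, 1, dimnames = list(paste0("t", 1:4), "s"))
  expect_equal(alpha_diversity(x)$chao1, 4.5, tolerance = 1e-10)

  set.seed(611)
  for (i in 1:200) {
    v <- rpois(sample(5:40, 1), lambda = sample(c(0.5, 2, 8), 1))
    if (sum(v) == 0) v[1] <- 1
    m <- matrix(v, length(v), 1, dimnames = list(seq_along(v), "s"))
    got <- alpha_diversity(m)
    want <- oracle_alpha(v)
    expect_equal(got$richness, unname(want["richness"]))
    expect_equal(got$chao1, unname(want["chao1"]), tolerance = 1e-10)
    expect_equal(got$shannon, unname(want["shannon"]), tolerance = 1e-10)
    expect_equal(got$simpson, unname(want["simpson"]), tolerance = 1e-10)
    if (!is.na(want["pielou"]))
      expect_equal(got$pielou, unname(want["pielou"]), tolerance = 1e-10)
    if (is.finite(want["ace"]))
      expect_equal(got$ace, unname(want["ace"]), tolerance = 1e-8)
    expect_gte(got$chao1, got$richness)
    expect_gte(got$ace + 1e-9, got$richness)
  }

  allz <- matrix(0, 3, 1, dimnames = list(1:3, "s"))
  expect_warning(z <- alpha_diversity(allz), "all-zero")
  expect_true(is.na(z$richness))
  expect_error(alpha_diversity(matrix(1.5, 1, 1, dimnames = list("a", "s"))),
               "integer")
})

test_that("pooling two samples never decreases richness", {
  set.seed(612)
  for (i in 1:30) {
    m <- matrix(rpois(40, 1.2), 20, 2, dimnames = list(1:20, c("a", "b")))
    if (sum(m[, 1]) == 0 || sum(m) == 0) next
    pooled <- matrix(m[, 1] + m[, 2], 20, 1, dimnames = list(1:20, "p"))
    suppressWarnings({
      r1 <- alpha_diversity(m)$richness[1]
      rp <- alpha_diversity(pooled)$richness
    })
    expect_gte(rp, r1)
  }
})

test_that("Bray-Curtis matches its formula, with defined all-zero behavior", {
  m <- matrix(c(1, 2, 3, 1, 2, 3, 0, 0, 5), 3, 3,
              dimnames = list(paste0("f", 1:3), c("a", "b", "c")))
  d <- bray_curtis(m)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "b"], d["b", "a"])

  disjoint <- matrix(c(3, 0, 0, 4), 2, 2,
                     dimnames = list(c("f1", "f2"), c("a", "b")))
  expect_equal(bray_curtis(disjoint)["a", "b"], 1)

  set.seed(621)
  for (i in 1:50) {
    m <- matrix(rpois(16, 4), 4, 4,
                dimnames = list(paste0("f", 1:4), paste0("s", 1:4)))
    if (any(colSums(m) == 0)) next
    d <- bray_curtis(m)
    for (a in 1:3) for (b in (a + 1):4)
      expect_equal(d[a, b], oracle_bray(m[, a], m[, b]), tolerance = 1e-12)
  }

  zz <- matrix(0, 2, 2, dimnames = list(c("f1", "f2"), c("a", "b")))
  expect_warning(dz <- bray_curtis(zz), "all-zero")
  expect_equal(dz["a", "b"], 0)
})

test_that("UPGMA reproduces the hand-worked 3-point case and oracle cophenetics", {
  d <- matrix(c(0, 0.2, 0.8,
                0.2, 0, 0.8,
                0.8, 0.8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d)
  hc <- attr(tr, "hclust")
  expect_equal(sort(hc$height), c(0.2, 0.8))
  # ultrametric node heights are half the merge dissimilarity: 0.1 and 0.4
  depth <- max(ape::node.depth.edgelength(tr))
  expect_equal(depth, 0.4)
  expect_equal(ape::cophenetic.phylo(tr)["A", "B"], 0.2)
  # ((A,B),C) topology
  expect_true(ape::is.monophyletic(tr, c("A", "B")))

  two <- matrix(c(0, 0.6, 0.6, 0), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma_tree(two)
  expect_equal(unname(t2$edge.length), c(0.3, 0.3))

  set.seed(631)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    m <- matrix(runif(n * n), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
    tr <- upgma_tree(m)
    got <- ape::cophenetic.phylo(tr)[rownames(m), rownames(m)]
    want <- oracle_upgma_cophenetic(m)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }

  bad <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(upgma_tree(bad), "symmetric")
})

test_that("network statistics match hand values and a brute-force oracle", {
  tri <- data.frame(a = c("x", "y", "z"), b = c("y", "z", "x"))
  s <- network_stats(tri)
  expect_equal(s$density, 1.0)
  expect_equal(s$avg_clustering_coefficient, 1.0)
  expect_equal(s$avg_neighbors, 2.0)

  star <- data.frame(a = c("hub", "hub", "hub"), b = c("l1", "l2", "l3"))
  s2 <- network_stats(star)
  expect_equal(s2$density, 0.5)
  expect_equal(s2$avg_clustering_coefficient, 0.0)
  expect_equal(s2$avg_neighbors, 1.5)

  # self-loops and duplicate edges are dropped and counted
  messy <- data.frame(a = c("x", "x", "x", "y"), b = c("y", "y", "x", "z"))
  s3 <- network_stats(messy)
  expect_equal(s3$n_edges, 2L)
  expect_equal(s3$n_dropped, 2L)

  set.seed(641)
  for (i in 1:20) {
    nodes <- paste0("n", 1:10)
    e <- unique(data.frame(a = sample(nodes, 20, TRUE),
                           b = sample(nodes, 20, TRUE)))
    e <- e[e$a != e$b, ]
    e <- e[!duplicated(t(apply(e, 1, sort))), ]
    if (nrow(e) < 2) next
    got <- network_stats(e, nodes = nodes)
    want <- oracle_network(e, nodes = nodes)
    expect_equal(got$density, want$density, tolerance = 1e-12)
    expect_equal(got$avg_neighbors, want$avg_neighbors, tolerance = 1e-12)
    expect_equal(got$avg_clustering_coefficient, want$avg_clustering,
                 tolerance = 1e-12)
  }
})
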