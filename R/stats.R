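#' TPM normalization
#'
#' Transcripts/fragments per kilobase per million: per sample,
#' `TPM_i = 1e6 * (c_i / L_i) / sum_j (c_j / L_j)`. Every sample column sums
#' to one million (within floating point), making abundances comparable
#' across samples of different sequencing depth.
#'
#' @param counts Feature-by-sample count matrix (non-negative).
#' @param lengths_bp Feature lengths in bp, recycled against rows by name or
#'   position.
#' @return TPM matrix of the same shape.
#' @export
tpm_normalize <- function(counts, lengths_bp) {
  if (any(counts < 0)) stop("negative count", call. = FALSE)
  if (!is.null(names(lengths_bp)) && !is.null(rownames(counts)))
    lengths_bp <- lengths_bp[rownames(counts)]
  stopifnot(length(lengths_bp) == nrow(counts), all(lengths_bp > 0))
  rate <- counts / lengths_bp
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("all-zero sample(s): ",
            paste(colnames(counts)[zero], collapse = ", "))
    denom[zero] <- 1
  }
  sweep(rate, 2L, denom, "/") * 1e6
}

#' Alpha diversity indices per sample
#'
#' Computes, per sample (column): observed richness, bias-corrected Chao1 and
#' ACE richness estimators (via \pkg{vegan}, integer counts required),
#' Shannon entropy (natural log by default), Gini-Simpson index
#' `1 - sum(p^2)`, and Pielou evenness `H / log(S)` (absent when richness is
#' 0 or 1). All-zero samples get NA rows with a warning.
#'
#' @param counts Feature-by-sample matrix of integer counts.
#' @param params A [viro_params()] object (`shannon_base`).
#' @return Data.frame with one row per sample: `sample_id`, `richness`,
#'   `chao1`, `ace`, `shannon`, `simpson`, `pielou`.
#' @export
alpha_diversity <- function(counts, params = viro_params()) {
  stopifnot(is.matrix(counts))
  if (max(abs(counts - round(counts))) > 1e-9)
    stop("alpha diversity estimators require integer counts", call. = FALSE)
  samples <- colnames(counts)
  out <- data.frame(sample_id = samples, richness = NA_real_,
                    chao1 = NA_real_, ace = NA_real_, shannon = NA_real_,
                    simpson = NA_real_, pielou = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(samples)) {
    x <- round(counts[, j])
    if (sum(x) == 0) {
      warning("all-zero sample: ", samples[j])
      next
    }
    # vegan warns on degenerate estimator inputs; those cases are resolved
    # explicitly below
    est <- suppressWarnings(vegan::estimateR(x))
    s <- sum(x > 0)
    h <- vegan::diversity(x, index = "shannon", base = params$shannon_base)
    out$richness[j] <- s
    out$chao1[j] <- unname(est["S.chao1"])
    ace <- unname(est["S.ACE"])
    # no rare species (all counts above the cutoff): the abundance-based
    # coverage estimator degenerates to the observed richness
    out$ace[j] <- if (is.finite(ace)) ace else s
    out$shannon[j] <- h
    out$simpson[j] <- vegan::diversity(x, index = "simpson")
    out$pielou[j] <- if (s > 1) h / log(s, base = params$shannon_base) else NA
  }
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over features, computed with
#' \pkg{vegan}. The distance between two all-zero samples is defined as 0
#' (with a warning) rather than NaN.
#'
#' @param abundance Feature-by-sample matrix (counts or TPM).
#' @return A symmetric sample-by-sample matrix with zero diagonal.
#' @export
bray_curtis <- function(abundance) {
  d <- as.matrix(suppressWarnings(vegan::vegdist(t(abundance),
                                                 method = "bray")))
  if (any(is.nan(d))) {
    warning("all-zero sample pair(s); Bray-Curtis defined as 0")
    d[is.nan(d)] <- 0
  }
  d
}

#' UPGMA clustering of samples
#'
#' Average-linkage agglomeration on a symmetric dissimilarity matrix. Columns
#' are ordered by sample id before clustering so tie-breaking is
#' deterministic. Node heights of the returned ultrametric tree are half the
#' merge dissimilarity (each tip is `merge/2` below its ancestor).
#'
#' @param dissimilarity Symmetric matrix with zero diagonal.
#' @return An [ape::as.phylo()] tree; the underlying `hclust` object is kept
#'   in `attr(, "hclust")`.
#' @export
upgma_tree <- function(dissimilarity) {
  d <- as.matrix(dissimilarity)
  if (!isSymmetric(unname(d), tol = 1e-12))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tr <- ape::as.phylo(hc)
  attr(tr, "hclust") <- hc
  tr
}

#' Whole-graph summary statistics
#'
#' Builds a simple undirected graph from an edge list (self-loops and
#' duplicate edges dropped, their count reported) and computes: density
#' `2E / (N (N - 1))`, average neighbor count `2E / N`, and the mean local
#' clustering coefficient, counting nodes of degree below 2 as 0 (the
#' NetworkAnalyzer convention; set
#' `clustering_include_low_degree = FALSE` to average over degree >= 2 nodes
#' only).
#'
#' @param edges Two-column data.frame (or matrix) of endpoint pairs.
#' @param nodes Optional vector of node ids, to include isolated nodes.
#' @param params A [viro_params()] object.
#' @return List: `n_nodes`, `n_edges`, `n_dropped` (self-loops/multi-edges),
#'   `density`, `avg_neighbors`, `avg_clustering_coefficient`. Density is NA
#'   when the graph has fewer than 2 nodes.
#' @export
network_stats <- function(edges, nodes = NULL, params = viro_params()) {
  el <- as.matrix(edges[, 1:2, drop = FALSE])
  storage.mode(el) <- "character"
  if (is.null(nodes)) nodes <- unique(as.vector(el))
  g <- igraph::graph_from_data_frame(
    as.data.frame(el, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes))
  raw_edges <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  dens <- if (n < 2L) NA_real_ else 2 * e / (n * (n - 1))
  local_c <- igraph::transitivity(g, type = "local", isolates = "zero")
  avg_c <- if (params$clustering_include_low_degree) mean(local_c)
           else mean(local_c[igraph::degree(g) >= 2])
  list(n_nodes = n, n_edges = e, n_dropped = raw_edges - e,
       density = dens, avg_neighbors = if (n > 0L) 2 * e / n else NA_real_,
       avg_clustering_coefficient = avg_c)
}
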