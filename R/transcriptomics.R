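# Imaging transcriptomics: per-region count normalization, cell-type
# marker derivation, gene ranking by Spearman correlation with a regional
# map, and weighted-KS set enrichment, all with spin-based spatial nulls.

#' Normalize expression within each region to a fixed total
#'
#' Scales every region (row) so its gene values sum to `total`.
#'
#' @param expr Region x gene matrix of non-negative values.
#' @param total Target row sum (default 10000).
#' @return Normalized matrix.
#' @export
normalize_per_region <- function(expr, total = 10000) {
  expr <- as.matrix(expr)
  assert_that(all(expr >= 0), "expression must be non-negative")
  rs <- rowSums(expr)
  if (any(rs == 0)) {
    bad <- rownames(expr)[rs == 0] %||% which(rs == 0)
    stop_sfgc(paste("all-zero region(s):", paste(bad, collapse = ", ")))
  }
  expr * (total / rs)
}

#' Derive cell-type marker gene sets from a cell x gene table
#'
#' For each cell type, computes a per-gene Welch t statistic of
#' log1p-transformed expression in cells of that type against all other
#' cells, ranks genes by the statistic descending, and retains the top k.
#'
#' @param cell_expr Cell x gene matrix.
#' @param cell_labels Cell-type label per cell (>= 2 cells per type).
#' @param top_k Markers per type (default 200; capped at the gene universe
#'   with a warning).
#' @return Named list of character gene vectors (a gene-set collection).
#' @export
derive_markers <- function(cell_expr, cell_labels, top_k = 200L) {
  X <- log1p(as.matrix(cell_expr))
  genes <- colnames(X) %||% paste0("g", seq_len(ncol(X)))
  types <- unique(cell_labels)
  if (top_k > ncol(X)) {
    warn("top_k exceeds the gene universe; capping")
    top_k <- ncol(X)
  }
  out <- lapply(types, function(ty) {
    inn <- cell_labels == ty
    assert_that(sum(inn) >= 2 && sum(!inn) >= 2,
                "each cell type needs >= 2 cells (and >= 2 others)")
    m1 <- colMeans(X[inn, , drop = FALSE])
    m0 <- colMeans(X[!inn, , drop = FALSE])
    v1 <- apply(X[inn, , drop = FALSE], 2, var)
    v0 <- apply(X[!inn, , drop = FALSE], 2, var)
    se <- sqrt(v1 / sum(inn) + v0 / sum(!inn))
    tstat <- (m1 - m0) / pmax(se, 1e-12)
    genes[order(-tstat, genes)][seq_len(top_k)]
  })
  setNames(out, types)
}

# Spearman correlations of one map against every gene column, via Pearson
# on centered ranks (single matrix product)
spearman_vs_genes <- function(map_ranks, expr_ranks) {
  drop(cor(map_ranks, expr_ranks))
}

#' Gene-wise Spearman correlation with a regional map, spin-adjusted
#'
#' Computes Spearman's rank correlation of every gene's regional expression
#' with the map, and a spatially adjusted p-value per gene by recomputing
#' the correlation on every spun copy of the map.
#'
#' @param heritability_map Per-region values (named or in row order of
#'   `expr`).
#' @param expr Region x gene expression matrix (>= 5 regions).
#' @param spins A `spin_set` on the region centroids.
#' @return Tibble with `gene`, `r`, `p_spin`, and `constant` flag for genes
#'   with no regional variation (r undefined).
#' @export
gene_map_correlation <- function(heritability_map, expr, spins) {
  expr <- as.matrix(expr)
  R <- nrow(expr)
  assert_that(length(heritability_map) == R,
              "map and expression regions differ")
  assert_that(R >= 5, "need at least 5 regions")
  genes <- colnames(expr) %||% paste0("g", seq_len(ncol(expr)))
  const <- apply(expr, 2, function(v) sd(v) == 0)
  er <- apply(expr, 2, rank)
  mr <- rank(heritability_map)
  r_obs <- suppressWarnings(spearman_vs_genes(mr, er))
  null_r <- matrix(NA_real_, nrow(spins$indices), ncol(expr))
  for (s in seq_len(nrow(spins$indices))) {
    null_r[s, ] <- suppressWarnings(
      spearman_vs_genes(rank(heritability_map[spins$indices[s, ]]), er))
  }
  p <- vapply(seq_len(ncol(expr)), function(g) {
    if (const[g]) return(NA_real_)
    spin_pvalue(r_obs[g], null_r[, g])
  }, numeric(1))
  tibble(gene = genes, r = unname(ifelse(const, NA_real_, r_obs)),
         p_spin = p, constant = unname(const))
}

#' Rank genes by descending correlation
#'
#' Strict descending order on the correlation, ties broken by gene id
#' (stable lexicographic order).
#'
#' @param correlations Tibble from [gene_map_correlation()] or a named
#'   numeric vector.
#' @return Tibble with `gene` and `r` in ranked order.
#' @export
rank_genes <- function(correlations) {
  if (is.numeric(correlations))
    correlations <- tibble(gene = names(correlations),
                           r = unname(correlations))
  assert_that(all(is.finite(correlations$r)), "correlations must be finite")
  correlations[order(-correlations$r, correlations$gene),
               c("gene", "r")]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked gene list accumulating `|r|^exponent` (normalized over
#' the set) at hits and a uniform decrement at misses; the enrichment score
#' is the extremum (signed) of the running sum. `exponent = 0` reduces to
#' the classical unweighted KS statistic. A set equal to the whole universe
#' has no misses; that degenerate case returns 0 with a warning.
#'
#' @param ranked Tibble from [rank_genes()] (columns `gene`, `r`).
#' @param gene_set Character vector, a subset of the universe.
#' @param exponent Weighting exponent on `|r|` (default 1).
#' @return Enrichment score in `[-1, 1]`.
#' @export
gsea_es <- function(ranked, gene_set, exponent = 1) {
  hits <- ranked$gene %in% gene_set
  if (!any(hits)) stop_sfgc("gene set does not intersect the universe")
  if (all(hits)) {
    warn("gene set equals the universe: enrichment score defined as 0")
    return(0)
  }
  w <- abs(ranked$r)^exponent
  wh <- w * hits
  if (sum(wh) == 0) wh[hits] <- 1   # all-zero weights: fall back to uniform
  inc <- wh / sum(wh)
  dec <- (!hits) / sum(!hits)
  running <- cumsum(inc - dec)
  running[which.max(abs(running))]
}

#' Spin-adjusted gene-set enrichment against a regional map
#'
#' For the observed map: per-gene Spearman correlations, ranking, and the
#' weighted-KS enrichment score per set. The null re-runs the whole
#' pipeline (correlate, re-rank, re-score) on every spun map, and the
#' spatially adjusted p-value compares the observed score against that
#' null.
#'
#' @param heritability_map Per-region values.
#' @param expr Region x gene matrix.
#' @param gene_sets Named list of gene sets.
#' @param spins A `spin_set` on the region centroids.
#' @param exponent Weighting exponent (default 1).
#' @return Tibble with `set`, `es`, `p_spin`, `p_bh`, `n_hits`.
#' @export
spin_adjusted_enrichment <- function(heritability_map, expr, gene_sets,
                                     spins, exponent = 1) {
  expr <- as.matrix(expr)
  er <- apply(expr, 2, rank)
  genes <- colnames(expr) %||% paste0("g", seq_len(ncol(expr)))
  score_map <- function(map_vals) {
    r <- suppressWarnings(spearman_vs_genes(rank(map_vals), er))
    r[!is.finite(r)] <- 0
    ranked <- rank_genes(setNames(r, genes))
    vapply(gene_sets, function(gs) gsea_es(ranked, gs, exponent), numeric(1))
  }
  es_obs <- score_map(heritability_map)
  n_spins <- nrow(spins$indices)
  es_null <- matrix(NA_real_, n_spins, length(gene_sets))
  for (s in seq_len(n_spins))
    es_null[s, ] <- score_map(heritability_map[spins$indices[s, ]])
  p <- vapply(seq_along(gene_sets), function(k)
    spin_pvalue(es_obs[k], es_null[, k]), numeric(1))
  tibble(set = names(gene_sets), es = unname(es_obs), p_spin = p,
         p_bh = fdr_bh(p),
         n_hits = unname(vapply(gene_sets, function(gs) sum(genes %in% gs),
                                numeric(1))))
}
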