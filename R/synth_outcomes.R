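# Synthetic behavioral outcomes driven by chosen coupling features, and
# synthetic expression tables with a planted spatial correlation to a
# target regional map plus planted cell-type marker blocks.

#' Generate behavioral outcomes linearly driven by coupling features
#'
#' Builds a latent signal from a sparse weight vector over the feature
#' matrix and adds Gaussian noise scaled so the population variance
#' explained of the linear signal equals the configured `r2`. The
#' continuous outcome is the noisy latent; the binary outcome thresholds an
#' independent noisy copy at its median (balanced classes).
#'
#' @param features Subject x feature matrix (e.g. coupling values).
#' @param behavior_effects List with `support` (column indices or names),
#'   `weights`, and `r2` in `[0, 1)`; `r2 = 0` gives pure noise.
#' @param seed Integer seed.
#' @return Tibble with `continuous` and `binary` columns (binary coded
#'   0/1).
#' @export
gen_behavior <- function(features, behavior_effects, seed = 1L) {
  X <- as.matrix(features)
  assert_that(!anyNA(X), "feature matrix must be complete")
  n <- nrow(X)
  sup <- behavior_effects$support
  wts <- behavior_effects$weights
  r2 <- behavior_effects$r2 %||% 0.25
  signal <- if (length(sup) == 0) rep(0, n)
            else drop(X[, sup, drop = FALSE] %*% wts)
  vs <- var(signal)
  noise_sd <- if (vs == 0 || r2 <= 0) 1
              else if (r2 >= 1) 0
              else sqrt(vs * (1 - r2) / r2)
  with_seed(derive_seed(seed, "behavior"), {
    cont <- signal + rnorm(n, sd = noise_sd)
    lat <- signal + rnorm(n, sd = noise_sd)
    bin <- as.integer(lat > median(lat))
    tibble(continuous = cont, binary = bin)
  })
}

#' Generate region x gene and cell x gene expression tables
#'
#' The first `block_size` genes form a block whose expected Spearman
#' correlation with the target regional map equals `planted_corr` (the
#' underlying Gaussian mixing coefficient is de-attenuated via the
#' grade-of-membership relation `rho_pearson = 2 sin(pi rho_s / 6)`);
#' remaining genes are spatially unrelated. Expression is exponentiated to
#' positive count-like values, which preserves rank correlations. The cell
#' table gives each cell type a disjoint marker block overexpressed in its
#' own cells at the configured log-scale effect size.
#'
#' @param region_map Per-region target values (e.g. a heritability map).
#' @param n_genes Total genes.
#' @param n_celltypes Number of cell types.
#' @param planted_corr Target Spearman correlation of the planted block,
#'   `|rho| <= 1`.
#' @param block_size Genes in the correlated block (default 20).
#' @param marker_size Marker genes per cell type (default 20).
#' @param cells_per_type Cells per type (default 50).
#' @param marker_effect Log-scale overexpression of markers in their own
#'   type (default 3 = strong).
#' @param noise_sd Log-scale biological noise of the cell table (default
#'   1); 0 gives noiseless separation.
#' @param seed Integer seed.
#' @return List: `region_expr` (region x gene matrix), `cell_expr` (cell x
#'   gene matrix), `cell_labels`, `marker_truth` (named list of gene
#'   vectors), `correlated_genes`.
#' @export
gen_expression <- function(region_map, n_genes = 200L, n_celltypes = 4L,
                           planted_corr = 0.8, block_size = 20L,
                           marker_size = 20L, cells_per_type = 50L,
                           marker_effect = 3, noise_sd = 1, seed = 1L) {
  assert_that(abs(planted_corr) <= 1, "|planted_corr| must be <= 1")
  R <- length(region_map)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  m <- scale(rank(region_map))[, 1]
  with_seed(derive_seed(seed, "expression"), {
    Z <- matrix(rnorm(R * n_genes), R, n_genes)
    if (block_size > 0) {
      if (abs(planted_corr) == 1) {
        Z[, seq_len(block_size)] <- matrix(rep(sign(planted_corr) * m,
                                               block_size), R)
      } else {
        rho_p <- 2 * sin(pi * planted_corr / 6)
        Z[, seq_len(block_size)] <- rho_p * m +
          sqrt(1 - rho_p^2) * Z[, seq_len(block_size), drop = FALSE]
      }
    }
    region_expr <- exp(2 + 0.8 * Z)
    dimnames(region_expr) <- list(names(region_map) %||%
                                    sprintf("region%03d", seq_len(R)),
                                  gene_ids)
    types <- sprintf("type%d", seq_len(n_celltypes))
    cell_labels <- rep(types, each = cells_per_type)
    n_cells <- length(cell_labels)
    logc <- matrix(rnorm(n_cells * n_genes, sd = noise_sd), n_cells)
    marker_truth <- list()
    for (k in seq_len(n_celltypes)) {
      gidx <- block_size + (k - 1) * marker_size + seq_len(marker_size)
      assert_that(max(gidx) <= n_genes,
                  "n_genes too small for the requested marker blocks")
      logc[cell_labels == types[k], gidx] <-
        logc[cell_labels == types[k], gidx] + marker_effect
      marker_truth[[types[k]]] <- gene_ids[gidx]
    }
    cell_expr <- exp(logc)
    dimnames(cell_expr) <- list(sprintf("cell%04d", seq_len(n_cells)),
                                gene_ids)
    list(region_expr = region_expr, cell_expr = cell_expr,
         cell_labels = cell_labels, marker_truth = marker_truth,
         correlated_genes = gene_ids[seq_len(block_size)])
  })
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character gene vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Read gene sets from GMT format
#'
#' @param path GMT file path.
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1],
                       character(1), USE.NAMES = FALSE)
  out
}
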