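# Gradient construction: QC filter, Fisher-z, proportional thresholding,
# cosine affinity, anisotropic diffusion-map embedding, component selection,
# Procrustes alignment to a cohort template.

#' Diffusion embedding configuration
#'
#' @param alpha Anisotropy exponent in `[0, 1]`; 0.5 balances sampling
#'   density.
#' @param t Diffusion time (virtual random-walk steps); 0 preserves the full
#'   spectrum.
#' @param n_components_computed Number of non-trivial components computed.
#' @param n_components_retained Cap D on retained components.
#' @param variance_threshold Cumulative variance fraction at which retention
#'   stops.
#' @param sparsity_keep_fraction Fraction of strongest edges kept by
#'   proportional thresholding.
#' @param normalization_exponent `"alpha"` (standard, reweights the affinity
#'   by the degree to the power -alpha) or `"inv_alpha"` (power -1/alpha).
#' @return A `diffusion_config` list.
#' @export
diffusion_config <- function(alpha = 0.5, t = 0,
                             n_components_computed = 200L,
                             n_components_retained = 20L,
                             variance_threshold = 0.70,
                             sparsity_keep_fraction = 0.10,
                             normalization_exponent = c("alpha", "inv_alpha")) {
  normalization_exponent <- match.arg(normalization_exponent)
  assert_that(alpha >= 0 && alpha <= 1, "alpha must be in [0, 1]")
  assert_that(t >= 0, "t must be >= 0")
  assert_that(n_components_retained <= n_components_computed,
              "D must be <= n_components_computed")
  assert_that(variance_threshold > 0 && variance_threshold <= 1,
              "variance_threshold must be in (0, 1]")
  assert_that(sparsity_keep_fraction > 0 && sparsity_keep_fraction <= 1,
              "sparsity_keep_fraction must be in (0, 1]")
  structure(list(alpha = alpha, t = t,
                 n_components_computed = as.integer(n_components_computed),
                 n_components_retained = as.integer(n_components_retained),
                 variance_threshold = variance_threshold,
                 sparsity_keep_fraction = sparsity_keep_fraction,
                 normalization_exponent = normalization_exponent),
            class = "diffusion_config")
}

#' Head-motion quality-control filter
#'
#' Retains subjects whose mean framewise displacement does not exceed the
#' cutoff (exclusion is strictly `mean_fd > threshold`), preserving order.
#'
#' @param cohort Cohort tibble with a `mean_fd` column (mm).
#' @param threshold Cutoff in mm (default 0.3).
#' @return Character vector of retained subject ids.
#' @export
qc_filter_fd <- function(cohort, threshold = 0.3) {
  if (anyNA(cohort$mean_fd)) {
    bad <- cohort$subject[is.na(cohort$mean_fd)]
    stop_sfgc(paste("missing mean_fd for:", paste(bad, collapse = ", ")))
  }
  keep <- cohort$subject[cohort$mean_fd <= threshold]
  if (length(keep) == 0)
    warn("all subjects exceed the motion threshold; empty retention set")
  keep
}

#' Fisher z-transform of a correlation matrix
#'
#' Applies `atanh` off-diagonal and sets the diagonal to zero (self-edges
#' never enter the edge ranking).
#'
#' @param fc_matrix Symmetric correlation matrix with off-diagonal entries in
#'   (-1, 1).
#' @return Transformed matrix.
#' @export
fisher_z <- function(fc_matrix) {
  check_symmetric(fc_matrix, tol = 1e-8, what = "FC matrix")
  off <- fc_matrix[upper.tri(fc_matrix) | lower.tri(fc_matrix)]
  if (any(abs(off) >= 1))
    stop_sfgc("off-diagonal correlations must have |r| < 1")
  z <- atanh(fc_matrix)
  diag(z) <- 0
  z
}

#' Proportional thresholding of a connectivity matrix
#'
#' Ranks all non-diagonal connection weights globally (on the upper triangle,
#' mirrored) and retains the strongest fraction of undirected edges, zeroing
#' the rest. Ties are broken by stable index order.
#'
#' @param matrix Symmetric matrix.
#' @param keep_fraction Fraction of edges to keep, in (0, 1].
#' @return Sparsified symmetric matrix.
#' @export
threshold_top_fraction <- function(matrix, keep_fraction = 0.10) {
  assert_that(keep_fraction > 0 && keep_fraction <= 1,
              "keep_fraction must be in (0, 1]")
  check_symmetric(matrix, tol = 1e-8, what = "input")
  ut <- which(upper.tri(matrix))
  n_keep <- ceiling(keep_fraction * length(ut))
  ord <- order(matrix[ut], decreasing = TRUE)   # stable: ties by index
  keep_idx <- ut[ord[seq_len(n_keep)]]
  out <- array(0, dim(matrix))
  out[keep_idx] <- matrix[keep_idx]
  out <- out + t(out)
  diag(out) <- diag(matrix)
  out
}

#' Cosine-similarity affinity matrix
#'
#' Converts a sparsified connectivity matrix into the affinity used for
#' diffusion embedding: entry (i, j) is the cosine of rows i and j, with
#' negative values clamped to zero (the Markov operator requires
#' non-negative weights) and unit diagonal.
#'
#' @param sparse_matrix Symmetric matrix; no all-zero rows.
#' @return Symmetric non-negative affinity with unit diagonal.
#' @export
cosine_affinity <- function(sparse_matrix) {
  nrm <- sqrt(rowSums(sparse_matrix^2))
  if (any(nrm == 0))
    stop_sfgc(paste("all-zero rows (over-thresholding?) at vertices:",
                    paste(which(nrm == 0), collapse = ", ")))
  a <- tcrossprod(sparse_matrix / nrm)
  a[a < 0] <- 0
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

new_gradient_set <- function(embedding, eigenvalues, variance_explained,
                             subject = NA_character_, modality = NA_character_,
                             aligned = FALSE, config = NULL) {
  structure(list(subject = subject, modality = modality,
                 embedding = embedding, eigenvalues = eigenvalues,
                 variance_explained = variance_explained,
                 aligned = aligned, config = config),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("<gradient_set %s/%s> %d x %d (aligned: %s)\n",
              x$subject, x$modality, nrow(x$embedding), ncol(x$embedding),
              x$aligned))
  invisible(x)
}

#' Anisotropic diffusion-map embedding of an affinity matrix
#'
#' Forms the anisotropically reweighted affinity `W = Gamma^-e A Gamma^-e`
#' (with `e = alpha` by default), row-normalizes it into a Markov operator
#' `P = Gamma_W^-1 W`, and solves the eigenproblem through the symmetric
#' conjugate `Gamma_W^-1/2 W Gamma_W^-1/2`. Embedding columns are the
#' non-trivial right eigenvectors of `P` (unit-normalized), ordered by
#' descending eigenvalue and scaled by `lambda^t`; the trivial `lambda = 1`
#' constant eigenvector is omitted. Variance explained is reported as
#' `lambda^2 / sum(lambda^2)` over the computed non-trivial spectrum.
#'
#' @param A Symmetric non-negative affinity with positive row sums.
#' @param config A [diffusion_config()].
#' @param subject,modality Optional labels carried on the result.
#' @return A `gradient_set`.
#' @export
diffusion_embedding <- function(A, config = diffusion_config(),
                                subject = NA_character_,
                                modality = NA_character_) {
  check_symmetric(A, tol = 1e-8, what = "affinity")
  if (any(A < 0)) stop_sfgc("affinity must be non-negative")
  deg <- rowSums(A)
  if (any(deg <= 0)) stop_sfgc("affinity has a zero row sum")
  e <- if (config$normalization_exponent == "alpha") config$alpha
       else 1 / config$alpha
  dinv <- deg^(-e)
  W <- A * (dinv %o% dinv)
  dw <- rowSums(W)
  s <- 1 / sqrt(dw)
  S <- W * (s %o% s)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  # right eigenvectors of P = Dw^-1 W are Dw^-1/2 * (eigenvectors of S)
  phi <- es$vectors * s
  lam <- es$values
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]; phi <- phi[, ord, drop = FALSE]
  # drop the trivial lambda_0 = 1 stationary eigenvector
  lam <- lam[-1]; phi <- phi[, -1, drop = FALSE]
  ncomp <- min(config$n_components_computed, length(lam))
  lam <- lam[seq_len(ncomp)]; phi <- phi[, seq_len(ncomp), drop = FALSE]
  phi <- sweep(phi, 2, sqrt(colSums(phi^2)), "/")
  emb <- sweep(phi, 2, lam^config$t, "*")
  ve <- lam^2 / sum(lam^2)
  new_gradient_set(emb, lam, ve, subject, modality, aligned = FALSE,
                   config = config)
}

#' Number of gradients needed to reach a variance threshold
#'
#' Returns `min(d_max, smallest d whose cumulative lambda^2 fraction reaches
#' the threshold)`.
#'
#' @param eigenvalues Non-trivial eigenvalues, sorted descending.
#' @param variance_threshold Cumulative variance fraction (default 0.70).
#' @param d_max Cap on the retained count (default 20).
#' @return Integer retained count.
#' @export
select_components <- function(eigenvalues, variance_threshold = 0.70,
                              d_max = 20L) {
  assert_that(length(eigenvalues) > 0, "empty spectrum")
  assert_that(!is.unsorted(rev(eigenvalues)) ||
                all(diff(eigenvalues) <= 1e-12),
              "eigenvalues must be sorted descending")
  frac <- cumsum(eigenvalues^2) / sum(eigenvalues^2)
  d <- which(frac >= variance_threshold)[1]
  if (is.na(d)) d <- length(eigenvalues)
  as.integer(min(d_max, d))
}

#' Orthogonal Procrustes alignment of a gradient set to a template
#'
#' Multiplies the subject embedding by the orthogonal matrix minimizing the
#' Frobenius distance to the template (rotation/reflection only: no scaling,
#' no translation). Aligning an already-aligned set is idempotent.
#'
#' @param subject_gs,template `gradient_set` objects with matching
#'   dimensions.
#' @return The aligned `gradient_set`.
#' @export
procrustes_align <- function(subject_gs, template) {
  S <- subject_gs$embedding; Tm <- template$embedding
  if (!all(dim(S) == dim(Tm)))
    stop_sfgc("subject and template dimensions differ")
  sv <- svd(crossprod(S, Tm))
  R <- sv$u %*% t(sv$v)
  out <- subject_gs
  out$embedding <- S %*% R
  out$aligned <- TRUE
  out
}

preprocess_connectome <- function(conn, config) {
  m <- conn$matrix
  if (identical(conn$modality, "FC")) m <- fisher_z(m) else diag(m) <- 0
  m
}

#' Connectome-to-gradients pipeline for one subject
#'
#' Fisher-z (FC only), proportional thresholding, cosine affinity, diffusion
#' embedding — the standard per-subject path.
#'
#' @param conn A `connectome`.
#' @param config A [diffusion_config()].
#' @return A `gradient_set`.
#' @export
compute_gradients <- function(conn, config = diffusion_config()) {
  m <- preprocess_connectome(conn, config)
  m <- threshold_top_fraction(m, config$sparsity_keep_fraction)
  a <- cosine_affinity(m)
  diffusion_embedding(a, config, subject = conn$subject,
                      modality = conn$modality)
}

# pin eigenvector signs: orient each template gradient so its correlation
# with a fixed reference axis is non-negative; fall back across coordinates
# when a gradient is numerically orthogonal to the reference
pin_signs <- function(embedding, reference) {
  ref <- as.matrix(reference)
  for (d in seq_len(ncol(embedding))) {
    g <- embedding[, d]
    for (k in seq_len(ncol(ref))) {
      r <- suppressWarnings(cor(g, ref[, k]))
      if (!is.na(r) && abs(r) > 1e-8) {
        if (r < 0) embedding[, d] <- -g
        break
      }
    }
  }
  embedding
}

#' Cohort-level gradient template
#'
#' Embeds the element-wise mean of the per-subject preprocessed connectomes
#' (mean taken at the Fisher-z / zero-diagonal stage, then thresholded,
#' converted to affinity, and embedded once). Template gradient signs are
#' pinned to a reference axis so the orientation is reproducible; subject
#' gradients inherit the orientation through alignment.
#'
#' @param connectomes List of `connectome` objects (same modality).
#' @param config A [diffusion_config()].
#' @param reference Optional V x k matrix of reference axes for sign pinning
#'   (e.g. sphere coordinates); columns tried in order.
#' @return A `gradient_set` with subject id `"template"`.
#' @export
build_template <- function(connectomes, config = diffusion_config(),
                           reference = NULL) {
  assert_that(length(connectomes) >= 1, "need at least one subject")
  acc <- NULL
  for (cn in connectomes) {
    m <- preprocess_connectome(cn, config)
    acc <- if (is.null(acc)) m else acc + m
  }
  mmean <- acc / length(connectomes)
  mmean <- threshold_top_fraction(mmean, config$sparsity_keep_fraction)
  a <- cosine_affinity(mmean)
  gs <- diffusion_embedding(a, config, subject = "template",
                            modality = connectomes[[1]]$modality)
  if (!is.null(reference)) gs$embedding <- pin_signs(gs$embedding, reference)
  gs$aligned <- TRUE
  gs
}

#' Spatial correspondence between two maps with a spin-based null
#'
#' Pearson correlation between two vertex/parcel maps plus a spatially
#' constrained permutation p-value: the second map is evaluated against spun
#' copies of the first.
#'
#' @param map_a,map_b Numeric maps on the same locations.
#' @param spins A `spin_set` from [generate_spins()] on those locations.
#' @return List with `r` and `p`.
#' @export
gradient_correspondence <- function(map_a, map_b, spins) {
  assert_that(length(map_a) == length(map_b), "maps must have equal length")
  if (sd(map_a) == 0 || sd(map_b) == 0)
    stop_sfgc("correlation undefined for a constant map")
  r_obs <- cor(map_a, map_b)
  r_null <- apply(spins$indices, 1, function(idx) cor(map_a[idx], map_b))
  list(r = r_obs, p = spin_pvalue(r_obs, r_null))
}
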