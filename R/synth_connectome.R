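# Planted smooth connectivity axes and per-subject connectome synthesis.
#
# The functional and structural latent axes are low-order polynomials of the
# spherical coordinates (spherical-harmonic-like), so they are smooth over
# the cortex and recoverable by diffusion embedding. Within each parcel the
# first structural axis is a planted mixture of the first functional axis
# and an orthogonal smooth direction, so the within-parcel cosine alignment
# equals the configured coupling strength exactly at the axis level.

smooth_basis <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  # real spherical harmonics that are even in x (mirror-symmetric across
  # hemispheres); mutually orthogonal on the sphere, so axes never alias
  b <- cbind(z, y,
             3 * z^2 - 1, y * z, x^2 - y^2,
             5 * z^3 - 3 * z, y * (5 * z^2 - 1), z * (x^2 - y^2),
             y^3 - 3 * x^2 * y,
             35 * z^4 - 30 * z^2 + 3)
  b <- scale(b, center = TRUE, scale = FALSE)
  # orthonormalize (Gram-Schmidt order preserved) so distinct axes never
  # alias each other; pin signs to the raw functions for determinism
  q <- qr.Q(qr(b))
  sgn <- sign(colSums(q * b))
  sgn[sgn == 0] <- 1
  sweep(q, 2, sgn, "*")
}

#' Planted latent axes for a synthetic cohort
#'
#' Returns the cohort-level ground-truth axes the connectome generator embeds:
#' functional axes, structural axes (whose first axis realizes the per-parcel
#' planted coupling against the first functional axis), the sphere geometry
#' and the parcellation. Deterministic given the config.
#'
#' @param config A [synth_config()].
#' @return List with `f_axes`, `s_axes` (V x L matrices, unit-norm columns),
#'   `sphere`, `parcellation`, and `axis_weights`.
#' @export
planted_axes <- function(config) {
  sph <- gen_sphere(config$n_vertices, config$n_parcels)
  coords <- as.matrix(sph$vertices[, c("x", "y", "z")])
  B <- smooth_basis(coords)
  L <- config$n_latent_axes
  assert_that(L >= 1 && L <= 5, "n_latent_axes must be in 1..5")
  f_axes <- B[, seq_len(L), drop = FALSE]
  # structural higher axes use a disjoint part of the basis
  s_axes <- B[, 5 + seq_len(L), drop = FALSE]
  # first structural axis: per-parcel mixture of the first functional axis
  # with a globally smooth companion field, mixing coefficients solved so
  # the within-parcel (uncentered) cosine equals the planted strength
  f1 <- f_axes[, 1]
  u <- B[, 9]                       # smooth companion (y^3-like)
  u <- u - sum(u * f1) * f1         # globally orthogonal to f1
  u <- u / sqrt(sum(u^2))
  s1 <- numeric(length(f1))
  labels <- sph$vertices$parcel
  for (j in seq_len(config$n_parcels)) {
    idx <- which(labels == j)
    fh <- f1[idx] / sqrt(sum(f1[idx]^2))
    uh <- u[idx] / sqrt(sum(u[idx]^2))
    rho <- config$coupling_strength[j]
    if (rho >= 1 - 1e-12) {
      sj <- fh
    } else {
      cj <- sum(fh * uh)
      a <- -cj + rho * sqrt(1 - cj^2) / sqrt(1 - rho^2)
      sj <- a * fh + uh
      sj <- sj / sqrt(sum(sj^2))
    }
    # carry the functional axis' parcel-norm profile for smoothness
    s1[idx] <- sj * sqrt(sum(f1[idx]^2))
  }
  s_axes[, 1] <- s1 / sqrt(sum(s1^2))
  w <- 0.75^(seq_len(L) - 1)
  # short-range spatial autocorrelation kernel shared by both modalities
  # (keeps every vertex connected to its lattice neighborhood, as head
  # tissue smoothness does in real data)
  d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") -
    2 * tcrossprod(coords)
  d2[d2 < 0] <- 0
  dnn <- sqrt(apply(d2 + diag(Inf, nrow(coords)), 1, min))
  Ksp <- exp(-d2 / (2 * (2.5 * stats::median(dnn))^2))
  list(f_axes = f_axes, s_axes = s_axes, sphere = sph,
       parcellation = parcellation(sph$vertices, name = "longitude_wedges"),
       axis_weights = w, spatial_kernel = Ksp)
}

new_connectome <- function(subject, modality, matrix, vertices = NULL) {
  check_symmetric(matrix, tol = 1e-8, what = paste(modality, "matrix"))
  structure(list(subject = subject, modality = modality, matrix = matrix,
                 vertices = vertices %||% seq_len(nrow(matrix))),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome %s/%s> %d x %d\n", x$subject, x$modality,
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

subject_axes <- function(axes, noise, seed) {
  if (noise <= 0) return(axes)
  with_seed(seed, {
    V <- nrow(axes)
    E <- matrix(rnorm(V * ncol(axes)), V)
    E <- sweep(E, 2, sqrt(colSums(E^2)), "/")
    out <- (axes + noise * E) / sqrt(1 + noise^2)
    out
  })
}

#' Generate one subject's structural and functional connectome pair
#'
#' Functional connectivity is the correlation matrix of synthetic vertex
#' "time series" driven by the planted functional axes plus a global
#' component (unit diagonal, entries in (-1, 1)). Structural connectivity is
#' a Gaussian kernel of distance in the weighted structural-axis profile
#' space, floored to zero for weak connections (non-negative, symmetric).
#' Per-subject variability perturbs the axes by the configured noise scale.
#'
#' @param subject Subject id (used to derive the per-subject seed).
#' @param config A [synth_config()].
#' @param axes Optional precomputed [planted_axes()] (avoids recomputation in
#'   loops).
#' @return List with `sc` and `fc`, both `connectome` objects.
#' @export
gen_connectome_pair <- function(subject, config, axes = planted_axes(config)) {
  L <- config$n_latent_axes
  V <- config$n_vertices
  w <- axes$axis_weights
  seed_f <- derive_seed(config$seed, paste0("fc-", subject))
  seed_s <- derive_seed(config$seed, paste0("sc-", subject))
  Fi <- subject_axes(axes$f_axes, config$subject_noise, seed_f)
  Si <- subject_axes(axes$s_axes, config$subject_noise, seed_s)

  beta_sp <- 0.15
  latent_corr <- function(axes_i, seed) {
    with_seed(seed, {
      Tn <- config$n_timepoints
      # global component keeps profile angles small; the short-range
      # spatial kernel is blended in as in spatially smooth acquisitions
      load <- cbind(1.5 / sqrt(V), sweep(axes_i, 2, w, "*")) * sqrt(V)
      At <- matrix(rnorm(Tn * (L + 1)), Tn)
      ts <- At %*% t(load) + matrix(rnorm(Tn * V, sd = 0.3), Tn)
      C <- (1 - beta_sp) * cor(ts) + beta_sp * axes$spatial_kernel
      (C + t(C)) / 2
    })
  }
  fc <- latent_corr(Fi, derive_seed(config$seed, paste0("fc-ts-", subject)))
  diag(fc) <- 1

  # SC decays exponentially with the correlation distance between latent
  # streamline-density profiles, floored to zero
  sc <- latent_corr(Si, derive_seed(config$seed, paste0("sc-m-", subject)))
  sc <- exp(-(1 - sc) / 0.5)
  sc[sc < exp(-4)] <- 0
  diag(sc) <- 1

  verts <- axes$sphere$vertices$vertex
  list(sc = new_connectome(subject, "SC", sc, verts),
       fc = new_connectome(subject, "FC", fc, verts))
}
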