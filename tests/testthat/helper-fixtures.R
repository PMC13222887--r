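# Shared small fixtures, built in code.

# deterministic random symmetric affinity (non-negative, positive row sums)
random_affinity <- function(V, seed) {
  withr::with_seed(seed, {
    m <- matrix(runif(V * V), V)
    a <- (m + t(m)) / 2
    diag(a) <- 1
    a
  })
}

# two-community planted affinity: strong within blocks, weak across
community_affinity <- function(V, seed, p_in = 0.9, p_out = 0.05) {
  withr::with_seed(seed, {
    half <- V / 2
    block <- matrix(p_out, V, V)
    block[1:half, 1:half] <- p_in
    block[(half + 1):V, (half + 1):V] <- p_in
    a <- block + matrix(runif(V * V, 0, 0.02), V)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    a
  })
}

# small twin cohort: n_mz MZ pairs, n_dz DZ pairs, n_single singletons
twin_cohort <- function(n_mz, n_dz, n_single = 0, n_fs = 0, seed = 1) {
  synth_config(
    n_subjects = 2 * (n_mz + n_dz + n_fs) + n_single,
    n_vertices = 8, n_parcels = 2,
    pedigree_spec = list(mz_pairs = n_mz, dz_pairs = n_dz,
                         fullsib_pairs = n_fs, halfsib_pairs = 0,
                         singletons = n_single),
    seed = seed) |>
    gen_cohort()
}

# dense-oracle diffusion embedding: explicitly form P^(alpha) and take its
# right eigenvectors (independent of the symmetric-conjugate route)
dense_embedding_oracle <- function(A, alpha = 0.5, exponent = "alpha") {
  deg <- rowSums(A)
  e <- if (exponent == "alpha") alpha else 1 / alpha
  W <- A * (deg^(-e) %o% deg^(-e))
  P <- W / rowSums(W)
  ee <- eigen(P)
  ord <- order(Re(ee$values), decreasing = TRUE)
  lam <- Re(ee$values)[ord][-1]
  phi <- Re(ee$vectors)[, ord, drop = FALSE][, -1, drop = FALSE]
  phi <- sweep(phi, 2, sqrt(colSums(phi^2)), "/")
  list(values = lam, vectors = phi)
}

# maximum column-wise discrepancy up to sign
max_coldiff_upto_sign <- function(A, B) {
  max(vapply(seq_len(ncol(A)), function(j)
    min(max(abs(A[, j] - B[, j])), max(abs(A[, j] + B[, j]))), numeric(1)))
}
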