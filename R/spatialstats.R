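# Spatially constrained permutation inference (spin tests) and the
# classical tests used throughout: Welch and paired t, BH adjustment,
# hemispheric asymmetry.

random_rotation <- function() {
  qr_g <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_g)
  # fix the QR sign ambiguity, then force det +1
  Q <- Q %*% diag(sign(diag(qr.R(qr_g))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Generate spin-rotation permutations for a two-hemisphere map
#'
#' Draws rotations uniform on SO(3) (orthonormalized Gaussian frames with
#' determinant fixed to +1) for the left hemisphere; the right hemisphere
#' uses the same rotation mirrored through the sagittal plane. After
#' rotating the coordinates, each original location is assigned the value of
#' its nearest rotated location within hemisphere, yielding one index
#' reassignment per spin.
#'
#' @param coords Matrix (n x 3) of unit-norm coordinates (vertices or parcel
#'   centroids).
#' @param hemisphere Character vector ("L"/"R") tagging each row.
#' @param n_spins Number of permutations (study setting 10000; desk-scale
#'   runs use fewer).
#' @param seed Integer seed; regeneration is bit-identical.
#' @return A `spin_set`: `indices` (n_spins x n reassignment matrix),
#'   `rotations`, `seed`.
#' @export
generate_spins <- function(coords, hemisphere, n_spins = 1000L, seed = 1L) {
  coords <- as.matrix(coords)
  assert_that(ncol(coords) == 3, "coords must be n x 3")
  assert_that(all(abs(sqrt(rowSums(coords^2)) - 1) < 1e-6),
              "coordinates must be unit norm")
  lh <- which(hemisphere == "L"); rh <- which(hemisphere == "R")
  if (length(lh) < 3 || length(rh) < 3)
    stop_sfgc("need at least 3 locations per hemisphere")
  # unfold each hemisphere's longitudinal half onto its own full sphere
  # (the analogue of per-hemisphere spherical registration), so rotations
  # act bijectively on the hemisphere's domain
  unfold <- function(idx_h, side) {
    lat <- asin(pmin(pmax(coords[idx_h, 3], -1), 1))
    phi <- atan2(coords[idx_h, 2], coords[idx_h, 1])
    phi2 <- if (side == "L") {
      2 * ((phi %% (2 * pi)) - pi / 2)       # (pi/2, 3pi/2) -> (0, 2pi)
    } else {
      2 * (phi + pi / 2)                     # (-pi/2, pi/2) -> (0, 2pi)
    }
    cbind(cos(lat) * cos(phi2), cos(lat) * sin(phi2), sin(lat))
  }
  sc_l <- unfold(lh, "L"); sc_r <- unfold(rh, "R")
  # sagittal mirroring corresponds to negating the unfolded longitude
  M <- diag(c(1, -1, 1))
  idx <- matrix(NA_integer_, n_spins, nrow(coords))
  rots <- vector("list", n_spins)
  with_seed(seed, {
    for (s in seq_len(n_spins)) {
      R <- random_rotation()
      rots[[s]] <- R
      for (side in list(list(i = lh, C = sc_l, R = R),
                        list(i = rh, C = sc_r, R = M %*% R %*% M))) {
        rot <- side$C %*% t(side$R)
        # unit vectors: nearest = largest dot product
        sim <- tcrossprod(side$C, rot)
        idx[s, side$i] <- side$i[max.col(sim, ties.method = "first")]
      }
    }
  })
  spin_coords <- matrix(NA_real_, nrow(coords), 3)
  spin_coords[lh, ] <- sc_l; spin_coords[rh, ] <- sc_r
  structure(list(indices = idx, rotations = rots, seed = seed,
                 hemisphere = hemisphere, spin_coords = spin_coords),
            class = "spin_set")
}

#' @export
print.spin_set <- function(x, ...) {
  cat(sprintf("<spin_set> %d spins over %d locations\n",
              nrow(x$indices), ncol(x$indices)))
  invisible(x)
}

#' Spin permutation p-value
#'
#' Two-sided on magnitude with the +1 correction:
#' `p = (1 + #(|null| >= |obs|)) / (1 + n_null)`.
#'
#' @param observed_stat Observed statistic.
#' @param null_stats Null statistics from the spins.
#' @param two_sided Compare magnitudes (default TRUE).
#' @return p-value in (0, 1].
#' @export
spin_pvalue <- function(observed_stat, null_stats, two_sided = TRUE) {
  assert_that(length(null_stats) >= 1, "empty null distribution")
  if (two_sided)
    (1 + sum(abs(null_stats) >= abs(observed_stat))) / (1 + length(null_stats))
  else
    (1 + sum(null_stats >= observed_stat)) / (1 + length(null_stats))
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t with Satterthwaite degrees of freedom, two-sided.
#'
#' @param a,b Numeric samples (each length >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  assert_that(length(a) >= 2 && length(b) >= 2, "each sample needs >= 2 values")
  if (var(a) == 0 && var(b) == 0)
    stop_sfgc("zero variance in both samples")
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Paired t-test
#'
#' One-sample t on the differences, two-sided.
#'
#' @param a,b Paired numeric samples of equal length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t <- function(a, b) {
  assert_that(length(a) == length(b), "paired samples must have equal length")
  assert_that(length(a) >= 2, "need >= 2 pairs")
  if (sd(a - b) == 0)
    stop_sfgc("constant differences: paired t undefined")
  ht <- t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvals Numeric vector in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
fdr_bh <- function(pvals) {
  assert_that(all(pvals >= 0 & pvals <= 1, na.rm = TRUE),
              "p-values must be in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Hemispheric asymmetry of a gradient map, per network
#'
#' For each homologous network pair (left parcel j vs its right homolog),
#' tests per-subject left minus right network means with a two-sided paired
#' t-test; also reports a global test pooling all networks.
#'
#' @param values Subject x parcel matrix of per-parcel gradient means (parcel
#'   columns ordered as in the parcellation).
#' @param parc A [parcellation()] whose parcels `1..J/2` are left-hemisphere
#'   homologs of `J/2+1..J`.
#' @return Tibble with `network` ("global" plus one row per homolog pair),
#'   `t`, `p`.
#' @export
hemisphere_asymmetry_test <- function(values, parc) {
  J <- parc$J
  assert_that(J %% 2 == 0, "need an even parcel count with LH/RH homologs")
  half <- J / 2
  lh <- which(parc$hemisphere[as.character(parc$parcels)] == "L")
  rh <- which(parc$hemisphere[as.character(parc$parcels)] == "R")
  assert_that(length(lh) == length(rh), "missing hemisphere homolog")
  rows <- purrr::map(seq_len(half), function(k) {
    res <- paired_t(values[, lh[k]], values[, rh[k]])
    tibble(network = paste0("net", k), t = res$t, p = res$p)
  }) |> bind_rows()
  glob <- paired_t(rowMeans(values[, lh, drop = FALSE]),
                   rowMeans(values[, rh, drop = FALSE]))
  bind_rows(tibble(network = "global", t = glob$t, p = glob$p), rows)
}
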