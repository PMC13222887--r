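#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data module: geometry (vertices,
#' parcels), planted latent axes, per-parcel structure-function alignment,
#' site batch effects, the twin/sibling pedigree, ACE variance components,
#' behavioral effects, and the master seed. The generator's defaults define
#' the study conditions used throughout the test-suite and the reproduction
#' script.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param n_vertices Number of cortical vertices V (even; split across two
#'   hemispheres).
#' @param n_parcels Number of parcels J (even; half per hemisphere).
#' @param n_latent_axes Number of smooth planted connectivity axes shared
#'   within the cohort.
#' @param coupling_strength Per-parcel planted cosine alignment of the first
#'   structural axis to the first functional axis, each value in `[0, 1]`.
#'   A scalar is recycled over parcels.
#' @param n_sites Number of acquisition sites.
#' @param batch_shift_sd SD of the per-site, per-feature additive location
#'   shift.
#' @param batch_scale_sd SD (log scale) of the per-site multiplicative scale
#'   factor.
#' @param pedigree_spec Named list with counts `mz_pairs`, `dz_pairs`,
#'   `fullsib_pairs`, `halfsib_pairs`, `singletons`; pair members share a
#'   family id.
#' @param variance_components Length-3 numeric `(sigma_a2, sigma_c2,
#'   sigma_e2)` summing to 1.
#' @param behavior_effects List with `support` (feature indices), `weights`
#'   (matching numeric), and `r2` (population variance explained of the
#'   linear signal).
#' @param age_range Age range (years) the cohort is drawn from.
#' @param subject_noise SD of per-subject perturbation of the latent axes
#'   (the single inter-subject variability knob).
#' @param n_timepoints Synthetic time points used to build functional
#'   connectivity as a correlation of latent loadings.
#' @param seed Integer master seed; fixes every draw.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 300L,
                         n_vertices = 300L,
                         n_parcels = 14L,
                         n_latent_axes = 5L,
                         coupling_strength = 0.7,
                         n_sites = 3L,
                         batch_shift_sd = 0.5,
                         batch_scale_sd = 0.2,
                         pedigree_spec = list(mz_pairs = 0L, dz_pairs = 0L,
                                              fullsib_pairs = 0L,
                                              halfsib_pairs = 0L,
                                              singletons = n_subjects),
                         variance_components = c(0.5, 0.2, 0.3),
                         behavior_effects = list(support = integer(0),
                                                 weights = numeric(0),
                                                 r2 = 0.25),
                         age_range = c(9.00, 10.92),
                         subject_noise = 0.1,
                         n_timepoints = 200L,
                         seed = 1L) {
  assert_that(n_vertices %% 2 == 0, "n_vertices must be even")
  assert_that(n_parcels %% 2 == 0, "n_parcels must be even")
  assert_that(n_vertices >= 2 * n_parcels && n_parcels >= 2,
              "need V >= 2*J >= 4")
  vc <- as.numeric(variance_components)
  assert_that(length(vc) == 3 && all(vc >= 0),
              "variance_components must be 3 non-negative values")
  assert_that(abs(sum(vc) - 1) <= 1e-12,
              "variance_components must sum to 1 (within 1e-12)")
  cs <- rep_len(as.numeric(coupling_strength), n_parcels)
  assert_that(all(cs >= 0 & cs <= 1), "coupling_strength values must be in [0, 1]")
  ped <- pedigree_spec
  for (f in c("mz_pairs", "dz_pairs", "fullsib_pairs", "halfsib_pairs",
              "singletons"))
    ped[[f]] <- as.integer(ped[[f]] %||% 0L)
  n_from_ped <- 2L * (ped$mz_pairs + ped$dz_pairs + ped$fullsib_pairs +
                        ped$halfsib_pairs) + ped$singletons
  if (n_from_ped != n_subjects)
    stop_sfgc(sprintf(
      "pedigree_spec accounts for %d subjects but n_subjects = %d",
      n_from_ped, n_subjects), class = "sfgc_config_error")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_vertices = as.integer(n_vertices),
    n_parcels = as.integer(n_parcels),
    n_latent_axes = as.integer(n_latent_axes),
    coupling_strength = cs,
    n_sites = as.integer(n_sites),
    batch_shift_sd = batch_shift_sd,
    batch_scale_sd = batch_scale_sd,
    pedigree_spec = ped,
    variance_components = setNames(vc, c("sigma_a2", "sigma_c2", "sigma_e2")),
    behavior_effects = behavior_effects,
    age_range = as.numeric(age_range),
    subject_noise = subject_noise,
    n_timepoints = as.integer(n_timepoints),
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  subjects: %d  vertices: %d  parcels: %d  axes: %d\n",
              x$n_subjects, x$n_vertices, x$n_parcels, x$n_latent_axes))
  cat(sprintf("  sites: %d  seed: %d\n", x$n_sites, x$seed))
  cat(sprintf("  variance components (A,C,E): %s\n",
              paste(signif(x$variance_components, 3), collapse = ", ")))
  invisible(x)
}
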