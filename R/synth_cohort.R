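#' Generate a synthetic subject cohort with pedigree structure
#'
#' Draws a covariate table emulating a developmental imaging cohort: ages
#' uniform over the configured range, balanced sex, subjects assigned to
#' sites/scanners, head-motion summaries (mean framewise displacement,
#' log-normal so that a small tail exceeds typical QC cutoffs), and a family
#' structure containing the configured numbers of monozygotic (MZ) twin
#' pairs, dizygotic (DZ) twin pairs, full-sibling pairs, half-sibling pairs,
#' and singletons. Twin and sibling pair members share a family id.
#'
#' @param config A [synth_config()].
#' @param study Study label stored for every subject (used by the bridging
#'   harmonization step).
#' @return A tibble with columns `subject`, `age`, `sex`, `site`, `scanner`,
#'   `study`, `family`, `zygosity`, `mean_fd`.
#' @export
gen_cohort <- function(config, study = "child") {
  ped <- config$pedigree_spec
  n <- config$n_subjects
  if (n == 0) {
    return(tibble(subject = character(0), age = numeric(0), sex = character(0),
                  site = character(0), scanner = character(0),
                  study = character(0), family = character(0),
                  zygosity = character(0), mean_fd = numeric(0)))
  }
  with_seed(derive_seed(config$seed, paste0("cohort-", study)), {
    zyg_pairs <- c(rep("MZ", ped$mz_pairs), rep("DZ", ped$dz_pairs),
                   rep("full_sib", ped$fullsib_pairs),
                   rep("half_sib", ped$halfsib_pairs))
    n_fam_pairs <- length(zyg_pairs)
    fam_ids <- sprintf("fam%04d", seq_len(n_fam_pairs + ped$singletons))
    zygosity <- c(rep(zyg_pairs, each = 2), rep("singleton", ped$singletons))
    family <- c(rep(fam_ids[seq_len(n_fam_pairs)], each = 2),
                fam_ids[n_fam_pairs + seq_len(ped$singletons)])
    site <- sample(sprintf("site%02d", seq_len(config$n_sites)), n,
                   replace = TRUE)
    # family members are scanned at the same site, as in multi-site twin studies
    for (f in unique(family[duplicated(family)]))
      site[family == f] <- site[which(family == f)[1]]
    scanner <- paste0(site, "_scanner1")
    tibble(
      subject = sprintf("sub%05d", seq_len(n)),
      age = runif(n, config$age_range[1], config$age_range[2]),
      sex = sample(c("male", "female"), n, replace = TRUE),
      site = site,
      scanner = scanner,
      study = study,
      family = family,
      zygosity = zygosity,
      mean_fd = exp(rnorm(n, log(0.12), 0.55))
    )
  })
}

#' Count twin/sibling pairs in a cohort table
#'
#' Bookkeeping helper used by the pedigree invariants: extracts the number of
#' MZ, DZ, full-sibling and half-sibling pairs and singletons.
#'
#' @param cohort A cohort tibble from [gen_cohort()].
#' @return Named integer vector.
#' @export
count_pedigree <- function(cohort) {
  pairs <- cohort |>
    filter(.data$zygosity != "singleton") |>
    group_by(.data$family) |>
    summarise(zyg = .data$zygosity[1], n = n(), .groups = "drop")
  c(mz_pairs = sum(pairs$zyg == "MZ" & pairs$n == 2),
    dz_pairs = sum(pairs$zyg == "DZ" & pairs$n == 2),
    fullsib_pairs = sum(pairs$zyg == "full_sib" & pairs$n == 2),
    halfsib_pairs = sum(pairs$zyg == "half_sib" & pairs$n == 2),
    singletons = sum(cohort$zygosity == "singleton"))
}
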