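# End-to-end orchestration on synthetic data: simulate -> QC -> gradients
# -> coupling -> harmonization (with bridging) -> prediction ->
# heritability + power -> spin inference -> transcriptomics, with a JSON
# provenance manifest per stage.

#' Pipeline configuration
#'
#' All stage parameters with two presets: `desk` (small, minutes on one
#' CPU) and `study` (the study-scale settings: 10000 spins, 5000 power
#' replicates, 100 split replicates).
#'
#' @param out_dir Output directory.
#' @param seed Global seed; every stage derives its own stream from it.
#' @param preset `"desk"` or `"study"`.
#' @param ... Overrides of individual fields (e.g. `n_child`, `n_spins`,
#'   `stages`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("sfgc_run_"), seed = 1L,
                            preset = c("desk", "study"), ...) {
  preset <- match.arg(preset)
  base <- list(
    out_dir = out_dir, seed = as.integer(seed), preset = preset,
    n_vertices = 300L, n_parcels = 14L,
    n_child = 300L, n_adult = 120L, n_bridge = 40L,
    fd_threshold = 0.3,
    alpha = 0.5, t = 0, D = 20L, keep_fraction = 0.10,
    variance_threshold = 0.70,
    n_spins = 200L, power_reps = 200L,
    power_h2_grid = c(0.05, 0.2, 0.5, 0.8),
    power_rho_grid = c(0, 0.3, 0.5, 0.8),
    predict_replicates = 10L, k_folds = 10L,
    lambda_grid = KRR_LAMBDA_GRID,
    n_genes = 120L, top_k_markers = 20L, expr_planted_corr = 0.8,
    normalize_total = 10000,
    behavior_r2 = 0.25, n_behavior_support = 5L,
    stages = c("simulate", "coupling", "harmonize", "predict",
               "heritability", "spin", "transcriptomics")
  )
  if (preset == "study") {
    base$n_spins <- 10000L
    base$power_reps <- 5000L
    base$predict_replicates <- 100L
    base$power_h2_grid <- c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7,
                            0.8)
  }
  over <- list(...)
  base[names(over)] <- over
  structure(base, class = "pipeline_config")
}

write_tsv_file <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_tsv_file <- function(path) {
  as_tibble(read.table(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE))
}

# gradients for one cohort: stream subjects, accumulate the mean
# preprocessed connectome for the template, then align everyone to it
cohort_gradients <- function(cohort, scfg, dcfg, axes) {
  acc_f <- NULL; acc_s <- NULL
  subj_gs <- list()
  for (sub in cohort$subject) {
    pair <- gen_connectome_pair(sub, scfg, axes)
    mf <- preprocess_connectome(pair$fc, dcfg)
    ms <- preprocess_connectome(pair$sc, dcfg)
    acc_f <- if (is.null(acc_f)) mf else acc_f + mf
    acc_s <- if (is.null(acc_s)) ms else acc_s + ms
    subj_gs[[sub]] <- list(
      f = diffusion_embedding(cosine_affinity(
        threshold_top_fraction(mf, dcfg$sparsity_keep_fraction)), dcfg,
        subject = sub, modality = "FC"),
      s = diffusion_embedding(cosine_affinity(
        threshold_top_fraction(ms, dcfg$sparsity_keep_fraction)), dcfg,
        subject = sub, modality = "SC"))
  }
  ref <- as.matrix(axes$sphere$vertices[, c("x", "y", "z")])
  embed_mean <- function(acc) {
    m <- threshold_top_fraction(acc / nrow(cohort),
                                dcfg$sparsity_keep_fraction)
    gs <- diffusion_embedding(cosine_affinity(m), dcfg,
                              subject = "template")
    gs$embedding <- pin_signs(gs$embedding, ref)
    gs$aligned <- TRUE
    gs
  }
  tpl_f <- embed_mean(acc_f); tpl_s <- embed_mean(acc_s)
  for (sub in names(subj_gs)) {
    subj_gs[[sub]]$f <- procrustes_align(subj_gs[[sub]]$f, tpl_f)
    subj_gs[[sub]]$s <- procrustes_align(subj_gs[[sub]]$s, tpl_s)
  }
  list(subjects = subj_gs, template_f = tpl_f, template_s = tpl_s)
}

stage_record <- function(manifest, name, files, config, t0) {
  manifest$stages[[name]] <- list(
    outputs = as.list(files),
    md5 = as.list(unname(tools::md5sum(unlist(files)))),
    runtime_s = round(as.numeric(Sys.time()) - t0, 2),
    config = config)
  manifest
}

# a twin/sib whose co-member was excluded by QC becomes a singleton
normalize_orphans <- function(cohort) {
  pairs <- cohort$zygosity != "singleton"
  for (f in unique(cohort$family[pairs])) {
    idx <- cohort$family == f
    if (sum(idx) == 1) cohort$zygosity[idx] <- "singleton"
  }
  cohort
}

parcel_map <- function(values, parc) {
  vapply(parc$parcels, function(j) mean(values[parc$labels == j]),
         numeric(1))
}

#' Run the full synthetic study pipeline
#'
#' Executes the requested stages in dependency order, writing each
#' stage's outputs as TSV plus a JSON provenance manifest (file hashes,
#' per-stage config, runtimes). A stage that is toggled off is skipped;
#' downstream stages then read the cached TSV outputs of the earlier run
#' from `out_dir`. Reruns with the same config and seed reproduce all
#' deterministic outputs bit-identically.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (also written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, preset = config$preset,
                   stages = list())
  dcfg <- diffusion_config(alpha = config$alpha, t = config$t,
                           n_components_retained = config$D,
                           variance_threshold = config$variance_threshold,
                           sparsity_keep_fraction = config$keep_fraction)
  on <- function(stage) stage %in% config$stages
  cached <- function(file) {
    path <- file.path(config$out_dir, file)
    if (!file.exists(path))
      stop_sfgc(paste("stage input missing and not cached:", path))
    read_tsv_file(path)
  }

  n_ad <- config$n_adult
  ped_adult <- list(mz_pairs = round(n_ad * 0.2),
                    dz_pairs = round(n_ad * 0.15),
                    fullsib_pairs = round(n_ad * 0.1), halfsib_pairs = 0L)
  ped_adult$singletons <- n_ad - 2 * (ped_adult$mz_pairs +
                                        ped_adult$dz_pairs +
                                        ped_adult$fullsib_pairs)
  scfgs <- list(
    child = synth_config(n_subjects = config$n_child,
                         n_vertices = config$n_vertices,
                         n_parcels = config$n_parcels,
                         coupling_strength = 0.7, n_sites = 3L,
                         seed = derive_seed(config$seed, "child")),
    adult = synth_config(n_subjects = n_ad,
                         n_vertices = config$n_vertices,
                         n_parcels = config$n_parcels,
                         coupling_strength = 0.5, n_sites = 1L,
                         pedigree_spec = ped_adult,
                         age_range = c(22, 37),
                         seed = derive_seed(config$seed, "adult")),
    bridge = synth_config(n_subjects = config$n_bridge,
                          n_vertices = config$n_vertices,
                          n_parcels = config$n_parcels,
                          coupling_strength = 0.7, n_sites = 1L,
                          seed = derive_seed(config$seed, "bridge")))
  parc <- planted_axes(scfgs$child)$parcellation

  # --- simulate (+ motion QC) ------------------------------------------
  cohorts <- NULL
  if (on("simulate")) {
    t0 <- as.numeric(Sys.time())
    cohorts <- purrr::imap(scfgs, function(sc, nm) {
      co <- gen_cohort(sc, nm)
      co <- co[co$subject %in% qc_filter_fd(co, config$fd_threshold), ]
      normalize_orphans(co)
    })
    files <- purrr::imap(cohorts, function(co, nm)
      write_tsv_file(co, file.path(config$out_dir,
                                   paste0("cohort_", nm, ".tsv"))))
    manifest <- stage_record(manifest, "simulate", files,
                             list(n = vapply(cohorts, nrow, numeric(1)),
                                  fd_threshold = config$fd_threshold), t0)
  }
  get_cohorts <- function() {
    if (is.null(cohorts))
      cohorts <<- list(child = cached("cohort_child.tsv"),
                       adult = cached("cohort_adult.tsv"),
                       bridge = cached("cohort_bridge.tsv"))
    cohorts
  }

  # --- gradients + coupling --------------------------------------------
  couplings <- NULL; grads <- NULL
  if (on("coupling")) {
    t0 <- as.numeric(Sys.time())
    cohorts <- get_cohorts()
    grads <- list(); couplings <- list()
    files <- list()
    for (nm in names(cohorts)) {
      axes <- planted_axes(scfgs[[nm]])
      g <- cohort_gradients(cohorts[[nm]], scfgs[[nm]], dcfg, axes)
      grads[[nm]] <- g
      macro <- bind_rows(lapply(g$subjects, function(s)
        macroscale_sfgc(s$f, s$s, D = config$D)))
      subn <- bind_rows(lapply(g$subjects, function(s)
        subnetwork_sfgc(s$f, s$s, parc, D = config$D)))
      couplings[[nm]] <- list(macro = macro, subnetwork = subn)
      files[[paste0(nm, "_macro")]] <- write_tsv_file(
        macro, file.path(config$out_dir,
                         paste0("coupling_macro_", nm, ".tsv")))
      files[[paste0(nm, "_subnetwork")]] <- write_tsv_file(
        subn, file.path(config$out_dir,
                        paste0("coupling_subnetwork_", nm, ".tsv")))
      # serialized interfaces consumed by the spin stage
      files[[paste0(nm, "_template")]] <- write_tsv_file(
        tibble(parcel = parc$parcels,
               g1 = parcel_map(g$template_f$embedding[, 1], parc)),
        file.path(config$out_dir,
                  paste0("template_g1_parcels_", nm, ".tsv")))
      g1_means <- aggregate_gradient_phenotypes(
        lapply(g$subjects, function(s) s$f), parc, D = 1L)
      files[[paste0(nm, "_g1means")]] <- write_tsv_file(
        g1_means, file.path(config$out_dir,
                            paste0("gradient_parcel_means_", nm, ".tsv")))
    }
    manifest <- stage_record(manifest, "coupling", files,
                             list(D = config$D, J = parc$J,
                                  alpha = config$alpha, t = config$t,
                                  keep_fraction = config$keep_fraction),
                             t0)
  }
  get_coupling <- function(cohort_nm, scale = "subnetwork") {
    if (!is.null(couplings)) return(couplings[[cohort_nm]][[scale]])
    cached(paste0("coupling_", scale, "_", cohort_nm, ".tsv"))
  }

  # --- harmonize --------------------------------------------------------
  child_h <- NULL
  feats <- function(cp) as.matrix(cp[, !(names(cp) %in%
                                           c("subject", "scale"))])
  covs <- function(co) data.frame(age = co$age, sex = co$sex)
  if (on("harmonize")) {
    t0 <- as.numeric(Sys.time())
    cohorts <- get_cohorts()
    child_h <- combat_fit_transform(feats(get_coupling("child")),
                                    cohorts$child$site,
                                    covs(cohorts$child))
    delta <- estimate_bridge_delta(child_h$features,
                                   feats(get_coupling("bridge")),
                                   covs(cohorts$child),
                                   covs(cohorts$bridge))
    adult_b <- apply_bridge(feats(get_coupling("adult")), delta)
    files <- list(
      child = write_tsv_file(child_h$features,
                             file.path(config$out_dir,
                                       "harmonized_child_subnetwork.tsv")),
      adult = write_tsv_file(adult_b,
                             file.path(config$out_dir,
                                       "bridged_adult_subnetwork.tsv")),
      delta = write_tsv_file(tibble(feature = names(delta),
                                    delta = unname(delta)),
                             file.path(config$out_dir,
                                       "bridge_delta.tsv")))
    manifest <- stage_record(manifest, "harmonize", files,
                             list(batch = "site",
                                  covariates = c("age", "sex")), t0)
  }

  # --- predict ----------------------------------------------------------
  if (on("predict")) {
    t0 <- as.numeric(Sys.time())
    cohorts <- get_cohorts()
    Xs <- if (!is.null(child_h)) as.matrix(child_h$features)
          else as.matrix(cached("harmonized_child_subnetwork.tsv"))
    sup <- with_seed(derive_seed(config$seed, "support"),
                     sample.int(ncol(Xs), config$n_behavior_support))
    beh <- gen_behavior(Xs, list(support = sup,
                                 weights = rep(1,
                                               config$n_behavior_support),
                                 r2 = config$behavior_r2),
                        seed = derive_seed(config$seed, "behavior"))
    res_cont <- run_prediction(Xs, beh$continuous, cohorts$child,
                               "continuous", "krr",
                               n_replicates = config$predict_replicates,
                               k = config$k_folds,
                               seed = derive_seed(config$seed,
                                                  "pred-cont"))
    res_bin <- run_prediction(Xs, beh$binary, cohorts$child, "binary",
                              "krr",
                              n_replicates = config$predict_replicates,
                              k = config$k_folds,
                              seed = derive_seed(config$seed, "pred-bin"))
    pred_tab <- bind_rows(
      mutate(res_cont$metrics, outcome = "continuous", model = "krr"),
      mutate(res_bin$metrics, outcome = "binary", model = "krr"))
    fi_tab <- tibble(feature = colnames(res_cont$importance),
                     importance = colMeans(res_cont$importance))
    files <- list(
      metrics = write_tsv_file(pred_tab,
                               file.path(config$out_dir,
                                         "prediction_metrics.tsv")),
      importance = write_tsv_file(fi_tab,
                                  file.path(config$out_dir,
                                            "feature_importance.tsv")))
    manifest <- stage_record(manifest, "predict", files,
                             list(replicates = config$predict_replicates,
                                  support = sup), t0)
  }

  # --- heritability -----------------------------------------------------
  h2_map <- NULL
  if (on("heritability")) {
    t0 <- as.numeric(Sys.time())
    cohorts <- get_cohorts()
    kin <- build_kinship(cohorts$adult)
    Xcov <- stats::model.matrix(~ age + sex,
                                data = cohorts$adult)[, -1, drop = FALSE]
    y_pl <- gen_twin_phenotype(kin, X = Xcov,
                               variance_components = c(0.5, 0.2, 0.3),
                               beta = c(0, 0.01, 0.2),
                               seed = derive_seed(config$seed,
                                                  "ace-pheno"))
    fit_pl <- fit_ace(y_pl, Xcov, kin)
    sub_adult <- get_coupling("adult")
    h2_map <- vapply(parc$parcels, function(j) {
      y <- sub_adult[[sprintf("P%d_F1_S1", j)]]
      fit_ace(y, Xcov, kin, restarts = 1L)$h2
    }, numeric(1))
    pw <- power_simulation(kin, Xcov, h2_grid = config$power_h2_grid,
                           rho_grid = config$power_rho_grid,
                           n_reps = config$power_reps,
                           seed = derive_seed(config$seed, "power"))
    files <- list(
      h2 = write_tsv_file(tibble(parcel = parc$parcels, h2 = h2_map),
                          file.path(config$out_dir,
                                    "heritability_map.tsv")),
      planted = write_tsv_file(tidy(fit_pl),
                               file.path(config$out_dir,
                                         "ace_planted_fit.tsv")),
      power = write_tsv_file(pw, file.path(config$out_dir,
                                           "power_curve.tsv")))
    manifest <- stage_record(manifest, "heritability", files,
                             list(n = nrow(cohorts$adult),
                                  power_reps = config$power_reps), t0)
  }
  get_h2_map <- function() {
    if (!is.null(h2_map)) return(h2_map)
    cached("heritability_map.tsv")$h2
  }

  # --- spin inference ---------------------------------------------------
  spins <- NULL
  make_spins <- function() {
    cent <- planted_axes(scfgs$adult)$sphere$centroids
    generate_spins(as.matrix(cent[, c("x", "y", "z")]), cent$hemisphere,
                   n_spins = config$n_spins,
                   seed = derive_seed(config$seed, "spins"))
  }
  if (on("spin")) {
    t0 <- as.numeric(Sys.time())
    spins <- make_spins()
    tpl_child <- if (!is.null(grads))
      tibble(parcel = parc$parcels,
             g1 = parcel_map(grads$child$template_f$embedding[, 1], parc))
    else cached("template_g1_parcels_child.tsv")
    tpl_adult <- if (!is.null(grads))
      tibble(parcel = parc$parcels,
             g1 = parcel_map(grads$adult$template_f$embedding[, 1], parc))
    else cached("template_g1_parcels_adult.tsv")
    corr <- gradient_correspondence(tpl_child$g1, tpl_adult$g1, spins)
    g1_means <- if (!is.null(grads))
      aggregate_gradient_phenotypes(
        lapply(grads$adult$subjects, function(s) s$f), parc, D = 1L)
    else cached("gradient_parcel_means_adult.tsv")
    asym <- hemisphere_asymmetry_test(as.matrix(g1_means[, -1]), parc)
    files <- list(
      corr = write_tsv_file(tibble(r = corr$r, p = corr$p),
                            file.path(config$out_dir,
                                      "gradient_correspondence.tsv")),
      asym = write_tsv_file(asym,
                            file.path(config$out_dir,
                                      "hemisphere_asymmetry.tsv")))
    manifest <- stage_record(manifest, "spin", files,
                             list(n_spins = config$n_spins), t0)
  }

  # --- transcriptomics --------------------------------------------------
  if (on("transcriptomics")) {
    t0 <- as.numeric(Sys.time())
    if (is.null(spins)) spins <- make_spins()
    h2v <- get_h2_map()
    expr <- gen_expression(setNames(h2v, paste0("region", parc$parcels)),
                           n_genes = config$n_genes, n_celltypes = 4L,
                           planted_corr = config$expr_planted_corr,
                           marker_size = config$top_k_markers,
                           seed = derive_seed(config$seed, "expr"))
    norm_expr <- normalize_per_region(expr$region_expr,
                                      config$normalize_total)
    markers <- derive_markers(expr$cell_expr, expr$cell_labels,
                              top_k = config$top_k_markers)
    enr <- spin_adjusted_enrichment(h2v, norm_expr, markers, spins)
    gcor <- gene_map_correlation(h2v, norm_expr, spins)
    files <- list(
      enrichment = write_tsv_file(enr,
                                  file.path(config$out_dir,
                                            "enrichment.tsv")),
      gene_corr = write_tsv_file(gcor,
                                 file.path(config$out_dir,
                                           "gene_correlations.tsv")))
    write_gmt(markers, file.path(config$out_dir, "markers.gmt"))
    files$markers <- file.path(config$out_dir, "markers.gmt")
    manifest <- stage_record(manifest, "transcriptomics", files,
                             list(n_genes = config$n_genes), t0)
  }

  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summary tables from a completed pipeline run
#'
#' Reads the stage outputs referenced by a manifest back into tibbles:
#' prediction metrics, feature importance, heritability map, power curve,
#' enrichment results, spatial correspondence and asymmetry tables. A
#' manifest from a partial run yields a partial report with a warning.
#'
#' @param manifest Manifest returned by [run_pipeline()] (or the path to
#'   the run directory).
#' @return Named list of tibbles.
#' @export
report <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(file.path(manifest, "manifest.json"))
  out <- list()
  grab <- function(stage, key) {
    st <- manifest$stages[[stage]]
    if (is.null(st)) return(NULL)
    path <- unlist(st$outputs)[key]
    if (is.null(path) || is.na(path) || !file.exists(path)) return(NULL)
    read_tsv_file(path)
  }
  out$prediction <- grab("predict", "metrics")
  out$feature_importance <- grab("predict", "importance")
  out$heritability <- grab("heritability", "h2")
  out$power <- grab("heritability", "power")
  out$enrichment <- grab("transcriptomics", "enrichment")
  out$correspondence <- grab("spin", "corr")
  out$asymmetry <- grab("spin", "asym")
  incomplete <- vapply(out, is.null, logical(1))
  if (any(incomplete))
    warn(paste("incomplete manifest; missing:",
               paste(names(out)[incomplete], collapse = ", ")))
  out[!incomplete]
}
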