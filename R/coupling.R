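# Structural-functional gradient coupling: pairwise cosine similarity
# between functional and structural gradient columns, whole-cortex
# (macroscale) or restricted to each parcel (subnetwork).

coupling_names <- function(D, parcels = NULL) {
  dd <- expand.grid(s = seq_len(D), f = seq_len(D))
  # (d, d') row-major: functional index varies slowest
  base <- sprintf("F%d_S%d", dd$f, dd$s)
  if (is.null(parcels)) return(base)
  as.vector(vapply(parcels, function(j) paste0("P", j, "_", base),
                   character(length(base))))
}

pairwise_cosine <- function(Fm, Sm, zero_norm = c("error", "zero")) {
  zero_norm <- match.arg(zero_norm)
  nf <- sqrt(colSums(Fm^2)); ns <- sqrt(colSums(Sm^2))
  if (any(nf == 0) || any(ns == 0)) {
    if (zero_norm == "error")
      stop_sfgc("zero-norm gradient column (degenerate embedding)")
    warn("zero-norm gradient sub-column; coupling recorded as 0")
  }
  nf[nf == 0] <- Inf; ns[ns == 0] <- Inf
  crossprod(sweep(Fm, 2, nf, "/"), sweep(Sm, 2, ns, "/"))
}

#' Macroscale structural-functional gradient coupling
#'
#' For one subject, the cosine similarity between every functional gradient
#' column and every structural gradient column over all vertices, flattened
#' into a length-`D^2` vector named `F{d}_S{d'}` (functional-major order).
#'
#' @param gf,gs Aligned `gradient_set` objects (same V); the first `D`
#'   columns of each are used.
#' @param D Number of gradients per modality (default 20).
#' @return One-row tibble: `subject`, `scale`, then the `D^2` coupling
#'   columns.
#' @export
macroscale_sfgc <- function(gf, gs, D = 20L) {
  assert_that(nrow(gf$embedding) == nrow(gs$embedding),
              "gradient sets must share V")
  D <- min(D, ncol(gf$embedding), ncol(gs$embedding))
  Fm <- gf$embedding[, seq_len(D), drop = FALSE]
  Sm <- gs$embedding[, seq_len(D), drop = FALSE]
  cs <- pairwise_cosine(Fm, Sm, zero_norm = "error")
  vals <- as.vector(t(cs))  # F-major: F1_S1, F1_S2, ...
  stopifnot(all(abs(vals) <= 1 + 1e-12))
  out <- as_tibble(as.list(setNames(vals, coupling_names(D))))
  dplyr::bind_cols(tibble(subject = gf$subject, scale = "macroscale"), out)
}

#' Subnetwork-level structural-functional gradient coupling
#'
#' Restriction of the macroscale coupling to each parcel's vertices: for
#' parcel j the cosine is computed over that parcel's rows only, giving a
#' length `J * D^2` vector in parcel-major order (`P{j}_F{d}_S{d'}`). A
#' zero-norm sub-column yields 0 with a warning rather than an error.
#'
#' @param gf,gs Aligned `gradient_set` objects.
#' @param parc A [parcellation()] covering all vertices.
#' @param D Number of gradients per modality.
#' @return One-row tibble: `subject`, `scale`, then `J * D^2` columns.
#' @export
subnetwork_sfgc <- function(gf, gs, parc, D = 20L) {
  assert_that(length(parc$labels) == nrow(gf$embedding),
              "parcellation must cover all vertices")
  D <- min(D, ncol(gf$embedding), ncol(gs$embedding))
  Fm <- gf$embedding[, seq_len(D), drop = FALSE]
  Sm <- gs$embedding[, seq_len(D), drop = FALSE]
  vals <- unlist(lapply(parc$parcels, function(j) {
    idx <- parc$labels == j
    cs <- pairwise_cosine(Fm[idx, , drop = FALSE], Sm[idx, , drop = FALSE],
                          zero_norm = "zero")
    as.vector(t(cs))
  }))
  stopifnot(all(abs(vals) <= 1 + 1e-12))
  out <- as_tibble(as.list(setNames(vals, coupling_names(D, parc$parcels))))
  dplyr::bind_cols(tibble(subject = gf$subject, scale = "subnetwork"), out)
}

coupling_matrix <- function(coupling_row) {
  vals <- coupling_row[, !(names(coupling_row) %in% c("subject", "scale"))]
  unlist(vals)
}

#' Mean coupling strength across subjects
#'
#' Per coupling feature, the mean over subjects of the absolute (default) or
#' signed coupling value — the quantity shown in coupling-strength matrices
#' and per-network radar summaries.
#'
#' @param coupling Tibble of per-subject coupling rows (from
#'   [macroscale_sfgc()] / [subnetwork_sfgc()]).
#' @param absolute Use `|psi|` (default TRUE).
#' @return Tibble with `feature` and `strength`.
#' @export
coupling_strength <- function(coupling, absolute = TRUE) {
  feats <- setdiff(names(coupling), c("subject", "scale"))
  f <- if (absolute) function(v) mean(abs(v)) else mean
  tibble(feature = feats,
         strength = unname(vapply(coupling[feats], f, numeric(1))))
}

#' Cohort differences in absolute coupling, per gradient pair
#'
#' Two-sample Welch's t-test on `|psi|` for every coupling feature, with
#' Benjamini-Hochberg adjustment across features.
#'
#' @param coupling_a,coupling_b Coupling tibbles for the two cohorts
#'   (>= 2 subjects each).
#' @return Tibble with `feature`, `t`, `p`, `p_adj`.
#' @export
cohort_coupling_difference <- function(coupling_a, coupling_b) {
  assert_that(nrow(coupling_a) >= 2 && nrow(coupling_b) >= 2,
              "need at least two subjects per cohort")
  feats <- setdiff(names(coupling_a), c("subject", "scale"))
  res <- purrr::map(feats, function(f) {
    wt <- welch_t(abs(coupling_a[[f]]), abs(coupling_b[[f]]))
    tibble(feature = f, t = wt$t, p = wt$p)
  }) |> bind_rows()
  res$p_adj <- fdr_bh(res$p)
  res
}

#' Heatmap of a macroscale coupling-strength matrix
#'
#' @param strength Tibble from [coupling_strength()] on macroscale features.
#' @return A ggplot object (functional gradients on rows, structural on
#'   columns).
#' @export
plot_coupling_matrix <- function(strength) {
  parts <- do.call(rbind, regmatches(strength$feature,
                                     regexec("F(\\d+)_S(\\d+)$",
                                             strength$feature)))
  df <- tibble(f = as.integer(parts[, 2]), s = as.integer(parts[, 3]),
               strength = strength$strength)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$f,
                                   fill = .data$strength)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "structural gradient", y = "functional gradient",
                  fill = "|coupling|") +
    ggplot2::theme_minimal()
}
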