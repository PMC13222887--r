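# Site/scanner harmonization: empirical-Bayes location/scale batch model
# (parametric priors: normal for location, inverse-gamma for scale) with
# biological covariates preserved, plus the study-bridging additive offset
# that places two cohorts in a comparable feature space.

build_covariate_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(0, n, 0))
  df <- as.data.frame(covariates)
  mm <- stats::model.matrix(~., data = df)[, -1, drop = FALSE]
  mm
}

#' Fit and apply batch harmonization (ComBat-style)
#'
#' Standardizes each feature using a pooled model with batch and covariate
#' terms, estimates per-batch location and scale, shrinks them with
#' parametric empirical-Bayes priors (normal location, inverse-gamma scale),
#' removes the batch effects and restores the covariate effects and pooled
#' scale. With `eb = FALSE` the exact per-batch estimates are used instead
#' of shrunk ones (useful for very small synthetic batches).
#'
#' @param features Numeric matrix or data frame (subjects x features).
#' @param batch Factor-like batch labels, one per subject.
#' @param covariates Optional data frame of biological covariates (e.g. age,
#'   sex) whose effects are preserved.
#' @param eb Use empirical-Bayes shrinkage (default TRUE).
#' @return List with `features` (harmonized tibble) and `model` (a
#'   `harmonization_model` holding gamma-star/delta-star per batch in
#'   standardized units, pooled scale, grand location, and the covariate
#'   fit).
#' @export
combat_fit_transform <- function(features, batch, covariates = NULL,
                                 eb = TRUE) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  batch <- factor(batch)
  nb <- nlevels(batch)
  if (nb < 2) {
    warn("single batch: harmonization is the identity transform")
    model <- structure(list(identity = TRUE, batches = levels(batch)),
                       class = "harmonization_model")
    return(list(features = as_tibble(as.data.frame(X)), model = model))
  }
  tab <- table(batch)
  assert_that(all(tab >= 2), "every batch needs >= 2 subjects")
  B <- stats::model.matrix(~ 0 + batch)
  Cm <- build_covariate_design(covariates, n)
  Dm <- cbind(B, Cm)
  if (qr(Dm)$rank < ncol(Dm))
    stop_sfgc("rank-deficient batch + covariate design")
  beta <- solve(crossprod(Dm), crossprod(Dm, X))
  gamma_hat0 <- beta[seq_len(nb), , drop = FALSE]     # per-batch locations
  beta_cov <- beta[-seq_len(nb), , drop = FALSE]
  w <- as.numeric(tab) / n
  alpha <- drop(crossprod(gamma_hat0, w))             # grand location
  fitted_full <- Dm %*% beta
  sigma2 <- colSums((X - fitted_full)^2) / n
  sigma <- sqrt(pmax(sigma2, 1e-12))
  cov_part <- if (ncol(Cm)) Cm %*% beta_cov else matrix(0, n, p)
  Z <- sweep(sweep(X - cov_part, 2, alpha, "-"), 2, sigma, "/")

  gamma_hat <- matrix(NA_real_, nb, p)
  delta2_hat <- matrix(NA_real_, nb, p)
  for (b in seq_len(nb)) {
    zb <- Z[batch == levels(batch)[b], , drop = FALSE]
    gamma_hat[b, ] <- colMeans(zb)
    delta2_hat[b, ] <- apply(zb, 2, var)
  }
  delta2_hat[delta2_hat < 1e-12] <- 1e-12

  if (eb && p >= 3) {
    gamma_star <- gamma_hat; delta2_star <- delta2_hat
    for (b in seq_len(nb)) {
      g <- gamma_hat[b, ]; d2 <- delta2_hat[b, ]
      gbar <- mean(g); tau2 <- var(g)
      m <- mean(d2); s2 <- var(d2)
      # inverse-gamma hyperparameters by method of moments
      a_pr <- (2 * s2 + m^2) / s2
      b_pr <- (m * s2 + m^3) / s2
      nb_i <- tab[b]
      zb <- Z[batch == levels(batch)[b], , drop = FALSE]
      g_st <- g; d2_st <- d2
      for (it in seq_len(100)) {
        g_new <- (nb_i * tau2 * g + d2_st * gbar) / (nb_i * tau2 + d2_st)
        ss <- colSums(sweep(zb, 2, g_new, "-")^2)
        d2_new <- (b_pr + 0.5 * ss) / (nb_i / 2 + a_pr - 1)
        if (max(abs(g_new - g_st), abs(d2_new - d2_st)) < 1e-8) {
          g_st <- g_new; d2_st <- d2_new; break
        }
        g_st <- g_new; d2_st <- d2_new
      }
      gamma_star[b, ] <- g_st
      delta2_star[b, ] <- d2_st
    }
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
  }

  bidx <- as.integer(batch)
  Z_adj <- (Z - gamma_star[bidx, , drop = FALSE]) /
    sqrt(delta2_star[bidx, , drop = FALSE])
  X_adj <- sweep(Z_adj, 2, sigma, "*") + cov_part
  X_adj <- sweep(X_adj, 2, alpha, "+")
  colnames(X_adj) <- colnames(X)
  model <- structure(list(
    identity = FALSE, batches = levels(batch), batch_sizes = as.numeric(tab),
    gamma_star = gamma_star, delta2_star = delta2_star,
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    alpha = alpha, sigma = sigma, beta_cov = beta_cov, eb = eb
  ), class = "harmonization_model")
  list(features = as_tibble(as.data.frame(X_adj)), model = model)
}

#' @export
print.harmonization_model <- function(x, ...) {
  if (isTRUE(x$identity)) cat("<harmonization_model> identity (single batch)\n")
  else cat(sprintf("<harmonization_model> %d batches, %d features (EB: %s)\n",
                   length(x$batches), length(x$sigma), x$eb))
  invisible(x)
}

#' Estimate the study-bridging offset between two cohorts
#'
#' Runs a batch harmonization fit treating study membership as the batch
#' over the combined child + bridge samples (with covariates preserved) and
#' returns the per-feature covariate-adjusted study location difference
#' (child minus bridge) in original feature units. This offset is later
#' added to the non-bridged cohort so both end up in a comparable space.
#'
#' @param features_child,features_bridge Feature matrices/data frames
#'   (already harmonized within cohort).
#' @param covariates_child,covariates_bridge Matching covariate data frames
#'   (row-bound in order).
#' @return Named numeric vector `delta_bridge`, one value per feature.
#' @export
estimate_bridge_delta <- function(features_child, features_bridge,
                                  covariates_child = NULL,
                                  covariates_bridge = NULL) {
  a <- as.matrix(features_child); b <- as.matrix(features_bridge)
  assert_that(nrow(a) > 0 && nrow(b) > 0, "both studies must be non-empty")
  X <- rbind(a, b)
  study <- factor(rep(c("child", "bridge"), c(nrow(a), nrow(b))),
                  levels = c("child", "bridge"))
  cov <- if (!is.null(covariates_child))
    dplyr::bind_rows(as.data.frame(covariates_child),
                     as.data.frame(covariates_bridge))
  else NULL
  fit <- combat_fit_transform(X, study, cov, eb = FALSE)
  m <- fit$model
  delta <- (m$gamma_star[1, ] - m$gamma_star[2, ]) * m$sigma
  setNames(delta, colnames(X))
}

#' Apply the study-bridging offset
#'
#' Adds the same per-feature shift to every subject; within-cohort
#' covariance is untouched.
#'
#' @param features Feature matrix/data frame of the cohort to shift.
#' @param delta_bridge Per-feature offset from [estimate_bridge_delta()].
#' @return Shifted tibble.
#' @export
apply_bridge <- function(features, delta_bridge) {
  X <- as.matrix(features)
  assert_that(ncol(X) == length(delta_bridge),
              "feature dimension does not match delta_bridge")
  as_tibble(as.data.frame(sweep(X, 2, delta_bridge, "+")))
}
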