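# ACE twin modeling: kinship construction from zygosity and family ids,
# maximum-likelihood variance components on the residuals of the
# fixed-effect (age, sex) model, the 50:50 chi-square mixture LRT for the
# boundary-constrained additive genetic variance, and power simulation.

#' Build genetic-relatedness and shared-environment matrices from a pedigree
#'
#' K holds 1 for MZ co-twins, 0.5 for DZ co-twins and full siblings, 0.25
#' for half siblings, 0 across families, 1 on the diagonal. Lambda is the
#' within-family indicator. The family block structure is precomputed so
#' that likelihood evaluations factorize over families.
#'
#' @param cohort Cohort tibble with `subject`, `family`, `zygosity`.
#' @return A `kinship` object: `K`, `Lambda`, `subjects`, `family`, and
#'   internal `blocks`.
#' @export
build_kinship <- function(cohort) {
  n <- nrow(cohort)
  fam <- cohort$family
  zyg <- cohort$zygosity
  # sanity: a declared twin must have exactly one co-member in the family
  for (f in unique(fam)) {
    idx <- which(fam == f)
    if (length(idx) > 1 && length(unique(zyg[idx])) > 1)
      stop_sfgc(sprintf("family %s mixes zygosity labels", f))
  }
  if (any(zyg %in% c("MZ", "DZ")))
    for (f in unique(fam[zyg %in% c("MZ", "DZ")]))
      if (sum(fam == f) != 2)
        stop_sfgc(sprintf("twin family %s does not have exactly 2 members", f))
  kin_value <- function(z) switch(z, MZ = 1, DZ = 0.5, full_sib = 0.5,
                                  half_sib = 0.25, singleton = 0, 0)
  K <- diag(n); Lam <- diag(n)
  for (f in unique(fam)) {
    idx <- which(fam == f)
    if (length(idx) < 2) next
    kv <- kin_value(zyg[idx[1]])
    for (i in idx) for (j in idx) if (i != j) {
      K[i, j] <- kv
      Lam[i, j] <- 1
    }
  }
  rownames(K) <- colnames(K) <- cohort$subject
  rownames(Lam) <- colnames(Lam) <- cohort$subject
  structure(list(K = K, Lambda = Lam, subjects = cohort$subject,
                 family = fam,
                 blocks = kinship_blocks(K, Lam, fam)),
            class = "kinship")
}

# split subjects into singletons / pairs / larger families for fast
# block-wise likelihood evaluation
kinship_blocks <- function(K, Lam, fam) {
  singles <- integer(0)
  pair_i <- integer(0); pair_j <- integer(0)
  pair_k <- numeric(0); pair_l <- numeric(0)
  general <- list()
  for (f in unique(fam)) {
    idx <- which(fam == f)
    if (length(idx) == 1) singles <- c(singles, idx)
    else if (length(idx) == 2) {
      pair_i <- c(pair_i, idx[1]); pair_j <- c(pair_j, idx[2])
      pair_k <- c(pair_k, K[idx[1], idx[2]])
      pair_l <- c(pair_l, Lam[idx[1], idx[2]])
    } else {
      general <- c(general, list(list(idx = idx,
                                      K = K[idx, idx, drop = FALSE],
                                      L = Lam[idx, idx, drop = FALSE])))
    }
  }
  list(singles = singles, pair_i = pair_i, pair_j = pair_j,
       pair_k = pair_k, pair_l = pair_l, general = general)
}

# kinship object from raw matrices: families recovered as connected
# components of the off-diagonal support
as_kinship <- function(K, Lam) {
  if (inherits(K, "kinship")) return(K)
  n <- nrow(K)
  fam <- integer(n); cur <- 0L
  adj <- (K + Lam) > 0; diag(adj) <- FALSE
  for (i in seq_len(n)) {
    if (fam[i] == 0L) {
      cur <- cur + 1L
      stack <- i
      while (length(stack)) {
        v <- stack[[1]]; stack <- stack[-1]
        if (fam[v] == 0L) {
          fam[v] <- cur
          stack <- c(stack, which(adj[v, ] & fam == 0L))
        }
      }
    }
  }
  structure(list(K = K, Lambda = Lam, subjects = seq_len(n),
                 family = as.character(fam),
                 blocks = kinship_blocks(K, Lam, as.character(fam))),
            class = "kinship")
}

# log-likelihood of residuals under covariance sa*K + sc*Lam + se*I,
# factorized over family blocks (closed form for singletons and pairs)
ace_loglik <- function(r, blocks, sa, sc, se) {
  s <- sa + sc + se
  if (s <= 0) return(-Inf)
  ll <- 0
  if (length(blocks$singles)) {
    rs <- r[blocks$singles]
    ll <- ll - 0.5 * sum(log(2 * pi * s) + rs^2 / s)
  }
  if (length(blocks$pair_i)) {
    a <- sa * blocks$pair_k + sc * blocks$pair_l
    det <- s^2 - a^2
    if (any(det <= 0)) return(-Inf)
    r1 <- r[blocks$pair_i]; r2 <- r[blocks$pair_j]
    q <- (s * (r1^2 + r2^2) - 2 * a * r1 * r2) / det
    ll <- ll - 0.5 * sum(2 * log(2 * pi) + log(det) + q)
  }
  for (blk in blocks$general) {
    Sig <- sa * blk$K + sc * blk$L + se * diag(length(blk$idx))
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    rb <- r[blk$idx]
    z <- backsolve(ch, rb, transpose = TRUE)
    ll <- ll - 0.5 * (length(rb) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(z^2))
  }
  ll
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 1e-10, log(expm1(pmin(y, 30))), -25)

ace_optimize <- function(r, blocks, fix_a = FALSE, restarts = 5L,
                         tol = 1e-8) {
  vtot <- max(var(r), 1e-10)
  negll <- if (fix_a) {
    function(th) -ace_loglik(r, blocks, 0, softplus(th[1]), softplus(th[2]))
  } else {
    function(th) -ace_loglik(r, blocks, softplus(th[1]), softplus(th[2]),
                             softplus(th[3]))
  }
  # simplex-grid warm start over variance fractions
  fr <- seq(0, 0.9, by = 0.1)
  best <- NULL
  for (fa in (if (fix_a) 0 else fr)) for (fc in fr) {
    if (fa + fc > 0.95) next
    sa <- fa * vtot; sc <- fc * vtot; se <- (1 - fa - fc) * vtot
    ll <- ace_loglik(r, blocks, sa, sc, se)
    if (is.null(best) || ll > best$ll)
      best <- list(ll = ll, sa = sa, sc = sc, se = se)
  }
  th0 <- if (fix_a) softplus_inv(c(best$sc, best$se))
         else softplus_inv(c(best$sa, best$sc, best$se))
  starts <- list(th0)
  # deterministic spread of alternative starts (keeps whole fits
  # reproducible without consuming the RNG stream)
  offsets <- rbind(c(2, -2, 0), c(-2, 2, 0), c(0, 2, -2), c(-2, -2, 2),
                   c(2, 0, 2), c(-1, 1, 1), c(1, -1, -1))
  if (restarts > 0)
    for (k in seq_len(restarts))
      starts <- c(starts,
                  list(th0 + offsets[1 + (k - 1) %% nrow(offsets),
                                     seq_along(th0)]))
  opt_best <- NULL
  for (st in starts) {
    o <- tryCatch(
      optim(st, negll, method = "Nelder-Mead",
            control = list(maxit = 800, reltol = tol)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(opt_best) || o$value < opt_best$value))
      opt_best <- o
  }
  if (is.null(opt_best))
    return(list(sigma2 = c(NA, NA, NA), loglik = NA_real_, converged = FALSE))
  th <- opt_best$par
  sig <- if (fix_a) c(0, softplus(th)) else softplus(th)
  sig[sig < 1e-10] <- 0
  list(sigma2 = sig, loglik = -opt_best$value,
       converged = opt_best$convergence == 0)
}

#' Fit the ACE variance-component model
#'
#' Two-stage estimation exactly as stated by the model: ordinary least
#' squares for the fixed effects (age, sex, ...), then maximum likelihood
#' for the non-negative variance components `(sigma_a2, sigma_c2,
#' sigma_e2)` of the residuals under covariance `sigma_a2 K + sigma_c2
#' Lambda + sigma_e2 I`. Optimization runs on softplus-transformed
#' variances from a simplex-grid warm start with random restarts;
#' heritability is `h2 = sigma_a2 / (sigma_a2 + sigma_c2 + sigma_e2)`. With
#' only MZ-like relatives (no variation in relatedness among members of a
#' shared household) A and C are confounded and the fit is flagged
#' non-identifiable.
#'
#' @param y Phenotype vector.
#' @param X Fixed-effect design (without intercept; one is added), or NULL
#'   for intercept only.
#' @param kinship A `kinship` object (or K matrix with `Lambda=`).
#' @param Lambda Shared-environment matrix when `kinship` is a plain matrix.
#' @param restarts Random optimizer restarts after the warm start.
#' @return An `ace_fit`: `beta`, `sigma2`, `loglik`, `h2`, `converged`,
#'   `identifiable`, `n`.
#' @export
fit_ace <- function(y, X = NULL, kinship, Lambda = NULL, restarts = 5L) {
  kin <- if (inherits(kinship, "kinship")) kinship
         else as_kinship(as.matrix(kinship), as.matrix(Lambda))
  n <- length(y)
  assert_that(n == nrow(kin$K), "phenotype and kinship dimensions differ")
  assert_that(n >= 3, "need at least 3 subjects")
  Xd <- cbind(`(Intercept)` = rep(1, n), if (!is.null(X)) as.matrix(X))
  assert_that(qr(Xd)$rank == ncol(Xd), "fixed-effect design is rank deficient")
  beta <- solve(crossprod(Xd), crossprod(Xd, y))
  r <- drop(y - Xd %*% beta)
  blocks <- kin$blocks
  # identifiability: A and C separate only if related pairs vary in kinship
  rel_k <- blocks$pair_k[blocks$pair_l > 0]
  for (blk in blocks$general)
    rel_k <- c(rel_k, blk$K[upper.tri(blk$K)])
  identifiable <- length(unique(round(rel_k, 6))) >= 2
  fit <- ace_optimize(r, blocks, fix_a = FALSE, restarts = restarts)
  sig <- fit$sigma2
  structure(list(beta = drop(beta), sigma2 = setNames(sig,
                   c("sigma_a2", "sigma_c2", "sigma_e2")),
                 loglik = fit$loglik,
                 h2 = sig[1] / sum(sig),
                 converged = fit$converged,
                 identifiable = identifiable,
                 n = n, residuals = r, blocks = blocks),
            class = "ace_fit")
}

#' Fit the reduced (CE) model with the additive genetic variance fixed at 0
#'
#' @inheritParams fit_ace
#' @return An `ace_fit` with `sigma_a2 = 0`.
#' @export
fit_ce <- function(y, X = NULL, kinship, Lambda = NULL, restarts = 5L) {
  full <- fit_ace(y, X, kinship, Lambda, restarts = 0L)  # reuse residuals
  fit <- ace_optimize(full$residuals, full$blocks, fix_a = TRUE,
                      restarts = restarts)
  out <- full
  out$sigma2 <- setNames(fit$sigma2, names(full$sigma2))
  out$loglik <- fit$loglik
  out$h2 <- 0
  out$converged <- fit$converged
  structure(out, class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf(
    "<ace_fit> n=%d  sigma2=(%.3f, %.3f, %.3f)  h2=%.3f  logLik=%.3f%s\n",
    x$n, x$sigma2[1], x$sigma2[2], x$sigma2[3], x$h2, x$loglik,
    if (!x$identifiable) "  [A/C not identifiable]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ace_fit <- function(x, ...) {
  tibble(term = c(names(x$sigma2), "h2"),
         estimate = c(unname(x$sigma2), unname(x$h2)))
}

#' @export
glance.ace_fit <- function(x, ...) {
  tibble(h2 = unname(x$h2), logLik = x$loglik, n = x$n,
         converged = x$converged, identifiable = x$identifiable)
}

#' Boundary-corrected likelihood-ratio test for heritability
#'
#' The statistic `2 (ll_full - ll_reduced)` is clipped at zero and referred
#' to the 50:50 mixture of a point mass at zero and a chi-square with one
#' degree of freedom, appropriate for a variance component tested on its
#' boundary: `p = 0.5 P(chi2_1 >= stat)` for positive statistics and 1 at
#' zero.
#'
#' @param full ACE fit.
#' @param reduced Matching CE fit (`sigma_a2` fixed at 0).
#' @param tol Tolerance for detecting optimizer failure (reduced beating
#'   full).
#' @return List with `stat` and `p`.
#' @export
lrt_h2 <- function(full, reduced, tol = 1e-4) {
  if (reduced$loglik > full$loglik + tol)
    stop_sfgc("reduced model exceeds full model log-likelihood: optimizer failure")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (stat == 0) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  list(stat = stat, p = p)
}

# draw n_reps phenotype vectors with covariance sa*K + sc*Lam + se*I,
# block-wise (closed form for pairs)
sample_ace_blocks <- function(blocks, n, sa, sc, se, n_reps) {
  s <- sa + sc + se
  Y <- matrix(0, n, n_reps)
  if (length(blocks$singles))
    Y[blocks$singles, ] <- matrix(
      rnorm(length(blocks$singles) * n_reps, sd = sqrt(s)), ncol = n_reps)
  if (length(blocks$pair_i)) {
    np <- length(blocks$pair_i)
    a <- sa * blocks$pair_k + sc * blocks$pair_l
    z1 <- matrix(rnorm(np * n_reps), np)
    z2 <- matrix(rnorm(np * n_reps), np)
    Y[blocks$pair_i, ] <- sqrt(s) * z1
    Y[blocks$pair_j, ] <- (a / sqrt(s)) * z1 +
      sqrt(pmax(s - a^2 / s, 0)) * z2
  }
  for (blk in blocks$general) {
    Sig <- sa * blk$K + sc * blk$L + se * diag(length(blk$idx))
    ch <- chol(Sig)
    Y[blk$idx, ] <- t(ch) %*% matrix(rnorm(length(blk$idx) * n_reps),
                                     length(blk$idx))
  }
  Y
}

#' Simulate phenotypes under the ACE generative model
#'
#' Draws `y ~ N(X beta, sigma_a2 K + sigma_c2 Lambda + sigma_e2 I)`.
#'
#' @param kinship A `kinship` object or K matrix.
#' @param Lambda Shared-environment matrix when `kinship` is a plain matrix.
#' @param X Fixed-effect design (without intercept) or NULL.
#' @param variance_components Length-3 `(sigma_a2, sigma_c2, sigma_e2)`.
#' @param beta Fixed effects (intercept first), or NULL for zeros.
#' @param seed Integer seed.
#' @param n_reps Number of replicate draws.
#' @return Numeric vector (n_reps = 1) or n x n_reps matrix.
#' @export
gen_twin_phenotype <- function(kinship, Lambda = NULL, X = NULL,
                               variance_components, beta = NULL, seed = 1L,
                               n_reps = 1L) {
  kin <- if (inherits(kinship, "kinship")) kinship
         else as_kinship(as.matrix(kinship), as.matrix(Lambda))
  vc <- as.numeric(variance_components)
  assert_that(all(vc >= 0), "variance components must be non-negative")
  n <- nrow(kin$K)
  # PSD guard on the total covariance (catches bad kinship construction)
  Sig_test <- vc[1] * kin$K + vc[2] * kin$Lambda + vc[3] * diag(n)
  ok <- tryCatch({ chol(Sig_test); TRUE }, error = function(e) FALSE)
  if (!ok) stop_sfgc("total covariance is not positive definite")
  Xd <- cbind(rep(1, n), if (!is.null(X)) as.matrix(X))
  mu <- if (is.null(beta)) rep(0, n) else drop(Xd[, seq_along(beta)] %*% beta)
  Y <- with_seed(seed,
    sample_ace_blocks(kin$blocks, n, vc[1], vc[2], vc[3], n_reps))
  Y <- Y + mu
  if (n_reps == 1) drop(Y) else Y
}

#' Power of the heritability LRT over a grid of true parameter values
#'
#' For each grid cell `(h2, rho)` with total variance one — so `sigma_a2 =
#' h2`, `sigma_c2 = (1 - h2) rho`, `sigma_e2 = (1 - h2)(1 - rho)` —
#' simulates phenotypes under the ACE model, fits the full and reduced
#' models, applies the boundary-mixture LRT and records the rejection
#' fraction at the given level.
#'
#' @param kinship A `kinship` object.
#' @param X Fixed-effect design or NULL.
#' @param h2_grid True heritabilities (default a 0.01-0.80 grid).
#' @param rho_grid Shared-environment proportions `sigma_c2 / (sigma_c2 +
#'   sigma_e2)` (default `{0, 0.3, 0.5, 0.8}`).
#' @param n_reps Simulations per cell (study setting 5000; desk scale
#'   smaller).
#' @param alpha Test level (default 0.05).
#' @param seed Integer seed.
#' @param restarts Optimizer restarts per fit (warm start always runs).
#' @return Tibble with `h2`, `rho`, `power`, `n_reps`, `n_fail`.
#' @export
power_simulation <- function(kinship, X = NULL,
                             h2_grid = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4,
                                         0.5, 0.6, 0.7, 0.8),
                             rho_grid = c(0, 0.3, 0.5, 0.8),
                             n_reps = 500L, alpha = 0.05, seed = 1L,
                             restarts = 2L) {
  assert_that(length(h2_grid) > 0 && length(rho_grid) > 0,
              "grids must be non-empty")
  kin <- if (inherits(kinship, "kinship")) kinship else as_kinship(kinship, X)
  n <- nrow(kin$K)
  Xd <- cbind(rep(1, n), if (!is.null(X)) as.matrix(X))
  Mproj <- diag(n) - Xd %*% solve(crossprod(Xd), t(Xd))
  out <- list()
  for (h2 in h2_grid) for (rho in rho_grid) {
    sa <- h2; sc <- (1 - h2) * rho; se <- (1 - h2) * (1 - rho)
    cell_seed <- derive_seed(seed, sprintf("power-%g-%g", h2, rho))
    Y <- with_seed(cell_seed,
                   sample_ace_blocks(kin$blocks, n, sa, sc, se, n_reps))
    R <- Mproj %*% Y
    rej <- 0L; fail <- 0L
    with_seed(derive_seed(cell_seed, "fits"), {
      for (rep in seq_len(n_reps)) {
        r <- R[, rep]
        f_full <- ace_optimize(r, kin$blocks, fix_a = FALSE,
                               restarts = restarts)
        f_red <- ace_optimize(r, kin$blocks, fix_a = TRUE,
                              restarts = restarts)
        if (!is.finite(f_full$loglik) || !is.finite(f_red$loglik)) {
          fail <- fail + 1L
          next
        }
        stat <- max(0, 2 * (f_full$loglik - f_red$loglik))
        p <- if (stat == 0) 1 else 0.5 * pchisq(stat, 1, lower.tail = FALSE)
        if (p < alpha) rej <- rej + 1L
      }
    })
    out[[length(out) + 1]] <- tibble(h2 = h2, rho = rho,
                                     power = rej / (n_reps - fail),
                                     n_reps = n_reps, n_fail = fail)
  }
  res <- bind_rows(out)
  class(res) <- c("power_curve", class(res))
  res
}

#' @export
autoplot.power_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$h2, y = .data$power,
                                       color = factor(.data$rho))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(true ~ h^2), y = "power",
                  color = expression(rho)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Subnetwork-aggregated gradient phenotypes
#'
#' Averages vertex-wise gradient scores within each parcel for every
#' subject, producing the per-subnetwork unimodal phenotypes used in
#' heritability comparisons.
#'
#' @param gradient_sets Named list of aligned `gradient_set` objects (one
#'   per subject).
#' @param parc A [parcellation()].
#' @param D Number of gradients to aggregate.
#' @return Tibble: `subject`, then `P{j}_G{d}` columns.
#' @export
aggregate_gradient_phenotypes <- function(gradient_sets, parc, D = 20L) {
  assert_that(all(vapply(parc$parcels,
                         function(j) sum(parc$labels == j) > 0, logical(1))),
              "empty parcel")
  rows <- purrr::imap(gradient_sets, function(gs, nm) {
    D_use <- min(D, ncol(gs$embedding))
    vals <- unlist(lapply(parc$parcels, function(j) {
      colMeans(gs$embedding[parc$labels == j, seq_len(D_use), drop = FALSE])
    }))
    nms <- as.vector(vapply(parc$parcels, function(j)
      sprintf("P%d_G%d", j, seq_len(D_use)), character(D_use)))
    sub <- if (!is.na(gs$subject)) gs$subject else nm
    dplyr::bind_cols(tibble(subject = sub),
                     as_tibble(as.list(setNames(vals, nms))))
  })
  bind_rows(rows)
}

#' Paired comparisons of heritability across modalities
#'
#' Two-sided paired t-tests of matched per-subnetwork heritability vectors
#' (e.g. coupling vs its functional or structural gradient), Bonferroni
#' corrected across the comparisons supplied.
#'
#' @param comparisons Named list; each element is a list with vectors `a`
#'   and `b` matched by subnetwork.
#' @return Tibble with `comparison`, `t`, `p`, `p_adj`.
#' @export
compare_heritability_paired <- function(comparisons) {
  rows <- purrr::imap(comparisons, function(cmp, nm) {
    assert_that(length(cmp$a) == length(cmp$b),
                "paired heritability vectors must match in length")
    if (all(cmp$a == cmp$b)) return(tibble(comparison = nm, t = 0, p = 1))
    res <- paired_t(cmp$a, cmp$b)
    tibble(comparison = nm, t = res$t, p = res$p)
  }) |> bind_rows()
  rows$p_adj <- p.adjust(rows$p, method = "bonferroni")
  rows
}
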