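# ACE modeling: kinship construction, likelihood correctness, parameter
# recovery, boundary LRT, power simulation, subnetwork aggregation, paired
# comparisons.

test_that("kinship matrices encode the documented relatedness values", {
  co <- tibble::tibble(
    subject = paste0("s", 1:6),
    family = c("f1", "f1", "f2", "f2", "f3", "f4"),
    zygosity = c("MZ", "MZ", "half_sib", "half_sib", "singleton",
                 "singleton"))
  kin <- build_kinship(co)
  K_hand <- diag(6)
  K_hand[1, 2] <- K_hand[2, 1] <- 1
  K_hand[3, 4] <- K_hand[4, 3] <- 0.25
  L_hand <- diag(6)
  L_hand[1, 2] <- L_hand[2, 1] <- 1
  L_hand[3, 4] <- L_hand[4, 3] <- 1
  expect_equal(unname(kin$K), K_hand)
  expect_equal(unname(kin$Lambda), L_hand)
  # two singletons: identity
  co2 <- tibble::tibble(subject = c("a", "b"), family = c("x", "y"),
                        zygosity = c("singleton", "singleton"))
  kin2 <- build_kinship(co2)
  expect_equal(unname(kin2$K), diag(2))
  expect_equal(unname(kin2$Lambda), diag(2))
  # DZ and full sibs get 0.5
  co3 <- twin_cohort(n_mz = 1, n_dz = 1, n_fs = 1, seed = 2)
  kin3 <- build_kinship(co3)
  dz <- which(co3$zygosity == "DZ")
  fs <- which(co3$zygosity == "full_sib")
  expect_equal(kin3$K[dz[1], dz[2]], 0.5)
  expect_equal(kin3$K[fs[1], fs[2]], 0.5)
  # contradictory labels error
  co_bad <- tibble::tibble(subject = c("a", "b"), family = c("x", "x"),
                           zygosity = c("MZ", "DZ"))
  expect_error(build_kinship(co_bad), "zygosity")
})

test_that("block likelihood equals the dense multivariate-normal density", {
  cohort <- twin_cohort(n_mz = 10, n_dz = 10, n_single = 5, seed = 3)
  kin <- build_kinship(cohort)
  n <- nrow(cohort)
  r <- withr::with_seed(4, rnorm(n))
  for (vc in list(c(0.4, 0.3, 0.3), c(0, 0.2, 0.8), c(0.9, 0, 0.1))) {
    Sig <- vc[1] * kin$K + vc[2] * kin$Lambda + vc[3] * diag(n)
    dense <- as.numeric(-0.5 * (n * log(2 * pi) +
                                  determinant(Sig)$modulus +
                                  crossprod(r, solve(Sig, r))))
    blockwise <- sfgc:::ace_loglik(r, kin$blocks, vc[1], vc[2], vc[3])
    expect_equal(blockwise, dense, tolerance = 1e-8)
  }
})

test_that("pure-noise phenotypes give near-zero heritability", {
  cohort <- twin_cohort(n_mz = 30, n_dz = 30, seed = 5)
  kin <- build_kinship(cohort)
  X <- cbind(age = cohort$age)
  y <- drop(2 + 0.3 * cohort$age) + withr::with_seed(6, rnorm(nrow(cohort),
                                                              sd = 0.1))
  fit <- fit_ace(y, X, kin, restarts = 2)
  expect_lt(fit$h2, 0.25)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta[2]), 0.3, tolerance = 0.05)
})

test_that("maximum likelihood matches a dense simplex-grid oracle on a small toy", {
  cohort <- twin_cohort(n_mz = 8, n_dz = 8, n_single = 8, seed = 7)
  kin <- build_kinship(cohort)
  y <- gen_twin_phenotype(kin, variance_components = c(0.5, 0.2, 0.3),
                          seed = 8)
  fit <- fit_ace(y, NULL, kin, restarts = 3)
  # dense 21^2 grid over simplex fractions at several total variances
  r <- fit$residuals
  best <- -Inf
  for (tot in seq(0.4, 2.5, by = 0.05)) {
    for (fa in seq(0, 1, by = 0.05)) for (fc in seq(0, 1 - fa, by = 0.05)) {
      ll <- sfgc:::ace_loglik(r, kin$blocks, fa * tot, fc * tot,
                              (1 - fa - fc) * tot)
      if (ll > best) best <- ll
    }
  }
  expect_gte(fit$loglik + 1e-2, best)
})

test_that("parameter recovery across the simulation grid is unbiased", {
  cohort <- twin_cohort(n_mz = 150, n_dz = 150, seed = 9)
  kin <- build_kinship(cohort)
  for (cell in list(c(0.5, 0.2, 0.3), c(0.2, 0.4, 0.4))) {
    Y <- gen_twin_phenotype(kin, variance_components = cell,
                            seed = 11 + round(100 * cell[1]), n_reps = 30)
    est <- vapply(seq_len(ncol(Y)), function(i)
      fit_ace(Y[, i], NULL, kin, restarts = 1)$sigma2, numeric(3))
    expect_lt(max(abs(rowMeans(est) - cell)), 0.05)
  }
})

test_that("MZ-only pedigrees are flagged as non-identifiable", {
  cohort <- twin_cohort(n_mz = 20, n_dz = 0, seed = 13)
  kin <- build_kinship(cohort)
  y <- gen_twin_phenotype(kin, variance_components = c(0.5, 0.2, 0.3),
                          seed = 14)
  fit <- fit_ace(y, NULL, kin, restarts = 1)
  expect_false(fit$identifiable)
  cohort2 <- twin_cohort(n_mz = 10, n_dz = 10, seed = 13)
  expect_true(fit_ace(y[1:40], NULL, build_kinship(cohort2),
                      restarts = 0)$identifiable)
})

test_that("boundary LRT follows the 50:50 chi-square mixture", {
  mk_fit <- function(ll) structure(list(loglik = ll), class = "ace_fit")
  expect_equal(lrt_h2(mk_fit(-100), mk_fit(-100))$p, 1)
  res <- lrt_h2(mk_fit(-100 + 2.706 / 2), mk_fit(-100))
  expect_equal(res$stat, 2.706)
  expect_equal(res$p, 0.05, tolerance = 1e-3)
  expect_error(lrt_h2(mk_fit(-101), mk_fit(-100)), "optimizer")
})

test_that("gradient phenotypes aggregate to parcel means", {
  emb <- cbind(rep(1:4, each = 5), rep(c(2, -2), each = 10))
  gs <- sfgc:::new_gradient_set(emb, c(0.9, 0.8), c(0.5, 0.4),
                                subject = "s1")
  verts <- tibble::tibble(vertex = 1:20, parcel = rep(1:2, each = 10),
                          hemisphere = rep(c("L", "R"), each = 10))
  parc <- parcellation(verts)
  agg <- aggregate_gradient_phenotypes(list(s1 = gs), parc, D = 2)
  expect_equal(agg$P1_G1, mean(rep(1:2, each = 5)))
  expect_equal(agg$P2_G1, mean(rep(3:4, each = 5)))
  expect_equal(agg$P1_G2, 2)
  expect_equal(agg$P2_G2, -2)
  # constant gradient: every parcel mean equals the constant
  gsc <- sfgc:::new_gradient_set(cbind(rep(7, 20)), 0.9, 0.5,
                                 subject = "s2")
  aggc <- aggregate_gradient_phenotypes(list(s2 = gsc), parc, D = 1)
  expect_equal(unname(unlist(aggc[, -1])), c(7, 7))
})

test_that("paired heritability comparisons use Bonferroni and catch offsets", {
  withr::with_seed(15, {
    base <- runif(14, 0.1, 0.4)
    noisy <- base + 0.1 + rnorm(14, sd = 0.01)
  })
  res <- compare_heritability_paired(list(
    identical = list(a = base, b = base),
    shifted = list(a = noisy, b = base)))
  expect_equal(res$t[res$comparison == "identical"], 0)
  expect_equal(res$p_adj[res$comparison == "identical"], 1)
  expect_lt(res$p_adj[res$comparison == "shifted"], 0.001)
  # bonferroni is multiplication capped at 1
  res2 <- compare_heritability_paired(list(
    a = list(a = c(1, 2, 3), b = c(2, 3, 4.2)),
    b = list(a = c(1, 2, 3), b = c(1.1, 2.2, 3.1))))
  expect_equal(res2$p_adj, pmin(1, res2$p * 2))
})

test_that("power simulation is calibrated at the null and monotone in h2", {
  cohort <- twin_cohort(n_mz = 100, n_dz = 100, seed = 17)
  kin <- build_kinship(cohort)
  pw <- power_simulation(kin, NULL, h2_grid = c(0, 0.3, 0.6),
                         rho_grid = c(0, 0.5), n_reps = 150, seed = 18,
                         restarts = 0)
  expect_true(all(pw$power >= 0 & pw$power <= 1))
  for (rho in c(0, 0.5)) {
    cell <- pw[pw$rho == rho, ]
    expect_lt(abs(cell$power[cell$h2 == 0] - 0.05), 0.06)
    # monotone non-decreasing within 2 Monte-Carlo SEs
    mc_se <- sqrt(0.25 / 150)
    expect_true(all(diff(cell$power[order(cell$h2)]) >= -2 * mc_se))
  }
})

test_that("tidy and glance summarize an ACE fit", {
  cohort <- twin_cohort(n_mz = 10, n_dz = 10, seed = 19)
  kin <- build_kinship(cohort)
  y <- gen_twin_phenotype(kin, variance_components = c(0.4, 0.1, 0.5),
                          seed = 20)
  fit <- fit_ace(y, NULL, kin, restarts = 0)
  td <- generics::tidy(fit)
  expect_equal(td$term, c("sigma_a2", "sigma_c2", "sigma_e2", "h2"))
  gl <- generics::glance(fit)
  expect_true(all(c("h2", "logLik", "converged") %in% names(gl)))
  expect_equal(gl$h2, unname(fit$sigma2[1] / sum(fit$sigma2)))
})
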