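# Prediction: family-grouped folds, standardization, KRR closed form vs a
# numerical oracle, metrics, importance, and the network head-to-head.

test_that("family-grouped folds never split a family and balance sizes", {
  co <- tibble::tibble(subject = sprintf("s%03d", 1:100),
                       family = c(rep("famA", 4),
                                  sprintf("f%03d", 5:100)))
  sch <- make_family_folds(co, k = 10, n_replicates = 20, seed = 3)
  for (r in unique(sch$replicate)) {
    fr <- sch[sch$replicate == r, ]
    fam_folds <- fr$fold[match(co$subject[co$family == "famA"], fr$subject)]
    expect_equal(length(unique(fam_folds)), 1)
    expect_equal(sort(unique(fr$fold)), 1:10)
    expect_true(all(table(fr$fold) >= 8))
  }
  # all singletons with k = n gives leave-one-out structure
  co1 <- tibble::tibble(subject = paste0("s", 1:8), family = paste0("f", 1:8))
  loo <- make_family_folds(co1, k = 8, n_replicates = 1, seed = 1)
  expect_equal(sort(table(loo$fold)), sort(table(1:8)), ignore_attr = TRUE)
  expect_error(make_family_folds(co1, k = 20, n_replicates = 1), "folds")
})

test_that("standardization uses training statistics only and drops constants", {
  withr::with_seed(2, {
    tr <- cbind(rnorm(50, 5, 2), rnorm(50), rep(3, 50))
    te <- cbind(rnorm(20, 9, 2), rnorm(20), rep(3, 20))
  })
  expect_warning(st <- standardize(tr, te), "constant")
  expect_equal(ncol(st$train), 2)
  expect_lt(max(abs(colMeans(st$train))), 1e-12)
  expect_equal(apply(st$train, 2, sd), rep(1, 2))
  # shifted test set is NOT zero-mean under training stats
  expect_gt(abs(mean(st$test[, 1])), 1)
})

test_that("KRR solves the printed dual objective exactly", {
  withr::with_seed(8, {
    X <- matrix(rnorm(25 * 6), 25)
    y <- rnorm(25)
  })
  lam <- 0.5
  m <- fit_krr(X, y, lambda_grid = lam)
  psi <- tcrossprod(X)
  n <- nrow(X)
  obj <- function(w) sum((y - psi %*% w)^2) / n + lam * sum(w^2)
  # numerical-minimization oracle of the printed loss
  o <- optim(rep(0, n), obj, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(max(abs(m$w - o$par)), 1e-4)
  expect_lt(abs(obj(m$w) - o$value), 1e-6)
  expect_lte(obj(m$w), o$value + 1e-10)
  # monotone shrinkage: the top grid value kills the weights
  m_hi <- fit_krr(X, y, lambda_grid = 1e5)
  m_mid <- fit_krr(X, y, lambda_grid = 10)
  expect_lt(sum(m_hi$w^2), sum(m_mid$w^2))
  expect_lt(max(abs(predict(m_hi, X))), 0.05)
})

test_that("the selected regularization comes from the documented grid", {
  withr::with_seed(1, {
    X <- matrix(rnorm(80 * 10), 80)
    y <- X[, 1] + rnorm(80, sd = 0.5)
  })
  m <- fit_krr(X, y, seed = 4)
  expect_true(m$lambda %in% c(0.01, 0.1, 0.5, 1, 5, 10, 50, 1e2, 1e3, 1e4,
                              1e5))
})

test_that("rkhs penalty switch reproduces standard kernel ridge", {
  withr::with_seed(10, {
    X <- matrix(rnorm(30 * 5), 30)
    y <- rnorm(30)
  })
  lam <- 2
  m <- fit_krr(X, y, lambda_grid = lam, penalty = "rkhs")
  w_ref <- solve(tcrossprod(X) + nrow(X) * lam * diag(30), y)
  expect_equal(m$w, w_ref, tolerance = 1e-8)
})

test_that("metrics: Pearson r and tie-aware AUC match brute force", {
  expect_equal(evaluate(c(1, 2, 3, 4), c(1, 2, 3, 4), "continuous"), 1)
  expect_equal(evaluate(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), "binary"), 1)
  # brute-force pair enumeration on a 6-subject toy with ties
  pred <- c(0.3, 0.5, 0.5, 0.2, 0.9, 0.1)
  obs <- c(1, 1, 0, 0, 1, 0)
  pairs <- expand.grid(i = which(obs == 1), j = which(obs == 0))
  brute <- mean(ifelse(pred[pairs$i] > pred[pairs$j], 1,
                       ifelse(pred[pairs$i] == pred[pairs$j], 0.5, 0)))
  expect_equal(evaluate(pred, obs, "binary"), brute)
  expect_warning(r <- evaluate(c(1, 2), c(1, 2), "continuous"), "fewer")
  expect_true(is.na(r))
  expect_warning(a <- evaluate(c(1, 2), c(1, 1), "binary"), "one-class")
  expect_true(is.na(a))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(3, {
    obs <- rbinom(60, 1, 0.5)
    pred <- obs * 0.8 + rnorm(60)
  })
  ours <- evaluate(pred, obs, "binary")
  ref <- as.numeric(suppressMessages(pROC::auc(obs, pred)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("KRR importance is X'w with duplicate-feature symmetry", {
  withr::with_seed(5, {
    X <- matrix(rnorm(40 * 3), 40)
  })
  X <- cbind(X, X[, 2])  # duplicated feature
  y <- X[, 1] + rnorm(40, sd = 0.3)
  m <- fit_krr(X, y, lambda_grid = 1)
  fi <- krr_importance(m)
  expect_equal(fi, drop(crossprod(X, m$w)))
  expect_equal(fi[2], fi[4], tolerance = 1e-10)
})

test_that("min-max importance normalization matches the closed form", {
  expect_equal(normalize_importance(c(-2, 0, 1)), c(1, 0, 0.5))
  withr::with_seed(1, v <- rnorm(30))
  nv <- normalize_importance(v)
  expect_equal(range(nv), c(0, 1))
  expect_equal(normalize_importance(5 * v), nv)   # scale invariant
  expect_warning(z <- normalize_importance(rep(2, 4)), "constant")
  expect_equal(z, rep(0, 4))
})

test_that("importance aggregation takes block maxima per parcel", {
  fi <- setNames(c(0.1, 0.9, 0.4, 0.2, 0.6, 0.3),
                 c("P1_F1_S1", "P1_F1_S2", "P1_F2_S1",
                   "P2_F1_S1", "P2_F1_S2", "P2_F2_S1"))
  agg <- aggregate_importance(fi)
  expect_equal(agg$max_importance, c(0.9, 0.6))
  # averaging across two methods then block-max
  fi2 <- fi; fi2["P2_F1_S2"] <- 1.0
  agg2 <- aggregate_importance(list(fi, fi2))
  expect_equal(agg2$max_importance[2], 0.8)
})

test_that("the network trains deterministically and saliency matches finite differences", {
  withr::with_seed(21, {
    X <- matrix(rnorm(60 * 5), 60)
    y <- X[, 1] - 0.5 * X[, 3] + rnorm(60, sd = 0.2)
  })
  spec <- mlp_spec(hidden = 16, max_epochs = 5, inner_folds = 0)
  m1 <- fit_mlp(X, y, spec, seed = 7)
  m2 <- fit_mlp(X, y, spec, seed = 7)
  expect_identical(m1$par, m2$par)
  # exact gradient vs central finite differences on 5 random inputs
  sal <- mlp_saliency(m1, X[1:5, , drop = FALSE])
  eps <- 1e-5
  fd <- vapply(1:5, function(d) {
    Xp <- X[1:5, , drop = FALSE]; Xm <- Xp
    Xp[, d] <- Xp[, d] + eps; Xm[, d] <- Xm[, d] - eps
    mean((predict(m1, Xp) - predict(m1, Xm)) / (2 * eps))
  }, numeric(1))
  expect_equal(sal, fd, tolerance = 1e-4)
  # binary head: sigmoid probabilities in (0,1), saliency still exact
  yb <- as.integer(y > median(y))
  mb <- fit_mlp(X, yb, spec, binary = TRUE, seed = 7)
  expect_true(all(predict(mb, X) > 0 & predict(mb, X) < 1))
  salb <- mlp_saliency(mb, X[1:5, , drop = FALSE])
  fdb <- vapply(1:5, function(d) {
    Xp <- X[1:5, , drop = FALSE]; Xm <- Xp
    Xp[, d] <- Xp[, d] + eps; Xm[, d] <- Xm[, d] - eps
    mean((predict(mb, Xp) - predict(mb, Xm)) / (2 * eps))
  }, numeric(1))
  expect_equal(salb, fdb, tolerance = 1e-4)
})

test_that("a separable binary toy reaches training AUC 1", {
  withr::with_seed(2, {
    X <- matrix(rnorm(80 * 2), 80)
    yb <- as.integer(X[, 1] > 0)
  })
  m <- fit_mlp(X, yb, mlp_spec(hidden = 16, max_epochs = 50, lr = 0.01,
                               inner_folds = 0), binary = TRUE, seed = 1)
  expect_gt(evaluate(predict(m, X), yb, "binary"), 0.99)
})

test_that("a disconnected input feature has zero saliency", {
  withr::with_seed(4, {
    X <- matrix(rnorm(30 * 4), 30)
    y <- rnorm(30)
  })
  m <- fit_mlp(X, y, mlp_spec(hidden = 8, max_epochs = 2, inner_folds = 0),
               seed = 2)
  m$par$W1[4, ] <- 0
  expect_equal(mlp_saliency(m, X)[4], 0)
})

test_that("cross-validated prediction recovers planted sparse signal features", {
  withr::with_seed(31, {
    n <- 150; p <- 30
    X <- matrix(rnorm(n * p), n,
                dimnames = list(NULL, sprintf("P%d_F1_S%d",
                                              rep(1:5, each = 6), 1:6)))
    beta <- numeric(p); sup <- c(3, 8, 15, 22, 27); beta[sup] <- 1
    y <- drop(X %*% beta) + rnorm(n, sd = 0.8)
  })
  co <- tibble::tibble(subject = sprintf("s%03d", 1:n),
                       family = sprintf("f%03d", 1:n))
  res <- run_prediction(X, y, co, "continuous", "krr", n_replicates = 20,
                        k = 5, seed = 9)
  expect_gt(res$mean_metric, 0.5)
  top5 <- apply(res$importance, 1, function(v) order(-v)[1:5])
  hit <- mean(apply(top5, 2, function(ix) length(intersect(ix, sup)) == 5))
  expect_gte(hit, 0.9)
})

test_that("the network matches kernel ridge on a linear-signal toy", {
  withr::with_seed(41, {
    n <- 300; p <- 10
    X <- matrix(rnorm(n * p), n)
    y <- drop(X %*% c(1, -1, rep(0, 8))) + rnorm(n, sd = 1)
    tr <- 1:200; te <- 201:300
  })
  st <- standardize(X[tr, ], X[te, ])
  mk <- fit_krr(st$train, y[tr], seed = 1)
  r_krr <- cor(predict(mk, st$test), y[te])
  mm <- fit_mlp(st$train, y[tr],
                mlp_spec(hidden = 32, max_epochs = 30, inner_folds = 2),
                seed = 1)
  r_mlp <- cor(predict(mm, st$test), y[te])
  expect_lt(abs(r_krr - r_mlp), 0.1)
})
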