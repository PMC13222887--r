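# Family-aware out-of-sample prediction: grouped cross-validation folds,
# feature standardization with training statistics, kernel ridge regression
# with the dual objective penalizing ||w||^2, metrics (Pearson r / AUC),
# and normalized feature importance.

KRR_LAMBDA_GRID <- c(0.01, 0.1, 0.5, 1, 5, 10, 50, 1e2, 1e3, 1e4, 1e5)

#' Family-grouped cross-validation fold assignments
#'
#' Builds `n_replicates` independent k-fold partitions in which all members
#' of one family always share a fold (preventing leakage of familial
#' correlation into test folds). Families are shuffled per replicate and
#' assigned greedily to the currently smallest fold, so fold sizes are
#' balanced within one family-size granularity.
#'
#' @param cohort Cohort tibble with `subject` and `family`.
#' @param k Folds per replicate (default 10).
#' @param n_replicates Number of replicate partitions (default 100).
#' @param seed Integer seed.
#' @return A `split_scheme`: tibble with `replicate`, `subject`, `fold`.
#' @export
make_family_folds <- function(cohort, k = 10L, n_replicates = 100L,
                              seed = 1L) {
  assert_that(!anyNA(cohort$family), "family id required for every subject")
  fams <- unique(cohort$family)
  if (k > length(fams))
    stop_sfgc("more folds than families: grouped k-fold impossible")
  fam_sizes <- table(cohort$family)
  out <- with_seed(seed, {
    purrr::map(seq_len(n_replicates), function(rep) {
      ord <- sample(fams)
      ord <- ord[order(-fam_sizes[ord], sample.int(length(ord)))]
      load <- numeric(k)
      fold_of <- setNames(integer(length(ord)), ord)
      for (f in ord) {
        tgt <- which.min(load)
        fold_of[f] <- tgt
        load[tgt] <- load[tgt] + fam_sizes[[f]]
      }
      tibble(replicate = rep, subject = cohort$subject,
             fold = unname(fold_of[cohort$family]))
    }) |> bind_rows()
  })
  structure(out, class = c("split_scheme", class(out)), k = k)
}

#' Standardize features with training statistics
#'
#' Column z-scoring computed on the training rows only; the same means/SDs
#' transform the test rows. Zero-SD features are dropped with a warning.
#'
#' @param train,test Feature matrices.
#' @return List with `train`, `test`, `center`, `scale`, `kept`.
#' @export
standardize <- function(train, test = NULL) {
  train <- as.matrix(train)
  ctr <- colMeans(train)
  scl <- apply(train, 2, sd)
  kept <- scl > 0
  if (!all(kept))
    warn(sprintf("dropping %d constant feature(s)", sum(!kept)))
  tr <- sweep(sweep(train[, kept, drop = FALSE], 2, ctr[kept], "-"),
              2, scl[kept], "/")
  te <- if (!is.null(test)) {
    test <- as.matrix(test)
    sweep(sweep(test[, kept, drop = FALSE], 2, ctr[kept], "-"),
          2, scl[kept], "/")
  }
  list(train = tr, test = te, center = ctr[kept], scale = scl[kept],
       kept = kept)
}

# solve the dual objective (1/n)||y - psi w||^2 + lambda ||w||^2
# via the normal equations (psi^2 + n lambda I) w = psi y, using one
# eigendecomposition of psi for the whole lambda grid.
# penalty = "rkhs" solves standard KRR instead: (psi + n lambda I) w = y.
krr_solve <- function(eig, y, lambda, n, penalty = "primal") {
  Q <- eig$vectors; ev <- eig$values
  qy <- crossprod(Q, y)
  if (penalty == "primal") {
    denom <- ev^2 + n * lambda
    if (any(denom < 1e-12)) {
      warn("near-singular kernel system; pseudo-inverse solution")
      denom[denom < 1e-12] <- Inf
    }
    drop(Q %*% (ev * qy / denom))
  } else {
    drop(Q %*% (qy / (ev + n * lambda)))
  }
}

#' Fit kernel ridge regression with inner cross-validated regularization
#'
#' Linear kernel `psi(x_i, x_j) = x_i' x_j`. The default objective is
#' `(1/n) ||y - psi w||^2 + lambda ||w||^2`, solved exactly through its
#' normal equations; `penalty = "rkhs"` switches to the standard
#' reproducing-kernel penalty `lambda w' psi w`. The regularization is
#' selected from the 11-value grid by grouped inner cross-validation
#' minimizing squared error.
#'
#' @param X_train Standardized training features (n x d).
#' @param y_train Outcome vector.
#' @param lambda_grid Candidate regularization values.
#' @param inner_folds Inner CV folds (default 5).
#' @param family Optional family ids for grouped inner folds.
#' @param penalty `"primal"` (printed objective; default) or `"rkhs"`.
#' @param seed Seed for the inner fold shuffle.
#' @return A `krr_model`: dual weights `w`, chosen `lambda`, training
#'   features, penalty.
#' @export
fit_krr <- function(X_train, y_train, lambda_grid = KRR_LAMBDA_GRID,
                    inner_folds = 5L, family = NULL,
                    penalty = c("primal", "rkhs"), seed = 1L) {
  penalty <- match.arg(penalty)
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  assert_that(n >= 2, "need at least 2 training subjects")
  if (is.null(family)) family <- as.character(seq_len(n))
  lambda <- if (length(lambda_grid) == 1) lambda_grid else {
    folds <- make_family_folds(tibble(subject = as.character(seq_len(n)),
                                      family = family),
                               k = min(inner_folds, length(unique(family))),
                               n_replicates = 1L, seed = seed)
    fold_id <- folds$fold[match(as.character(seq_len(n)), folds$subject)]
    errs <- numeric(length(lambda_grid))
    for (f in unique(fold_id)) {
      tr <- fold_id != f
      Xtr <- X_train[tr, , drop = FALSE]
      eig <- eigen(tcrossprod(Xtr), symmetric = TRUE)
      kx <- tcrossprod(X_train[!tr, , drop = FALSE], Xtr)
      for (li in seq_along(lambda_grid)) {
        w <- krr_solve(eig, y_train[tr], lambda_grid[li], sum(tr), penalty)
        errs[li] <- errs[li] + sum((y_train[!tr] - drop(kx %*% w))^2)
      }
    }
    lambda_grid[which.min(errs)]
  }
  psi <- tcrossprod(X_train)
  eig <- eigen(psi, symmetric = TRUE)
  w <- krr_solve(eig, y_train, lambda, n, penalty)
  structure(list(w = w, lambda = lambda, X_train = X_train,
                 penalty = penalty),
            class = "krr_model")
}

#' @export
predict.krr_model <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% crossprod(object$X_train, object$w))
}

#' Raw KRR feature importance: primal coefficients
#'
#' `FI0 = X' w`, the feature-space weights recovered from the dual
#' solution.
#'
#' @param model A `krr_model`.
#' @param X_train Features the model was fitted on (defaults to the stored
#'   ones).
#' @return Numeric vector of length d.
#' @export
krr_importance <- function(model, X_train = model$X_train) {
  drop(crossprod(as.matrix(X_train), model$w))
}

#' Out-of-sample performance metric
#'
#' Pearson correlation for continuous outcomes; for binary outcomes the
#' area under the ROC curve computed as the Mann-Whitney probability of
#' correct ranking with ties counted half.
#'
#' @param predictions Predicted values / probabilities.
#' @param observed Observed outcomes (binary outcomes coded 0/1).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @return Metric value, or NA with a warning for a degenerate fold.
#' @export
evaluate <- function(predictions, observed,
                     outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  if (outcome_type == "continuous") {
    if (length(observed) < 3) {
      warn("fewer than 3 test subjects: correlation skipped")
      return(NA_real_)
    }
    return(cor(predictions, observed))
  }
  pos <- observed == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warn("one-class test fold: AUC undefined, fold skipped")
    return(NA_real_)
  }
  rk <- rank(predictions)   # ties averaged => ties counted half
  (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Min-max normalized feature importance
#'
#' `FI = (|FI0| - min|FI0|) / (max|FI0| - min|FI0|)`, mapping the weakest
#' feature to 0 and the strongest to 1.
#'
#' @param fi0 Raw importance vector.
#' @return Normalized vector in `[0, 1]` (all zeros with a warning when
#'   `|FI0|` is constant).
#' @export
normalize_importance <- function(fi0) {
  a <- abs(fi0)
  rng <- range(a)
  if (rng[2] - rng[1] <= 0) {
    warn("constant |FI0|: normalized importance set to zero")
    return(rep(0, length(a)))
  }
  (a - rng[1]) / (rng[2] - rng[1])
}

#' Aggregate feature importance to subnetwork maxima
#'
#' Averages normalized importance vectors across splits (and methods, when
#' several are given), then reports the maximum within each parcel's
#' feature block.
#'
#' @param fi_list List of normalized importance vectors (named by
#'   subnetwork coupling features `P{j}_...`), e.g. one per split or
#'   method.
#' @return Tibble with `parcel` and `max_importance`.
#' @export
aggregate_importance <- function(fi_list) {
  if (is.numeric(fi_list)) fi_list <- list(fi_list)
  avg <- Reduce(`+`, fi_list) / length(fi_list)
  feats <- names(avg)
  assert_that(!is.null(feats) && all(grepl("^P\\d+_", feats)),
              "importance vectors must be named by subnetwork features")
  parcel <- as.integer(sub("^P(\\d+)_.*$", "\\1", feats))
  tibble(parcel = parcel, importance = unname(avg)) |>
    group_by(.data$parcel) |>
    summarise(max_importance = max(.data$importance), .groups = "drop")
}

#' Cross-validated association between features and an outcome
#'
#' The full evaluation loop: for each replicate of the family-grouped split
#' scheme, standardizes features with training statistics, fits the model
#' per fold, pools out-of-fold predictions, computes the replicate metric,
#' and records the replicate's normalized feature importance (averaged over
#' fold models).
#'
#' @param features Subject x feature matrix or tibble (rows in cohort
#'   order).
#' @param outcome Outcome vector (binary outcomes coded 0/1).
#' @param cohort Cohort tibble (`subject`, `family`).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param model `"krr"` (default) or `"mlp"`.
#' @param n_replicates,k Split scheme parameters.
#' @param seed Integer seed.
#' @param mlp_spec An [mlp_spec()] when `model = "mlp"`.
#' @param penalty Passed to [fit_krr()].
#' @return A `prediction_result`: `metrics` tibble (replicate, metric),
#'   `importance` (replicate x feature matrix of normalized importance),
#'   `mean_metric`.
#' @export
run_prediction <- function(features, outcome, cohort,
                           outcome_type = c("continuous", "binary"),
                           model = c("krr", "mlp"),
                           n_replicates = 100L, k = 10L, seed = 1L,
                           mlp_spec = NULL, penalty = "primal") {
  outcome_type <- match.arg(outcome_type)
  model <- match.arg(model)
  X <- as.matrix(features)
  scheme <- make_family_folds(cohort, k = k, n_replicates = n_replicates,
                              seed = derive_seed(seed, "folds"))
  feat_names <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  metrics <- numeric(n_replicates)
  imp <- matrix(NA_real_, n_replicates, ncol(X),
                dimnames = list(NULL, feat_names))
  for (rep in seq_len(n_replicates)) {
    fr <- scheme[scheme$replicate == rep, ]
    fold_id <- fr$fold[match(cohort$subject, fr$subject)]
    preds <- rep(NA_real_, nrow(X))
    fold_metrics <- c()
    fi_acc <- numeric(ncol(X)); fi_n <- 0
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f
      st <- standardize(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
      fam_tr <- cohort$family[tr]
      fit_seed <- derive_seed(seed, sprintf("fit-%d-%d", rep, f))
      if (model == "krr") {
        m <- fit_krr(st$train, outcome[tr], family = fam_tr,
                     penalty = penalty, seed = fit_seed)
        preds[!tr] <- predict(m, st$test)
        fi0 <- krr_importance(m)
      } else {
        spec <- mlp_spec %||% mlp_spec()
        m <- fit_mlp(st$train, outcome[tr], spec = spec,
                     binary = outcome_type == "binary", seed = fit_seed)
        preds[!tr] <- predict(m, st$test)
        fi0 <- mlp_saliency(m, st$train)
      }
      full_fi <- numeric(ncol(X)); full_fi[st$kept] <- fi0
      fi_acc <- fi_acc + abs(full_fi); fi_n <- fi_n + 1
      fold_metrics <- c(fold_metrics,
                        evaluate(preds[!tr], outcome[!tr], outcome_type))
    }
    # per-fold metrics averaged within the replicate: unbiased at the
    # null, unlike pooling out-of-fold predictions across fold-specific
    # models (which acquires a negative bias under inner model selection)
    metrics[rep] <- mean(fold_metrics, na.rm = TRUE)
    imp[rep, ] <- normalize_importance(fi_acc / fi_n)
  }
  structure(list(metrics = tibble(replicate = seq_len(n_replicates),
                                  metric = metrics),
                 importance = imp,
                 mean_metric = mean(metrics, na.rm = TRUE),
                 outcome_type = outcome_type, model = model),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result %s/%s> mean %s = %.3f over %d replicates\n",
              x$model, x$outcome_type,
              if (x$outcome_type == "binary") "AUC" else "r",
              x$mean_metric, nrow(x$metrics)))
  invisible(x)
}

#' @export
tidy.prediction_result <- function(x, ...) x$metrics

#' @export
glance.prediction_result <- function(x, ...) {
  tibble(model = x$model, outcome_type = x$outcome_type,
         mean_metric = x$mean_metric, n_replicates = nrow(x$metrics))
}
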