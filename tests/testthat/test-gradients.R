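# Gradient construction: QC filter, Fisher-z, proportional thresholding,
# affinity, diffusion embedding vs dense oracle, component selection,
# Procrustes alignment, template, spatial correspondence.

test_that("motion QC excludes strictly above the cutoff and preserves order", {
  co <- tibble::tibble(subject = c("a", "b", "c"),
                       mean_fd = c(0.1, 0.3, 0.31))
  expect_equal(qc_filter_fd(co), c("a", "b"))
  co$mean_fd <- c(0.05, 0.1, 0.2)
  expect_equal(qc_filter_fd(co), co$subject)
  co$mean_fd <- c(0.5, 0.6, 0.7)
  expect_warning(keep <- qc_filter_fd(co), "empty")
  expect_length(keep, 0)
  co$mean_fd[2] <- NA
  expect_error(qc_filter_fd(co), "b")
})

test_that("fisher z-transform is atanh off-diagonal with zero diagonal", {
  m <- matrix(c(1, 0.5, 0, 0.5, 1, -0.3, 0, -0.3, 1), 3)
  z <- fisher_z(m)
  expect_equal(z[1, 2], atanh(0.5))
  expect_equal(z[1, 2], 0.5493, tolerance = 1e-4)
  expect_equal(z[2, 3], atanh(-0.3))
  expect_equal(diag(z), rep(0, 3))
  expect_equal(z, t(z))
  m[1, 2] <- m[2, 1] <- 1
  expect_error(fisher_z(m), "\\|r\\| < 1")
})

test_that("proportional thresholding keeps exactly the strongest edges", {
  withr::with_seed(42, {
    m <- matrix(rnorm(16), 4); m <- m + t(m); diag(m) <- 0
  })
  # keep 2 of 6 undirected edges; compare against brute-force sort
  thr <- threshold_top_fraction(m, 2 / 6)
  ut <- which(upper.tri(m))
  top2 <- ut[order(m[ut], decreasing = TRUE)][1:2]
  expect_equal(sum(thr[upper.tri(thr)] != 0), 2)
  expect_setequal(which(thr[ut] != 0), match(top2, ut))
  # all retained >= all zeroed
  expect_gte(min(m[ut][thr[ut] != 0]), max(m[ut][thr[ut] == 0]))
  # density contract at 10%
  withr::with_seed(1, {
    big <- matrix(rnorm(50 * 50), 50); big <- big + t(big); diag(big) <- 0
  })
  t10 <- threshold_top_fraction(big, 0.10)
  n_edges <- sum(t10[upper.tri(t10)] != 0)
  expect_equal(n_edges, ceiling(0.10 * choose(50, 2)))
  # identity at keep_fraction 1
  expect_equal(threshold_top_fraction(big, 1), big)
  expect_error(threshold_top_fraction(big, 0), "keep_fraction")
})

test_that("raising the keep fraction never drops a retained edge", {
  withr::with_seed(9, {
    m <- matrix(rnorm(30 * 30), 30); m <- m + t(m); diag(m) <- 0
  })
  prev <- threshold_top_fraction(m, 0.05) != 0
  for (kf in c(0.1, 0.2, 0.5, 1)) {
    cur <- threshold_top_fraction(m, kf) != 0
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("cosine affinity matches closed forms and clamps negatives", {
  m <- rbind(c(0, 1, 0, 2), c(0, 2, 0, 1), c(0, 1, 0, 2), c(1, 0, 1, 0))
  m <- (m + t(m)) / 2  # symmetrize for the interface
  a <- cosine_affinity(rbind(c(1, 0, 2), c(2, 0, 1), c(1, 0, 2)))
  expect_equal(a[1, 2], 0.8)
  expect_equal(a[1, 3], 1)
  expect_equal(diag(a), rep(1, 3))
  # orthogonal rows give zero; negative cosines clamp to zero
  b <- cosine_affinity(rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0)))
  expect_equal(b[1, 2], 0)
  expect_equal(b[1, 3], 0)  # cosine -1 clamped
  expect_error(cosine_affinity(rbind(c(1, 1), c(0, 0))), "all-zero")
})

test_that("diffusion embedding matches the dense Markov-operator oracle", {
  for (seed in 1:20) {
    V <- sample(10:60, 1)
    A <- random_affinity(V, seed)
    for (expo in c("alpha", "inv_alpha")) {
      cfg <- diffusion_config(n_components_computed = V - 1,
                              n_components_retained = min(20, V - 1),
                              normalization_exponent = expo)
      gs <- diffusion_embedding(A, cfg)
      or <- dense_embedding_oracle(A, 0.5, expo)
      k <- min(5, V - 2)
      expect_equal(gs$eigenvalues[1:k], or$values[1:k], tolerance = 1e-8)
      expect_lt(max_coldiff_upto_sign(gs$embedding[, 1:k],
                                      or$vectors[, 1:k]), 1e-8)
    }
  }
})

test_that("two disconnected cliques give a unit eigenvalue separating them", {
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- 1; A[6:10, 6:10] <- 1
  gs <- diffusion_embedding(A, diffusion_config())
  expect_equal(gs$eigenvalues[1], 1, tolerance = 1e-10)
  g1 <- gs$embedding[, 1]
  expect_equal(sd(g1[1:5]), 0, tolerance = 1e-8)
  expect_equal(sd(g1[6:10]), 0, tolerance = 1e-8)
  expect_true(sign(g1[1]) != sign(g1[10]))
})

test_that("diffusion time scales columns by lambda^t exactly", {
  A <- random_affinity(30, 3)
  g0 <- diffusion_embedding(A, diffusion_config(t = 0))
  g2 <- diffusion_embedding(A, diffusion_config(t = 2))
  expect_equal(g2$embedding,
               sweep(g0$embedding, 2, g0$eigenvalues^2, "*"),
               tolerance = 1e-12)
})

test_that("planted two-community affinity is separated by the leading gradient", {
  for (seed in 1:100) {
    A <- community_affinity(50, seed)
    g1 <- diffusion_embedding(A, diffusion_config())$embedding[, 1]
    labels <- rep(c(1, 2), each = 25)
    split <- sign(g1 - median(g1))
    errs <- min(sum(split[labels == 1] > 0) + sum(split[labels == 2] < 0),
                sum(split[labels == 1] < 0) + sum(split[labels == 2] > 0))
    expect_equal(errs, 0)
  }
})

test_that("component selection follows the lambda^2 variance convention", {
  expect_equal(select_components(c(0.9, 0.1, 0), 0.7), 1L)  # 0.81/0.82
  expect_equal(select_components(rep(0.5, 100), 1.0, d_max = 20), 20L)
  expect_equal(select_components(c(0.5, 0.5, 0.5), 0.5), 2L)
  expect_error(select_components(numeric(0)), "empty")
  # default config downstream dimension: D = 20 -> 400 macroscale couplings
  expect_equal(diffusion_config()$n_components_retained^2, 400)
})

test_that("procrustes alignment is exact for orthogonal transforms and idempotent", {
  withr::with_seed(5, {
    E <- qr.Q(qr(matrix(rnorm(40 * 5), 40)))
    R <- qr.Q(qr(matrix(rnorm(25), 5)))
  })
  tpl <- sfgc:::new_gradient_set(E, rep(0.5, 5), rep(0.2, 5))
  self <- procrustes_align(tpl, tpl)
  expect_equal(self$embedding, E, tolerance = 1e-12)
  # permuted and sign-flipped template is absorbed exactly
  perm <- E[, c(3, 1, 2, 5, 4)] %*% diag(c(1, -1, 1, -1, 1))
  sub <- sfgc:::new_gradient_set(perm, rep(0.5, 5), rep(0.2, 5))
  al <- procrustes_align(sub, tpl)
  expect_equal(al$embedding, E, tolerance = 1e-10)
  # random rotation restored
  rot <- sfgc:::new_gradient_set(E %*% R, rep(0.5, 5), rep(0.2, 5))
  al2 <- procrustes_align(rot, tpl)
  expect_equal(al2$embedding, E, tolerance = 1e-8)
  expect_error(procrustes_align(
    sfgc:::new_gradient_set(E[1:10, ], rep(0.5, 5), rep(0.2, 5)), tpl),
    "dimension")
})

test_that("procrustes agrees with an independent reference implementation", {
  skip_if_not_installed("vegan")
  withr::with_seed(6, {
    X <- scale(matrix(rnorm(30 * 4), 30), scale = FALSE)
    Tm <- scale(matrix(rnorm(30 * 4), 30), scale = FALSE)
  })
  sub <- sfgc:::new_gradient_set(X, rep(0.5, 4), rep(0.2, 4))
  tpl <- sfgc:::new_gradient_set(Tm, rep(0.5, 4), rep(0.2, 4))
  ours <- procrustes_align(sub, tpl)$embedding
  ref <- vegan::procrustes(Tm, X, scale = FALSE, translation = FALSE,
                           symmetric = FALSE)
  expect_equal(ours, ref$Yrot, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("cohort template recovers the planted axis and single-subject reduction", {
  cfg <- synth_config(n_subjects = 50, n_vertices = 120, n_parcels = 4,
                      subject_noise = 0.1, seed = 21)
  ax <- planted_axes(cfg)
  dcfg <- diffusion_config(n_components_retained = 5)
  conns <- lapply(cfg$n_subjects |> seq_len(), function(i)
    gen_connectome_pair(paste0("s", i), cfg, ax)$fc)
  tpl <- build_template(conns, dcfg,
                        reference = as.matrix(ax$sphere$vertices[, c("x", "y", "z")]))
  expect_gt(abs(cor(tpl$embedding[, 1], ax$f_axes[, 1])), 0.95)
  # single subject: template equals that subject's embedding
  tpl1 <- build_template(conns[1], dcfg)
  own <- compute_gradients(conns[[1]], dcfg)
  expect_lt(max_coldiff_upto_sign(tpl1$embedding[, 1:3],
                                  own$embedding[, 1:3]), 1e-8)
  # two identical subjects: same as one
  tpl2 <- build_template(conns[c(1, 1)], dcfg)
  expect_equal(tpl2$embedding, tpl1$embedding, tolerance = 1e-10)
  expect_error(build_template(list(), dcfg), "at least one")
})

test_that("gradient correspondence gives r = 1 with minimal p for identical maps", {
  sph <- gen_sphere(60, 4)
  co <- as.matrix(sph$vertices[, c("x", "y", "z")])
  spins <- generate_spins(co, sph$vertices$hemisphere, n_spins = 99,
                          seed = 2)
  map <- sph$vertices$z + 0.1 * sph$vertices$y
  res <- gradient_correspondence(map, map, spins)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)
  expect_error(gradient_correspondence(rep(1, 60), map, spins), "constant")
})
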