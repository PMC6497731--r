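test_that("choose_dim returns the minimal prefix reaching the threshold", {
  expect_equal(choose_dim(c(5, 3, 2), 0.8), 2L)   # 8/10 exactly
  expect_equal(choose_dim(c(8, 1, 1), 0.8), 1L)   # boundary of the rule
  expect_equal(choose_dim(10, 0.5), 1L)
  expect_equal(choose_dim(10, 1), 1L)
  expect_error(choose_dim(numeric(0), 0.8), "empty")
  expect_error(choose_dim(c(2, -1), 0.8), "positive")
  # linear-scan oracle on random spectra
  set.seed(31)
  for (r in 1:20) {
    ev <- sort(rexp(sample(2:12, 1)) + 1e-3, decreasing = TRUE)
    thr <- runif(1, 0.05, 1)
    scan <- which(cumsum(ev) / sum(ev) >= thr - 1e-12)[1]
    expect_equal(choose_dim(ev, thr), as.integer(scan))
  }
})

test_that("local decomposition solves the centered low-rank problem", {
  # exact rank-1 input: outer product plus constant rows
  set.seed(17)
  u <- rnorm(12); y <- rnorm(6)
  W <- outer(u, y) + matrix(rep(rnorm(12), 6), 12, 6)
  lp <- local_decompose(W, 0.8)
  expect_equal(lp$dim, 1L)
  recon <- lp$center + lp$loadings %*% lp$pattern
  expect_lt(sum((W - recon)^2), 1e-16 * sum(W^2))

  # random W: orthonormal loadings, pattern identity, error = discarded
  # eigenvalue mass, and optimality against an independent SVD oracle
  W <- matrix(rnorm(200), 20, 10)
  lp <- local_decompose(W, 0.8)
  expect_lt(max(abs(crossprod(lp$loadings) - diag(lp$dim))), 1e-8)
  C <- W - rowMeans(W)
  expect_equal(lp$pattern, crossprod(lp$loadings, C), tolerance = 1e-10)
  err <- sum((C - lp$loadings %*% lp$pattern)^2)
  discarded <- sum(lp$eigenvalues[-seq_len(lp$dim)])
  expect_equal(err, discarded, tolerance = 1e-6 * max(discarded, 1))
  # no rank-d centered factorization does better: the SVD truncation bound
  sv <- svd(C)
  best <- sum(sv$d[-seq_len(lp$dim)]^2)
  expect_equal(err, best, tolerance = 1e-8 * max(best, 1))
  # eigenvalues match squared singular values
  expect_equal(lp$eigenvalues, sv$d[sv$d^2 > 1e-10 * max(sv$d^2)]^2,
               tolerance = 1e-8)
})

test_that("tall matrices take the Gram dual route to the same answer", {
  set.seed(23)
  W <- matrix(rnorm(300 * 8), 300, 8)   # m >> n triggers the dual
  lp <- local_decompose(W, 0.9)
  C <- W - rowMeans(W)
  sv <- svd(C)
  expect_equal(lp$eigenvalues, sv$d[sv$d^2 > 1e-10 * max(sv$d^2)]^2,
               tolerance = 1e-8)
  expect_lt(max(abs(crossprod(lp$loadings) - diag(lp$dim))), 1e-8)
  err <- sum((C - lp$loadings %*% lp$pattern)^2)
  expect_equal(err, sum(lp$eigenvalues[-seq_len(lp$dim)]),
               tolerance = 1e-6 * sum(lp$eigenvalues))
  expect_error(local_decompose(matrix(5, 4, 4)), "degenerate")
})

test_that("single-view and identical-view alignments are exact", {
  lp <- local_decompose(matrix(rnorm(60), 10, 6), 0.8, view_name = "v")
  g1 <- align_patterns(list(lp))
  expect_equal(g1$pattern, lp$pattern)
  expect_equal(unname(g1$view_weights), 1)
  expect_equal(unname(g1$residuals), 0)

  g3 <- align_patterns(list(lp, lp, lp))
  expect_equal(g3$pattern, lp$pattern, tolerance = 1e-8)
  expect_equal(unname(g3$view_weights), rep(1 / 3, 3), tolerance = 1e-8)
  expect_lt(max(g3$residuals), 1e-12)
})

test_that("alignment recovers a planted pattern from noisy rotated views", {
  set.seed(41)
  n <- 40
  G <- rbind(c(rep(-2, 20), rep(2, 20)), rnorm(n))  # planted 2-D pattern
  locals <- lapply(1:3, function(i) {
    M <- qr.Q(qr(matrix(rnorm(30 * 2), 30, 2)))      # random frame
    W <- M %*% G + matrix(rnorm(30 * n, sd = 0.05), 30, n)
    local_decompose(W, 0.95, view_name = paste0("v", i))
  })
  g <- align_patterns(locals)
  expect_true(g$converged)
  # recovery up to an orthogonal transform and scale: compare sample
  # distance matrices of the top-2 global dimensions with the truth
  Dg <- as.matrix(dist(t(g$pattern)))
  Dt <- as.matrix(dist(t(G)))
  expect_gt(cor(Dg[upper.tri(Dg)], Dt[upper.tri(Dt)]), 0.99)
  # per-entry error after optimal Procrustes fit is below the noise scale
  sc <- sqrt(sum(G^2) / sum(g$pattern[1:2, ]^2))
  sv <- svd(tcrossprod(G, sc * g$pattern[1:2, ]))
  R <- sv$u %*% t(sv$v)
  expect_lt(mean(abs(R %*% (sc * g$pattern[1:2, ]) - G)), 0.1)
})

test_that("alignment objective is monotone and errors are informative", {
  set.seed(43)
  locals <- lapply(1:3, function(i) {
    local_decompose(matrix(rnorm(25 * 12), 25, 12) +
                      outer(rnorm(25), rep(c(-1, 1), each = 6)),
                    0.8, view_name = paste0("v", i))
  })
  g <- align_patterns(locals)
  expect_true(all(diff(g$objective_trace) <= 1e-8))
  expect_equal(sum(g$view_weights), 1, tolerance = 1e-10)
  expect_true(all(g$view_weights >= 0))
  expect_lte(g$n_iter, 100L)
  # orthonormal view maps
  for (A in g$view_maps) {
    expect_lt(max(abs(crossprod(A) - diag(ncol(A)))), 1e-8)
  }

  short <- local_decompose(matrix(rnorm(50), 10, 5), 0.8, view_name = "odd")
  expect_error(align_patterns(list(locals[[1]], short)), "sample counts")
})

test_that("hci_fit orchestrates the stages and degrades gracefully", {
  sim <- simulate_expression(synthetic_spec(n_samples = 30, n_features = 80,
                                            k_true = 3, effect_size = 5,
                                            dropout_rate = 0.1, seed = 2))
  Xp <- normalize_columns(filter_zero_features(sim$X), "log1p-zscore")

  # max_order 0 on one view reduces to the plain local decomposition
  f0 <- hci_fit(Xp, max_order = 0)
  lp <- local_decompose(Xp$values, 0.8)
  expect_equal(unname(f0$global$pattern), unname(lp$pattern))

  f2 <- hci_fit(Xp, max_order = 2)
  expect_length(f2$locals, 3L)
  expect_equal(vapply(f2$locals, `[[`, "", "view_name"),
               c("mRNA", "mRNA.F1", "mRNA.F2"))

  # sample-permutation equivariance: distances between samples unchanged
  perm <- sample(ncol(Xp$values))
  Xperm <- expression_matrix(Xp$values[, perm], rownames(Xp$values),
                             colnames(Xp$values)[perm])
  fp <- hci_fit(Xperm, max_order = 2)
  D1 <- as.matrix(dist(t(f2$global$pattern)))
  D2 <- as.matrix(dist(t(fp$global$pattern)))
  expect_equal(D2, D1[perm, perm], tolerance = 1e-6)

  # planted clusters are recovered end to end
  cl <- kmeans_on_pattern(f2, 3, seed = 1)
  expect_equal(adjusted_rand_index(cl$labels, sim$labels), 1)
})

test_that("multi-view fits separate groups shared across omics layers", {
  spec <- synthetic_spec(n_samples = 30, n_features = 60, k_true = 2,
                         n_views = 3, effect_size = 2.5, dropout_rate = 0.1,
                         seed = 5)
  sim <- simulate_multiview(spec)
  views <- lapply(sim$views, function(v)
    normalize_columns(filter_zero_features(v), "log1p-zscore"))
  fit <- hci_fit(views, max_order = 2)
  expect_length(fit$locals, 9L)
  cl <- kmeans_on_pattern(fit, 2, seed = 1)
  # silhouette-like check: true groups are separated in the fused space
  expect_gt(adjusted_rand_index(cl$labels, sim$labels), 0.9)
  pts <- t(fit$global$pattern)
  lab <- sim$labels[rownames(pts)]
  D <- as.matrix(dist(pts))
  same <- outer(lab, lab, "==") & upper.tri(D)
  btw <- (!outer(lab, lab, "==")) & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[btw]))
})
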