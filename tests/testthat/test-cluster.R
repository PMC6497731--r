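two_clouds <- function(n_per = 10, gap = 10, d = 2, seed = 1) {
  set.seed(seed)
  pts <- rbind(matrix(rnorm(n_per * d), n_per, d),
               matrix(rnorm(n_per * d) + gap, n_per, d))
  rownames(pts) <- paste0("s", seq_len(2 * n_per))
  list(Y = t(pts), truth = rep(1:2, each = n_per))
}

test_that("k-means on the pattern separates well-separated clouds", {
  tc <- two_clouds()
  cl <- kmeans_on_pattern(tc$Y, 2, seed = 4)
  expect_equal(adjusted_rand_index(cl$labels, tc$truth), 1)
  expect_equal(length(unique(cl$labels)), 2L)

  # determinism: same seed, same result
  cl2 <- kmeans_on_pattern(tc$Y, 2, seed = 4)
  expect_identical(cl$labels, cl2$labels)
  expect_identical(cl$inertia, cl2$inertia)

  # k = n - 1 on distinct points merges exactly one pair
  set.seed(9)
  Y <- matrix(rnorm(2 * 8), 2, 8, dimnames = list(NULL, paste0("s", 1:8)))
  cl7 <- kmeans_on_pattern(Y, 7, seed = 1)
  expect_equal(length(unique(cl7$labels)), 7L)
  expect_equal(sort(unname(table(cl7$labels)), decreasing = TRUE)[1], 2L,
               ignore_attr = TRUE)

  expect_error(kmeans_on_pattern(tc$Y, 1, seed = 1), "k must be")
  expect_error(kmeans_on_pattern(tc$Y, 20, seed = 1), "k must be")
})

test_that("RDC equals the all-pairs oracle and the hand-worked example", {
  # 1-D points {0,1} vs {10,11}: D_in = 1, D_out = (10+11+9+10)/4 = 10
  Y <- matrix(c(0, 1, 10, 11), 1, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(rdc(Y, c(1, 1, 2, 2)), 0.1)

  # two clusters collapsed to repeated points: D_in = 0
  Yc <- matrix(c(0, 0, 5, 5), 1, 4, dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(rdc(Yc, c(1, 1, 2, 2)), 0)

  # random labeled point sets vs brute-force enumeration
  set.seed(19)
  for (r in 1:10) {
    n <- sample(6:15, 1)
    pts <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2 || all(table(lab) == 1)) next
    Yr <- t(pts); colnames(Yr) <- paste0("s", 1:n)
    expect_equal(rdc(Yr, lab), oracle_rdc(pts, lab), tolerance = 1e-12)
  }

  expect_error(rdc(Y, rep(1, 4)), ">= 2 clusters")
  expect_error(rdc(Y, 1:4), "singleton")
})

test_that("RDC is invariant to rotation and scaling of the pattern", {
  set.seed(27)
  Y <- matrix(rnorm(3 * 12), 3, 12, dimnames = list(NULL, paste0("s", 1:12)))
  lab <- rep(1:3, each = 4)
  base <- rdc(Y, lab)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(rdc(Q %*% Y, lab), base, tolerance = 1e-10)
  expect_equal(rdc(7.3 * Y, lab), base, tolerance = 1e-10)
})

test_that("true labels give lower RDC than permuted labels on separated data", {
  tc <- two_clouds(n_per = 15, gap = 8, seed = 33)
  truth_rdc <- rdc(tc$Y, tc$truth)
  set.seed(71)
  perms <- replicate(20, rdc(tc$Y, sample(tc$truth)))
  expect_true(all(truth_rdc < perms))
})

test_that("adjusted Rand index matches pair counting and known cases", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(1:6, rep(1, 6)), 0)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 2, 2)),
               oracle_ari(c(1, 1, 2, 2), c(1, 2, 2, 2)), tolerance = 1e-12)

  set.seed(55)
  for (r in 1:20) {
    n <- sample(5:25, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b),
                 tolerance = 1e-12)
    # symmetry and relabeling invariance
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
    relab <- c(40, 10, 30, 20)[a]
    expect_equal(adjusted_rand_index(relab, b), adjusted_rand_index(a, b))
  }

  # independent cross-check against an established implementation
  skip_if_not_installed("mclust")
  set.seed(77)
  for (r in 1:10) {
    a <- sample(1:3, 20, replace = TRUE)
    b <- sample(1:5, 20, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }

  expect_error(adjusted_rand_index(1:3, 1:4), "different lengths")
})

test_that("the RDC curve elbows at the planted cluster number", {
  sim <- simulate_expression(synthetic_spec(n_samples = 45, n_features = 150,
                                            k_true = 3, effect_size = 4,
                                            dropout_rate = 0.1, seed = 8))
  Xp <- normalize_columns(filter_zero_features(sim$X), "log1p-zscore")
  fit <- hci_fit(Xp, max_order = 2)
  curve <- estimate_k(fit, k_max = 7, n_repeats = 5, seed = 8, n_restarts = 5)
  expect_equal(curve$chosen_k, 3L)
  expect_true(all(curve$mean_rdc >= 0))
  expect_equal(curve$k_values, 2:7)
  expect_true(3L %in% curve$plateau_k)

  # determinism with a single repeat
  c1 <- estimate_k(fit, k_max = 5, n_repeats = 1, seed = 3, n_restarts = 3)
  c2 <- estimate_k(fit, k_max = 5, n_repeats = 1, seed = 3, n_restarts = 3)
  expect_identical(c1$mean_rdc, c2$mean_rdc)
  expect_identical(c1$chosen_k, c2$chosen_k)
})

test_that("hierarchical structure elbows at the super-cluster level", {
  # 4 clusters collapsed pairwise into 2 super-clusters with tiny
  # sub-separation: the elbow sits at 2
  set.seed(12)
  n_per <- 12
  centers <- rbind(c(0, 0), c(0.8, 0), c(30, 0), c(30.8, 0))
  pts <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(n_per * 2, sd = 0.3), n_per, 2), 2, centers[i, ], "+")))
  Y <- t(pts); colnames(Y) <- paste0("s", seq_len(4 * n_per))
  curve <- estimate_k(Y, k_max = 6, n_repeats = 5, seed = 2, n_restarts = 5)
  expect_equal(curve$chosen_k, 2L)
})

test_that("fused views do not cluster worse than the expression view alone", {
  # paired comparison on the noisy standard benchmark (reduced replicate
  # count; the acceptance suite runs the full 20 seeds)
  aris <- vapply(1:6, function(s) {
    sim <- simulate_expression(synthetic_spec(n_samples = 60,
                                              n_features = 300, seed = s))
    Xp <- normalize_columns(filter_zero_features(sim$X), "log1p-zscore")
    full <- kmeans_on_pattern(hci_fit(Xp, max_order = 2), 3, seed = s)
    xonly <- kmeans_on_pattern(hci_fit(Xp, max_order = 0), 3, seed = s)
    c(adjusted_rand_index(full$labels, sim$labels),
      adjusted_rand_index(xonly$labels, sim$labels))
  }, numeric(2))
  expect_gte(mean(aris[1, ]), mean(aris[2, ]))
})
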