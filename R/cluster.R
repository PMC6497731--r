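# Run an expression with the RNG seeded, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Derive a child seed from a master seed, kept inside the 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483647)
}

pattern_points <- function(Y) {
  g <- if (inherits(Y, "hci_fit")) Y$global else Y
  p <- if (inherits(g, "GlobalPattern")) g$pattern else g
  stopifnot(is.matrix(p))
  t(p)  # samples as points
}

# k-means++ style seeding: spread initial centers by squared-distance sampling.
kmeanspp_centers <- function(pts, k) {
  n <- nrow(pts)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- colSums((t(pts) - pts[centers[1], ])^2)
  if (k > 1) for (j in 2:k) {
    prob <- d2 / sum(d2)
    if (!all(is.finite(prob)) || sum(d2) <= 0) {
      centers[j] <- sample.int(n, 1)
    } else {
      centers[j] <- sample.int(n, 1, prob = prob)
    }
    d2 <- pmin(d2, colSums((t(pts) - pts[centers[j], ])^2))
  }
  pts[centers, , drop = FALSE]
}

#' K-means clustering of the global sample pattern
#'
#' Clusters the sample columns of the global pattern matrix (samples as
#' points in the fused low-dimensional space, Euclidean metric) with
#' K-means, taking the best of `n_restarts` k-means++-seeded runs by total
#' within-cluster sum of squares. Fully deterministic given `seed`.
#'
#' @param Y An `hci_fit`, `GlobalPattern`, or d x n numeric matrix.
#' @param k Number of clusters, `2 <= k <= n - 1`.
#' @param n_restarts Independent seeded restarts (default 10).
#' @param seed Integer master seed.
#' @return A `ClusteringOutcome`: list with `labels` (named integer vector),
#'   `k`, `inertia` (best total within-cluster SS), `seed`.
#' @export
kmeans_on_pattern <- function(Y, k, n_restarts = 10L, seed = 1L) {
  pts <- pattern_points(Y)
  n <- nrow(pts)
  if (!is.numeric(k) || k < 2 || k > n - 1) {
    stop(sprintf("k must be in [2, %d]", n - 1), call. = FALSE)
  }
  k <- as.integer(k)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- kmeanspp_centers(pts, k)
      km <- tryCatch(
        stats::kmeans(pts, centers = init, iter.max = 100L),
        error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("k-means failed on all restarts", call. = FALSE)
  labels <- stats::setNames(as.integer(best$cluster), rownames(pts))
  structure(list(labels = labels, k = k, inertia = best$tot.withinss,
                 seed = as.integer(seed)),
            class = "ClusteringOutcome")
}

#' @export
print.ClusteringOutcome <- function(x, ...) {
  cat(sprintf("ClusteringOutcome: k = %d over %d samples, inertia %.4g\n",
              x$k, length(x$labels), x$inertia))
  invisible(x)
}

#' Ratio of within- to between-cluster distance (RDC)
#'
#' `RDC = D_in / D_out` where `D_in` is the mean Euclidean distance over
#' all within-cluster sample pairs and `D_out` the mean over all
#' between-cluster pairs, computed on the columns of the pattern matrix.
#' Compact, well-separated clusterings give small values; the flattening of
#' the mean RDC curve over K estimates the cluster number. Singleton
#' clusters contribute no within-pairs.
#'
#' @param Y An `hci_fit`, `GlobalPattern`, or d x n matrix.
#' @param labels Cluster assignment per sample (vector or
#'   `ClusteringOutcome`).
#' @return The RDC value (nonnegative scalar).
#' @export
rdc <- function(Y, labels) {
  pts <- pattern_points(Y)
  if (inherits(labels, "ClusteringOutcome")) labels <- labels$labels
  if (length(labels) != nrow(pts)) {
    stop("labels length does not match sample count", call. = FALSE)
  }
  lab <- as.integer(factor(labels))
  if (length(unique(lab)) < 2) {
    stop("RDC needs >= 2 clusters (between-cluster distance undefined)",
         call. = FALSE)
  }
  D <- as.matrix(stats::dist(pts))
  same <- outer(lab, lab, "==")
  upper <- upper.tri(D)
  win <- D[upper & same]
  btw <- D[upper & !same]
  if (!length(win)) {
    stop("RDC undefined: all clusters are singletons", call. = FALSE)
  }
  mean(win) / mean(btw)
}

#' Estimate the number of clusters from the RDC curve
#'
#' For each K on the grid, runs seeded K-means `n_repeats` times and
#' records the RDC of each clustering; the chosen K is the smallest one at
#' which the mean curve stops decreasing meaningfully: the forward change
#' `meanRDC(K+1) - meanRDC(K)` is greater than `-slope_threshold` times
#' the range of the mean curve ("the slope is nearly 0"). The change is
#' deliberately signed: past the true cluster number the curve typically
#' flattens or even rises (splitting a real cluster brings the new
#' centers close together), and a rise is evidence of no further
#' structure, not of structure. All K satisfying the flatness condition
#' are reported as `plateau_k` so ties across a plateau stay visible.
#'
#' @param Y An `hci_fit`, `GlobalPattern`, or d x n matrix.
#' @param k_max Largest K to scan (grid is `2:k_max`); capped at `n - 2`
#'   so the forward slope at the last grid point is defined.
#' @param n_repeats K-means realizations per K (default 100).
#' @param slope_threshold Flatness threshold as a fraction of the mean
#'   curve's range (default 0.05).
#' @param seed Master seed; per-run seeds are derived from it.
#' @param n_restarts Restarts per K-means run.
#' @return An `RDCCurve`: list with `k_values`, `mean_rdc`, `sd_rdc`,
#'   `per_run_rdc` (repeats x K matrix), `chosen_k`, `plateau_k`,
#'   `slope_threshold`.
#' @export
estimate_k <- function(Y, k_max = 15L, n_repeats = 100L,
                       slope_threshold = 0.05, seed = 1L, n_restarts = 10L) {
  pts <- pattern_points(Y)
  n <- nrow(pts)
  k_max <- min(as.integer(k_max), n - 2L)
  if (k_max < 3) stop("k_max must be >= 3 (and n >= 5)", call. = FALSE)
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  ks <- 2:k_max
  per_run <- matrix(NA_real_, n_repeats, length(ks),
                    dimnames = list(NULL, paste0("K", ks)))
  for (j in seq_along(ks)) {
    for (r in seq_len(n_repeats)) {
      cl <- kmeans_on_pattern(t(pts), ks[j], n_restarts = n_restarts,
                              seed = derive_seed(seed, j * 100003L + r))
      per_run[r, j] <- rdc(t(pts), cl$labels)
    }
  }
  mean_rdc <- colMeans(per_run)
  sd_rdc <- apply(per_run, 2, stats::sd)
  rng <- max(mean_rdc) - min(mean_rdc)
  if (rng <= .Machine$double.eps) {
    warning("flat RDC curve: defaulting to K = 2", call. = FALSE)
    chosen <- 2L
    plateau <- ks[-length(ks)]
  } else {
    slopes <- diff(mean_rdc)  # signed change between K and K+1
    flat <- slopes > -slope_threshold * rng
    plateau <- ks[-length(ks)][flat]
    chosen <- if (any(flat)) ks[which(flat)[1]] else ks[length(ks)]
  }
  structure(list(k_values = ks, mean_rdc = unname(mean_rdc),
                 sd_rdc = unname(sd_rdc), per_run_rdc = per_run,
                 chosen_k = as.integer(chosen),
                 plateau_k = as.integer(plateau),
                 slope_threshold = slope_threshold),
            class = "RDCCurve")
}

#' @export
print.RDCCurve <- function(x, ...) {
  cat(sprintf("RDCCurve over K = %d..%d: chosen K = %d\n",
              min(x$k_values), max(x$k_values), x$chosen_k))
  cat("  mean RDC:", paste(sprintf("%.3f", x$mean_rdc), collapse = " "), "\n")
  invisible(x)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples
#' (Hubert-Arabie form): `(Index - E[Index]) / (Max - E[Index])` computed
#' from the contingency table of the two partitions. 1 for identical
#' partitions up to relabeling; about 0 for independent ones.
#'
#' @param a,b Label vectors of equal length (any atomic type), or
#'   `ClusteringOutcome`s. If both carry sample names the vectors are
#'   aligned by name first.
#' @return The ARI, in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (inherits(a, "ClusteringOutcome")) a <- a$labels
  if (inherits(b, "ClusteringOutcome")) b <- b$labels
  if (length(a) != length(b)) {
    stop("partitions have different lengths", call. = FALSE)
  }
  if (!is.null(names(a)) && !is.null(names(b)) &&
      all(sort(names(a)) == sort(names(b)))) {
    b <- b[names(a)]
  }
  n <- length(a)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps) {
    # both partitions all-singletons or both single-cluster: identical
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Write a labels TSV and an RDC curve TSV
#'
#' @param outcome A `ClusteringOutcome`.
#' @param path Output path.
#' @export
write_cluster_labels <- function(outcome, path) {
  stopifnot(inherits(outcome, "ClusteringOutcome"))
  write_labels(outcome$labels, path)
}

#' @rdname write_cluster_labels
#' @param curve An `RDCCurve`.
#' @export
write_rdc_curve <- function(curve, path) {
  stopifnot(inherits(curve, "RDCCurve"))
  df <- data.frame(K = curve$k_values, mean_rdc = curve$mean_rdc,
                   sd_rdc = curve$sd_rdc)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
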