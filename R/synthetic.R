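#' Specification of a synthetic benchmark dataset
#'
#' Describes a ground-truth-labeled expression dataset with planted sample
#' clusters, in the regime the method targets: a genes x samples matrix
#' with balanced clusters, cluster-specific mean shifts on a subset of
#' marker genes, log-normal-style nonnegative values, and optional dropout
#' zeros emulating scRNA-seq technical zeros. The defaults describe the
#' package's standard recovery benchmark: 90 cells, 500 genes, 3 clusters,
#' 10% marker genes with a 3-standard-deviation shift, 30% dropout.
#'
#' @param n_samples Number of samples (cells); default 90.
#' @param n_features Number of features (genes); default 500.
#' @param k_true Number of planted clusters (each cluster gets at least 3
#'   samples); default 3.
#' @param signal_feature_fraction Fraction of features carrying the
#'   cluster signal; default 0.1.
#' @param effect_size Cluster mean shift on signal features, in units of
#'   `noise_sd`; default 3.
#' @param noise_sd Standard deviation of the log-scale Gaussian noise;
#'   default 1.
#' @param dropout_rate Probability an entry is zeroed after
#'   exponentiation; default 0.3.
#' @param n_views Number of matched views for multi-view simulation;
#'   default 1.
#' @param base_mean Log-scale baseline expression; default 1.
#' @param family `"lognormal"` (default) or `"nb"` for negative-binomial
#'   counts with the same log-scale mean structure.
#' @param nb_size Negative-binomial dispersion (size) when
#'   `family = "nb"`; default 2.
#' @param seed Master seed; default 1.
#' @return A `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_samples = 90L, n_features = 500L, k_true = 3L,
                           signal_feature_fraction = 0.1, effect_size = 3,
                           noise_sd = 1, dropout_rate = 0.3, n_views = 1L,
                           base_mean = 1, family = c("lognormal", "nb"),
                           nb_size = 2, seed = 1L) {
  family <- match.arg(family)
  spec <- list(n_samples = as.integer(n_samples),
               n_features = as.integer(n_features),
               k_true = as.integer(k_true),
               signal_feature_fraction = signal_feature_fraction,
               effect_size = effect_size, noise_sd = noise_sd,
               dropout_rate = dropout_rate, n_views = as.integer(n_views),
               base_mean = base_mean, family = family, nb_size = nb_size,
               seed = as.integer(seed))
  if (spec$n_samples < 6 || spec$n_features < 2) {
    stop("need >= 6 samples and >= 2 features", call. = FALSE)
  }
  if (spec$k_true < 1 || spec$k_true > spec$n_samples / 3) {
    stop("k_true must satisfy 1 <= k_true <= n_samples / 3", call. = FALSE)
  }
  for (f in c("signal_feature_fraction", "dropout_rate")) {
    if (spec[[f]] < 0 || spec[[f]] > 1) {
      stop(f, " must be in [0, 1]", call. = FALSE)
    }
  }
  if (spec$noise_sd < 0 || spec$effect_size < 0) {
    stop("noise_sd and effect_size must be nonnegative", call. = FALSE)
  }
  if (spec$n_views < 1) stop("n_views must be >= 1", call. = FALSE)
  class(spec) <- "SyntheticSpec"
  spec
}

# balanced labels 1..k over n samples (sizes differ by at most 1)
balanced_labels <- function(n, k) {
  sort(rep_len(seq_len(k), n))
}

# one view's matrix given labels; RNG must already be seeded
simulate_view_values <- function(spec, labels, view_name) {
  n <- length(labels)
  m <- spec$n_features
  k <- spec$k_true
  n_sig <- round(spec$signal_feature_fraction * m)
  # each signal feature is a marker of one cluster: its log-mean is raised
  # by effect_size * noise_sd in that cluster only
  mu <- matrix(spec$base_mean, m, n)
  signal_rows <- if (n_sig > 0) sample.int(m, n_sig) else integer(0)
  marker_of <- if (n_sig > 0) sample(rep_len(seq_len(k), n_sig)) else integer(0)
  for (i in seq_along(signal_rows)) {
    mu[signal_rows[i], labels == marker_of[i]] <-
      spec$base_mean + spec$effect_size * spec$noise_sd
  }
  logx <- mu + matrix(stats::rnorm(m * n, sd = spec$noise_sd), m, n)
  vals <- if (spec$family == "nb") {
    matrix(stats::rnbinom(m * n, size = spec$nb_size, mu = exp(logx)), m, n)
  } else {
    exp(logx)
  }
  if (spec$dropout_rate > 0) {
    drop <- matrix(stats::runif(m * n) < spec$dropout_rate, m, n)
    vals[drop] <- 0
  }
  dimnames(vals) <- list(sprintf("%s_gene%04d", view_name, seq_len(m)),
                         sprintf("cell%04d", seq_len(n)))
  attr(vals, "signal_rows") <- sort(signal_rows)
  vals
}

#' Simulate a labeled single-view expression dataset
#'
#' Draws a genes x samples matrix under the spec's planted-cluster model:
#' balanced cluster sizes, marker genes shifted by `effect_size * noise_sd`
#' on the log scale in their cluster, log-normal (or negative-binomial)
#' nonnegative values, then independent Bernoulli dropout zeroing.
#' Deterministic given `spec$seed`.
#'
#' @param spec A `SyntheticSpec`.
#' @return A list with `X` (an `ExpressionMatrix`; attribute
#'   `"signal_rows"` on `X$values` marks the planted signal features) and
#'   `labels` (named integer vector of true cluster labels).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_seed(spec$seed, {
    labels <- balanced_labels(spec$n_samples, spec$k_true)
    vals <- simulate_view_values(spec, labels, "mRNA")
    X <- expression_matrix(vals, view_name = "mRNA")
    attr(X$values, "signal_rows") <- attr(vals, "signal_rows")
    list(X = X, labels = stats::setNames(labels, colnames(vals)))
  })
}

#' Simulate matched multi-view datasets over one sample partition
#'
#' Generates `spec$n_views` expression views sharing the same sample
#' labels but with independent feature spaces and independent noise.
#' Per-view effect sizes can differ; a view with effect size 0 is pure
#' noise, useful for testing that the alignment down-weights
#' uninformative views.
#'
#' @param spec A `SyntheticSpec` with `n_views >= 2`.
#' @param effect_sizes Optional numeric vector (length `n_views`) of
#'   per-view effect sizes; defaults to `spec$effect_size` for every view.
#' @param noise_views Indices of views forced to pure noise (effect 0).
#' @return A list with `views` (list of `ExpressionMatrix`) and `labels`.
#' @export
simulate_multiview <- function(spec, effect_sizes = NULL, noise_views = integer(0)) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (spec$n_views < 2) stop("n_views must be >= 2 for multi-view simulation",
                             call. = FALSE)
  if (is.null(effect_sizes)) effect_sizes <- rep(spec$effect_size, spec$n_views)
  if (length(effect_sizes) != spec$n_views) {
    stop("effect_sizes must have length n_views", call. = FALSE)
  }
  effect_sizes[noise_views] <- 0
  view_names <- paste0("view", seq_len(spec$n_views))
  with_seed(spec$seed, {
    labels <- balanced_labels(spec$n_samples, spec$k_true)
    seeds <- vapply(seq_len(spec$n_views), function(i) derive_seed(spec$seed, i),
                    integer(1))
    views <- vector("list", spec$n_views)
    for (i in seq_len(spec$n_views)) {
      vs <- spec
      vs$effect_size <- effect_sizes[i]
      set.seed(seeds[i])
      vals <- simulate_view_values(vs, labels, view_names[i])
      views[[i]] <- expression_matrix(vals, view_name = view_names[i])
    }
    list(views = views,
         labels = stats::setNames(labels, colnames(views[[1]]$values)))
  })
}
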