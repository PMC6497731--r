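#' Configuration for a pipeline run
#'
#' Collects every tunable of the end-to-end workflows with its default;
#' the config is echoed verbatim into each run's `summary.json` so a run
#' can be re-executed bit-identically.
#'
#' @param normalization Column normalization method (see
#'   [normalize_columns()]).
#' @param cv_gene_fraction Fraction of most-variable genes kept; 1 keeps
#'   all.
#' @param max_zero_fraction Per-view sparsity filter used by the
#'   multi-view workflow.
#' @param max_order Highest correlation order added as views.
#' @param var_threshold_x,var_threshold_f Cumulative variance thresholds
#'   for expression and correlation views.
#' @param k Fixed cluster number; `NULL` (default) estimates K from the
#'   RDC curve.
#' @param k_max,n_repeats,slope_threshold,n_restarts See [estimate_k()].
#' @param cv_quantile Quantile defining the differential-feature threshold.
#' @param seed Master seed.
#' @return A `RunConfig` list.
#' @export
run_config <- function(normalization = "log1p-zscore", cv_gene_fraction = 1,
                       max_zero_fraction = 0.8, max_order = 2L,
                       var_threshold_x = 0.8, var_threshold_f = 0.9,
                       k = NULL, k_max = 15L, n_repeats = 100L,
                       slope_threshold = 0.05, n_restarts = 10L,
                       cv_quantile = 0.9, seed = 1L) {
  structure(list(normalization = normalization,
                 cv_gene_fraction = cv_gene_fraction,
                 max_zero_fraction = max_zero_fraction,
                 max_order = as.integer(max_order),
                 var_threshold_x = var_threshold_x,
                 var_threshold_f = var_threshold_f,
                 k = if (is.null(k)) NULL else as.integer(k),
                 k_max = as.integer(k_max), n_repeats = as.integer(n_repeats),
                 slope_threshold = slope_threshold,
                 n_restarts = as.integer(n_restarts),
                 cv_quantile = cv_quantile, seed = as.integer(seed)),
            class = "RunConfig")
}

preprocess_view <- function(X, config, sparse_filter = FALSE) {
  X <- filter_zero_features(X)
  if (sparse_filter) X <- filter_sparse_features(X, config$max_zero_fraction)
  if (config$cv_gene_fraction < 1) {
    X <- select_top_variable_features(X, config$cv_gene_fraction)
  }
  normalize_columns(X, config$normalization)
}

cluster_fit <- function(fit, config, reference_labels = NULL) {
  curve <- NULL
  k <- config$k
  if (is.null(k)) {
    curve <- estimate_k(fit, k_max = config$k_max,
                        n_repeats = config$n_repeats,
                        slope_threshold = config$slope_threshold,
                        seed = config$seed, n_restarts = config$n_restarts)
    k <- curve$chosen_k
  }
  outcome <- kmeans_on_pattern(fit, k, n_restarts = config$n_restarts,
                               seed = derive_seed(config$seed, 999983L))
  ari <- NULL
  if (!is.null(reference_labels)) {
    ref <- reference_labels
    if (!is.null(names(ref))) ref <- ref[names(outcome$labels)]
    ari <- adjusted_rand_index(outcome$labels, ref)
  }
  list(curve = curve, outcome = outcome, k = k, ari = ari)
}

write_summary <- function(path, config, extra) {
  s <- c(list(package_version = as.character(utils::packageVersion("hci")),
              config = unclass(config)), extra)
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Single-matrix clustering workflow
#'
#' Runs preprocessing, high-order correlation construction, pattern
#' fusion, K estimation and K-means clustering on one expression matrix,
#' writing `pattern.tsv`, `labels.tsv`, `rdc_curve.tsv`, `model.rds` and
#' `summary.json` under `outdir`.
#'
#' @param input Path to an expression matrix, or an `ExpressionMatrix`.
#' @param outdir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @param config A `RunConfig`.
#' @param labels Optional reference labels (path or named vector) for ARI
#'   evaluation.
#' @param format Input format passed to [load_expression()].
#' @return Invisibly, a list with `fit`, `curve`, `outcome`, `chosen_k`,
#'   `ari`.
#' @export
run_hci_cluster <- function(input, outdir = NULL, config = run_config(),
                            labels = NULL, format = "auto") {
  X <- if (inherits(input, "ExpressionMatrix")) input else
    load_expression(input, format = format)
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    labels <- load_labels(labels)
  }
  message(sprintf("[preprocess] %d features x %d samples in", nrow(X$values),
                  ncol(X$values)))
  Xp <- preprocess_view(X, config)
  message(sprintf("[preprocess] %d features retained", nrow(Xp$values)))
  fit <- hci_fit(Xp, max_order = config$max_order,
                 var_threshold_x = config$var_threshold_x,
                 var_threshold_f = config$var_threshold_f)
  message(sprintf("[fit] %d views, global dim %d", length(fit$locals),
                  nrow(fit$global$pattern)))
  cl <- cluster_fit(fit, config, labels)
  message(sprintf("[cluster] chosen K = %d%s", cl$k,
                  if (is.null(cl$ari)) "" else sprintf(", ARI = %.3f", cl$ari)))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_pattern(fit, file.path(outdir, "pattern.tsv"))
    write_cluster_labels(cl$outcome, file.path(outdir, "labels.tsv"))
    if (!is.null(cl$curve)) {
      write_rdc_curve(cl$curve, file.path(outdir, "rdc_curve.tsv"))
    }
    saveRDS(fit, file.path(outdir, "model.rds"))
    write_summary(file.path(outdir, "summary.json"), config,
                  list(workflow = "cluster",
                       n_features_in = nrow(X$values),
                       n_features_used = nrow(Xp$values),
                       n_samples = ncol(Xp$values),
                       views = vapply(fit$locals, `[[`, "", "view_name"),
                       chosen_k = cl$k, ari = cl$ari))
  }
  invisible(list(fit = fit, curve = cl$curve, outcome = cl$outcome,
                 chosen_k = cl$k, ari = cl$ari))
}

#' Multi-omics integration workflow
#'
#' Aligns two or more views (mRNA, miRNA, methylation, ...) on their
#' shared samples, applies the per-view sparsity filter (more than
#' `max_zero_fraction` zeros removes a feature), builds each view's
#' correlation matrices, fuses everything and clusters.
#'
#' @param inputs List of paths or `ExpressionMatrix` objects (>= 2).
#' @param outdir Output directory, or `NULL`.
#' @param config A `RunConfig`.
#' @param labels Optional reference labels for ARI.
#' @param write_weights Also emit per-view feature weight tables.
#' @return Invisibly, as [run_hci_cluster()], plus `weights` when
#'   requested.
#' @export
run_hci_integrate <- function(inputs, outdir = NULL, config = run_config(),
                              labels = NULL, write_weights = FALSE) {
  stopifnot(length(inputs) >= 2)
  views <- lapply(seq_along(inputs), function(i) {
    x <- inputs[[i]]
    if (inherits(x, "ExpressionMatrix")) x else
      load_expression(x, view_name = paste0("view", i))
  })
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    labels <- load_labels(labels)
  }
  shared <- Reduce(intersect, lapply(views, function(v) colnames(v$values)))
  if (!length(shared)) stop("empty sample intersection across views", call. = FALSE)
  message(sprintf("[integrate] %d shared samples across %d views",
                  length(shared), length(views)))
  views <- lapply(views, function(v) {
    v <- expression_matrix(v$values[, shared, drop = FALSE],
                           view_name = v$view_name)
    preprocess_view(v, config, sparse_filter = TRUE)
  })
  fit <- hci_fit(views, max_order = config$max_order,
                 var_threshold_x = config$var_threshold_x,
                 var_threshold_f = config$var_threshold_f)
  cl <- cluster_fit(fit, config, labels)
  message(sprintf("[cluster] chosen K = %d%s", cl$k,
                  if (is.null(cl$ari)) "" else sprintf(", ARI = %.3f", cl$ari)))
  weights <- NULL
  if (write_weights) {
    weights <- lapply(vapply(views, `[[`, "", "view_name"), function(vn) {
      select_differential(cv_weights(fit, view = vn),
                          quantile = config$cv_quantile)
    })
    names(weights) <- vapply(views, `[[`, "", "view_name")
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_pattern(fit, file.path(outdir, "pattern.tsv"))
    write_cluster_labels(cl$outcome, file.path(outdir, "labels.tsv"))
    if (!is.null(cl$curve)) {
      write_rdc_curve(cl$curve, file.path(outdir, "rdc_curve.tsv"))
    }
    saveRDS(fit, file.path(outdir, "model.rds"))
    if (!is.null(weights)) {
      for (vn in names(weights)) {
        write_feature_weights(weights[[vn]],
                              file.path(outdir, paste0("weights_", vn, ".tsv")))
      }
    }
    write_summary(file.path(outdir, "summary.json"), config,
                  list(workflow = "integrate", n_samples = length(shared),
                       views = vapply(fit$locals, `[[`, "", "view_name"),
                       chosen_k = cl$k, ari = cl$ari))
  }
  invisible(list(fit = fit, curve = cl$curve, outcome = cl$outcome,
                 chosen_k = cl$k, ari = cl$ari, weights = weights))
}

#' Differential-feature workflow over a saved model
#'
#' Loads the model bundle written by a clustering/integration run and
#' emits per-view feature weight tables and a combined ranked list.
#'
#' @param model Path to `model.rds` or an `hci_fit`.
#' @param outdir Output directory, or `NULL`.
#' @param config A `RunConfig` (for the cv quantile).
#' @param views Expression-view names to analyze; default: every view
#'   whose local pattern has feature loadings (the non-correlation views).
#' @return Invisibly, the named list of selected `FeatureWeightTable`s.
#' @export
run_hci_features <- function(model, outdir = NULL, config = run_config(),
                             views = NULL) {
  fit <- if (inherits(model, "hci_fit")) model else {
    if (!file.exists(model)) stop("model bundle not found: ", model, call. = FALSE)
    readRDS(model)
  }
  stopifnot(inherits(fit, "hci_fit"))
  nms <- vapply(fit$locals, `[[`, "", "view_name")
  if (is.null(views)) views <- nms[!grepl("\\.F[0-9]+$", nms)]
  tabs <- lapply(views, function(vn) {
    select_differential(cv_weights(fit, view = vn), quantile = config$cv_quantile)
  })
  names(tabs) <- views
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (vn in views) {
      write_feature_weights(tabs[[vn]],
                            file.path(outdir, paste0("weights_", vn, ".tsv")))
    }
    do.call(export_edges, c(unname(tabs),
                            list(path = file.path(outdir, "ranked_features.tsv"))))
  }
  invisible(tabs)
}

#' Fixture-generation workflow
#'
#' Simulates a labeled dataset (single- or multi-view per
#' `spec$n_views`) and writes the same dense TSV and label formats the
#' loaders read.
#'
#' @param spec A `SyntheticSpec`.
#' @param outdir Output directory.
#' @return Invisibly, the simulated object.
#' @export
run_hci_simulate <- function(spec, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (spec$n_views >= 2) {
    sim <- simulate_multiview(spec)
    for (i in seq_along(sim$views)) {
      write_expression(sim$views[[i]],
                       file.path(outdir, sprintf("view%d.tsv", i)))
    }
  } else {
    sim <- simulate_expression(spec)
    write_expression(sim$X, file.path(outdir, "expression.tsv"))
  }
  write_labels(sim$labels, file.path(outdir, "labels.tsv"))
  jsonlite::write_json(unclass(spec), file.path(outdir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}
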