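#' Coefficient of variation of loading rows
#'
#' Ranks the molecules of an expression view by how unevenly they load on
#' the pattern dimensions: for each feature row of the loading matrix,
#' `cv = sd / |mean|`. Features that drive the sample separation load
#' strongly on a few dimensions and weakly elsewhere, giving a large cv;
#' background features load diffusely. By default the loadings analyzed
#' are the view's loadings adjusted to the global pattern (the regression
#' of the centered view onto the fused pattern), so the ranking reflects
#' the integrated model rather than a single view; `use_alignment = FALSE`
#' ranks on the raw local eigenvector loadings instead.
#'
#' Because factor loadings are sign-indeterminate (each eigenvector is
#' defined up to its sign) and sign-mixed within a row, the default
#' statistic is computed on the loading magnitudes: `mu = mean(|u|)`,
#' `delta = sd(|u|)`, `cv = delta / mu`. On all-positive rows this is the
#' plain sd-over-mean ratio; on sign-mixed rows it avoids the degenerate
#' division by a near-zero signed mean, which would hand the largest cv
#' values to featureless rows whose positive and negative loadings happen
#' to cancel. `signed_mean = TRUE` switches to the raw signed statistic.
#' Rows whose mean weight is below 1e-12 in magnitude get `cv = Inf` and
#' are excluded from default selection.
#'
#' @param fit An `hci_fit`, or a single `LocalPattern` (then
#'   `use_alignment` is ignored).
#' @param view Name of the expression view to analyze (default: the first
#'   local pattern, which is the first expression view).
#' @param use_alignment Use globally adjusted loadings (default `TRUE`).
#' @param signed_mean Compute sd/mean on the raw signed loadings instead
#'   of their magnitudes.
#' @return A `FeatureWeightTable`: data.frame with columns `feature_id`,
#'   `view_name`, `mean_weight`, `sd_weight`, `cv`, `selected` (all
#'   `FALSE` until [select_differential()] is applied), carrying the
#'   threshold used as attribute `"threshold"` once selected.
#' @export
cv_weights <- function(fit, view = NULL, use_alignment = TRUE,
                       signed_mean = FALSE) {
  if (inherits(fit, "LocalPattern")) {
    local <- fit
    U <- local$loadings
    vn <- local$view_name
  } else {
    stopifnot(inherits(fit, "hci_fit"))
    nms <- vapply(fit$locals, `[[`, character(1), "view_name")
    if (is.null(view)) view <- nms[1]
    idx <- match(view, nms)
    if (is.na(idx)) {
      stop("no view named '", view, "'; available: ",
           paste(nms, collapse = ", "), call. = FALSE)
    }
    local <- fit$locals[[idx]]
    if (use_alignment) {
      # loadings adjusted to the global pattern: W - c1' ~ U* Y_global.
      # Columns are rescaled to unit norm afterwards so all pattern
      # dimensions weigh in on a comparable scale, as they do for the
      # orthonormal local eigenvector loadings: raw regression
      # coefficients on low-eigenvalue dimensions have inflated variance
      # and would swamp the row statistic.
      Yg <- fit$global$pattern
      C <- local$loadings %*% local$pattern  # centered view, rank-d
      G <- tcrossprod(Yg)
      U <- t(solve(G + diag(1e-12 * max(diag(G)), nrow(G)),
                   Yg %*% t(C)))
      cn <- sqrt(colSums(U^2))
      U <- sweep(U, 2, pmax(cn, 1e-12), "/")
      rownames(U) <- rownames(local$loadings)
    } else {
      U <- local$loadings
    }
    vn <- local$view_name
  }
  if (ncol(U) < 2) {
    stop("CV undefined for one-dimensional loadings (view '", vn, "')",
         call. = FALSE)
  }
  Um <- if (signed_mean) U else abs(U)
  mu <- rowMeans(Um)
  sdv <- apply(Um, 1, stats::sd)
  cv <- ifelse(abs(mu) < 1e-12, Inf, sdv / mu)
  out <- data.frame(feature_id = rownames(U), view_name = vn,
                    mean_weight = mu, sd_weight = sdv, cv = cv,
                    selected = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("FeatureWeightTable", "data.frame")
  out
}

#' Call differential features by cv threshold
#'
#' Flags features whose loading-row coefficient of variation is strictly
#' greater than the threshold `T`. By default `T` is the 90th percentile of
#' the finite cv values in the table, so a selection is defined on any
#' dataset; pass an absolute value to override. Features with infinite cv
#' (near-zero mean weight) are never selected.
#'
#' @param table A `FeatureWeightTable` from [cv_weights()].
#' @param threshold Absolute cv threshold, or `NULL` for the
#'   `quantile`-quantile default.
#' @param quantile Quantile used when `threshold` is `NULL` (default 0.9).
#' @return The table with `selected` set; attributes `"threshold"` and
#'   `"n_selected"` record the cut.
#' @export
select_differential <- function(table, threshold = NULL, quantile = 0.9) {
  stopifnot(inherits(table, "FeatureWeightTable"))
  finite <- is.finite(table$cv)
  if (is.null(threshold)) {
    if (!any(finite)) stop("no finite cv values to take a quantile of",
                           call. = FALSE)
    threshold <- stats::quantile(table$cv[finite], quantile, names = FALSE)
  }
  table$selected <- finite & table$cv > threshold
  attr(table, "threshold") <- threshold
  attr(table, "n_selected") <- sum(table$selected)
  table
}

#' Export ranked differential-feature lists
#'
#' Writes the selected features of one or more views as a single ranked
#' table (descending cv, ties broken by feature id) for downstream network
#' or enrichment tools; no external database is queried.
#'
#' @param ... One or more `FeatureWeightTable`s (e.g. selected mRNAs and
#'   selected miRNAs from the same fitted model).
#' @param path Output path for the TSV.
#' @param selected_only Keep only rows flagged by [select_differential()]
#'   (default `TRUE`).
#' @return The combined ranked data.frame, invisibly.
#' @export
export_edges <- function(..., path, selected_only = TRUE) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1,
            all(vapply(tabs, inherits, logical(1), "FeatureWeightTable")))
  all <- do.call(rbind, lapply(tabs, function(t) as.data.frame(t)))
  if (selected_only) all <- all[all$selected, , drop = FALSE]
  if (!nrow(all)) warning("empty selection: writing an empty list", call. = FALSE)
  ord <- order(-all$cv, all$feature_id)
  all <- all[ord, c("feature_id", "view_name", "cv", "mean_weight", "sd_weight"),
             drop = FALSE]
  utils::write.table(all, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(all)
}

#' Write a feature weight table as TSV
#'
#' @param table A `FeatureWeightTable`.
#' @param path Output path.
#' @export
write_feature_weights <- function(table, path) {
  stopifnot(inherits(table, "FeatureWeightTable"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
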