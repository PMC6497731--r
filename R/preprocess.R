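#' Remove features with zero expression everywhere
#'
#' Drops every row whose entries are all exactly zero; such features carry
#' no information for sample clustering. Row order of survivors is
#' preserved.
#'
#' @param X An `ExpressionMatrix`.
#' @return A filtered `ExpressionMatrix`.
#' @export
filter_zero_features <- function(X) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  keep <- rowSums(X$values != 0) > 0
  if (!any(keep)) stop("no informative features: all rows are zero", call. = FALSE)
  expression_matrix(X$values[keep, , drop = FALSE], view_name = X$view_name)
}

#' Remove features that are mostly zero
#'
#' Drops rows whose fraction of zero entries is strictly greater than
#' `max_zero_fraction`. The default of 0.8 removes features with more than
#' 80% zeros across samples, the filter applied to each omics level before
#' multi-view integration; a row with exactly the threshold fraction is
#' kept. All-zero rows are always removed (they carry no information at
#' any threshold).
#'
#' @param X An `ExpressionMatrix`.
#' @param max_zero_fraction Maximum tolerated zero fraction in `[0, 1]`.
#' @return A filtered `ExpressionMatrix`.
#' @export
filter_sparse_features <- function(X, max_zero_fraction = 0.8) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (!is.numeric(max_zero_fraction) || max_zero_fraction < 0 ||
      max_zero_fraction > 1) {
    stop("max_zero_fraction must be in [0, 1]", call. = FALSE)
  }
  zf <- rowMeans(X$values == 0)
  keep <- zf <= max_zero_fraction & zf < 1
  if (!any(keep)) stop("no informative features after sparsity filter", call. = FALSE)
  expression_matrix(X$values[keep, , drop = FALSE], view_name = X$view_name)
}

#' Normalize each sample column
#'
#' Per-column standardization so that samples are on a comparable scale
#' before factorization. `"zscore"` centers and scales each column to mean
#' 0 and unit sample variance; `"log1p-zscore"` applies `log(x + 1)` first,
#' appropriate for nonnegative count-like units (FPKM/CPM/UMI counts);
#' `"none"` returns the input unchanged.
#'
#' @param X An `ExpressionMatrix`.
#' @param method `"log1p-zscore"` (default), `"zscore"`, or `"none"`.
#' @return An `ExpressionMatrix` of identical shape and identifiers.
#' @export
normalize_columns <- function(X, method = c("log1p-zscore", "zscore", "none")) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  method <- match.arg(method)
  if (method == "none") return(X)
  v <- X$values
  if (method == "log1p-zscore") {
    if (any(v < 0)) {
      stop("log1p-zscore requires nonnegative values; use method = 'zscore'",
           call. = FALSE)
    }
    v <- log1p(v)
  }
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  zero_var <- sdv < .Machine$double.eps
  if (any(zero_var)) {
    stop("zero-variance column(s) under zscore: ",
         paste(utils::head(colnames(v)[zero_var], 5), collapse = ", "),
         call. = FALSE)
  }
  v <- sweep(sweep(v, 2, mu, "-"), 2, sdv, "/")
  expression_matrix(v, view_name = X$view_name)
}

#' Keep the most variable features
#'
#' Retains the `ceiling(fraction * m)` rows with the largest per-row sample
#' variance (or coefficient of variation with `use_cv = TRUE`), the
#' high-variability gene subsets used in robustness experiments. Ties at
#' the cut are broken in favor of the earlier row; surviving rows keep
#' their original order.
#'
#' @param X An `ExpressionMatrix`.
#' @param fraction Fraction of rows to keep, in `(0, 1]`.
#' @param use_cv If `TRUE` rank rows by sd/mean instead of variance.
#' @return A filtered `ExpressionMatrix`.
#' @export
select_top_variable_features <- function(X, fraction, use_cv = FALSE) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  m <- nrow(X$values)
  n_keep <- ceiling(fraction * m)
  score <- apply(X$values, 1, stats::var)
  if (use_cv) {
    mu <- rowMeans(X$values)
    score <- sqrt(score) / abs(mu)
  }
  # stable order: ties resolved by original row index
  top <- order(-score, seq_len(m))[seq_len(n_keep)]
  keep <- sort(top)
  expression_matrix(X$values[keep, , drop = FALSE], view_name = X$view_name)
}
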