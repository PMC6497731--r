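#' Minimal dimension reaching a cumulative eigenvalue ratio
#'
#' Scans the prefix sums of a nonincreasing positive spectrum and returns
#' the smallest d such that the first d eigenvalues carry at least
#' `threshold` of the total. Defaults elsewhere in the package: 0.8 for
#' expression views, 0.9 for correlation views (whose feature dimension is
#' the sample count, not the gene count).
#'
#' @param eigenvalues Nonincreasing positive numeric vector.
#' @param threshold Cumulative variance ratio in `(0, 1]`.
#' @return Integer dimension.
#' @export
choose_dim <- function(eigenvalues, threshold) {
  if (length(eigenvalues) == 0) stop("empty eigenvalue list", call. = FALSE)
  if (any(eigenvalues <= 0)) stop("eigenvalues must be positive", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  ratio <- cumsum(eigenvalues) / sum(eigenvalues)
  as.integer(which(ratio >= threshold - 1e-12)[1])
}

# Deterministic eigenvector sign: largest-magnitude entry positive.
fix_signs <- function(U) {
  s <- apply(U, 2, function(u) sign(u[which.max(abs(u))]))
  s[s == 0] <- 1
  sweep(U, 2, s, "*")
}

#' Local pattern extraction for one view
#'
#' Centers the view on its per-feature means and finds the best rank-d
#' approximation `W ~ c 1' + U Y` in Frobenius norm: `U` holds the top-d
#' eigenvectors of the centered outer product `(W - c1')(W - c1')'` and
#' `Y = U'(W - c1')` is the view's low-dimensional sample pattern. The
#' dimension d is the smallest one whose eigenvalues carry at least
#' `variance_threshold` of the total nonzero spectrum.
#'
#' When the view has many more features than samples the eigendecomposition
#' is done on the n x n Gram matrix `(W - c1')'(W - c1')`, which has the
#' same nonzero spectrum.
#'
#' @param W Numeric view matrix (features x samples), or an
#'   `ExpressionMatrix` / `CorrelationMatrix`.
#' @param variance_threshold Cumulative eigenvalue ratio in `(0, 1]`.
#' @param view_name View tag recorded on the result.
#' @return A `LocalPattern`: list with `view_name`, `center`, `loadings`
#'   (features x d, orthonormal), `pattern` (d x n), `eigenvalues` (all
#'   nonzero, nonincreasing), `dim`, `variance_threshold`.
#' @export
local_decompose <- function(W, variance_threshold = 0.8, view_name = NULL) {
  if (inherits(W, "ExpressionMatrix")) {
    if (is.null(view_name)) view_name <- W$view_name
    W <- W$values
  } else if (inherits(W, "CorrelationMatrix")) {
    if (is.null(view_name)) view_name <- paste0("F", W$order)
    W <- W$values
  }
  if (is.null(view_name)) view_name <- "view"
  stopifnot(is.matrix(W), is.numeric(W))
  if (ncol(W) < 2) stop("view needs >= 2 samples", call. = FALSE)
  if (!all(is.finite(W))) stop("view contains non-finite entries", call. = FALSE)

  m <- nrow(W); n <- ncol(W)
  ctr <- rowMeans(W)
  C <- W - ctr

  if (m > n) {
    # dual route: eigen of C'C shares the nonzero spectrum of CC'
    eg <- eigen(crossprod(C), symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    nz <- vals > 1e-10 * max(vals, .Machine$double.eps)
    if (!any(nz)) stop("degenerate view: centered matrix has rank 0", call. = FALSE)
    vals <- vals[nz]
    d <- choose_dim(vals, variance_threshold)
    V <- eg$vectors[, which(nz)[seq_len(d)], drop = FALSE]
    U <- C %*% V %*% diag(1 / sqrt(vals[seq_len(d)]), d)
  } else {
    eg <- eigen(tcrossprod(C), symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    nz <- vals > 1e-10 * max(vals, .Machine$double.eps)
    if (!any(nz)) stop("degenerate view: centered matrix has rank 0", call. = FALSE)
    vals <- vals[nz]
    d <- choose_dim(vals, variance_threshold)
    U <- eg$vectors[, which(nz)[seq_len(d)], drop = FALSE]
  }
  U <- fix_signs(U)
  Y <- crossprod(U, C)
  rownames(U) <- rownames(W)
  colnames(Y) <- colnames(W)
  structure(list(view_name = view_name, center = ctr, loadings = U,
                 pattern = Y, eigenvalues = vals, dim = d,
                 variance_threshold = variance_threshold),
            class = "LocalPattern")
}

#' @export
print.LocalPattern <- function(x, ...) {
  cat(sprintf("LocalPattern '%s': dim %d of %d nonzero eigenvalues (>= %.0f%% variance)\n",
              x$view_name, x$dim, length(x$eigenvalues),
              100 * x$variance_threshold))
  invisible(x)
}

# Pad a d_i x n pattern with zero rows up to d rows.
pad_rows <- function(Y, d) {
  if (nrow(Y) == d) return(Y)
  rbind(Y, matrix(0, d - nrow(Y), ncol(Y)))
}

#' Align local patterns into the global sample-pattern matrix
#'
#' Fuses the per-view local patterns `Y_i` into one global d x n pattern
#' `Y` by adaptively weighted generalized Procrustes alignment: block
#' coordinate descent on `sum_i w_i ||Y - A_i Y_i||_F^2` where each view
#' map `A_i` is constrained to have orthonormal columns. Given `Y`, the
#' optimal `A_i` is the polar factor of `Y Y_i'` (Procrustes rotation);
#' given the maps, `Y` is the weight-averaged image `sum_i w_i A_i Y_i`;
#' the weights are then refreshed as `w_i ~ exp(-r_i / lambda)` with `r_i`
#' the view's residual, so views that disagree with the consensus (noisy
#' or uninformative ones) are down-weighted. The orthogonality constraint
#' matters: an unconstrained regression would let any view whose local
#' dimension equals the global dimension reproduce `Y` exactly and absorb
#' all the weight, so no fusion would happen. Local patterns are first
#' rescaled to a common Frobenius norm (the mean of the views' norms, so
#' identical views are left untouched) because the views live in
#' different units.
#'
#' The three steps are exact block minimizers of the single objective
#' `sum_i w_i r_i + lambda * sum_i w_i log w_i` over the weight simplex
#' (the softmax weight update is the closed-form minimizer of the
#' entropy-regularized weighted residual), so the objective trace is
#' monotonically nonincreasing; its relative change is the convergence
#' criterion. The temperature `lambda` is fixed at the mean per-view
#' residual of the first sweep: entropy regularization at the natural
#' residual scale keeps the weights interior, whereas raw
#' inverse-residual weights degenerate to winner-take-all (the best
#' fitting view absorbs weight 1 and the "fusion" returns that single
#' view).
#'
#' @param locals List of `LocalPattern` objects over the same samples in
#'   the same order.
#' @param target_dim Global dimension d; default the maximum of the local
#'   dims. Patterns with fewer rows are padded with zero rows.
#' @param tol Relative change of the surrogate objective at which to stop.
#' @param max_iter Maximum number of sweeps.
#' @param eps Numerical floor for the weight temperature `lambda`.
#' @return A `GlobalPattern`: list with `pattern` (d x n), `view_maps`
#'   (list of d x d_i matrices with orthonormal columns), `view_weights`
#'   (nonnegative, sum 1), `residuals` (final per-view squared Frobenius
#'   residuals), `view_scales` (per-view norm-equalization factors),
#'   `objective_trace`, `n_iter`, `converged`.
#' @export
align_patterns <- function(locals, target_dim = NULL, tol = 1e-6,
                           max_iter = 100L, eps = 1e-8) {
  if (!length(locals)) stop("need >= 1 local pattern", call. = FALSE)
  if (inherits(locals, "LocalPattern")) locals <- list(locals)
  stopifnot(all(vapply(locals, inherits, logical(1), "LocalPattern")))
  ns <- vapply(locals, function(l) ncol(l$pattern), integer(1))
  if (length(unique(ns)) != 1) {
    stop("sample counts differ across views: ",
         paste(sprintf("%s=%d", vapply(locals, `[[`, "", "view_name"), ns),
               collapse = ", "), call. = FALSE)
  }
  nm <- vapply(locals, `[[`, character(1), "view_name")
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  names(locals) <- nm

  dims <- vapply(locals, `[[`, integer(1), "dim")
  d <- if (is.null(target_dim)) max(dims) else as.integer(target_dim)
  n <- ns[1]
  N <- length(locals)

  if (N == 1) {
    Y <- pad_rows(locals[[1]]$pattern, d)
    return(structure(list(pattern = Y,
                          view_maps = stats::setNames(list(diag(d)[, seq_len(dims[1]), drop = FALSE]), nm),
                          view_weights = stats::setNames(1, nm),
                          residuals = stats::setNames(0, nm),
                          view_scales = stats::setNames(1, nm),
                          objective_trace = numeric(0),
                          n_iter = 0L, converged = TRUE),
                     class = "GlobalPattern"))
  }

  Ys <- lapply(locals, `[[`, "pattern")
  # equalize view scales: rescale every pattern to the mean Frobenius norm
  norms <- vapply(Ys, function(Yi) sqrt(sum(Yi^2)), numeric(1))
  if (any(norms <= 0)) stop("degenerate local pattern with zero norm", call. = FALSE)
  scales <- mean(norms) / norms
  Ys <- Map(function(Yi, s) Yi * s, Ys, scales)
  # initialize from the view with the largest local dimension
  Y <- pad_rows(Ys[[which.max(dims)]], d)
  w <- rep(1 / N, N)
  A <- vector("list", N)
  obj <- numeric(0)
  converged <- FALSE
  it <- 0L
  resid_of <- function(Y) {
    vapply(seq_len(N), function(i) sum((Y - A[[i]] %*% Ys[[i]])^2), numeric(1))
  }
  lambda <- NA_real_
  softmax_w <- function(r) {
    e <- exp(-(r - min(r)) / lambda)
    e / sum(e)
  }
  for (it in seq_len(max_iter)) {
    # A-step: Procrustes rotation, the orthonormal-column minimizer of
    # ||Y - A_i Y_i||_F given Y (polar factor of Y Y_i')
    for (i in seq_len(N)) {
      sv <- svd(tcrossprod(Y, Ys[[i]]))
      A[[i]] <- sv$u %*% t(sv$v)
    }
    r_pre <- resid_of(Y)
    if (it == 1) lambda <- max(mean(r_pre), eps)
    # w-step: entropy-regularized closed form at the current residuals
    w <- softmax_w(r_pre)
    # Y-step: weighted average of the mapped views
    Y <- matrix(0, d, n)
    for (i in seq_len(N)) Y <- Y + w[i] * (A[[i]] %*% Ys[[i]])
    r <- resid_of(Y)
    obj <- c(obj, sum(w * r) + lambda * sum(w * log(pmax(w, 1e-300))))
    if (it > 1 && abs(obj[it] - obj[it - 1]) <=
        tol * max(abs(obj[it - 1]), 1)) {
      converged <- TRUE
      break
    }
  }
  # adaptive weights at the final pattern
  w <- softmax_w(r)
  colnames(Y) <- colnames(Ys[[1]])
  structure(list(pattern = Y,
                 view_maps = stats::setNames(A, nm),
                 view_weights = stats::setNames(w, nm),
                 residuals = stats::setNames(r, nm),
                 view_scales = stats::setNames(scales, nm),
                 objective_trace = obj,
                 n_iter = it, converged = converged),
            class = "GlobalPattern")
}

#' @export
print.GlobalPattern <- function(x, ...) {
  cat(sprintf("GlobalPattern: %d x %d; %d views; %d iterations (%s)\n",
              nrow(x$pattern), ncol(x$pattern), length(x$view_weights),
              x$n_iter, if (x$converged) "converged" else "not converged"))
  if (length(x$view_weights) > 1) {
    cat("  weights:", paste(sprintf("%s=%.3f", names(x$view_weights),
                                    x$view_weights), collapse = " "), "\n")
  }
  invisible(x)
}

#' Fit the high-order correlation integration model
#'
#' The full fusion pipeline: for each input expression view, compute its
#' first- and second-order sample-correlation matrices (up to `max_order`),
#' extract a local pattern from the expression matrix (cumulative variance
#' threshold `var_threshold_x`) and from each correlation matrix
#' (`var_threshold_f`), then align all local patterns into the global
#' sample-pattern matrix on which clustering operates. With `max_order = 0`
#' no correlation views are added and the fit reduces to a plain one-view
#' (or plain multi-view) factorization.
#'
#' @param x An `ExpressionMatrix` or a list of them sharing sample ids
#'   (multi-omics views). Views are aligned on the intersection of their
#'   sample ids, in the order of the first view.
#' @param max_order Highest correlation order to include (0 = none).
#' @param var_threshold_x Cumulative variance threshold for expression
#'   views (default 0.8).
#' @param var_threshold_f Threshold for correlation views (default 0.9).
#' @param target_dim,tol,max_iter Passed to [align_patterns()].
#' @param on_constant Passed to the correlation constructor.
#' @return An `hci_fit` object: list with `global` (a `GlobalPattern`),
#'   `locals` (all `LocalPattern`s), `sample_ids`, and the thresholds used.
#' @export
hci_fit <- function(x, max_order = 2L, var_threshold_x = 0.8,
                    var_threshold_f = 0.9, target_dim = NULL,
                    tol = 1e-6, max_iter = 100L,
                    on_constant = c("error", "zero")) {
  on_constant <- match.arg(on_constant)
  views <- if (inherits(x, "ExpressionMatrix")) list(x) else x
  stopifnot(length(views) >= 1,
            all(vapply(views, inherits, logical(1), "ExpressionMatrix")))
  vn <- vapply(views, `[[`, character(1), "view_name")
  if (anyDuplicated(vn)) vn <- make.unique(vn)

  # align all views on the shared sample set, ordered as in the first view
  shared <- Reduce(intersect, lapply(views, function(v) colnames(v$values)))
  if (length(shared) < 3) {
    stop("fewer than 3 shared samples across views", call. = FALSE)
  }
  views <- lapply(views, function(v) {
    expression_matrix(v$values[, shared, drop = FALSE], view_name = v$view_name)
  })

  locals <- list()
  for (i in seq_along(views)) {
    v <- views[[i]]
    lp <- tryCatch(
      local_decompose(v$values, var_threshold_x, view_name = vn[i]),
      error = function(e) stop("stage local_decompose [", vn[i], "]: ",
                               conditionMessage(e), call. = FALSE))
    locals[[length(locals) + 1]] <- lp
    if (max_order >= 1) {
      fs <- tryCatch(
        high_order_correlation(v, max_order = max_order,
                               on_constant = on_constant),
        error = function(e) stop("stage hocorr [", vn[i], "]: ",
                                 conditionMessage(e), call. = FALSE))
      for (k in seq_along(fs)) {
        lp <- tryCatch(
          local_decompose(fs[[k]]$values, var_threshold_f,
                          view_name = paste0(vn[i], ".F", k)),
          error = function(e) stop("stage local_decompose [", vn[i], ".F", k,
                                   "]: ", conditionMessage(e), call. = FALSE))
        locals[[length(locals) + 1]] <- lp
      }
    }
  }
  global <- tryCatch(
    align_patterns(locals, target_dim = target_dim, tol = tol,
                   max_iter = max_iter),
    error = function(e) stop("stage align_patterns: ", conditionMessage(e),
                             call. = FALSE))
  structure(list(global = global, locals = locals, sample_ids = shared,
                 max_order = as.integer(max_order),
                 var_threshold_x = var_threshold_x,
                 var_threshold_f = var_threshold_f),
            class = "hci_fit")
}

#' @export
print.hci_fit <- function(x, ...) {
  cat(sprintf("hci_fit: %d samples, %d local views, global dim %d\n",
              length(x$sample_ids), length(x$locals), nrow(x$global$pattern)))
  invisible(x)
}

#' Export the global sample-pattern matrix as TSV
#'
#' @param fit An `hci_fit` or `GlobalPattern`.
#' @param path Output path; one row per pattern dimension, columns are
#'   samples.
#' @export
write_pattern <- function(fit, path) {
  g <- if (inherits(fit, "hci_fit")) fit$global else fit
  stopifnot(inherits(g, "GlobalPattern"))
  df <- data.frame(dimension = paste0("dim", seq_len(nrow(g$pattern))),
                   g$pattern, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("dimension", colnames(g$pattern))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
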