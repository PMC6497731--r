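#' Construct an ExpressionMatrix
#'
#' The basic data container of the package: a numeric feature-by-sample
#' matrix (genes, miRNAs or probes in rows; cells or patients in columns)
#' together with unique identifiers on both axes and a view tag naming the
#' data level (e.g. `"mRNA"`, `"miRNA"`, `"methylation"`).
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param feature_ids Character vector of unique row identifiers. Defaults
#'   to `rownames(values)`.
#' @param sample_ids Character vector of unique column identifiers. Defaults
#'   to `colnames(values)`.
#' @param view_name Single string tagging the data level.
#' @param impute_zero If `TRUE`, missing entries are replaced by 0 with a
#'   warning; if `FALSE` (default) missing values are an error.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix, with dimnames set), and `view_name`.
#' @export
expression_matrix <- function(values, feature_ids = rownames(values),
                              sample_ids = colnames(values),
                              view_name = "expression",
                              impute_zero = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("feature and sample identifiers are required", call. = FALSE)
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values)) {
    stop("length(feature_ids) must equal nrow(values)", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) must equal ncol(values)", call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) {
    dup <- unique(feature_ids[duplicated(feature_ids)])
    stop("duplicate feature identifiers: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicate sample identifiers: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) {
    if (impute_zero) {
      n_na <- sum(is.na(values))
      warning(sprintf("imputed %d missing entries to 0", n_na), call. = FALSE)
      values[is.na(values)] <- 0
    } else {
      stop("matrix contains missing values (use impute_zero = TRUE to zero-fill)",
           call. = FALSE)
    }
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(values = values, view_name = as.character(view_name)[1]),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix '%s': %d features x %d samples\n",
              x$view_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Load an expression matrix from disk
#'
#' Reads either a dense delimited table (first column feature ids, header
#' row sample ids) or a Matrix Market coordinate triplet with companion
#' one-id-per-line feature and sample files, as written by droplet
#' platforms.
#'
#' @param path Path to the matrix file (`.tsv`/`.csv` dense table, or `.mtx`).
#' @param format One of `"auto"`, `"dense-tsv"`, `"dense-csv"`,
#'   `"mtx-triplet"`. `"auto"` guesses from the file extension.
#' @param feature_path,sample_path For `mtx-triplet` only: companion id
#'   files. Default to `features.tsv`/`genes.tsv` and `barcodes.tsv` next to
#'   the matrix file.
#' @param view_name View tag passed to [expression_matrix()].
#' @param impute_zero Passed to [expression_matrix()].
#'
#' @return An `ExpressionMatrix`.
#' @export
load_expression <- function(path,
                            format = c("auto", "dense-tsv", "dense-csv", "mtx-triplet"),
                            feature_path = NULL, sample_path = NULL,
                            view_name = "expression", impute_zero = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     mtx = "mtx-triplet",
                     csv = "dense-csv",
                     "dense-tsv")
  }
  if (format == "mtx-triplet") {
    dir <- dirname(path)
    if (is.null(feature_path)) {
      for (cand in file.path(dir, c("features.tsv", "genes.tsv"))) {
        if (file.exists(cand)) { feature_path <- cand; break }
      }
    }
    if (is.null(sample_path)) {
      cand <- file.path(dir, "barcodes.tsv")
      if (file.exists(cand)) sample_path <- cand
    }
    if (is.null(feature_path) || !file.exists(feature_path)) {
      stop("mtx-triplet input needs a feature id file (features.tsv/genes.tsv)",
           call. = FALSE)
    }
    if (is.null(sample_path) || !file.exists(sample_path)) {
      stop("mtx-triplet input needs a sample id file (barcodes.tsv)", call. = FALSE)
    }
    m <- tryCatch(Matrix::readMM(path), error = function(e) {
      stop("malformed Matrix Market file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
    feats <- utils::read.table(feature_path, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    samps <- utils::read.table(sample_path, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (length(feats) != nrow(m)) {
      stop(sprintf("feature file has %d ids but matrix has %d rows",
                   length(feats), nrow(m)), call. = FALSE)
    }
    if (length(samps) != ncol(m)) {
      stop(sprintf("sample file has %d ids but matrix has %d columns",
                   length(samps), ncol(m)), call. = FALSE)
    }
    return(expression_matrix(as.matrix(m), feats, samps, view_name,
                             impute_zero = impute_zero))
  }
  sep <- if (format == "dense-csv") "," else "\t"
  tab <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "",
                      quote = "\""),
    error = function(e) {
      stop("malformed table '", path, "': ", conditionMessage(e), call. = FALSE)
    })
  if (ncol(tab) < 2) stop("dense table needs a feature id column plus >= 1 sample",
                          call. = FALSE)
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!apply(tab[, -1, drop = FALSE], 2, is.numeric))
    stop("non-numeric expression values in column(s): ",
         paste(names(bad), collapse = ", "), call. = FALSE)
  }
  expression_matrix(vals, ids, colnames(tab)[-1], view_name,
                    impute_zero = impute_zero)
}

#' Load per-sample labels
#'
#' Reads a two-column table (`sample_id`, `label`) with or without a header.
#'
#' @param path Path to a TSV file.
#' @return A named character vector of labels, names = sample ids.
#' @export
load_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2) stop("label file must have two columns (sample_id, label)",
                          call. = FALSE)
  if (identical(tolower(as.character(tab[1, 1])), "sample_id")) {
    tab <- tab[-1, , drop = FALSE]
  }
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Write an expression matrix as a dense TSV
#'
#' Inverse of the dense-TSV reader: first column `feature_id`, header row of
#' sample ids.
#'
#' @param X An `ExpressionMatrix`.
#' @param path Output path.
#' @export
write_expression <- function(X, path) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  df <- data.frame(feature_id = rownames(X$values), X$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample labels as a two-column TSV
#'
#' @param labels Named vector (names = sample ids) or unnamed vector with
#'   `sample_ids` given.
#' @param path Output path.
#' @param sample_ids Optional explicit sample ids.
#' @export
write_labels <- function(labels, path, sample_ids = names(labels)) {
  if (is.null(sample_ids)) stop("sample ids required", call. = FALSE)
  df <- data.frame(sample_id = sample_ids, label = as.character(labels),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
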