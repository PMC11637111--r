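#' Construct a regression dataset
#'
#' A `reg_dataset` bundles a fully numeric predictor matrix, a response
#' vector and a family hint. The family hint records what kind of response
#' the dataset carries: `"gaussian"` for an unconstrained continuous
#' response, `"unit_interval"` for a response that must lie strictly inside
#' (0, 1), as required by the beta-family models.
#'
#' @param X numeric matrix of predictors (n rows, p named columns), no
#'   missing entries.
#' @param y numeric response of length `nrow(X)`.
#' @param family_hint `"gaussian"` or `"unit_interval"`.
#' @param provenance free-text source tag (file path, generator call, ...).
#'
#' @return An object of class `reg_dataset` with elements `X`, `y`,
#'   `family_hint`, `column_names`, `n`, `p`, `provenance`.
#' @export
reg_dataset <- function(X, y, family_hint = c("gaussian", "unit_interval"),
                        provenance = "") {
  family_hint <- match.arg(family_hint)
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("predictor matrix must be numeric")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed in a reg_dataset")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  cn <- colnames(X)
  if (is.null(cn)) {
    cn <- paste0("x", seq_len(ncol(X)))
    colnames(X) <- cn
  }
  if (anyDuplicated(cn)) stop("duplicate predictor column names: ",
                              paste(unique(cn[duplicated(cn)]), collapse = ", "))
  if (family_hint == "unit_interval" && (any(y <= 0) || any(y >= 1)))
    stop("family_hint = 'unit_interval' requires every response strictly inside (0, 1)")
  structure(list(X = X, y = as.numeric(y), family_hint = family_hint,
                 column_names = cn, n = nrow(X), p = ncol(X),
                 provenance = provenance),
            class = "reg_dataset")
}

#' @export
print.reg_dataset <- function(x, ...) {
  cat("<reg_dataset> ", x$n, " records, ", x$p, " predictors (",
      x$family_hint, " response)\n", sep = "")
  cat("  predictors: ", paste(x$column_names, collapse = ", "), "\n", sep = "")
  if (nzchar(x$provenance)) cat("  source: ", x$provenance, "\n", sep = "")
  invisible(x)
}

# n >= p + 2 guard shared by the fitting functions
check_fittable <- function(dataset) {
  if (dataset$n < dataset$p + 2)
    stop("need at least p + 2 = ", dataset$p + 2, " complete rows, got ", dataset$n)
  invisible(dataset)
}

#' Load a delimited diagnostic table
#'
#' Reads a comma-delimited text file with a header row and builds a
#' [reg_dataset()] from the named response and predictor columns. Rows with
#' missing or non-numeric entries in any requested column abort the load
#' (with the offending row and column named) rather than being dropped
#' silently; the source table this loader targets has none.
#'
#' @param path path to a CSV file (header row, UTF-8).
#' @param response_column name of the response column.
#' @param predictor_columns character vector of predictor column names.
#'   Character columns (such as a B/M diagnosis label) are accepted and
#'   encoded via [encode_diagnosis()].
#' @param family_hint passed to [reg_dataset()].
#' @return A [reg_dataset()].
#' @export
load_table <- function(path, response_column, predictor_columns,
                       family_hint = "gaussian") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  wanted <- c(response_column, predictor_columns)
  missing_cols <- setdiff(wanted, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  sub <- raw[, wanted, drop = FALSE]
  num <- lapply(wanted, function(cl) {
    v <- sub[[cl]]
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      if (all(v %in% c("B", "M"))) return(encode_diagnosis(v))
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) & !anyNA(v)) {
        bad <- which(is.na(vn))[1L]
        stop("non-numeric value ", dQuote(v[bad]), " in column ", dQuote(cl),
             ", row ", bad)
      }
      v <- vn
    }
    v
  })
  names(num) <- wanted
  na_rows <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(na_rows))
    stop("missing value(s) in requested columns at row(s) ",
         paste(utils::head(na_rows, 5), collapse = ", "),
         "; rows with missing values are rejected, not dropped")
  X <- do.call(cbind, num[predictor_columns])
  colnames(X) <- predictor_columns
  ds <- reg_dataset(X, num[[response_column]], family_hint, provenance = path)
  check_fittable(ds)
}

#' Write a dataset back to delimited text
#'
#' Writes response and predictors as CSV with 17 significant digits so a
#' re-load through [load_table()] reproduces every double exactly.
#'
#' @param dataset a [reg_dataset()].
#' @param path output file.
#' @param response_name column name used for the response.
#' @return `path`, invisibly.
#' @export
write_table <- function(dataset, path, response_name = "y") {
  df <- cbind(stats::setNames(data.frame(dataset$y), response_name),
              as.data.frame(dataset$X))
  chr <- as.data.frame(lapply(df, function(v) sprintf("%.17g", v)),
                       check.names = FALSE)
  utils::write.csv(chr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Encode a benign/malignant diagnosis label
#'
#' Benign (`"B"`) maps to 0 and malignant (`"M"`) to 1, so a positive
#' diagnosis coefficient reads "malignant raises the response".
#'
#' @param labels character (or factor) vector of `"B"`/`"M"` labels.
#' @return Integer 0/1 vector of the same length.
#' @export
encode_diagnosis <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("B", "M"))
  if (length(bad))
    stop("unexpected diagnosis label(s): ", paste(dQuote(bad), collapse = ", "),
         " (expected 'B' or 'M')")
  as.integer(labels == "M")
}

#' Rescale a positive response into the unit interval
#'
#' Divides a strictly positive raw response by a fixed scale so the result
#' lies strictly inside (0, 1), as the beta-family models require. The
#' default scale of 100 suits a tumour radius measured in pixels.
#'
#' @param raw strictly positive numeric vector.
#' @param scale positive scalar, strictly larger than `max(raw)`.
#' @return `raw / scale`, every element strictly inside (0, 1).
#' @export
prepare_beta_response <- function(raw, scale = 100) {
  if (any(raw <= 0)) stop("raw response must be strictly positive")
  out <- raw / scale
  if (any(out >= 1) || any(out <= 0))
    stop("scaled response leaves (0, 1); choose a scale larger than max(raw) = ",
         format(max(raw)))
  out
}

#' Standardize predictor columns
#'
#' Centers every column and divides by a column scale. The default
#' `"unit_length"` convention divides each centered column by its root sum
#' of squares, so the cross-product of the scaled matrix is exactly the
#' correlation matrix of `X` -- the coordinate system in which classical
#' ridge theory is stated. `"z_score"` divides by the sample standard
#' deviation instead.
#'
#' @param X numeric predictor matrix; every column needs nonzero variance.
#' @param method `"unit_length"` (default) or `"z_score"`.
#' @return A list with `X_std` (scaled matrix), `center` and `scale`
#'   vectors; coefficients fitted on `X_std` back-transform exactly via
#'   `b_raw = b_std / scale`.
#' @export
standardize_predictors <- function(X, method = c("unit_length", "z_score")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  ss <- colSums(Xc^2)
  if (any(ss == 0)) {
    const <- colnames(X)[ss == 0]
    stop("constant column(s): ", paste(const, collapse = ", "))
  }
  scl <- switch(method,
                unit_length = sqrt(ss),
                z_score = sqrt(ss / (nrow(X) - 1)))
  list(X_std = sweep(Xc, 2, scl, "/"), center = ctr, scale = scl)
}
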