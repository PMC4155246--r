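#' Construct a time-course experimental design
#'
#' Validates and normalises a per-sample design table for a multi-series time
#' course: one row per sample with its observation time, replicate group and
#' series (experimental group) membership. One series acts as the reference;
#' the remaining `S - 1` series are encoded as binary dummy variables when the
#' regression design is built.
#'
#' @param data A data frame with one row per sample.
#' @param sample_id,time,replicate,series Names of the columns holding the
#'   sample label, numeric time, replicate-group index and series label. If
#'   the series column is absent the design is single-series.
#' @param ref Reference series level; defaults to the first-appearing series.
#'
#' @return A tibble of class `tc_design` with columns `sample_id`, `time`,
#'   `replicate` and `series` (a factor whose first level is the reference).
#' @examples
#' d <- tc_design(data.frame(
#'   sample_id = paste0("s", 1:8),
#'   time = rep(1:4, 2),
#'   replicate = rep(1:4, 2),
#'   series = rep(c("control", "treated"), each = 4)))
#' levels(d$series)
#' @export
tc_design <- function(data, sample_id = "sample_id", time = "time",
                      replicate = "replicate", series = "series", ref = NULL) {
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  need <- c(sample_id, time, replicate)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    abort(paste0("missing design column(s): ", paste(missing_cols, collapse = ", ")))

  ids <- as.character(data[[sample_id]])
  if (anyNA(ids) || any(!nzchar(ids))) abort("sample ids must be non-missing")
  if (anyDuplicated(ids))
    abort(paste0("duplicated sample id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))

  tt <- data[[time]]
  if (!is.numeric(tt) || anyNA(tt) || any(!is.finite(tt)))
    abort("`time` must be finite numeric")
  if (length(unique(tt)) < 2L)
    abort("at least two distinct time values are required")

  ser <- if (series %in% names(data)) as.character(data[[series]])
         else rep("reference", nrow(data))
  if (anyNA(ser)) abort("series labels must be non-missing")
  lev <- unique(ser)
  ref <- ref %||% lev[[1L]]
  if (!ref %in% lev)
    abort(paste0("reference series '", ref, "' has no samples in the design"))
  lev <- c(ref, setdiff(lev, ref))

  rep_g <- data[[replicate]]
  key <- paste(tt, ser, sep = "\r")
  bad <- tapply(key, rep_g, function(k) length(unique(k)) > 1L)
  if (any(bad))
    abort("all samples in a replicate group must share the same time and series")

  out <- tibble(sample_id = ids, time = as.numeric(tt),
                replicate = rep_g, series = factor(ser, levels = lev))
  class(out) <- c("tc_design", class(out))
  attr(out, "ref_series") <- ref
  out
}

#' Polynomial and dummy-variable regression design
#'
#' Expands a time-course design into the regression matrix of the polynomial
#' model: for a degree-`d` fit with `S` series the columns are
#' `[1, t, ..., t^d]` followed, for each non-reference series `s`, by
#' `[z_s, t z_s, ..., t^d z_s]`, where `z_s` is the 0/1 indicator of series
#' `s` — `(d + 1) * S` columns in total. With two series and `degree = 2`
#' this is the six-coefficient quadratic model
#' `b0 + b1 t + b2 t^2 + b3 z + b4 t z + b5 t^2 z`. Time enters in its given
#' units as raw powers; `center = TRUE` subtracts the mean time first, which
#' only reparameterises the same column space.
#'
#' @param design A [tc_design()] object.
#' @param degree Polynomial degree, a positive integer strictly smaller than
#'   the number of distinct time values.
#' @param center Centre time at its mean before taking powers (default off).
#'
#' @return An object of class `tc_design_matrix` with fields `values`
#'   (samples x regressors matrix), `column_names`, `degree` and
#'   `series_levels`.
#' @examples
#' d <- tc_design(data.frame(sample_id = paste0("s", 1:12),
#'   time = rep(1:6, 2), replicate = rep(1:6, 2),
#'   series = rep(c("ref", "alt"), each = 6)))
#' X <- build_design_matrix(d, degree = 2)
#' colnames(as.matrix(X))
#' @export
build_design_matrix <- function(design, degree = 2L, center = FALSE) {
  if (!inherits(design, "tc_design")) abort("`design` must be a tc_design object")
  if (!is.numeric(degree) || length(degree) != 1L || !is.finite(degree) ||
      degree < 1 || degree != round(degree))
    abort("`degree` must be a positive integer")
  degree <- as.integer(degree)
  tt <- design$time
  if (length(unique(tt)) <= degree)
    abort(paste0("saturated design: degree ", degree, " requires more than ",
                 degree, " distinct time values"))
  if (center) tt <- tt - mean(tt)

  powers <- outer(tt, seq_len(degree), `^`)
  poly_names <- c("time", if (degree > 1L) paste0("time", 2:degree))
  m <- cbind(1, powers)
  colnames(m) <- c("Intercept", poly_names)
  lev <- levels(design$series)
  for (s in lev[-1L]) {
    z <- as.numeric(design$series == s)
    block <- cbind(z, powers * z)
    colnames(block) <- c(s, paste0(poly_names, ":", s))
    m <- cbind(m, block)
  }
  rownames(m) <- design$sample_id
  structure(list(values = m, column_names = colnames(m), degree = degree,
                 center = center, series_levels = lev),
            class = "tc_design_matrix")
}

#' @export
as.matrix.tc_design_matrix <- function(x, ...) x$values

#' @export
dim.tc_design_matrix <- function(x) dim(x$values)

#' @export
print.tc_design_matrix <- function(x, ...) {
  cat("<tc_design_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " regressors (degree ", x$degree, ", ", length(x$series_levels),
      " series)\n", sep = "")
  cat("columns:", paste(x$column_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a design table from disk
#'
#' The on-disk layout has a header row and one row per sample: the first
#' column holds the sample id, then `Time`, `Replicate`, and one 0/1 column
#' per non-reference series (its header names the series). Samples with every
#' dummy equal to 0 belong to the reference series, named `ref_name`. A table
#' with no dummy columns is a single-series design.
#'
#' @param path File path; comma-separated if the extension is `.csv`,
#'   otherwise tab-separated (override with `sep`).
#' @param ref_name Label used for the reference series.
#' @param sep Field separator; default chosen from the file extension.
#' @return A [tc_design()] object.
#' @seealso [write_design_table()] for the inverse operation.
#' @export
parse_design_table <- function(path, ref_name = "reference", sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 3L)
    abort("design table must have sample id, Time and Replicate columns")
  tcol <- which(tolower(names(df)) == "time")[1L]
  rcol <- which(tolower(names(df)) == "replicate")[1L]
  if (is.na(tcol) || is.na(rcol))
    abort("design table must contain 'Time' and 'Replicate' columns")

  tt <- df[[tcol]]
  if (!is.numeric(tt)) {
    tt2 <- suppressWarnings(as.numeric(tt))
    if (anyNA(tt2)) abort("non-numeric Time value in design table")
    tt <- tt2
  }

  dummy_cols <- setdiff(seq_along(df)[-1L], c(tcol, rcol))
  ser <- rep(ref_name, nrow(df))
  if (length(dummy_cols)) {
    dm <- as.matrix(df[dummy_cols])
    if (!is.numeric(dm) || !all(dm %in% c(0, 1)))
      abort("series dummy columns must contain only 0 or 1")
    set_n <- rowSums(dm)
    if (any(set_n > 1))
      abort(paste0("ambiguous series assignment: sample(s) ",
                   paste(df[[1L]][set_n > 1], collapse = ", "),
                   " carry more than one series dummy"))
    for (j in seq_along(dummy_cols))
      ser[dm[, j] == 1] <- names(df)[dummy_cols[j]]
  }
  tc_design(data.frame(sample_id = as.character(df[[1L]]), time = tt,
                       replicate = df[[rcol]], series = ser,
                       stringsAsFactors = FALSE),
            ref = ref_name)
}

#' Write a design table to disk
#'
#' Inverse of [parse_design_table()]: columns `sample_id`, `Time`,
#' `Replicate`, then one 0/1 column per non-reference series. Reading the file
#' back with `parse_design_table(path, ref_name = levels(design$series)[1])`
#' reproduces the design.
#'
#' @param design A [tc_design()] object.
#' @param path Output file path; `.csv` selects comma separation.
#' @param sep Field separator; default chosen from the file extension.
#' @return Invisibly, `path`.
#' @export
write_design_table <- function(design, path, sep = NULL) {
  if (!inherits(design, "tc_design")) abort("`design` must be a tc_design object")
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- data.frame(sample_id = design$sample_id, Time = design$time,
                    Replicate = design$replicate, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (s in levels(design$series)[-1L])
    out[[s]] <- as.integer(design$series == s)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
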