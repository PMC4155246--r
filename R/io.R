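#' Read a count matrix
#'
#' Dense TSV/CSV layout: a header row of sample ids and one row per gene with
#' the gene id in the first column. Sparse layout: a matrix-market `.mtx`
#' triplet file with two sidecar id files (`<stem>_genes.txt`,
#' `<stem>_samples.txt`, one id per line). Duplicated ids, ragged rows and
#' negative values are rejected with the offending line where possible.
#'
#' @param path Input file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; inferred from the extension
#'   when omitted.
#' @param genes,samples Sidecar id file paths for `mtx` input (defaults
#'   derived from `path`).
#' @return A numeric genes x samples matrix with id dimnames.
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, format = NULL, genes = NULL, samples = NULL) {
  format <- format %||% infer_format(path)
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    genes <- genes %||% paste0(stem, "_genes.txt")
    samples <- samples %||% paste0(stem, "_samples.txt")
    m <- as.matrix(Matrix::readMM(path))
    gid <- readLines(genes)
    sid <- readLines(samples)
    if (length(gid) != nrow(m) || length(sid) != ncol(m))
      abort("matrix-market sidecar id files do not match the matrix dimensions")
    dimnames(m) <- list(gid, sid)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "\"", comment.char = "", fill = FALSE)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
      abort(paste0("duplicated gene id(s) in ", path, ": ",
                   paste(unique(ids[duplicated(ids)])[1:3], collapse = ", ")))
    vals <- df[-1L]
    if (!all(vapply(vals, is.numeric, logical(1))))
      abort(paste0("non-numeric count value(s) in ", path))
    m <- as.matrix(vals)
    rownames(m) <- ids
  }
  if (anyNA(m)) abort(paste0("missing count value(s) in ", path))
  if (any(m < 0)) {
    bad_row <- which(apply(m < 0, 1, any))[1L]
    abort(paste0("negative count value in ", path, " at line ", bad_row + 1L,
                 " (gene ", rownames(m)[bad_row] %||% bad_row, ")"))
  }
  storage.mode(m) <- "double"
  m
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]; dense output has the gene id in the first
#' column under the header `gene_id`. Matrix-market output writes the triplet
#' file plus the two id sidecars. Writing is deterministic: row and column
#' order is preserved as given.
#'
#' @param counts Genes x samples matrix (or data frame, first column ids).
#' @param path Output file.
#' @param format As in [read_counts()].
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path, format = NULL) {
  m <- as_counts_matrix(counts)
  format <- format %||% infer_format(path)
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m) %||% paste0("gene", seq_len(nrow(m))),
               paste0(stem, "_genes.txt"))
    writeLines(colnames(m) %||% paste0("sample", seq_len(ncol(m))),
               paste0(stem, "_samples.txt"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene_id = rownames(m) %||% paste0("gene", seq_len(nrow(m))),
                     m, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

infer_format <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx"
  else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
  else "tsv"
}

#' TMM scaling factors
#'
#' Between-sample normalization factors by the trimmed mean of M-values
#' method (30% trim on log-ratios, 5% on average log-expression, reference
#' chosen by upper-quartile proximity), as implemented in
#' \pkg{edgeR}'s `calcNormFactors()`. Factors are normalized so their
#' geometric mean is 1; genes with a zero count in either compared sample are
#' excluded pairwise by the method itself.
#'
#' @param counts Genes x samples count matrix with at least two samples.
#' @param ref_sample Optional reference sample id or index.
#' @return A named numeric vector of per-sample scaling factors.
#' @seealso [apply_normalization()]
#' @export
tmm_factors <- function(counts, ref_sample = NULL) {
  m <- as_counts_matrix(counts)
  if (ncol(m) < 2L) abort("TMM normalization needs at least two samples")
  zero <- colSums(m) <= 0
  if (any(zero))
    abort(paste0("sample(s) with all-zero counts: ",
                 paste((colnames(m) %||% seq_len(ncol(m)))[zero], collapse = ", ")))
  ref <- NULL
  if (!is.null(ref_sample)) {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(m)) else as.integer(ref_sample)
    if (is.na(ref) || ref < 1L || ref > ncol(m))
      abort("`ref_sample` does not name a sample in the matrix")
  }
  f <- edgeR::calcNormFactors(m, method = "TMM", refColumn = ref)
  stats::setNames(as.numeric(f), colnames(m))
}

#' Apply scaling factors to a count matrix
#'
#' Scales each sample by its normalization factor. In `"common_depth"` mode
#' (the default) values are additionally rescaled to a common library size:
#' `value / factor * (geometric-mean library size / library size)`, so pure
#' sequencing-depth differences vanish. `"factor_only"` divides by the
#' factor alone. The output is continuous; within-sample gene ranking is
#' preserved.
#'
#' @param counts Genes x samples matrix.
#' @param factors Positive per-sample factors (named vectors are matched to
#'   the columns by name).
#' @param mode `"common_depth"` or `"factor_only"`.
#' @return A numeric matrix of normalized values.
#' @export
apply_normalization <- function(counts, factors,
                                mode = c("common_depth", "factor_only")) {
  mode <- match.arg(mode)
  m <- as_counts_matrix(counts)
  if (!is.null(names(factors)) && !is.null(colnames(m))) {
    if (!setequal(names(factors), colnames(m)))
      abort("factor names do not match the sample ids")
    factors <- factors[colnames(m)]
  }
  if (length(factors) != ncol(m))
    abort("need exactly one scaling factor per sample")
  if (any(!is.finite(factors)) || any(factors <= 0))
    abort("scaling factors must be positive and finite")
  out <- sweep(m, 2, factors, "/")
  if (mode == "common_depth") {
    lib <- colSums(m)
    gm <- exp(mean(log(lib)))
    out <- sweep(out, 2, gm / lib, "*")
  }
  out
}

#' Discard genes with uniformly low counts
#'
#' The default (`mode = "any_sample"`) keeps a gene when at least one sample
#' reaches `min_total` reads, i.e. discards genes below the threshold in
#' every sample — the lenient reading of "fewer than 100 reads in all
#' samples". `mode = "total"` applies the strict reading: keep genes whose
#' summed counts reach the threshold.
#'
#' @param counts Genes x samples matrix.
#' @param min_total Threshold in reads (default 100).
#' @param mode `"any_sample"` (default) or `"total"`.
#' @param verbose Report kept/dropped counts.
#' @return The filtered matrix.
#' @export
filter_low_counts <- function(counts, min_total = 100,
                              mode = c("any_sample", "total"),
                              verbose = FALSE) {
  mode <- match.arg(mode)
  m <- as_counts_matrix(counts)
  if (!is.numeric(min_total) || min_total < 0)
    abort("`min_total` must be non-negative")
  keep <- if (mode == "any_sample") {
    apply(m, 1, max) >= min_total
  } else {
    rowSums(m) >= min_total
  }
  if (verbose)
    inform(sprintf("filter_low_counts: kept %d of %d genes (threshold %s, mode %s)",
                   sum(keep), nrow(m), format(min_total), mode))
  m[keep, , drop = FALSE]
}
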