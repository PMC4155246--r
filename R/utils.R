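# internal helpers shared across modules

# Coerce counts input to a numeric genes x samples matrix. Accepts a matrix
# (rownames = gene ids) or a data frame whose first column holds gene ids.
as_counts_matrix <- function(x, arg = "counts") {
  if (is.data.frame(x)) {
    if (ncol(x) >= 1L && !is.numeric(x[[1L]])) {
      rn <- as.character(x[[1L]])
      m <- as.matrix(x[-1L])
      rownames(m) <- rn
    } else {
      m <- as.matrix(x)
    }
  } else if (is.matrix(x) || inherits(x, "Matrix")) {
    m <- as.matrix(x)
  } else {
    abort(paste0("`", arg, "` must be a matrix or data frame"))
  }
  if (!is.numeric(m)) abort(paste0("`", arg, "` must be numeric"))
  storage.mode(m) <- "double"
  if (!is.null(rownames(m)) && anyDuplicated(rownames(m)))
    abort(paste0("duplicated gene id(s) in `", arg, "`: ",
                 paste(unique(rownames(m)[duplicated(rownames(m))])[1:3], collapse = ", ")))
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m)))
    abort(paste0("duplicated sample id(s) in `", arg, "`"))
  m
}

# Extract the raw numeric matrix from a design-matrix object or plain matrix.
design_values <- function(X) {
  if (inherits(X, "tc_design_matrix")) return(X$values)
  x <- as.matrix(X)
  if (is.null(colnames(x)))
    colnames(x) <- c("Intercept", paste0("x", seq_len(ncol(x) - 1L)))[seq_len(ncol(x))]
  x
}

# Integer apportionment by largest remainder; `x` are real targets that
# should sum (approximately) to `total`.
largest_remainder <- function(x, total = round(sum(x))) {
  fl <- floor(x)
  need <- as.integer(round(total)) - as.integer(sum(fl))
  if (need > 0L) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(need)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

# Deterministic small-integer seed derived from a base seed and tokens,
# kept strictly inside 32-bit range.
derive_seed <- function(base_seed, ...) {
  h <- as.numeric(base_seed) %% 2147483647
  for (tok in list(...)) {
    for (ch in utf8ToInt(paste0(as.character(tok), "|"))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(max(1, h))
}
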