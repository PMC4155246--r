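#' Likelihood-ratio test of a full gene model against the intercept-only model
#'
#' The deviance gap `delta = D0 - D1` between the intercept-only model (`D0`)
#' and the full polynomial model (`D1`) is referred to a chi-square
#' distribution with `p` degrees of freedom, `p` being the number of
#' non-intercept regressors actually estimated. For the gaussian family the
#' gap is first scaled by the residual-deviance dispersion estimate. A fit
#' that did not converge yields a missing p-value rather than a misleading
#' one.
#'
#' @param full A converged [fit_glm()] object for the full model.
#' @param null Optional [fit_glm()] object for the intercept-only model; when
#'   omitted, the full fit's internally computed null deviance is used.
#' @param gene_id Optional label carried into the output.
#' @param tolerance Negative-delta slack treated as numerical noise before a
#'   hard inconsistency error is raised.
#'
#' @return A one-row tibble with `gene_id`, `d0`, `d1`, `delta`, `df` and
#'   `p_value`.
#' @examples
#' y <- c(12, 15, 30, 28, 41, 50)
#' d <- tc_design(data.frame(sample_id = paste0("s", 1:6),
#'   time = 1:6, replicate = 1:6))
#' f <- fit_glm(y, build_design_matrix(d, 2), tc_family("nb"))
#' global_model_test(f)
#' @export
global_model_test <- function(full, null = NULL, gene_id = NA_character_,
                              tolerance = 1e-6) {
  if (!inherits(full, "tc_glmfit")) abort("`full` must be a tc_glmfit object")
  d1 <- full$deviance
  d0 <- if (is.null(null)) full$null_deviance else null$deviance
  p_full <- sum(!is.na(full$coefficients))
  p_null <- if (is.null(null)) 1L else sum(!is.na(null$coefficients))
  df <- as.integer(p_full - p_null)

  untestable <- !isTRUE(full$converged) ||
    (!is.null(null) && !isTRUE(null$converged)) || df < 1L
  if (untestable) {
    return(tibble(gene_id = gene_id, d0 = d0, d1 = d1, delta = NA_real_,
                  df = df, p_value = NA_real_))
  }
  delta <- d0 - d1
  if (is.finite(delta) && delta < -tolerance * max(1, abs(d0)))
    abort("numerical inconsistency: full-model deviance exceeds the null deviance")
  delta <- max(delta, 0)
  p <- stats::pchisq(delta / fit_dispersion(full), df = df, lower.tail = FALSE)
  tibble(gene_id = gene_id, d0 = d0, d1 = d1, delta = delta, df = df,
         p_value = p)
}

#' Benjamini-Hochberg adjustment with missing-value passthrough
#'
#' Step-up false discovery rate adjustment. Missing entries are passed
#' through as missing and excluded from the number of tests `m`, so genes
#' whose fit failed do not deflate the q-values of the rest.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Step 1: genome-wide screen for non-flat expression profiles
#'
#' Fits the full polynomial model to every gene and tests it against the
#' intercept-only model with the deviance chi-square test, then controls the
#' false discovery rate across genes by Benjamini-Hochberg. A gene is
#' selected when its q-value is at most `alpha`. Per-gene fit failures are
#' recorded in the `status` column (and excluded from the adjustment), never
#' fatal.
#'
#' @param counts Genes x samples matrix (or data frame whose first column is
#'   the gene id) of non-negative, possibly normalized, expression values.
#' @param design A [tc_design()] object; counts columns are matched to
#'   `design$sample_id` by name when column names are present.
#' @param degree Polynomial degree of the full model.
#' @param family A [tc_family()] object; the negative binomial with
#'   `theta = 10` is the count default, `tc_family("gaussian")` recovers the
#'   classical linear-model pathway.
#' @param alpha FDR level applied to q-values.
#' @param center Passed to [build_design_matrix()].
#' @param verbose Emit a per-run summary message.
#'
#' @return A tibble of class `tc_screen`, one row per gene: `gene_id`, `d0`,
#'   `d1`, `delta`, `df`, `p_value`, `q_value`, `selected`, `status`. The
#'   design matrix and family travel along as attributes for step 2.
#' @seealso [tc_stepwise()] for the second regression step.
#' @export
tc_screen <- function(counts, design, degree = 2L, family = tc_family(),
                      alpha = 0.05, center = FALSE, verbose = FALSE) {
  m <- as_counts_matrix(counts)
  if (!inherits(design, "tc_design")) abort("`design` must be a tc_design object")
  if (nrow(m) == 0L || ncol(m) == 0L) abort("empty count matrix")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1]")
  if (!is.null(colnames(m))) {
    if (!setequal(colnames(m), design$sample_id))
      abort("count matrix columns do not match the design sample ids")
    m <- m[, design$sample_id, drop = FALSE]
  } else if (ncol(m) != nrow(design)) {
    abort("count matrix has a different number of samples than the design")
  }

  X <- build_design_matrix(design, degree = degree, center = center)
  G <- nrow(m)
  d0 <- d1 <- delta <- pv <- rep(NA_real_, G)
  dfv <- rep(NA_integer_, G)
  status <- rep("ok", G)

  for (g in seq_len(G)) {
    y <- m[g, ]
    if (anyNA(y)) {
      status[g] <- "skipped"
      next
    }
    res <- tryCatch({
      fit <- fit_glm(y, X, family = family)
      if (!isTRUE(fit$converged)) {
        status[g] <- "fit_failed"
        list(d0 = fit$null_deviance, d1 = fit$deviance,
             delta = NA_real_, df = NA_integer_, p_value = NA_real_)
      } else {
        global_model_test(fit)
      }
    }, error = function(e) {
      status[g] <<- "fit_failed"
      NULL
    })
    if (is.null(res)) next
    d0[g] <- res$d0; d1[g] <- res$d1; delta[g] <- res$delta
    dfv[g] <- res$df; pv[g] <- res$p_value
  }

  q <- adjust_bh(pv)
  gene_ids <- rownames(m) %||% paste0("gene", seq_len(G))
  out <- tibble(gene_id = gene_ids, d0 = d0, d1 = d1, delta = delta,
                df = dfv, p_value = pv, q_value = q,
                selected = !is.na(q) & q <= alpha, status = status)
  if (verbose) {
    inform(sprintf("tc_screen: %d/%d genes selected at FDR %.3g (%d fit failures, %d skipped)",
                   sum(out$selected), G, alpha,
                   sum(status == "fit_failed"), sum(status == "skipped")))
  }
  class(out) <- c("tc_screen", class(out))
  attr(out, "design_matrix") <- X
  attr(out, "design") <- design
  attr(out, "family") <- family
  attr(out, "alpha") <- alpha
  out
}

#' @rdname tc_screen
#' @param x,object A `tc_screen` object.
#' @param ... Unused.
#' @method tidy tc_screen
#' @export
tidy.tc_screen <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "tc_screen")
  out
}

#' @rdname tc_screen
#' @method glance tc_screen
#' @export
glance.tc_screen <- function(x, ...) {
  tibble(n_genes = nrow(x), n_selected = sum(x$selected),
         n_fit_failed = sum(x$status == "fit_failed"),
         n_skipped = sum(x$status == "skipped"),
         alpha = attr(x, "alpha"),
         family = attr(x, "family")$family,
         degree = attr(x, "design_matrix")$degree)
}
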