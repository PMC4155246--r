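#' Fit a single gene's generalized linear model
#'
#' Maximum-likelihood fit of one response vector against a polynomial design
#' by iteratively reweighted least squares (via [stats::glm.fit()]), for the
#' gaussian (identity link), Poisson (log link) or negative binomial
#' (log link, fixed `theta`) family. Convergence is declared when the
#' relative deviance change falls below `epsilon`; a fit that fails to
#' converge within `maxit` iterations is returned with `converged = FALSE`,
#' never silently as converged. Rank-deficient designs are fitted with the
#' aliased columns dropped and reported in `$aliased`.
#'
#' @param y Numeric response vector (non-negative for count families;
#'   non-integer normalized counts are accepted).
#' @param X A [build_design_matrix()] object or plain numeric matrix whose
#'   first column is the intercept.
#' @param family A [tc_family()] object.
#' @param maxit,epsilon IRLS iteration cap and relative-deviance tolerance.
#' @param offset Optional per-sample offset on the linear-predictor scale.
#'
#' @return An object of class `tc_glmfit` with elements `coefficients`,
#'   `fitted`, `deviance`, `null_deviance` (intercept-only deviance on the
#'   same response), `log_likelihood`, `df_residual`, `converged`,
#'   `iterations`, `aliased` and `messages`.
#' @examples
#' d <- tc_design(data.frame(sample_id = paste0("s", 1:12),
#'   time = rep(1:6, each = 2), replicate = rep(1:6, each = 2)))
#' X <- build_design_matrix(d, degree = 1)
#' y <- rnbinom(12, mu = exp(2 + 0.3 * d$time), size = 10)
#' fit <- fit_glm(y, X, tc_family("nb", theta = 10))
#' coef(fit); deviance(fit)
#' @export
fit_glm <- function(y, X, family = tc_family(), maxit = 50L, epsilon = 1e-8,
                    offset = NULL) {
  x <- design_values(X)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) abort("length(y) must equal nrow(X)")
  if (length(y) < ncol(x)) abort("fewer observations than regressors")
  if (anyNA(y) || any(!is.finite(y))) abort("`y` must be finite and non-missing")
  if (family$family != "gaussian" && any(y < 0))
    abort("negative response values are outside the count-family domain")

  warns <- character()
  res <- withCallingHandlers(
    tryCatch(
      stats::glm.fit(x, y, family = family, offset = offset,
                     control = list(epsilon = epsilon, maxit = maxit),
                     intercept = TRUE),
      error = function(e) e),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  if (inherits(res, "error")) {
    return(structure(list(
      coefficients = stats::setNames(rep(NA_real_, ncol(x)), colnames(x)),
      fitted = rep(NA_real_, length(y)), deviance = NA_real_,
      null_deviance = NA_real_, log_likelihood = NA_real_,
      df_residual = NA_integer_, converged = FALSE, iterations = 0L,
      aliased = character(), family = family, y = y, design = x,
      messages = c(warns, conditionMessage(res))), class = "tc_glmfit"))
  }

  beta <- res$coefficients
  structure(list(
    coefficients = beta, fitted = res$fitted.values,
    deviance = res$deviance, null_deviance = res$null.deviance,
    log_likelihood = log_likelihood(y, res$fitted.values, family),
    df_residual = res$df.residual,
    converged = isTRUE(res$converged), iterations = res$iter,
    aliased = names(beta)[is.na(beta)],
    family = family, y = y, design = x, messages = warns),
    class = "tc_glmfit")
}

# Dispersion used to scale deviance differences into chi-square statistics:
# estimated from the residual deviance for the gaussian family (free scale),
# fixed at 1 for the count families.
fit_dispersion <- function(fit) {
  if (fit$family$family == "gaussian" && isTRUE(fit$df_residual > 0))
    max(fit$deviance / fit$df_residual, 1e-12)
  else 1
}

# Wald z/t p-values for the coefficients of a converged fit, from the
# observed Fisher information at the IRLS solution.
wald_p_values <- function(fit) {
  ok <- !is.na(fit$coefficients)
  x <- fit$design[, ok, drop = FALSE]
  mu <- fit$fitted
  w <- if (fit$family$link == "log") mu^2 / fit$family$variance(mu)
       else 1 / fit$family$variance(mu)
  info <- crossprod(x * sqrt(w))
  cov <- tryCatch(solve(info), error = function(e) NULL)
  p <- stats::setNames(rep(NA_real_, length(fit$coefficients)),
                       names(fit$coefficients))
  if (is.null(cov)) return(p)
  se <- sqrt(pmax(diag(cov), 0)) * sqrt(fit_dispersion(fit))
  z <- fit$coefficients[ok] / se
  p[ok] <- if (fit$family$family == "gaussian")
    2 * stats::pt(-abs(z), df = fit$df_residual)
  else 2 * stats::pnorm(-abs(z))
  p
}

#' @export
print.tc_glmfit <- function(x, ...) {
  cat("<tc_glmfit> family =", x$family$family,
      if (x$family$family == "negative_binomial") paste0("(theta = ", x$family$theta, ")"),
      "\n  deviance =", format(x$deviance), " null deviance =", format(x$null_deviance),
      "\n  converged =", x$converged, "in", x$iterations, "iterations\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.tc_glmfit <- function(object, ...) object$coefficients

#' @export
fitted.tc_glmfit <- function(object, ...) object$fitted

#' @export
deviance.tc_glmfit <- function(object, ...) object$deviance

#' @export
logLik.tc_glmfit <- function(object, ...) {
  structure(object$log_likelihood,
            df = sum(!is.na(object$coefficients)),
            nobs = length(object$y), class = "logLik")
}

#' @rdname fit_glm
#' @param x,object A `tc_glmfit` object.
#' @param ... Unused.
#' @method tidy tc_glmfit
#' @export
tidy.tc_glmfit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         p_value = unname(wald_p_values(x)))
}

#' @rdname fit_glm
#' @method glance tc_glmfit
#' @export
glance.tc_glmfit <- function(x, ...) {
  tibble(deviance = x$deviance, null_deviance = x$null_deviance,
         log_likelihood = x$log_likelihood, df_residual = x$df_residual,
         converged = x$converged, iterations = x$iterations,
         n_aliased = length(x$aliased))
}
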