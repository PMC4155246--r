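#' Exponential-family specification for per-gene model fitting
#'
#' Builds the family object used by [fit_glm()] and the screening/stepwise
#' pipeline. RNA-seq counts are overdispersed relative to Poisson, so the
#' negative binomial family with log link and a fixed size parameter `theta`
#' is the default: `Var(Y) = mu + mu^2 / theta`. When no external estimate of
#' `theta` is available, `theta = 10` is a serviceable default — results are
#' fairly insensitive to its exact value; a quick per-gene method-of-moments
#' estimate is available via [estimate_theta_mm()]. The gaussian family
#' (identity link) recovers classical linear-model behaviour for continuous
#' expression data, and the Poisson family is the `theta -> Inf` limit of the
#' negative binomial.
#'
#' @param family One of `"negative_binomial"` (alias `"nb"`), `"poisson"` or
#'   `"gaussian"`. `"gamma"` and `"binomial"` are recognised names but not
#'   implemented and raise an error.
#' @param theta Positive size (overdispersion) parameter of the negative
#'   binomial; ignored by the other families.
#' @param sigma2 Fixed gaussian variance used when evaluating
#'   [log_likelihood()]; with the default `sigma2 = 1` the gaussian deviance
#'   is the residual sum of squares.
#'
#' @return An object of class `c("tc_family", "family")`, usable anywhere a
#'   [stats::family] object is.
#' @examples
#' fam <- tc_family("nb", theta = 10)
#' fam$variance(5)          # 5 + 25/10
#' tc_family("gaussian")$family
#' @export
tc_family <- function(family = c("negative_binomial", "nb", "poisson", "gaussian",
                                 "gamma", "binomial"),
                      theta = 10, sigma2 = 1) {
  family <- match.arg(tolower(family[[1L]]),
                      c("negative_binomial", "nb", "poisson", "gaussian",
                        "gamma", "binomial"))
  if (family == "nb") family <- "negative_binomial"
  if (family %in% c("gamma", "binomial")) {
    abort(paste0("family '", family, "' is not implemented; ",
                 "use 'negative_binomial', 'poisson' or 'gaussian'"))
  }
  fam <- switch(family,
    negative_binomial = {
      if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
        abort("`theta` must be a positive finite number")
      f <- MASS::negative.binomial(theta = theta)
      f$family <- "negative_binomial"
      f$theta <- theta
      f
    },
    poisson = {
      f <- stats::poisson(link = "log")
      # log-gamma form so non-integer (normalized) counts evaluate silently
      f$aic <- function(y, n, mu, wt, dev)
        -2 * sum((y * log(mu) - mu - lgamma(y + 1)) * wt)
      f
    },
    gaussian = {
      if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) || sigma2 <= 0)
        abort("`sigma2` must be a positive finite number")
      f <- stats::gaussian()
      f$sigma2 <- sigma2
      f
    })
  class(fam) <- c("tc_family", "family")
  fam
}

check_family_domain <- function(y, mu, family) {
  if (length(y) != length(mu)) abort("`y` and `mu` must have the same length")
  if (anyNA(y) || anyNA(mu)) abort("`y` and `mu` must be non-missing")
  if (family$family != "gaussian") {
    if (any(y < 0)) abort("negative response values are outside the count-family domain")
    if (any(mu <= 0)) abort("`mu` must be strictly positive for log-link families")
  }
  invisible(TRUE)
}

#' Exact family log-likelihood
#'
#' Evaluates the log-likelihood of observations `y` at means `mu` under the
#' given family. Negative binomial and Poisson likelihoods are computed
#' through log-gamma functions, so non-integer values (e.g. TMM-normalized
#' counts) are accepted. The gaussian likelihood is evaluated at the fixed
#' variance `family$sigma2`.
#'
#' @param y Numeric vector of responses (non-negative for count families).
#' @param mu Numeric vector of means, strictly positive for log-link families.
#' @param family A [tc_family()] object.
#' @return A single numeric value.
#' @examples
#' log_likelihood(3, 2, tc_family("nb", theta = 10))
#' dnbinom(3, mu = 2, size = 10, log = TRUE)  # same value
#' @export
log_likelihood <- function(y, mu, family = tc_family()) {
  check_family_domain(y, mu, family)
  switch(family$family,
    gaussian = {
      s2 <- family$sigma2 %||% 1
      -length(y) / 2 * log(2 * pi * s2) - sum((y - mu)^2) / (2 * s2)
    },
    poisson = sum(y * log(mu) - mu - lgamma(y + 1)),
    negative_binomial = {
      th <- family$theta
      sum(lgamma(y + th) - lgamma(th) - lgamma(y + 1) +
            th * log(th / (th + mu)) + y * log(mu / (th + mu)))
    },
    abort(paste0("unsupported family: ", family$family)))
}

#' Deviance of observations against fitted means
#'
#' The deviance is twice the gap between the saturated-model log-likelihood
#' (means set to the observations, with the `y * log(y) := 0` convention at
#' zero counts) and the log-likelihood at `mu`. For the gaussian family with
#' unit scale this is the residual sum of squares; it is zero exactly when
#' `mu` equals `y` element-wise.
#'
#' @inheritParams log_likelihood
#' @return A single non-negative numeric value.
#' @examples
#' deviance_stat(c(1, 4, 2), c(1, 4, 2), tc_family("nb"))  # 0
#' @export
deviance_stat <- function(y, mu, family = tc_family()) {
  check_family_domain(y, mu, family)
  sum(family$dev.resids(y, mu, rep(1, length(y))))
}

#' Method-of-moments dispersion estimate
#'
#' Per-gene estimate `theta = mean^2 / (var - mean)` from a vector of counts,
#' falling back to `fallback` when the sample variance does not exceed the
#' mean (no evidence of overdispersion). This is a cheap pre-pass; `theta` is
#' held fixed during model fitting.
#'
#' @param y Numeric vector of counts for one gene.
#' @param fallback Value returned when the moment estimate is unavailable.
#' @return A positive scalar.
#' @examples
#' estimate_theta_mm(rnbinom(50, mu = 50, size = 10))
#' @export
estimate_theta_mm <- function(y, fallback = 10) {
  m <- mean(y)
  v <- stats::var(y)
  if (!is.finite(v) || !is.finite(m) || m <= 0 || v <= m) return(fallback)
  m^2 / (v - m)
}
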