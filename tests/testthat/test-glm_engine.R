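test_that("negative binomial log-likelihood matches the pmf and its Poisson limit", {
  fam <- tc_family("nb", theta = 10)
  # single observation against the pmf evaluated independently
  expect_equal(log_likelihood(3, 2, fam), dnbinom(3, mu = 2, size = 10, log = TRUE),
               tolerance = 1e-12)
  y <- c(0, 3, 7, 12, 41)
  mu <- c(1.5, 2, 8, 10, 35)
  expect_equal(log_likelihood(y, mu, fam), nb_loglik_oracle(y, mu, 10),
               tolerance = 1e-10)

  # theta -> Inf recovers the Poisson likelihood
  fam_big <- tc_family("nb", theta = 1e8)
  expect_equal(log_likelihood(y, mu, fam_big),
               sum(dpois(y, mu, log = TRUE)), tolerance = 1e-4)

  # gaussian likelihood at fixed variance is maximal when mu = y
  yg <- c(1.2, -0.5, 3.1)
  at_y <- log_likelihood(yg, yg, tc_family("gaussian"))
  expect_gt(at_y, log_likelihood(yg, yg + 0.1, tc_family("gaussian")))
  expect_equal(at_y, -length(yg) / 2 * log(2 * pi))

  expect_error(log_likelihood(c(-1, 2), c(1, 2), fam), "negative")
  expect_error(tc_family("gamma"), "not implemented")
})

test_that("deviance equals twice the saturated-model likelihood gap", {
  fam <- tc_family("nb", theta = 10)
  y <- c(4, 9, 2, 14, 7)
  expect_equal(deviance_stat(y, y, fam), 0, tolerance = 1e-12)

  mu <- c(5, 7, 3, 12, 8)
  # brute-force per-observation deviance via the pmf oracle (all y > 0)
  l_sat <- nb_loglik_oracle(y, y, 10)
  l_fit <- nb_loglik_oracle(y, mu, 10)
  expect_equal(deviance_stat(y, mu, fam), 2 * (l_sat - l_fit), tolerance = 1e-10)

  # zero counts use the y*log(y) := 0 limit: saturated contribution is 0
  y0 <- c(0, 3, 5)
  mu0 <- c(0.5, 4, 5)
  manual <- 2 * sum(ifelse(y0 > 0, y0 * log(y0 / mu0), 0) -
                      (y0 + 10) * log((y0 + 10) / (mu0 + 10)))
  expect_equal(deviance_stat(y0, mu0, fam), manual, tolerance = 1e-10)

  # gaussian deviance is the residual sum of squares
  yg <- c(1, 4, 2, 8)
  mug <- c(2, 3, 2, 7)
  expect_equal(deviance_stat(yg, mug, tc_family("gaussian")), sum((yg - mug)^2))
})

test_that("gaussian fits equal the ordinary least-squares closed form", {
  set.seed(101)
  for (i in 1:5) {
    n <- 20
    X <- cbind(Intercept = 1, time = seq_len(n), time2 = seq_len(n)^2)
    y <- drop(X %*% c(2, 0.5, -0.02)) + rnorm(n)
    fit <- fit_glm(y, X, tc_family("gaussian"))
    beta_ols <- solve(crossprod(X), crossprod(X, y))
    expect_equal(unname(coef(fit)), unname(drop(beta_ols)), tolerance = 1e-8)
    # scale equivariance
    fit2 <- fit_glm(3 * y, X, tc_family("gaussian"))
    expect_equal(unname(coef(fit2)), 3 * unname(coef(fit)), tolerance = 1e-8)
  }
})

test_that("NB fits recover the sample mean and the brute-force maximum likelihood", {
  fam <- tc_family("nb", theta = 10)
  y <- fixed_counts_12
  # intercept-only: log-link score equation forces the sample mean
  fit0 <- fit_glm(y, matrix(1, 12, 1, dimnames = list(NULL, "Intercept")), fam)
  expect_equal(unname(fit0$fitted), rep(mean(y), 12), tolerance = 1e-8)
  expect_equal(fit0$deviance, fit0$null_deviance, tolerance = 1e-8)

  # degree-1 single series: compare with an independent numeric optimiser of
  # the exact NB likelihood over (b0, b1)
  d <- make_design(times = 1:6, replicates = 2)
  X <- build_design_matrix(d, degree = 1)
  fit <- fit_glm(y, X, fam)
  negll <- function(b) -nb_loglik_oracle(y, exp(b[1] + b[2] * d$time), 10)
  opt <- optim(c(log(mean(y)), 0), negll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(coef(fit)), opt$par, tolerance = 1e-4)
})

test_that("score equations hold and deviance is monotone under nesting", {
  set.seed(77)
  fams <- list(tc_family("nb", theta = 10), tc_family("poisson"),
               tc_family("gaussian"))
  d <- make_design(times = 1:6, replicates = 2)
  X2 <- as.matrix(build_design_matrix(d, degree = 2))
  for (fam in fams) {
    for (i in 1:3) {
      mu_true <- exp(1.5 + 0.2 * d$time)
      y <- if (fam$family == "gaussian") mu_true + rnorm(12)
           else rnbinom(12, mu = mu_true, size = 10)
      fit <- fit_glm(y, X2, fam)
      # score: X' [(y - mu) dmu/deta / V(mu)] = 0 at the optimum
      mu <- fit$fitted
      dmu <- if (fam$link == "log") mu else rep(1, length(mu))
      score <- crossprod(X2, (y - mu) * dmu / fam$variance(mu))
      expect_lt(max(abs(score)) / max(1, max(abs(y))), 1e-4)
      # adding a column can only decrease the deviance
      fit1 <- fit_glm(y, X2[, 1:2], fam)
      expect_gte(fit1$deviance, fit$deviance - 1e-8)
    }
  }
})

test_that("large theta reproduces Poisson fits and failures are flagged, not hidden", {
  set.seed(5)
  d <- make_design(times = 1:6, replicates = 2)
  X <- build_design_matrix(d, degree = 1)
  y <- rnbinom(12, mu = exp(2 + 0.2 * d$time), size = 50)
  fit_nb <- fit_glm(y, X, tc_family("nb", theta = 1e8))
  fit_po <- fit_glm(y, X, tc_family("poisson"))
  expect_equal(coef(fit_nb), coef(fit_po), tolerance = 1e-5)

  # duplicated column -> aliased coefficient reported
  xm <- as.matrix(X)
  xdup <- cbind(xm, dup = xm[, "time"])
  fit_al <- fit_glm(y, xdup, tc_family("poisson"))
  expect_identical(fit_al$aliased, "dup")
  expect_true(fit_al$converged)

  # iteration starvation -> converged = FALSE, never silent
  fit_bad <- fit_glm(y, X, tc_family("nb", theta = 10), maxit = 1L)
  expect_false(fit_bad$converged)
})

test_that("method-of-moments theta falls back when variance does not exceed the mean", {
  set.seed(9)
  y <- rnbinom(5000, mu = 50, size = 10)
  th <- estimate_theta_mm(y)
  expect_gt(th, 5); expect_lt(th, 20)
  expect_identical(estimate_theta_mm(c(3, 3, 3)), 10)
  expect_identical(estimate_theta_mm(c(3, 3, 3), fallback = 7), 7)
})
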