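test_that("backward elimination recovers a clean log-linear trend and strips noise terms", {
  # nearly noiseless exponential trend shared by both series: only the linear
  # time term should survive; the oracle is the same refit-and-test sequence
  # executed by hand with fit_glm
  d <- make_design(times = 1:6, replicates = 3, n_series = 2)
  X <- build_design_matrix(d, degree = 2)
  y <- exp(1 + 0.5 * d$time)                 # exact means, theta huge
  fam <- tc_family("nb", theta = 1e7)

  gm <- stepwise_select(y, X, fam, step_alpha = 0.05)
  expect_identical(gm$retained, c("Intercept", "time"))
  expect_gt(gm$r_squared, 0.999)

  # hand-executed oracle: run the same elimination with direct fits
  xm <- as.matrix(X)
  keep <- colnames(xm)[-1]
  repeat {
    fit_cur <- fit_glm(y, xm[, c("Intercept", keep), drop = FALSE], fam)
    p <- vapply(keep, function(j) {
      f2 <- fit_glm(y, xm[, c("Intercept", setdiff(keep, j)), drop = FALSE], fam)
      pchisq(max(f2$deviance - fit_cur$deviance, 0), 1, lower.tail = FALSE)
    }, numeric(1))
    if (max(p) <= 0.05 || !length(keep)) break
    ties <- keep[p == max(p)]
    keep <- setdiff(keep, ties[length(ties)])
  }
  expect_identical(gm$retained, c("Intercept", keep))
})

test_that("flat genes collapse to the intercept and one-candidate stepwise equals the global test", {
  d <- make_design(times = 1:6, replicates = 2)
  X2 <- build_design_matrix(d, degree = 2)
  fam <- tc_family("nb", theta = 10)

  gm_flat <- stepwise_select(rep(9, nrow(d)), X2, fam)
  expect_identical(gm_flat$retained, "Intercept")
  expect_lt(gm_flat$r_squared, 1e-8)

  # degree-1 single series: the single elimination test is the global test
  X1 <- build_design_matrix(d, degree = 1)
  set.seed(31)
  for (i in 1:5) {
    y <- rnbinom(nrow(d), mu = exp(2 + 0.15 * d$time * (i %% 2)), size = 10)
    gm <- stepwise_select(y, X1, fam, step_alpha = 0.05)
    glob <- global_model_test(fit_glm(y, X1, fam))
    expect_identical("time" %in% gm$retained, glob$p_value <= 0.05)
  }
})

test_that("deviance-explained R-squared reduces to the classical one for gaussian data", {
  x <- cbind(Intercept = 1, time = 1:8)
  y <- c(2.3, 2.9, 4.1, 4.4, 5.8, 6.1, 7.4, 7.8)
  fit <- fit_glm(y, x, tc_family("gaussian"))
  rss <- sum((y - fitted(fit))^2)
  tss <- sum((y - mean(y))^2)
  expect_equal(goodness_of_fit(fit), 1 - rss / tss, tolerance = 1e-10)

  # intercept-only model explains nothing; an exact fit explains everything
  fit0 <- fit_glm(y, x[, 1, drop = FALSE], tc_family("gaussian"))
  expect_equal(goodness_of_fit(fit0), 0)
  y_exact <- drop(x %*% c(1, 0.7))
  expect_equal(goodness_of_fit(fit_glm(y_exact, x, tc_family("gaussian"))), 1,
               tolerance = 1e-10)
})

test_that("Wald tests agree with linear-model t-tests on gaussian fits", {
  set.seed(12)
  d <- make_design(times = 1:6, replicates = 2, n_series = 2)
  X <- as.matrix(build_design_matrix(d, degree = 2))
  y <- rnorm(nrow(X), mean = drop(X %*% c(5, 1, 0, 2, 0, 0)), sd = 1)
  fit <- fit_glm(y, X, tc_family("gaussian"))
  lm_p <- summary(lm(y ~ X - 1))$coefficients[, 4]
  expect_equal(unname(tidy(fit)$p_value), unname(lm_p), tolerance = 1e-8)
})

test_that("final models are stable and never out-explain the full model", {
  sim <- tc_simulate(tc_sim_spec("A", series = 2, replicates = 2,
                                 n_genes = 200, seed = 77))
  scr <- tc_screen(sim$counts, sim$design)
  mods <- tc_stepwise(sim$counts, scr)
  expect_gt(nrow(mods), 0)
  X <- attr(scr, "design_matrix")
  fam <- attr(scr, "family")
  xm <- as.matrix(X)
  for (i in seq_len(min(nrow(mods), 10))) {
    g <- mods$gene_id[i]
    y <- sim$counts[g, sim$design$sample_id]
    # sub-model deviance >= full-model deviance, so R2_final <= R2_full
    full <- fit_glm(y, X, fam)
    expect_lte(mods$r_squared[i], goodness_of_fit(full) + 1e-8)
    # re-running stepwise on the final term set removes nothing
    keep <- setdiff(mods$retained[[i]], "Intercept")
    gm2 <- stepwise_select(y, xm[, c("Intercept", keep), drop = FALSE], fam)
    expect_identical(gm2$retained, mods$retained[[i]])
    # every retained non-intercept term is significant at the final step
    if (length(keep)) expect_lte(max(mods$coef_p[[i]]), 0.05)
  }
})

test_that("the R-squared filter shrinks selections monotonically and validates its cutoff", {
  sim <- tc_simulate(tc_sim_spec("A", series = 2, replicates = 3,
                                 n_genes = 300, seed = 15))
  scr <- tc_screen(sim$counts, sim$design)
  mods <- tc_stepwise(sim$counts, scr)
  sizes <- vapply(seq(0, 0.9, by = 0.1),
                  function(r) sum(tc_select(mods, rsq = r)$selected), integer(1))
  expect_true(all(diff(sizes) <= 0))
  # disabled filter reproduces the step-1 selection
  expect_identical(sum(tc_select(mods, rsq = 0)$selected), sum(scr$selected))
  expect_error(tc_select(mods, rsq = 1.1), "\\[0, 1\\]")
  expect_error(tc_select(mods, rsq = -0.1), "\\[0, 1\\]")
})

test_that("hierarchy mode never leaves an orphaned higher-order term", {
  d <- make_design(times = 1:6, replicates = 2, n_series = 2)
  X <- build_design_matrix(d, degree = 2)
  fam <- tc_family("nb", theta = 10)
  set.seed(4)
  for (i in 1:5) {
    y <- rnbinom(nrow(d), mu = exp(2 + 0.1 * d$time + 0.02 * d$time^2), size = 10)
    gm <- stepwise_select(y, X, fam, hierarchy = TRUE)
    terms <- setdiff(gm$retained, "Intercept")
    if ("time2" %in% terms) expect_true("time" %in% terms)
    if ("time2:B" %in% terms) expect_true("time:B" %in% terms)
  }
})
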