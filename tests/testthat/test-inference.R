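# Small-but-real MCMC runs; schedules are deliberately short, the checks
# are either exact (determinism, degenerate limits) or conjugate closed
# forms with generous Monte Carlo tolerances.

test_that("the fixed-effects Gaussian model matches the conjugate closed form", {
  sim <- simulate_cohort(synthetic_config(
    n_patients = 30, p_missing_vl = 0, p_missing_cd4 = 0, p_missing_sex = 0,
    p_missing_bcd4 = 0, p_missing_blvl = 0, dropout_hazard = 0,
    sigma0 = 0, sigma1 = 0, rho = 0, sigma_eps = 50,
    truncate_negative = FALSE), seed = 31)
  co <- standardize_covariates(apply_exclusions(sim$cohort, "slope"))
  des <- build_design(co, cd4_model("slope", "poly2", cvl_adjusted = TRUE))
  fit <- fit_cd4(des, control = mcmc_control(
    adapt = 300, burn_in = 300, n_iter = 3000, seed = 2,
    random_effects = FALSE, fix_sigma = 50))
  exact <- conjugate_posterior(des$X, des$y, 50)
  got <- fit$summaries[match(des$coef_names, fit$summaries$parameter), ]
  expect_lt(max(abs(got$mean - exact$mean) / sqrt(diag(exact$V))), 0.15)
  expect_lt(max(abs(got$sd / sqrt(diag(exact$V)) - 1)), 0.1)
})

test_that("identical seeds give bitwise-identical draws; seeds differ otherwise", {
  co <- quick_cohort(n = 25, seed = 3)
  f1 <- fit_cd4(co, cd4_model("slope", "poly2", cvl_adjusted = TRUE),
                control = quick_control(seed = 9))
  f2 <- fit_cd4(co, cd4_model("slope", "poly2", cvl_adjusted = TRUE),
                control = quick_control(seed = 9))
  expect_identical(f1$pooled, f2$pooled)
  expect_identical(f1$cdic, f2$cdic)
  f3 <- fit_cd4(co, cd4_model("slope", "poly2", cvl_adjusted = TRUE),
                control = quick_control(seed = 10))
  expect_false(identical(f1$pooled, f3$pooled))
})

test_that("a near-degenerate prior pins its coefficient at the prior mean", {
  co <- quick_cohort(n = 25, seed = 6)
  pr <- prior_spec(mean = c(sex = 5), precision = c(sex = 1e10))
  fit <- fit_cd4(co, cd4_model("slope", "poly2", cvl_adjusted = FALSE),
                 priors = pr, control = quick_control(seed = 4))
  i <- match("sex", fit$summaries$parameter)
  expect_equal(fit$summaries$mean[i], 5, tolerance = 1e-3)
  expect_lt(fit$summaries$sd[i], 0.01)
})

test_that("conditional DIC matches the analytic conjugate oracle", {
  sim <- simulate_cohort(synthetic_config(
    n_patients = 5, p_missing_vl = 0, p_missing_cd4 = 0, p_missing_sex = 0,
    p_missing_bcd4 = 0, p_missing_blvl = 0, dropout_hazard = 0,
    sigma0 = 0, sigma1 = 0, rho = 0, sigma_eps = 40,
    truncate_negative = FALSE), seed = 13)
  co <- standardize_covariates(apply_exclusions(sim$cohort, "slope"))
  des <- build_design(co, cd4_model("slope", "poly2"))
  fit <- fit_cd4(des, control = mcmc_control(
    adapt = 300, burn_in = 500, n_iter = 5000, seed = 3,
    random_effects = FALSE, fix_sigma = 40))
  oracle <- conjugate_cdic(des$X, des$y, 40)
  expect_equal(fit$pD, oracle$pD, tolerance = 0.1)
  expect_lt(abs(fit$cdic - oracle$cdic), 1.5)
})

test_that("cDIC comparisons apply the 5/10 decision rules", {
  expect_equal(cdic_compare(47480, 47510)$label, "clear choice")
  expect_equal(cdic_compare(47480, 47510)$preferred, 1L)
  expect_equal(cdic_compare(100, 104)$label, "no clear choice")
  expect_true(is.na(cdic_compare(100, 104)$preferred))
  expect_equal(cdic_compare(100, 107)$label, "suggestive, no clear choice")
})

test_that("the standalone imputation step draws only the missing cells", {
  state <- list(phi_cd4 = c(0, 0.5, -0.2), omega_cd4 = 1,
                phi_lvl = c(0, -0.3, 0.1), omega_lvl = 1,
                phi_sex = c(0.5, -0.1, 0.3, 0.2))
  b <- data.frame(sex = c(1, NA, 0, NA), age = c(0.2, -1, 0.5, 1),
                  baseline_cd4 = c(NA, 0.3, -0.2, 0.7),
                  baseline_log_vl = c(0.1, NA, 0.4, -0.5))
  set.seed(1)
  out <- impute_step(b, state, current = data.frame(sex = c(1, 0, 0, 1)))
  expect_false(anyNA(out))
  expect_identical(out$sex[c(1, 3)], b$sex[c(1, 3)])           # observed kept
  expect_identical(out$baseline_cd4[-1], b$baseline_cd4[-1])
  expect_true(all(out$sex %in% c(0, 1)))

  complete <- b; complete[is.na(complete)] <- 0
  expect_identical(impute_step(complete, state), complete)     # no-op

  expect_error(impute_step(b, state[-1]), "phi_cd4")
  bad <- state; bad$omega_cd4 <- 0
  expect_error(impute_step(b, bad), "positive")
  # jointly missing sex and a linear target need a completed copy to
  # condition on (inside the sampler this is the previous iteration)
  b2 <- data.frame(sex = NA, age = 0, baseline_cd4 = 1, baseline_log_vl = NA)
  expect_error(impute_step(b2, state), "needs sex")
  set.seed(2)
  out2 <- impute_step(b2, state, current = data.frame(sex = 1))
  expect_true(out2$sex %in% c(0, 1))
  expect_false(anyNA(out2))
})

test_that("missing-sex draws are Bernoulli from the logistic conditional", {
  state <- list(phi_cd4 = c(0, 0, 0), omega_cd4 = 1,
                phi_lvl = c(0, 0, 0), omega_lvl = 1,
                phi_sex = c(2, 0, 0, 0))  # strong intercept: p ~ 0.88
  b <- data.frame(sex = rep(NA_real_, 2000), age = 0, baseline_cd4 = 0.5,
                  baseline_log_vl = 0.5)
  set.seed(3)
  out <- impute_step(b, state)
  expect_true(all(out$sex %in% c(0, 1)))
  expect_equal(mean(out$sex), plogis(2), tolerance = 0.03)
})

test_that("BGR is near 1 for well-mixed chains and flags separated ones", {
  set.seed(4)
  same <- lapply(1:3, function(i) matrix(rnorm(4000), ncol = 2,
                                         dimnames = list(NULL, c("a", "b"))))
  g <- bgr(same)
  expect_true(all(g >= 0.99 & g < 1.05))
  expect_true(all(attr(g, "converged")))

  # cross-check against the reference implementation on the same draws
  ml <- coda::mcmc.list(lapply(same, coda::mcmc))
  ref <- coda::gelman.diag(ml, autoburnin = FALSE)$psrf[, 1]
  expect_equal(unname(g), unname(ref), tolerance = 0.02,
               ignore_attr = TRUE)

  apart <- list(matrix(rnorm(1000), ncol = 1),
                matrix(rnorm(1000, 10), ncol = 1))
  expect_gt(bgr(apart)[1], 1.1)

  const <- list(matrix(1, 100, 1), matrix(1, 100, 1))
  expect_equal(unname(bgr(const)[1]), 1)
  sep_const <- list(matrix(1, 100, 1), matrix(2, 100, 1))
  expect_equal(unname(bgr(sep_const)[1]), Inf)
  expect_error(bgr(list(matrix(rnorm(100), ncol = 1))), "2 chains")
})

test_that("the MC-error rule passes iid draws and fails a near-unit-root chain", {
  set.seed(5)
  iid <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "x"))
  res <- mc_error_check(list(iid))
  expect_true(res$ok)
  expect_lt(res$ratio, 0.02)

  n <- 4000
  ar <- numeric(n)
  for (i in 2:n) ar[i] <- 0.999 * ar[i - 1] + rnorm(1)
  res2 <- mc_error_check(list(matrix(ar, ncol = 1)))
  expect_false(res2$ok)

  expect_error(mc_error_check(list(matrix(rnorm(50), ncol = 1))),
               "too few draws")
})

test_that("summary scales, residuals and simulate are internally consistent", {
  sim <- simulate_asymptote_cohort(synthetic_config(n_patients = 30),
                                   seed = 14)
  co <- standardize_covariates(apply_exclusions(sim$cohort, "asymptote"))
  fit <- fit_cd4(co, cd4_model("asymptote", "poly2", cvl_adjusted = TRUE),
                 control = quick_control(seed = 11))
  s_or <- summary(fit, scale = "odds_ratio")
  # mean odds ratio is the mean of exponentiated draws, not exp(mean)
  sex_draws <- fit$pooled[, "beta[2]"]
  i <- match("sex", s_or$coefficients$parameter)
  expect_equal(s_or$coefficients$mean[i], mean(exp(sex_draws)))
  expect_gt(mean(exp(sex_draws)), exp(mean(sex_draws)))
  # equal-tail interval from skewed draws is asymmetric around the median
  expect_equal(unname(s_or$coefficients$`2.5%`[i]),
               unname(quantile(exp(sex_draws), 0.025)))

  r <- residuals(fit)
  obs <- !is.na(fit$design$y)
  expect_true(all(abs(r[obs]) <= 1))
  y_rep <- simulate(fit, nsim = 3, seed = 1)
  expect_true(all(y_rep %in% 0:1))
  expect_equal(dim(y_rep), c(nrow(fit$design$X), 3))
})
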