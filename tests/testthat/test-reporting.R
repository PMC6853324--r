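fake_fit <- function(cdic, pD = 10, spec = cd4_model("slope", "poly2")) {
  structure(list(model = spec, cdic = cdic, pD = pD), class = "cd4_fit")
}

test_that("the comparison table sorts, annotates and refuses single fits", {
  fits <- list(adjusted = fake_fit(100, spec = cd4_model(
                 "slope", "poly2", cvl_adjusted = TRUE)),
               unadjusted = fake_fit(120))
  tab <- model_comparison_table(fits)
  expect_equal(tab$model, c("adjusted", "unadjusted"))
  expect_equal(tab$delta_cdic, c(0, 20))
  expect_equal(tab$vs_best, c("best", "clear choice"))

  near <- model_comparison_table(list(a = fake_fit(100), b = fake_fit(103)))
  expect_equal(near$vs_best[2], "no clear choice")

  expect_error(model_comparison_table(list(fake_fit(100))), "at least two")
})

test_that("stratified trajectories behave: ranges, widening, collapse", {
  sim <- simulate_cohort(synthetic_config(n_patients = 40), seed = 19)
  co <- standardize_covariates(apply_exclusions(sim$cohort, "slope"))
  fit <- fit_cd4(co, cd4_model("slope", "poly2", cvl_adjusted = TRUE),
                 control = quick_control(seed = 2))

  tr_mean <- predict_trajectories(fit, strata_spec("sex"), ndraws = 60,
                                  type = "mean")
  set.seed(1)
  tr_pred <- predict_trajectories(fit, strata_spec("sex"), ndraws = 60,
                                  type = "prediction")
  expect_equal(nrow(tr_mean), 2 * 11)
  # residual noise widens (never narrows) the interval, stratum by stratum
  expect_true(all(tr_pred$upper - tr_pred$lower >=
                    tr_mean$upper - tr_mean$lower - 1e-9))

  # identical patients, degenerate draws, one stratum: the interval
  # collapses to the point prediction
  v0 <- data.frame(patient_id = rep(c("u", "v", "w"), each = 3),
                   time_on_art = rep(c(0, 0.5, 1), 3),
                   cd4 = 100, viral_load = 300)
  b0 <- data.frame(patient_id = c("u", "v", "w"), sex = 1, age = 30,
                   baseline_cd4 = 100, baseline_log_vl = 5, in_care = 1)
  d0 <- build_design(cohort_table(v0, b0),
                     cd4_model("slope", "poly2", cvl_adjusted = TRUE))
  fit0 <- fit_cd4(d0, control = mcmc_control(
    adapt = 100, burn_in = 100, n_iter = 200, seed = 1,
    random_effects = FALSE, fix_sigma = 10))
  fit0$pooled <- fit0$pooled[rep(1, 4), , drop = FALSE]
  tr0 <- predict_trajectories(fit0, strata_spec("age", numeric(0)),
                              grid = c(0, 0.5, 1), ndraws = 4,
                              type = "mean")
  expect_equal(tr0$stratum, rep("all", 3))
  expect_equal(tr0$lower, tr0$upper)
  expect_equal(tr0$lower, tr0$median)

  # an empty stratum is an explicit error
  expect_error(
    predict_trajectories(fit, strata_spec("age", cutpoints = 200),
                         ndraws = 5),
    "empty stratum")
})

test_that("asymptote trajectories are probabilities", {
  sim <- simulate_asymptote_cohort(synthetic_config(n_patients = 40),
                                   seed = 23)
  co <- standardize_covariates(apply_exclusions(sim$cohort, "asymptote"))
  fit <- fit_cd4(co, cd4_model("asymptote", "poly2", cvl_adjusted = TRUE),
                 control = quick_control(seed = 8))
  tr <- predict_trajectories(fit, strata_spec("baseline_cd4",
                                              cutpoints = 100), ndraws = 40)
  expect_true(all(tr$median >= 0 & tr$median <= 1))
  expect_true(all(tr$lower >= 0 & tr$upper <= 1))
  expect_true(all(tr$lower <= tr$median & tr$median <= tr$upper))
})

test_that("heavier realized viremia predicts the lowest trajectory", {
  # extreme, low-noise exposure effect so the ordering is not a coin flip
  cfg <- synthetic_config(
    n_patients = 60, sigma0 = 20, sigma1 = 5, rho = 0, sigma_eps = 20,
    dropout_hazard = 0,
    beta = c(`(Intercept)` = 150, sex = 23.8, age = -6.3,
             baseline_cd4 = 82.9, baseline_log_vl = 7.5, time = 55.7,
             time_sq = -22.7, cvl2 = -100))
  sim <- simulate_cohort(cfg, seed = 17)
  co <- standardize_covariates(apply_exclusions(sim$cohort, "slope"))
  fit <- fit_cd4(co, cd4_model("slope", "poly2", cvl_adjusted = TRUE),
                 control = quick_control(seed = 3))
  tr <- predict_trajectories(fit, strata_spec("cvl2", cutpoints = c(0.8)),
                             ndraws = 60, type = "mean")
  at5 <- tr[tr$time == 5, ]
  expect_lt(at5$median[at5$stratum == ">0.8"],
            at5$median[at5$stratum == "<=0.8"])
  expect_error(predict_trajectories(
    fit_cd4(co, cd4_model("slope", "poly2"),
            control = quick_control(seed = 3)),
    strata_spec("cvl2"), ndraws = 5), "adjusted")
})

test_that("strata definitions use the raw baseline scale", {
  sim <- simulate_cohort(synthetic_config(n_patients = 60), seed = 29)
  co <- standardize_covariates(apply_exclusions(sim$cohort, "slope"))
  d <- build_design(co, cd4_model("slope", "poly2"))
  lab <- cd4cvl:::stratum_of(d, strata_spec("baseline_cd4"))
  raw <- sim$truth$baseline_cd4[match(d$baseline$patient_id,
                                      sim$cohort$baselines$patient_id)]
  obs <- !is.na(d$baseline$baseline_cd4)
  expect_equal(unname(lab[obs] == "<=100"), unname(raw[obs] <= 100))
  expect_error(strata_spec("age", cutpoints = c(60, 50)), "increasing")
})
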