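test_that("the noise-free limit reproduces the fixed-effect surface exactly", {
  cfg <- synthetic_config(n_patients = 40, sigma0 = 0, sigma1 = 0, rho = 0,
                          sigma_eps = 0, p_missing_vl = 0, p_missing_cd4 = 0,
                          p_missing_sex = 0, p_missing_bcd4 = 0,
                          p_missing_blvl = 0, truncate_negative = FALSE)
  sim <- simulate_cohort(cfg, seed = 9)
  tr <- sim$truth
  v <- sim$cohort$visits
  expect_equal(v$cd4, tr$eta)
  expect_equal(tr$eta, tr$eta_fixed)    # no random effects

  # the truth record suffices to rebuild the noiseless linear predictor
  std <- tr$standardization
  zs <- function(x, cv) (x - std$mean[std$covariate == cv]) /
    std$sd[std$covariate == cv]
  pid <- match(v$patient_id, sim$cohort$baselines$patient_id)
  beta <- tr$beta
  eta <- beta[["(Intercept)"]] + beta[["sex"]] * tr$sex[pid] +
    beta[["age"]] * zs(tr$age, "age")[pid] +
    beta[["baseline_cd4"]] * zs(tr$baseline_cd4, "baseline_cd4")[pid] +
    beta[["baseline_log_vl"]] * zs(tr$baseline_log_vl,
                                   "baseline_log_vl")[pid] +
    beta[["time"]] * v$time_on_art +
    beta[["time_sq"]] * zs(v$time_on_art^2, "time_sq") +
    beta[["cvl2"]] * tr$in_care[pid] * tr$cvl2
  expect_equal(eta, tr$eta_fixed)
})

test_that("baseline covariate distributions match the target medians", {
  sim <- simulate_cohort(synthetic_config(n_patients = 10000), seed = 123)
  tr <- sim$truth
  expect_lt(abs(median(tr$baseline_cd4) - 89) / 89, 0.05)
  expect_lt(abs(median(tr$age) - 36) / 36, 0.05)
  expect_lt(abs(median(tr$baseline_log_vl) - 5.1) / 5.1, 0.05)
  expect_lt(abs(mean(tr$sex) - 0.696), 0.02)
})

test_that("viral-load missingness hits the configured rate", {
  sim <- simulate_cohort(synthetic_config(n_patients = 750), seed = 55)
  v <- sim$cohort$visits
  post <- v$time_on_art > 0
  frac <- mean(is.na(v$viral_load[post]))
  expect_lt(abs(frac - 0.49), 0.02)
  expect_true(all(!is.na(v$viral_load[!post])))   # baseline VL anchors
})

test_that("generated cohorts validate, round-trip and are seed-reproducible", {
  sim1 <- simulate_cohort(synthetic_config(n_patients = 40), seed = 77)
  sim2 <- simulate_cohort(synthetic_config(n_patients = 40), seed = 77)
  expect_identical(sim1$cohort$visits, sim2$cohort$visits)
  expect_identical(sim1$truth$b, sim2$truth$b)
  sim3 <- simulate_cohort(synthetic_config(n_patients = 40), seed = 78)
  expect_false(identical(sim1$cohort$visits$cd4, sim3$cohort$visits$cd4))

  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim1$cohort, path)
  back <- read_cohort(path)
  expect_equal(back$visits$cd4, sim1$cohort$visits$cd4)
})

test_that("injected baseline-only patients and second-line visits are excluded", {
  cfg <- synthetic_config(n_patients = 30, n_baseline_only = 5,
                          p_second_line = 0.5)
  sim <- simulate_cohort(cfg, seed = 10)
  expect_equal(nrow(sim$cohort$baselines), 35)
  co <- apply_exclusions(sim$cohort, "slope")
  rep <- attr(co, "exclusions")
  expect_gte(rep$reasons$n_patients[rep$reasons$reason == "baseline-only"], 5)
  expect_gt(rep$n_second_line_visits, 0)
  expect_true(all(co$visits$first_line))
})

test_that("asymptote generator: null model gives 50% prevalence, seeds reproduce", {
  cfg0 <- synthetic_config(
    n_patients = 400,
    beta_logit = c(`(Intercept)` = 0, sex = 0, age = 0, baseline_cd4 = 0,
                   baseline_log_vl = 0, time = 0, time_sq = 0, cvl2 = 0),
    sigma0_logit = 0, sigma1_logit = 0, rho_logit = 0)
  sim <- simulate_asymptote_cohort(cfg0, seed = 21)
  y <- sim$truth$y
  expect_lt(abs(mean(y, na.rm = TRUE) - 0.5), 0.03)

  s1 <- simulate_asymptote_cohort(synthetic_config(n_patients = 30), seed = 5)
  s2 <- simulate_asymptote_cohort(synthetic_config(n_patients = 30), seed = 5)
  expect_identical(s1$cohort$visits, s2$cohort$visits)
})

test_that("stronger cumulative viremia lowers the chance of reaching 500", {
  sim <- simulate_asymptote_cohort(synthetic_config(n_patients = 1500),
                                   seed = 31)
  tr <- sim$truth
  v <- sim$cohort$visits
  cvl_max <- tapply(tr$cvl2, v$patient_id, max)
  keep <- tr$in_care == 1          # the effect acts through in_care * cvl2
  ter <- cut(cvl_max[keep], quantile(cvl_max[keep], c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE, labels = c("low", "mid", "high"))
  rate <- tapply(tr$ever_500[keep], ter, mean)
  expect_gt(rate[["low"]], rate[["high"]])

  # realism: roughly a third of patients ever cross 500 cells/uL
  expect_gt(mean(tr$ever_500), 0.338 - 0.15)
  expect_lt(mean(tr$ever_500), 0.338 + 0.15)

  # baseline CD4 >= 500 never occurs by construction
  expect_true(all(sim$cohort$baselines$baseline_cd4 < 500, na.rm = TRUE))
})
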