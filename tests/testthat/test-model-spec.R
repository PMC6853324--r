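test_that("the nine model variants map to their numbers and invalid combos fail", {
  expect_equal(model_number(cd4_model("slope", "poly2")), 1L)
  expect_equal(model_number(cd4_model("slope", "bspline3")), 2L)
  expect_equal(model_number(cd4_model("slope", "bspline5")), 3L)
  expect_equal(model_number(cd4_model("slope", "poly2",
                                      re_dist = "skew_normal")), 4L)
  expect_equal(model_number(cd4_model("slope", "poly2",
                                      re_dist = "skew_normal",
                                      error_dist = "skew_normal")), 5L)
  expect_equal(model_number(cd4_model("asymptote", "poly2")), 6L)
  expect_equal(model_number(cd4_model("asymptote", "poly2",
                                      re_dist = "skew_normal")), 7L)
  expect_equal(model_number(cd4_model("asymptote", "bspline3")), 8L)
  expect_equal(model_number(cd4_model("asymptote", "bspline5")), 9L)
  expect_error(cd4_model("asymptote", error_dist = "skew_normal"),
               "no error term")
})

test_that("time bases: raw quadratic, and B-splines that partition unity", {
  expect_equal(time_basis(2, "poly2"), cbind(time = 2, time_sq = 4))
  expect_equal(unname(time_basis(0, "poly2")), cbind(0, 0))
  expect_error(time_basis(5.2, "poly2"), "outside")
  expect_error(time_basis(-0.1, "bspline3"), "outside")

  tt <- seq(0, 5, by = 0.25)
  for (basis in c("bspline3", "bspline5")) {
    knots <- if (basis == "bspline3") c(1.25, 2.5, 3.751) else
      c(0.833, 1.666, 2.5, 3.334, 4.167)
    full <- splines::bs(tt, knots = knots, degree = 3,
                        Boundary.knots = c(0, 5), intercept = TRUE)
    expect_equal(rowSums(full), rep(1, length(tt)))   # partition of unity
    mine <- time_basis(tt, basis)
    expect_equal(ncol(mine), length(knots) + 3)
    expect_equal(unname(mine), unname(unclass(full)[, -1]))
  }
})

test_that("design matrices assemble per specification", {
  sim <- simulate_cohort(synthetic_config(n_patients = 25), seed = 8)
  co <- standardize_covariates(apply_exclusions(sim$cohort, "slope"))

  d_un <- build_design(co, cd4_model("slope", "poly2"))
  expect_equal(ncol(d_un$X), 5 + 2)
  expect_false("cvl2" %in% colnames(d_un$X))

  d_adj <- build_design(co, cd4_model("slope", "poly2", cvl_adjusted = TRUE))
  expect_equal(ncol(d_adj$X), 5 + 2 + 1)
  expect_equal(setdiff(colnames(d_adj$X), colnames(d_un$X)), "cvl2")

  d_bs <- build_design(co, cd4_model("slope", "bspline3",
                                     cvl_adjusted = TRUE))
  expect_equal(ncol(d_bs$X), 5 + 6 + 1)

  # lost-to-follow-up patients carry an identically zero cVL2 column
  out <- d_adj$baseline$in_care == 0
  if (any(out)) {
    rows <- d_adj$pat %in% which(out)
    expect_true(all(d_adj$X[rows, "cvl2"] == 0))
  }
  # missing covariate cells are flagged, not dropped
  expect_equal(nrow(d_adj$X), nrow(co$visits))
  expect_equal(length(d_adj$missing$sex), sum(is.na(co$baselines$sex)))
})

test_that("asymptote outcomes code the 500 cells/uL threshold at follow-up visits", {
  v <- data.frame(patient_id = rep("p", 4), time_on_art = c(0, 0.5, 1, 1.5),
                  cd4 = c(200, 499, 500, NA), viral_load = 1000)
  b <- data.frame(patient_id = "p", sex = 1, age = 30, baseline_cd4 = 200,
                  baseline_log_vl = 5, in_care = 1)
  co <- cohort_table(v, b)
  d <- build_design(co, cd4_model("asymptote", "poly2"))
  expect_equal(nrow(d$X), 3)                 # baseline row is not an outcome
  expect_equal(d$y, c(0, 1, NA))
  expect_true(all(d$y %in% c(0, 1, NA)))
})

test_that("skew-normal density integrates to one and collapses to the Gaussian", {
  for (delta in c(-2, 0, 1.5, 4)) {
    total <- integrate(dsn, -Inf, Inf, sigma = 1.3, delta = delta,
                       rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-7)
  }
  x <- seq(-4, 4, 0.5)
  expect_equal(dsn(x, sigma = 2, delta = 0), dnorm(x, 0, 2))
})

test_that("conditional log likelihood matches elementary cases", {
  v <- data.frame(patient_id = "p", time_on_art = c(0, 1), cd4 = c(0, 0),
                  viral_load = 1000)
  b <- data.frame(patient_id = "p", sex = 0, age = 0, baseline_cd4 = 0,
                  baseline_log_vl = 0, in_care = 1)
  co <- cohort_table(v, b)
  d <- build_design(co, cd4_model("slope", "poly2"))
  d$y <- c(0, NA)      # a single observed standard-normal point at zero
  p0 <- list(beta = rep(0, 7), b = matrix(0, 1, 2), sigma_eps = 1)
  expect_equal(cd4_log_lik(p0, d), -0.5 * log(2 * pi))

  # skew-normal error with delta = 0 equals the Gaussian log likelihood
  d$y <- c(1.3, -0.4)
  p1 <- list(beta = rep(0, 7), b = matrix(0, 1, 2), sigma_eps = 2,
             delta_eps = 0)
  p2 <- p1; p2$delta_eps <- 1e-300  # forces the SN branch
  expect_equal(cd4_log_lik(p1, d),
               sum(dnorm(d$y, 0, 2, log = TRUE)))
  expect_equal(cd4_log_lik(p2, d), cd4_log_lik(p1, d))

  # asymptote with linear predictor zero: log(1/2) per observation
  va <- data.frame(patient_id = "p", time_on_art = c(0, 1, 2),
                   cd4 = c(100, 600, 100), viral_load = 1000)
  coa <- cohort_table(va, b)
  da <- build_design(coa, cd4_model("asymptote", "poly2"))
  pa <- list(beta = rep(0, 7), b = matrix(0, 1, 2))
  expect_equal(cd4_log_lik(pa, da), 2 * log(0.5))
})
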