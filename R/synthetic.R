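#' Configuration of the synthetic ART cohort generator
#'
#' Defaults emulate the cohort the analysis targets: 750 patients seen
#' 6-monthly for 5 years, ~70% female, median baseline CD4 near 89 cells/uL
#' (gamma), median baseline log10 VL near 5.1 (normal), median baseline age
#' near 36 years (lognormal), about 49% of post-baseline viral loads
#' missing, sporadic missing baseline covariates, and true fixed effects
#' set to the published adjusted polynomial slope model estimates, including
#' a cVL2 effect of -19.6 cells/uL per log10 copy-year/mL. The quadratic
#' time coefficient is applied to the z-scored squared time over the visit
#' grid (the scale on which the published estimate lives); all other
#' continuous covariates enter z-scored by their population moments, linear
#' time in raw years, sex as 0/1.
#'
#' Viral-load trajectories follow a two-state (suppressed/detectable)
#' per-visit Markov process: a detectable patient suppresses with
#' probability `p_suppress` at each visit, a suppressed patient rebounds
#' with probability `p_rebound`; detectable values are drawn uniformly on
#' the log10 scale over `rebound_log10_range`, suppressed values over
#' `suppressed_log10_range` (below the 400 copies/mL analysis threshold).
#'
#' @param n_patients cohort size.
#' @param visit_interval years between scheduled visits.
#' @param horizon follow-up horizon (years); a multiple of `visit_interval`.
#' @param p_female probability of female sex.
#' @param age_meanlog,age_sdlog lognormal baseline age parameters.
#' @param cd4_shape,cd4_rate gamma baseline CD4 parameters.
#' @param lvl_mean,lvl_sd normal baseline log10 VL parameters.
#' @param p_suppress,p_rebound Markov transition probabilities per visit.
#' @param rebound_log10_range,suppressed_log10_range log10 VL ranges for the
#'   two states.
#' @param p_missing_vl fraction of post-baseline viral loads missing.
#' @param p_missing_sex,p_missing_bcd4,p_missing_blvl per-patient baseline
#'   covariate missingness.
#' @param p_missing_cd4 per-visit missingness of the CD4 outcome.
#' @param missing_mechanism `"mcar"` or `"mar"` (CD4 missingness then
#'   depends on the previous visit's CD4 through a logistic model).
#' @param dropout_hazard per-visit probability of dropping out of care
#'   (dropouts have `in_care = 0` and no further visits).
#' @param beta named true fixed effects: `(Intercept)`, `sex`, `age`,
#'   `baseline_cd4`, `baseline_log_vl`, `time`, `time_sq`, `cvl2`.
#' @param sigma0,sigma1,rho random intercept/slope sds and correlation.
#' @param delta random-effects skewness (0 = Gaussian).
#' @param sigma_eps residual sd (cells/uL).
#' @param delta_eps error skewness (0 = Gaussian errors).
#' @param truncate_negative clamp negative simulated CD4 counts at 0 (the
#'   count is reported in the truth record).
#' @param n_baseline_only extra patients with only a baseline visit
#'   (exercise the exclusion filters).
#' @param p_second_line fraction of patients switched to second-line ART at
#'   a random visit (later visits flagged `first_line = FALSE`).
#' @param detection_limit threshold used for the internally computed cVL2.
#' @param beta_logit,sigma0_logit,sigma1_logit,rho_logit,delta_logit true
#'   parameters of the asymptote (logit-scale) generator.
#' @return list of class `cd4_synth_config`.
#' @export
synthetic_config <- function(n_patients = 750,
                             visit_interval = 0.5,
                             horizon = 5,
                             p_female = 0.696,
                             age_meanlog = 3.585036, age_sdlog = 0.2254667,
                             cd4_shape = 1.504, cd4_rate = 0.013586,
                             lvl_mean = 5.1, lvl_sd = 0.6227,
                             p_suppress = 0.85, p_rebound = 0.08,
                             rebound_log10_range = c(3, 5),
                             suppressed_log10_range = c(log10(50), 2.55),
                             p_missing_vl = 0.49,
                             p_missing_sex = 0.02,
                             p_missing_bcd4 = 0.03,
                             p_missing_blvl = 0.03,
                             p_missing_cd4 = 0.03,
                             missing_mechanism = c("mcar", "mar"),
                             dropout_hazard = 0.03,
                             beta = c(`(Intercept)` = 87, sex = 23.8,
                                      age = -6.3, baseline_cd4 = 82.9,
                                      baseline_log_vl = 7.5, time = 55.7,
                                      time_sq = -22.7, cvl2 = -19.6),
                             sigma0 = 70, sigma1 = 25, rho = -0.2,
                             delta = 0, sigma_eps = 60, delta_eps = 0,
                             truncate_negative = TRUE,
                             n_baseline_only = 0, p_second_line = 0,
                             detection_limit = 400,
                             beta_logit = c(`(Intercept)` = -8.5,
                                            sex = 1.85, age = -0.62,
                                            baseline_cd4 = 1.10,
                                            baseline_log_vl = 0.23,
                                            time = 1.41, time_sq = -0.43,
                                            cvl2 = -0.87),
                             sigma0_logit = 1.5, sigma1_logit = 0.4,
                             rho_logit = 0, delta_logit = 0) {
  missing_mechanism <- match.arg(missing_mechanism)
  probs <- c(p_female, p_suppress, p_rebound, p_missing_vl, p_missing_sex,
             p_missing_bcd4, p_missing_blvl, p_missing_cd4, dropout_hazard,
             p_second_line)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (dropout_hazard >= 1) stop("dropout hazard must be < 1")
  k <- horizon / visit_interval
  if (abs(k - round(k)) > 1e-8)
    stop("horizon must be a multiple of visit_interval")
  cfg <- as.list(environment())
  class(cfg) <- "cd4_synth_config"
  cfg
}

# population standardization constants implied by a config
synth_standardization <- function(cfg) {
  grid <- seq(0, cfg$horizon, by = cfg$visit_interval)
  age_mean <- exp(cfg$age_meanlog + cfg$age_sdlog^2 / 2)
  age_sd <- age_mean * sqrt(exp(cfg$age_sdlog^2) - 1)
  data.frame(
    covariate = c("age", "baseline_cd4", "baseline_log_vl", "time_sq"),
    mean = c(age_mean, cfg$cd4_shape / cfg$cd4_rate, cfg$lvl_mean,
             mean(grid^2)),
    sd = c(age_sd, sqrt(cfg$cd4_shape) / cfg$cd4_rate, cfg$lvl_sd,
           stats::sd(grid^2)))
}

# shared simulation of covariates, visit schedule and viral-load series
synth_frame <- function(cfg) {
  P <- cfg$n_patients
  grid <- seq(0, cfg$horizon, by = cfg$visit_interval)
  nv <- length(grid)

  sex <- stats::rbinom(P, 1, cfg$p_female)
  age <- stats::rlnorm(P, cfg$age_meanlog, cfg$age_sdlog)
  bcd4 <- stats::rgamma(P, cfg$cd4_shape, cfg$cd4_rate)
  blvl <- stats::rnorm(P, cfg$lvl_mean, cfg$lvl_sd)

  # dropout: geometric number of completed post-baseline visits
  last_visit <- rep(nv, P)
  in_care <- rep(1, P)
  if (cfg$dropout_hazard > 0) {
    drop_at <- 1 + stats::rgeom(P, cfg$dropout_hazard)  # visit index of dropout
    lost <- drop_at < nv
    last_visit[lost] <- pmax(drop_at[lost], 2)  # keep >= 1 post-baseline visit
    in_care[lost] <- 0
  }

  vl <- matrix(NA_real_, P, nv)
  for (i in seq_len(P)) {
    detectable <- TRUE
    vl[i, 1] <- 10^blvl[i]
    for (k in 2:last_visit[i]) {
      detectable <- if (detectable) stats::runif(1) > cfg$p_suppress
        else stats::runif(1) < cfg$p_rebound
      rng <- if (detectable) cfg$rebound_log10_range
        else cfg$suppressed_log10_range
      vl[i, k] <- 10^stats::runif(1, rng[1], rng[2])
    }
  }
  # viral-load missingness is part of the measurement process: the exposure
  # covariate that drives the outcome is the bridged cVL2 computed from the
  # visits that will actually carry a measurement (baseline always measured)
  vl_obs <- vl
  if (cfg$p_missing_vl > 0) {
    miss <- matrix(stats::runif(P * nv) < cfg$p_missing_vl, P, nv)
    miss[, 1] <- FALSE
    vl_obs[miss] <- NA
  }
  list(grid = grid, nv = nv, sex = sex, age = age, bcd4 = bcd4, blvl = blvl,
       last_visit = last_visit, in_care = in_care, vl = vl, vl_obs = vl_obs)
}

# running cVL2 per patient from the observed (post-missingness) series,
# using the same bridged trapezoid rule the analysis applies
synth_cvl2 <- function(fr, cfg) {
  P <- nrow(fr$vl_obs)
  cvl <- matrix(0, P, fr$nv)
  for (i in seq_len(P)) {
    k <- seq_len(fr$last_visit[i])
    cvl[i, k] <- running_cvl2(fr$grid[k], fr$vl_obs[i, k],
                              cfg$detection_limit)
  }
  cvl
}

# bivariate random effects, Gaussian or skew-normal (location-zero)
synth_raneff <- function(P, s0, s1, rho, delta) {
  if (s0 == 0 && s1 == 0) {
    b <- matrix(0, P, 2)
  } else {
    z <- matrix(stats::rnorm(2 * P), P, 2)
    b <- cbind(s0 * z[, 1],
               s1 * (rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]))
  }
  if (delta != 0) b <- b + delta * abs(matrix(stats::rnorm(2 * P), P, 2))
  b
}

#' Generate a synthetic ART cohort for the slope model
#'
#' Draws baseline covariates, simulates suppressed/rebounding viral-load
#' series and the implied cumulative log viral load, generates CD4 counts
#' from the linear mixed model `CD4 = X beta + b0 + b1 t + eps` (random
#' effects Gaussian or skew-normal per `delta`), then applies missingness.
#' The returned truth record retains every random effect, the noiseless
#' linear predictor, and all pre-missingness values, so that recovery can
#' be checked exactly.
#'
#' @param cfg a [synthetic_config()].
#' @param seed optional integer seed.
#' @return list with `cohort` (a `cd4_cohort`, unstandardized) and `truth`.
#' @export
simulate_cohort <- function(cfg = synthetic_config(), seed = NULL) {
  stopifnot(inherits(cfg, "cd4_synth_config"))
  if (!is.null(seed)) set.seed(seed)
  fr <- synth_frame(cfg)
  std <- synth_standardization(cfg)
  cvl <- synth_cvl2(fr, cfg)
  P <- cfg$n_patients
  b <- synth_raneff(P, cfg$sigma0, cfg$sigma1, cfg$rho, cfg$delta)

  zs <- function(x, cov) (x - std$mean[std$covariate == cov]) /
    std$sd[std$covariate == cov]
  z_age <- zs(fr$age, "age")
  z_bcd4 <- zs(fr$bcd4, "baseline_cd4")
  z_blvl <- zs(fr$blvl, "baseline_log_vl")

  beta <- cfg$beta
  rows <- lapply(seq_len(P), function(i) {
    k <- seq_len(fr$last_visit[i])
    t <- fr$grid[k]
    eta <- beta[["(Intercept)"]] + beta[["sex"]] * fr$sex[i] +
      beta[["age"]] * z_age[i] + beta[["baseline_cd4"]] * z_bcd4[i] +
      beta[["baseline_log_vl"]] * z_blvl[i] +
      beta[["time"]] * t + beta[["time_sq"]] * zs(t^2, "time_sq") +
      beta[["cvl2"]] * fr$in_care[i] * cvl[i, k]
    data.frame(patient_id = sprintf("P%04d", i), time_on_art = t,
               eta = eta + b[i, 1] + b[i, 2] * t,
               eta_fixed = eta, viral_load = fr$vl_obs[i, k],
               vl_complete = fr$vl[i, k],
               cvl2 = cvl[i, k], stringsAsFactors = FALSE)
  })
  vis <- do.call(rbind, rows)
  n <- nrow(vis)
  eps <- stats::rnorm(n, 0, cfg$sigma_eps)
  if (cfg$delta_eps != 0) eps <- eps + cfg$delta_eps * abs(stats::rnorm(n))
  cd4 <- vis$eta + eps
  n_truncated <- sum(cd4 < 0)
  if (cfg$truncate_negative) cd4 <- pmax(cd4, 0)

  out <- assemble_cohort(cfg, fr, vis, cd4, z_scores = NULL)
  out$truth <- c(out$truth, list(
    beta = beta, b = b, eta = vis$eta, eta_fixed = vis$eta_fixed,
    cvl2 = vis$cvl2, cd4_complete = cd4,
    sigma0 = cfg$sigma0, sigma1 = cfg$sigma1, rho = cfg$rho,
    delta = cfg$delta, sigma_eps = cfg$sigma_eps,
    n_truncated = n_truncated,
    standardization = std))
  out
}

#' Generate a synthetic cohort for the asymptote model
#'
#' Binary outcomes (CD4 >= 500 at post-baseline visits) are drawn from the
#' logistic mixed model `logit P(y=1) = X beta_logit + b0 + b1 t`; a CD4
#' value consistent with each outcome is synthesized so the cohort passes
#' through the same pipeline as real data. Baseline CD4 draws at or above
#' 500 cells/uL are regenerated so the analysis precondition holds.
#'
#' @inheritParams simulate_cohort
#' @export
simulate_asymptote_cohort <- function(cfg = synthetic_config(),
                                      seed = NULL) {
  stopifnot(inherits(cfg, "cd4_synth_config"))
  if (!is.null(seed)) set.seed(seed)
  fr <- synth_frame(cfg)
  while (any(fr$bcd4 >= 500)) {
    i <- fr$bcd4 >= 500
    fr$bcd4[i] <- stats::rgamma(sum(i), cfg$cd4_shape, cfg$cd4_rate)
  }
  std <- synth_standardization(cfg)
  cvl <- synth_cvl2(fr, cfg)
  P <- cfg$n_patients
  b <- synth_raneff(P, cfg$sigma0_logit, cfg$sigma1_logit, cfg$rho_logit,
                    cfg$delta_logit)

  zs <- function(x, cov) (x - std$mean[std$covariate == cov]) /
    std$sd[std$covariate == cov]
  z_age <- zs(fr$age, "age")
  z_bcd4 <- zs(fr$bcd4, "baseline_cd4")
  z_blvl <- zs(fr$blvl, "baseline_log_vl")

  beta <- cfg$beta_logit
  rows <- lapply(seq_len(P), function(i) {
    k <- seq_len(fr$last_visit[i])
    t <- fr$grid[k]
    eta <- beta[["(Intercept)"]] + beta[["sex"]] * fr$sex[i] +
      beta[["age"]] * z_age[i] + beta[["baseline_cd4"]] * z_bcd4[i] +
      beta[["baseline_log_vl"]] * z_blvl[i] +
      beta[["time"]] * t + beta[["time_sq"]] * zs(t^2, "time_sq") +
      beta[["cvl2"]] * fr$in_care[i] * cvl[i, k]
    data.frame(patient_id = sprintf("P%04d", i), time_on_art = t,
               eta = eta + b[i, 1] + b[i, 2] * t, eta_fixed = eta,
               viral_load = fr$vl_obs[i, k], vl_complete = fr$vl[i, k],
               cvl2 = cvl[i, k],
               stringsAsFactors = FALSE)
  })
  vis <- do.call(rbind, rows)
  pi <- stats::plogis(vis$eta)
  y <- stats::rbinom(nrow(vis), 1, pi)
  baseline_row <- vis$time_on_art == 0
  # CD4 values consistent with the binary outcome; baseline = the covariate
  cd4 <- ifelse(y == 1, 500 + stats::rexp(nrow(vis), 1 / 150),
                stats::runif(nrow(vis), 10, 499))
  cd4[baseline_row] <- rep(fr$bcd4, vapply(rows, nrow, 1L))[baseline_row]
  y[baseline_row] <- NA  # outcome defined at post-baseline visits only

  out <- assemble_cohort(cfg, fr, vis, cd4, z_scores = NULL)
  out$truth <- c(out$truth, list(
    beta_logit = beta, b = b, eta = vis$eta, eta_fixed = vis$eta_fixed,
    cvl2 = vis$cvl2, y = y, prob = pi, cd4_complete = cd4,
    ever_500 = tapply(!is.na(y) & y == 1, vis$patient_id, any),
    standardization = std))
  out
}

# apply missingness and build the cd4_cohort + base truth record
assemble_cohort <- function(cfg, fr, vis, cd4, z_scores) {
  P <- cfg$n_patients
  n <- nrow(vis)
  post <- vis$time_on_art > 0

  cd4_obs <- cd4
  if (cfg$missing_mechanism == "mar") {
    prev <- c(NA, cd4[-n])
    prev[!post] <- NA
    pm <- stats::plogis(stats::qlogis(max(cfg$p_missing_cd4, 1e-6)) -
                          (prev - 200) / 200)
    pm[is.na(prev)] <- cfg$p_missing_cd4
    miss_cd4 <- stats::runif(n) < pm
  } else {
    miss_cd4 <- stats::runif(n) < cfg$p_missing_cd4
  }
  cd4_obs[miss_cd4] <- NA

  sex_obs <- fr$sex
  bcd4_obs <- fr$bcd4
  blvl_obs <- fr$blvl
  sex_obs[stats::runif(P) < cfg$p_missing_sex] <- NA
  bcd4_obs[stats::runif(P) < cfg$p_missing_bcd4] <- NA
  blvl_obs[stats::runif(P) < cfg$p_missing_blvl] <- NA

  first_line <- rep(TRUE, n)
  if (cfg$p_second_line > 0) {
    switchers <- which(stats::runif(P) < cfg$p_second_line)
    for (i in switchers) {
      rows <- which(vis$patient_id == sprintf("P%04d", i))
      if (length(rows) > 2) {
        sw <- sample(3:length(rows), 1)
        first_line[rows[sw:length(rows)]] <- FALSE
      }
    }
  }

  visits <- data.frame(patient_id = vis$patient_id,
                       time_on_art = vis$time_on_art,
                       cd4 = cd4_obs, viral_load = vis$viral_load,
                       first_line = first_line, stringsAsFactors = FALSE)
  baselines <- data.frame(patient_id = sprintf("P%04d", seq_len(P)),
                          sex = sex_obs, age = fr$age,
                          baseline_cd4 = bcd4_obs, baseline_log_vl = blvl_obs,
                          in_care = fr$in_care, stringsAsFactors = FALSE)
  if (cfg$n_baseline_only > 0) {
    ids <- sprintf("B%04d", seq_len(cfg$n_baseline_only))
    visits <- rbind(visits, data.frame(
      patient_id = ids, time_on_art = 0,
      cd4 = stats::rgamma(cfg$n_baseline_only, cfg$cd4_shape, cfg$cd4_rate),
      viral_load = 10^stats::rnorm(cfg$n_baseline_only, cfg$lvl_mean,
                                   cfg$lvl_sd),
      first_line = TRUE, stringsAsFactors = FALSE))
    baselines <- rbind(baselines, data.frame(
      patient_id = ids, sex = stats::rbinom(cfg$n_baseline_only, 1,
                                            cfg$p_female),
      age = stats::rlnorm(cfg$n_baseline_only, cfg$age_meanlog,
                          cfg$age_sdlog),
      baseline_cd4 = NA, baseline_log_vl = NA, in_care = 0,
      stringsAsFactors = FALSE))
    baselines$baseline_cd4[baselines$patient_id %in% ids] <-
      visits$cd4[match(ids, visits$patient_id)]
    baselines$baseline_log_vl[baselines$patient_id %in% ids] <-
      log10(visits$viral_load[match(ids, visits$patient_id)])
  }

  cohort <- cohort_table(visits, baselines)
  list(cohort = cohort,
       truth = list(config = cfg,
                    sex = fr$sex, age = fr$age, baseline_cd4 = fr$bcd4,
                    baseline_log_vl = fr$blvl, in_care = fr$in_care,
                    vl_complete = vis$vl_complete,
                    missing_vl = which(is.na(vis$viral_load)),
                    missing_cd4 = which(miss_cd4)))
}
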