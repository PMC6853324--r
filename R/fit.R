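#' MCMC sampler configuration
#'
#' @param n_chains number of chains (>= 2 for the BGR diagnostic).
#' @param adapt adaptation iterations.
#' @param burn_in burn-in iterations discarded before monitoring.
#' @param n_iter monitored iterations per chain.
#' @param thin thinning interval.
#' @param seed integer seed; drives the chain-specific RNG seeds and the
#'   dispersed initial values, making runs bitwise reproducible.
#' @param sn_center `"location"` (the skew-normal's zero is its location;
#'   default) or `"mean"` (the `delta*sqrt(2/pi)` correction is applied so
#'   zero is the mean).
#' @param delta_structure `"shared"` (one error-skewness parameter) or
#'   `"by_visit"` (one per visit rank).
#' @param sd_upper upper bound of the uniform prior on the residual sd.
#' @param random_effects set `FALSE` for the reduced fixed-effects-only
#'   validation model.
#' @param fix_sigma fix the residual sd at a known value (validation use).
#' @param mc_error_target Monte Carlo error threshold as a fraction of the
#'   posterior sd (default 0.05).
#' @param quiet suppress sampler progress output.
#' @return list of class `cd4_mcmc_control`.
#' @export
mcmc_control <- function(n_chains = 3, adapt = 300, burn_in = 1000,
                         n_iter = 2000, thin = 1, seed = 1,
                         sn_center = c("location", "mean"),
                         delta_structure = c("shared", "by_visit"),
                         sd_upper = 1000, random_effects = TRUE,
                         fix_sigma = NULL, mc_error_target = 0.05,
                         quiet = TRUE) {
  sn_center <- match.arg(sn_center)
  stopifnot(n_chains >= 1, burn_in > 0, n_iter > 0, thin >= 1)
  structure(list(n_chains = n_chains, adapt = adapt, burn_in = burn_in,
                 n_iter = n_iter, thin = thin, seed = as.integer(seed),
                 sn_center = sn_center,
                 sn_center_value = if (sn_center == "mean")
                   sqrt(2 / pi) else 0,
                 delta_structure = match.arg(delta_structure),
                 sd_upper = sd_upper, random_effects = random_effects,
                 fix_sigma = fix_sigma, mc_error_target = mc_error_target,
                 quiet = quiet),
            class = "cd4_mcmc_control")
}

#' Iteration-schedule presets
#'
#' `"desk"` is the scaled-down schedule used throughout the test suite
#' (3 chains, 1000 burn-in, 2000 monitored). The `"full_*"` presets are the
#' production schedules for the different model families: 20K/45K for the
#' polynomial slope models, 80K/100K for spline and asymptote variants,
#' 250K/250K for the skew-normal slope model and 500K/500K for the
#' skew-normal asymptote model.
#'
#' @param preset preset name.
#' @param ... overrides passed on to [mcmc_control()].
#' @export
mcmc_preset <- function(preset = c("desk", "full_poly2", "full_other",
                                   "full_sn_slope", "full_sn_asymptote"),
                        ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    desk = list(burn_in = 1000, n_iter = 2000),
    full_poly2 = list(burn_in = 20000, n_iter = 45000),
    full_other = list(burn_in = 80000, n_iter = 100000),
    full_sn_slope = list(burn_in = 250000, n_iter = 250000),
    full_sn_asymptote = list(burn_in = 500000, n_iter = 500000))
  do.call(mcmc_control, utils::modifyList(args, list(...)))
}

#' Fit a CD4 mixed-effects model by MCMC
#'
#' Runs the full Bayesian machinery for one model specification: several
#' chains from dispersed initial values; within every iteration, missing
#' baseline CD4 and baseline log viral load are drawn from their linear
#' imputation conditionals, missing sex from its binary conditional, and
#' missing outcomes from the model's predictive distribution; monitored
#' draws are summarized as posterior means with 95% equal-tail credible
#' intervals, and the conditional DIC, Brooks-Gelman-Rubin statistics and
#' Monte Carlo error flags are computed from the pooled draws.
#'
#' @param x a `cd4_cohort` (exclusions and standardization applied) or a
#'   prebuilt [build_design()] object.
#' @param model a [cd4_model()] (ignored when `x` is already a design).
#' @param priors a [prior_spec()]; vague Gaussian priors when `NULL`.
#' @param control a [mcmc_control()].
#' @param cvl,detection_limit,standardize_cvl passed to [build_design()].
#' @return Object of class `cd4_fit` with elements `draws` (a
#'   [coda::mcmc.list]), `summaries`, `cdic`, `pD`, `bgr`, `mc_error`,
#'   `imputed`, `design`, `model`, `control`.
#' @seealso [summary.cd4_fit()], [predict.cd4_fit()], [cdic()],
#'   [model_comparison_table()]
#' @export
fit_cd4 <- function(x, model = cd4_model("slope", "poly2",
                                         cvl_adjusted = TRUE),
                    priors = NULL, control = mcmc_control(), cvl = NULL,
                    detection_limit = 400, standardize_cvl = FALSE) {
  design <- if (inherits(x, "cd4_design")) x else
    build_design(x, model, cvl = cvl, detection_limit = detection_limit,
                 standardize_cvl = standardize_cvl)
  spec <- design$spec
  stopifnot(inherits(control, "cd4_mcmc_control"))
  if (!control$random_effects && spec$re_dist == "skew_normal")
    stop("random_effects = FALSE is incompatible with skew-normal ",
         "random effects")
  pv <- prior_vectors(priors, design$coef_names)

  code <- jags_model_code(design, control)
  dat <- jags_data(design, control, pv)
  inits <- make_inits(design, control)

  con <- textConnection(code)
  on.exit(close(con), add = TRUE)
  jm <- rjags::jags.model(con, data = dat, inits = inits,
                          n.chains = control$n_chains,
                          n.adapt = control$adapt, quiet = control$quiet)
  stats::update(jm, control$burn_in, progress.bar = "none")
  monitors <- fit_monitors(design, control)
  draws <- rjags::coda.samples(jm, monitors, n.iter = control$n_iter,
                               thin = control$thin, progress.bar = "none")

  finish_fit(draws, design, control, priors, match.call())
}

# monitored node names for a design/control pair
fit_monitors <- function(design, control) {
  spec <- design$spec
  impute <- length(design$missing$sex) +
    length(design$missing$baseline_cd4) +
    length(design$missing$baseline_log_vl) > 0
  mon <- "beta"
  if (spec$outcome == "slope" && is.null(control$fix_sigma))
    mon <- c(mon, "sigma_eps")
  if (control$random_effects) mon <- c(mon, "sigma0", "sigma1", "rho", "b")
  if (spec$re_dist == "skew_normal") mon <- c(mon, "delta_b")
  if (spec$outcome == "slope" && spec$error_dist == "skew_normal")
    mon <- c(mon, "delta_eps")
  if (impute) mon <- c(mon, "sex", "bcd4_z", "blvl_z",
                       "phi_sex", "phi_cd4", "phi_lvl",
                       "omega_cd4", "omega_lvl")
  if (length(design$missing$y) > 0) mon <- c(mon, "y_mis")
  mon
}

# dispersed, seed-deterministic initial values (one list per chain)
make_inits <- function(design, control) {
  spec <- design$spec
  set.seed(control$seed)
  m <- control$n_chains
  rng_seeds <- sample.int(2^30, m)

  X <- design$X
  y <- design$y
  cc <- stats::complete.cases(X) & !is.na(y)
  beta_hat <- rep(0, ncol(X))
  s_hat <- if (spec$outcome == "slope") max(stats::sd(y, na.rm = TRUE), 1)
    else NA
  if (sum(cc) > ncol(X) + 2) {
    ft <- tryCatch({
      if (spec$outcome == "slope")
        stats::lm.fit(X[cc, , drop = FALSE], y[cc])
      else suppressWarnings(
        stats::glm.fit(X[cc, , drop = FALSE], y[cc],
                       family = stats::binomial()))
    }, error = function(e) NULL)
    if (!is.null(ft)) {
      cf <- ft$coefficients
      cf[!is.finite(cf)] <- 0
      beta_hat <- cf
      if (spec$outcome == "slope")
        s_hat <- max(stats::sd(ft$residuals), 1)
    }
  }
  scale <- pmax(abs(beta_hat), 1)
  P <- length(design$patient_id)
  lapply(seq_len(m), function(ch) {
    disp <- (ch - (m + 1) / 2) * 0.4
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = rng_seeds[ch],
                beta = unname(beta_hat + disp * scale))
    if (spec$outcome == "slope" && is.null(control$fix_sigma))
      ini$sigma_eps <- min(s_hat * 2^disp, control$sd_upper * 0.9)
    if (control$random_effects) {
      ini$b <- matrix(0, P, 2)
      prec0 <- if (spec$outcome == "slope") c(1e-4, 1e-3) else c(1, 1)
      ini$Omega_b <- diag(prec0)
      if (spec$re_dist == "skew_normal") {
        ini$w <- matrix(0.5, P, 2)
        ini$delta_b <- 0
      }
    }
    if (spec$outcome == "slope" && spec$error_dist == "skew_normal") {
      ini$we <- rep(0.5, nrow(X))
      ini$delta_eps <- if (identical(control$delta_structure, "by_visit"))
        rep(0, max(design$vnum)) else 0
    }
    impute <- length(design$missing$sex) +
      length(design$missing$baseline_cd4) +
      length(design$missing$baseline_log_vl) > 0
    if (impute) {
      ini$phi_sex <- c(0, 0)
      ini$phi_cd4 <- c(0, 0, 0)
      ini$phi_lvl <- c(0, 0, 0)
      ini$omega_cd4 <- 1
      ini$omega_lvl <- 1
    }
    ini
  })
}

# assemble the cd4_fit object from raw coda draws
finish_fit <- function(draws, design, control, priors, call) {
  spec <- design$spec
  pooled <- as.matrix(draws)
  vn <- colnames(pooled)

  # human-readable names for the fixed effects
  beta_cols <- grep("^beta\\[", vn)
  coef_map <- setNames(design$coef_names,
                       sprintf("beta[%d]", seq_along(design$coef_names)))

  scalar_cols <- vn[!grepl("^(b|w|we|y_mis|sex|bcd4_z|blvl_z)\\[", vn)]
  summ <- t(apply(pooled[, scalar_cols, drop = FALSE], 2, function(col)
    c(mean = mean(col), sd = stats::sd(col),
      stats::quantile(col, c(0.025, 0.5, 0.975)))))
  summaries <- data.frame(parameter = scalar_cols, summ, check.names = FALSE,
                          row.names = NULL, stringsAsFactors = FALSE)
  pretty <- coef_map[summaries$parameter]
  summaries$parameter[!is.na(pretty)] <- pretty[!is.na(pretty)]

  diag_draws <- lapply(draws, function(ch)
    as.matrix(ch)[, scalar_cols, drop = FALSE])
  bgr_v <- bgr(diag_draws)
  mce <- mc_error_check(diag_draws, frac = control$mc_error_target)
  names(bgr_v) <- names(attr(bgr_v, "converged")) <-
    mce$parameter <- summaries$parameter

  imputed <- imputed_summaries(pooled, design)
  cd <- compute_cdic(pooled, design, control)

  structure(list(draws = draws, pooled = pooled, summaries = summaries,
                 coef_map = coef_map, cdic = cd$cdic, pD = cd$pD,
                 deviance_mean = cd$Dbar,
                 bgr = bgr_v, mc_error = mce, imputed = imputed,
                 design = design, model = spec, control = control,
                 priors = priors, call = call),
            class = "cd4_fit")
}

# posterior summaries of every imputed cell, plus the constancy check data
imputed_summaries <- function(pooled, design) {
  out <- list()
  vn <- colnames(pooled)
  grab <- function(node, idx, label) {
    if (!length(idx)) return(NULL)
    cols <- sprintf("%s[%d]", node, idx)
    cols <- cols[cols %in% vn]
    if (!length(cols)) return(NULL)
    m <- pooled[, cols, drop = FALSE]
    data.frame(cell = label, index = idx,
               patient_id = if (node == "y_mis") NA_character_ else
                 design$patient_id[idx],
               mean = colMeans(m), sd = apply(m, 2, stats::sd),
               lower = apply(m, 2, stats::quantile, 0.025),
               upper = apply(m, 2, stats::quantile, 0.975),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  rbind(grab("sex", design$missing$sex, "sex"),
        grab("bcd4_z", design$missing$baseline_cd4, "baseline_cd4"),
        grab("blvl_z", design$missing$baseline_log_vl, "baseline_log_vl"),
        grab("y_mis", seq_along(design$missing$y), "outcome"))
}

# ---- conditional DIC ---------------------------------------------------

# per-draw conditional deviance D(theta, b) = -2 log p(y | b, theta),
# conditioning on the random effects and on that draw's imputed covariates
deviance_draws <- function(pooled, design, control) {
  spec <- design$spec
  vn <- colnames(pooled)
  n <- nrow(design$X)
  P <- length(design$patient_id)
  p <- ncol(design$X)

  beta_d <- pooled[, sprintf("beta[%d]", seq_len(p)), drop = FALSE]
  re <- control$random_effects
  if (re) {
    b1 <- pooled[, sprintf("b[%d,1]", seq_len(P)), drop = FALSE]
    b2 <- pooled[, sprintf("b[%d,2]", seq_len(P)), drop = FALSE]
  }
  sigma_d <- if (spec$outcome == "slope") {
    if (!is.null(control$fix_sigma)) rep(control$fix_sigma, nrow(pooled))
    else pooled[, "sigma_eps"]
  }
  sn_err <- spec$outcome == "slope" && spec$error_dist == "skew_normal"
  delta_d <- if (sn_err) {
    if (identical(control$delta_structure, "by_visit"))
      pooled[, sprintf("delta_eps[%d]", seq_len(max(design$vnum))),
             drop = FALSE]
    else matrix(pooled[, "delta_eps"], ncol = 1)
  }

  # imputed covariate cells: (patient index, X column, draw column)
  cells <- rbind(
    if (length(design$missing$sex))
      data.frame(i = design$missing$sex, col = "sex",
                 node = sprintf("sex[%d]", design$missing$sex)),
    if (length(design$missing$baseline_cd4))
      data.frame(i = design$missing$baseline_cd4, col = "baseline_cd4",
                 node = sprintf("bcd4_z[%d]", design$missing$baseline_cd4)),
    if (length(design$missing$baseline_log_vl))
      data.frame(i = design$missing$baseline_log_vl, col = "baseline_log_vl",
                 node = sprintf("blvl_z[%d]",
                                design$missing$baseline_log_vl)))

  X <- design$X
  rows_of <- split(seq_len(n), design$pat)
  S <- nrow(pooled)
  dev <- numeric(S)
  for (s in seq_len(S)) {
    Xs <- X
    if (!is.null(cells)) for (k in seq_len(nrow(cells))) {
      Xs[rows_of[[cells$i[k]]], cells$col[k]] <- pooled[s, cells$node[k]]
    }
    params <- list(beta = beta_d[s, ], X = Xs,
                   b = if (re) cbind(b1[s, ], b2[s, ]),
                   sigma_eps = sigma_d[s],
                   delta_eps = if (sn_err) delta_d[s, ] else 0,
                   sn_center = control$sn_center_value)
    dev[s] <- -2 * cd4_log_lik(params, design)
  }
  dev
}

compute_cdic <- function(pooled, design, control) {
  spec <- design$spec
  dev <- deviance_draws(pooled, design, control)
  Dbar <- mean(dev)

  # plug-in deviance at the posterior means of (beta, b, scales, imputations)
  P <- length(design$patient_id)
  p <- ncol(design$X)
  cm <- colMeans(pooled)
  X <- design$X
  fill <- function(node, idx, col) {
    for (k in seq_along(idx)) {
      rows <- design$pat == idx[k]
      X[rows, col] <<- cm[sprintf("%s[%d]", node, idx[k])]
    }
  }
  fill("sex", design$missing$sex, "sex")
  fill("bcd4_z", design$missing$baseline_cd4, "baseline_cd4")
  fill("blvl_z", design$missing$baseline_log_vl, "baseline_log_vl")
  re <- control$random_effects
  sn_err <- spec$outcome == "slope" && spec$error_dist == "skew_normal"
  params <- list(
    beta = unname(cm[sprintf("beta[%d]", seq_len(p))]), X = X,
    b = if (re) cbind(cm[sprintf("b[%d,1]", seq_len(P))],
                      cm[sprintf("b[%d,2]", seq_len(P))]),
    sigma_eps = if (spec$outcome == "slope") {
      if (!is.null(control$fix_sigma)) control$fix_sigma
      else cm[["sigma_eps"]]
    },
    delta_eps = if (sn_err) {
      if (identical(control$delta_structure, "by_visit"))
        unname(cm[sprintf("delta_eps[%d]", seq_len(max(design$vnum)))])
      else cm[["delta_eps"]]
    } else 0,
    sn_center = control$sn_center_value)
  Dhat <- -2 * cd4_log_lik(params, design)
  pD <- Dbar - Dhat
  list(cdic = Dbar + pD, pD = pD, Dbar = Dbar)
}

#' Conditional DIC of a fit
#'
#' The conditional deviance information criterion: `cDIC = Dbar + pD` where
#' `Dbar` is the posterior mean of the conditional deviance
#' `-2 log p(y | b, theta)` (conditioning on the random effects and the
#' current imputations) and `pD = Dbar - D(posterior means)` the effective
#' number of parameters. Lower is better.
#'
#' @param fit a [fit_cd4()] result.
#' @return named numeric vector `c(cdic, pD)`.
#' @export
cdic <- function(fit) {
  stopifnot(inherits(fit, "cd4_fit"))
  c(cdic = fit$cdic, pD = fit$pD)
}

#' Compare two models by conditional DIC
#'
#' Differences below 5 cannot support a choice at all; a clear choice
#' requires the cDICs to differ by approximately 10 or more.
#'
#' @param cdic1,cdic2 cDIC values (or `cd4_fit` objects).
#' @return list with `delta` (`cdic1 - cdic2`), `preferred` (1, 2 or `NA`)
#'   and `label`.
#' @export
cdic_compare <- function(cdic1, cdic2) {
  g <- function(x) if (inherits(x, "cd4_fit")) x$cdic else as.numeric(x)
  d <- g(cdic1) - g(cdic2)
  label <- if (abs(d) >= 10) "clear choice"
    else if (abs(d) >= 5) "suggestive, no clear choice"
    else "no clear choice"
  list(delta = d,
       preferred = if (abs(d) >= 10) (if (d < 0) 1L else 2L) else NA_integer_,
       label = label)
}
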