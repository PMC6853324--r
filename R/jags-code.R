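# Internal generator of the JAGS model code for a cd4_design.
#
# The probabilistic model is assembled from blocks: the outcome likelihood
# (Gaussian or skew-normal slope errors, Bernoulli-logit asymptote), the
# random intercept/slope with Gaussian or skew-normal distribution (the
# skew-normal via its stochastic representation delta*|w| + Gaussian with
# half-normal latents w), Gaussian priors on the fixed effects with
# per-coefficient mean/precision supplied as data, uniform priors on scale
# parameters, an inverse-Wishart (Wishart on the precision) prior on the
# random-effects covariance, and - when baseline covariates are missing -
# the joint imputation submodels sex | age and (baseline CD4, baseline log
# VL) | sex, age, whose full conditionals realize the data-augmentation
# imputation within each MCMC iteration.
jags_model_code <- function(design, control) {
  spec <- design$spec
  p <- ncol(design$X)
  K <- design$K
  sn_re <- spec$re_dist == "skew_normal"
  sn_err <- spec$outcome == "slope" && spec$error_dist == "skew_normal"
  re <- isTRUE(control$random_effects)
  impute <- length(design$missing$sex) + length(design$missing$baseline_cd4) +
    length(design$missing$baseline_log_vl) > 0
  n_ymis <- length(design$missing$y)
  fix_sigma <- !is.null(control$fix_sigma)
  by_visit <- identical(control$delta_structure, "by_visit")

  mu <- c("beta[1]", "beta[2]*sex[pat[j]]", "beta[3]*age_z[pat[j]]",
          "beta[4]*bcd4_z[pat[j]]", "beta[5]*blvl_z[pat[j]]",
          sprintf("beta[%d]*TB[j,%d]", 5 + seq_len(K), seq_len(K)))
  if (spec$cvl_adjusted) mu <- c(mu, sprintf("beta[%d]*cvlx[j]", p))
  if (re) mu <- c(mu, "b[pat[j],1]", "b[pat[j],2]*t[j]")
  if (sn_err) {
    de <- if (by_visit) "delta_eps[vnum[j]]" else "delta_eps"
    mu <- c(mu, sprintf("%s*(we[j] - sn_center)", de))
  }
  mu_line <- paste0("    mu[j] <- ", paste(mu, collapse = " + "))

  lik <- if (spec$outcome == "slope") {
    c("    y[j] ~ dnorm(mu[j], tau_eps)",
      if (sn_err) "    we[j] ~ dnorm(0, 1) T(0,)")
  } else {
    c("    y[j] ~ dbern(pi[j])",
      "    logit(pi[j]) <- mu[j]")
  }

  re_block <- if (!re) character(0) else if (sn_re) c(
    "  for (i in 1:P) {",
    "    w[i,1] ~ dnorm(0, 1) T(0,)",
    "    w[i,2] ~ dnorm(0, 1) T(0,)",
    "    bm[i,1] <- delta_b * (w[i,1] - sn_center)",
    "    bm[i,2] <- delta_b * (w[i,2] - sn_center)",
    "    b[i,1:2] ~ dmnorm(bm[i,1:2], Omega_b)",
    "  }",
    "  delta_b ~ dnorm(0, 1.0E-2)"
  ) else c(
    "  for (i in 1:P) {",
    "    b[i,1:2] ~ dmnorm(zero2, Omega_b)",
    "  }"
  )
  cov_block <- if (!re) character(0) else c(
    "  Omega_b ~ dwish(R2, 3)",
    "  Sigma_b <- inverse(Omega_b)",
    "  sigma0 <- sqrt(Sigma_b[1,1])",
    "  sigma1 <- sqrt(Sigma_b[2,2])",
    "  rho <- Sigma_b[1,2] / (sigma0 * sigma1)"
  )

  err_block <- if (spec$outcome != "slope") character(0) else if (fix_sigma)
    "  tau_eps <- tau_fix"
  else c("  sigma_eps ~ dunif(0, sd_upper)",
         "  tau_eps <- pow(sigma_eps, -2)")
  if (sn_err) {
    err_block <- c(err_block, if (by_visit) c(
      "  for (v in 1:V) { delta_eps[v] ~ dnorm(0, 1.0E-2) }"
    ) else "  delta_eps ~ dnorm(0, 1.0E-2)")
  }

  impute_block <- if (!impute) character(0) else c(
    "  for (i in 1:P) {",
    "    sex[i] ~ dbern(psex[i])",
    "    logit(psex[i]) <- phi_sex[1] + phi_sex[2]*age_z[i]",
    "    bcd4_z[i] ~ dnorm(phi_cd4[1] + phi_cd4[2]*sex[i] + phi_cd4[3]*age_z[i], tau_cd4)",
    "    blvl_z[i] ~ dnorm(phi_lvl[1] + phi_lvl[2]*sex[i] + phi_lvl[3]*age_z[i], tau_lvl)",
    "  }",
    "  for (k in 1:3) {",
    "    phi_cd4[k] ~ dnorm(0, 1.0E-6)",
    "    phi_lvl[k] ~ dnorm(0, 1.0E-6)",
    "  }",
    "  phi_sex[1] ~ dnorm(0, 1.0E-6)",
    "  phi_sex[2] ~ dnorm(0, 1.0E-6)",
    "  omega_cd4 ~ dunif(0, 100)",
    "  tau_cd4 <- pow(omega_cd4, -2)",
    "  omega_lvl ~ dunif(0, 100)",
    "  tau_lvl <- pow(omega_lvl, -2)"
  )

  ymis_block <- if (n_ymis == 0) character(0) else c(
    "  for (k in 1:n_ymis) {",
    "    y_mis[k] <- y[ymis_idx[k]]",
    "  }"
  )

  paste(c("model {",
          "  for (j in 1:n) {",
          mu_line,
          lik,
          "  }",
          re_block,
          cov_block,
          err_block,
          "  for (k in 1:p) {",
          "    beta[k] ~ dnorm(prior_mean[k], prior_prec[k])",
          "  }",
          impute_block,
          ymis_block,
          "}"),
        collapse = "\n")
}

# data list for the generated model; drops unused entries
jags_data <- function(design, control, prior_v) {
  spec <- design$spec
  p <- ncol(design$X)
  K <- design$K
  b <- design$baseline
  re <- isTRUE(control$random_effects)
  sn <- spec$re_dist == "skew_normal" ||
    (spec$outcome == "slope" && spec$error_dist == "skew_normal")
  impute <- length(design$missing$sex) + length(design$missing$baseline_cd4) +
    length(design$missing$baseline_log_vl) > 0
  n_ymis <- length(design$missing$y)

  dat <- list(n = nrow(design$X), P = length(design$patient_id),
              y = design$y, t = design$t, pat = design$pat,
              p = p,
              sex = b$sex, age_z = b$age, bcd4_z = b$baseline_cd4,
              blvl_z = b$baseline_log_vl,
              TB = design$X[, 5 + seq_len(K), drop = FALSE],
              prior_mean = prior_v$mean, prior_prec = prior_v$prec)
  dimnames(dat$TB) <- NULL
  if (!re) {
    dat$t <- NULL
    if (!impute) dat$P <- NULL
  }
  if (spec$cvl_adjusted) dat$cvlx <- unname(design$X[, p])
  if (re) {
    dat$zero2 <- c(0, 0)
    dat$R2 <- diag(2)
    if (spec$re_dist == "skew_normal") dat$zero2 <- NULL
  }
  if (sn) dat$sn_center <- control$sn_center_value
  if (spec$outcome == "slope") {
    if (!is.null(control$fix_sigma)) dat$tau_fix <- 1 / control$fix_sigma^2
    else dat$sd_upper <- control$sd_upper
    if (spec$error_dist == "skew_normal" &&
        identical(control$delta_structure, "by_visit")) {
      dat$vnum <- design$vnum
      dat$V <- max(design$vnum)
    }
  }
  if (n_ymis > 0) {
    dat$ymis_idx <- design$missing$y
    dat$n_ymis <- n_ymis
  }
  if (!impute && anyNA(c(dat$sex, dat$bcd4_z, dat$blvl_z)))
    stop("internal: missing covariates without imputation block")
  dat
}
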