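#' One data-augmentation imputation step for missing baseline data
#'
#' Draws the missing baseline cells from their imputation conditionals given
#' the current parameter state, in the prescribed order: baseline CD4 and
#' baseline log viral load first, each from a linear model on sex and age
#' with Gaussian error; then sex from a logistic model on age, baseline CD4
#' and baseline log viral load, using the values just imputed. Observed
#' cells are never altered. Within full fits ([fit_cd4()]) the equivalent
#' augmentation happens inside the sampler at every iteration; this
#' standalone step exposes the conditional draws directly (e.g. for
#' initialization or for schemes driven outside the sampler).
#'
#' Covariates are expected on the scale the fit uses (standardized), with
#' sex coded 0/1.
#'
#' @param baselines data.frame with columns `sex`, `age`, `baseline_cd4`,
#'   `baseline_log_vl` (missing cells `NA`).
#' @param state parameter state: list with `phi_cd4` (length 3: intercept,
#'   sex, age), `omega_cd4` (residual sd), `phi_lvl`, `omega_lvl`, and
#'   `phi_sex` (length 4: intercept, age, baseline_cd4, baseline_log_vl).
#' @param current optional completed copy of `baselines` (e.g. the previous
#'   iteration's imputations) supplying values for conditioning when a
#'   conditional needs a cell that is itself missing in `baselines`.
#' @return `baselines` with every missing cell replaced by a draw.
#' @export
impute_step <- function(baselines, state, current = NULL) {
  b <- as.data.frame(baselines)
  stopifnot(all(c("sex", "age", "baseline_cd4", "baseline_log_vl") %in%
                  names(b)))
  need <- c("phi_cd4", "omega_cd4", "phi_lvl", "omega_lvl", "phi_sex")
  miss <- setdiff(need, names(state))
  if (length(miss)) stop("state is missing: ", paste(miss, collapse = ", "))
  if (state$omega_cd4 <= 0 || state$omega_lvl <= 0)
    stop("residual sds must be positive")
  if (anyNA(b$age)) stop("age must be observed")
  cond_sex <- b$sex
  if (!is.null(current)) {
    cond_sex[is.na(cond_sex)] <- current$sex[is.na(cond_sex)]
  }

  # linear conditionals first (Gaussian draws) ...
  i <- which(is.na(b$baseline_cd4))
  if (length(i)) {
    mu <- state$phi_cd4[1] + state$phi_cd4[2] * cond_sex[i] +
      state$phi_cd4[3] * b$age[i]
    if (anyNA(mu))
      stop("baseline_cd4 conditional needs sex; impute jointly via fit_cd4 ",
           "or supply sex first")
    b$baseline_cd4[i] <- stats::rnorm(length(i), mu, state$omega_cd4)
  }
  i <- which(is.na(b$baseline_log_vl))
  if (length(i)) {
    mu <- state$phi_lvl[1] + state$phi_lvl[2] * cond_sex[i] +
      state$phi_lvl[3] * b$age[i]
    if (anyNA(mu))
      stop("baseline_log_vl conditional needs sex; impute jointly via ",
           "fit_cd4 or supply sex first")
    b$baseline_log_vl[i] <- stats::rnorm(length(i), mu, state$omega_lvl)
  }
  # ... then the binary conditional, using the just-imputed values
  i <- which(is.na(b$sex))
  if (length(i)) {
    eta <- state$phi_sex[1] + state$phi_sex[2] * b$age[i] +
      state$phi_sex[3] * b$baseline_cd4[i] +
      state$phi_sex[4] * b$baseline_log_vl[i]
    b$sex[i] <- stats::rbinom(length(i), 1, stats::plogis(eta))
  }
  b
}
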