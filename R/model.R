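#' Specify one of the nine CD4 response models
#'
#' The model family crosses two outcomes (linear "slope" model for the CD4
#' count trajectory; logistic "asymptote" model for the odds of CD4 >= 500
#' cells/uL), three fixed-effect time bases (quadratic polynomial, cubic
#' B-splines with 3 or 5 inner knots), and Gaussian or skew-normal
#' distributions for the random effects and (slope only) the measurement
#' error. Each model comes in an unadjusted and a cVL2-adjusted flavour.
#'
#' The numbered variants are: 1 slope/poly2/Gaussian; 2-3 slope splines;
#' 4 slope skew-normal random effects; 5 slope skew-normal random effects
#' and errors; 6 asymptote/poly2/Gaussian; 7 asymptote skew-normal random
#' effects; 8-9 asymptote splines.
#'
#' @param outcome `"slope"` or `"asymptote"`.
#' @param time_basis `"poly2"`, `"bspline3"` or `"bspline5"`.
#' @param re_dist random-effects distribution, `"gaussian"` or
#'   `"skew_normal"`.
#' @param error_dist error distribution (slope models only).
#' @param cvl_adjusted include the `in_care * cVL2` covariate.
#' @param covariates baseline covariate columns, in design order.
#' @return object of class `cd4_model_spec`.
#' @export
cd4_model <- function(outcome = c("slope", "asymptote"),
                      time_basis = c("poly2", "bspline3", "bspline5"),
                      re_dist = c("gaussian", "skew_normal"),
                      error_dist = c("gaussian", "skew_normal"),
                      cvl_adjusted = FALSE,
                      covariates = c("sex", "age", "baseline_cd4",
                                     "baseline_log_vl")) {
  outcome <- match.arg(outcome)
  time_basis <- match.arg(time_basis)
  re_dist <- match.arg(re_dist)
  error_dist <- match.arg(error_dist)
  if (outcome == "asymptote" && error_dist == "skew_normal")
    stop("the asymptote (logistic) model has no error term; ",
         "error_dist = 'skew_normal' is invalid")
  spec <- structure(list(outcome = outcome, time_basis = time_basis,
                         re_dist = re_dist, error_dist = error_dist,
                         cvl_adjusted = isTRUE(cvl_adjusted),
                         covariates = covariates),
                    class = "cd4_model_spec")
  spec
}

#' Model number (1-9) of a specification
#'
#' @param spec a [cd4_model()].
#' @return integer model number, or `NA` if the combination is not one of
#'   the nine named variants.
#' @export
model_number <- function(spec) {
  stopifnot(inherits(spec, "cd4_model_spec"))
  with(spec, {
    if (outcome == "slope") {
      if (re_dist == "gaussian" && error_dist == "gaussian")
        return(switch(time_basis, poly2 = 1L, bspline3 = 2L, bspline5 = 3L))
      if (time_basis == "poly2" && re_dist == "skew_normal")
        return(if (error_dist == "gaussian") 4L else 5L)
    } else {
      if (re_dist == "gaussian")
        return(switch(time_basis, poly2 = 6L, bspline3 = 8L, bspline5 = 9L))
      if (time_basis == "poly2") return(7L)
    }
    NA_integer_
  })
}

#' @export
print.cd4_model_spec <- function(x, ...) {
  n <- model_number(x)
  cat(sprintf("CD4 %s model%s: time basis %s, %s random effects%s, %s\n",
              x$outcome,
              if (!is.na(n)) paste0(" (model ", n, ")") else "",
              x$time_basis, x$re_dist,
              if (x$outcome == "slope")
                paste0(", ", x$error_dist, " errors") else "",
              if (x$cvl_adjusted) "cVL2-adjusted" else "unadjusted"))
  invisible(x)
}

# fixed inner knots (years on ART) for the two spline bases
.bspline_knots <- list(bspline3 = c(1.250, 2.5, 3.751),
                       bspline5 = c(0.833, 1.666, 2.5, 3.334, 4.167))

#' Fixed-effects time basis
#'
#' `poly2` returns the raw quadratic basis `(t, t^2)`; the spline options
#' return a cubic B-spline basis at fixed inner knots -- (1.250, 2.5, 3.751)
#' or (0.833, 1.666, 2.5, 3.334, 4.167) years -- with boundary knots at 0
#' and the follow-up horizon, intercept column excluded (it is absorbed by
#' the model intercept).
#'
#' @param t times on ART (years), within `[0, horizon]`.
#' @param basis `"poly2"`, `"bspline3"` or `"bspline5"`.
#' @param horizon follow-up horizon in years (default 5).
#' @return numeric matrix, one row per time, with named columns.
#' @export
time_basis <- function(t, basis = c("poly2", "bspline3", "bspline5"),
                       horizon = 5) {
  basis <- match.arg(basis)
  if (any(t < 0 | t > horizon))
    stop("t outside [0, ", horizon, "]")
  if (basis == "poly2") {
    out <- cbind(time = t, time_sq = t^2)
  } else {
    out <- splines::bs(t, knots = .bspline_knots[[basis]], degree = 3,
                       Boundary.knots = c(0, horizon), intercept = FALSE)
    out <- unclass(out)[, , drop = FALSE]
    colnames(out) <- paste0("bs", seq_len(ncol(out)))
    attributes(out)[c("degree", "knots", "Boundary.knots", "intercept")] <- NULL
  }
  out
}

#' Build design matrices and outcomes for a model specification
#'
#' Assembles the fixed-effects matrix `X` (intercept, baseline covariates,
#' time basis and, when adjusted, the per-visit `in_care * cVL2` column),
#' the implicit random-effects design `Z = (1, t)` (random intercept and
#' slope on time on treatment -- the spline options alter only the fixed
#' time basis), and the outcome vector: the CD4 count for the slope model
#' (all visits), or the indicator `CD4 >= 500` at post-baseline visits for
#' the asymptote model. Missing covariate and outcome cells are flagged for
#' the within-MCMC imputation layer, never dropped.
#'
#' @param cohort a `cd4_cohort`, exclusions and standardization applied.
#' @param spec a [cd4_model()].
#' @param cvl a [compute_cvl2()] series; computed from the cohort when
#'   `NULL` and the spec is cVL2-adjusted.
#' @param detection_limit passed to [compute_cvl2()] when `cvl` is `NULL`.
#' @param standardize_cvl z-score the cVL2 column (off by default; the cVL2
#'   coefficient is then per log10 copy-year/mL).
#' @param horizon follow-up horizon for the time basis.
#' @return object of class `cd4_design`: list with `X`, `y`, `t`, `pat`
#'   (integer patient index), `patient_id`, `vnum` (visit rank within
#'   patient), `baseline` (per-patient covariates in design order),
#'   `missing` (index lists), `spec`, `coef_names`.
#' @export
build_design <- function(cohort, spec, cvl = NULL, detection_limit = 400,
                         standardize_cvl = FALSE, horizon = 5) {
  stopifnot(inherits(cohort, "cd4_cohort"), inherits(spec, "cd4_model_spec"))
  visits <- cohort$visits
  baselines <- cohort$baselines

  if (spec$cvl_adjusted) {
    if (is.null(cvl)) cvl <- compute_cvl2(cohort, detection_limit)
    if (!all(c("patient_id", "time_on_art", "cvl2") %in% names(cvl)))
      stop("cvl must be a cvl_series (patient_id, time_on_art, cvl2)")
    key <- paste(visits$patient_id, visits$time_on_art)
    ckey <- paste(cvl$patient_id, cvl$time_on_art)
    idx <- match(key, ckey)
    if (anyNA(idx)) stop("cvl series does not cover every visit")
    cvl2 <- cvl$cvl2[idx]
  }

  if (spec$outcome == "asymptote") {
    keep <- visits$time_on_art > 0
    if (spec$cvl_adjusted) cvl2 <- cvl2[keep]
    visits <- visits[keep, , drop = FALSE]
    if (!nrow(visits)) stop("no post-baseline visits for the asymptote model")
    y <- ifelse(is.na(visits$cd4), NA, as.numeric(visits$cd4 >= 500))
  } else {
    y <- visits$cd4
  }

  pid_levels <- unique(visits$patient_id)
  pat <- match(visits$patient_id, pid_levels)
  t <- visits$time_on_art
  vnum <- stats::ave(t, visits$patient_id, FUN = seq_along)

  b <- baselines[match(pid_levels, baselines$patient_id), , drop = FALSE]
  TB <- time_basis(t, spec$time_basis, horizon)

  X <- cbind(`(Intercept)` = 1,
             sex = b$sex[pat], age = b$age[pat],
             baseline_cd4 = b$baseline_cd4[pat],
             baseline_log_vl = b$baseline_log_vl[pat],
             TB)
  cvl_std <- NULL
  if (spec$cvl_adjusted) {
    cvlx <- b$in_care[pat] * cvl2
    if (standardize_cvl) {
      cvl_std <- c(mean = mean(cvlx), sd = stats::sd(cvlx))
      if (cvl_std["sd"] <= 0) stop("zero variance in cvl2")
      cvlx <- (cvlx - cvl_std["mean"]) / cvl_std["sd"]
    }
    X <- cbind(X, cvl2 = cvlx)
  }

  missing <- list(sex = which(is.na(b$sex)),
                  baseline_cd4 = which(is.na(b$baseline_cd4)),
                  baseline_log_vl = which(is.na(b$baseline_log_vl)),
                  y = which(is.na(y)))
  if (anyNA(b$age))
    stop("missing baseline age is not supported (no imputation model for age)")

  structure(list(X = X, y = y, t = t, pat = pat, patient_id = pid_levels,
                 vnum = as.integer(vnum), K = ncol(TB),
                 baseline = data.frame(patient_id = b$patient_id,
                                       sex = b$sex, age = b$age,
                                       baseline_cd4 = b$baseline_cd4,
                                       baseline_log_vl = b$baseline_log_vl,
                                       in_care = b$in_care,
                                       stringsAsFactors = FALSE),
                 missing = missing, spec = spec,
                 coef_names = colnames(X), horizon = horizon,
                 cvl_standardization = cvl_std,
                 standardization = cohort$standardization),
            class = "cd4_design")
}

#' @export
print.cd4_design <- function(x, ...) {
  cat("cd4_design:", nrow(x$X), "visits,", length(x$patient_id),
      "patients,", ncol(x$X), "fixed-effect columns\n")
  cat("columns:", paste(x$coef_names, collapse = ", "), "\n")
  nm <- vapply(x$missing, length, integer(1))
  cat("missing cells:", paste(names(nm), nm, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
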