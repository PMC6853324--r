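#' Prior variance from a published upper confidence limit
#'
#' Historical studies report a coefficient estimate and the upper limit of
#' its 95% confidence interval, `uCI = est + 1.96 * sqrt(s2 / n)`. Inverting
#' for the underlying variance gives `s2 = n * ((uCI - est) / 1.96)^2`,
#' which is the prior variance assigned to the coefficient. The constant
#' 1.96 is used exactly (not a higher-precision normal quantile) so that
#' published worked values are reproduced to their printed precision.
#'
#' @param mean historical coefficient estimate.
#' @param upper_ci upper 95% confidence limit from the same study.
#' @param n historical study size.
#' @return prior variance, in squared coefficient units.
#' @examples
#' variance_from_uci(35.2, 66.5, 459)   # 117054.8
#' @export
variance_from_uci <- function(mean, upper_ci, n) {
  if (any(n < 1)) stop("historical study size n must be >= 1")
  if (any(upper_ci == mean))
    stop("upper_ci equal to the estimate implies zero variance")
  n * ((upper_ci - mean) / 1.96)^2
}

#' Precision (1/variance)
#'
#' @param variance positive variance.
#' @return `1 / variance`.
#' @export
precision_from_variance <- function(variance) {
  if (any(variance <= 0)) stop("variance must be positive")
  1 / variance
}

#' Change-adjusted informative prior mean
#'
#' A historical estimate comes from a simple (single-covariate) model; the
#' analysis model adjusts for more covariates. The elicitation transfers the
#' adjustment observed on the current data: the change from the current
#' study's simple-model estimate to its full-model estimate is added to the
#' historical estimate.
#'
#' @param historical_est coefficient from the historical simple model.
#' @param simple_model_est the same simple model refitted on the current data.
#' @param full_model_est the full analysis model on the current data.
#' @return list with `mean` (the adjusted prior mean) and `change`
#'   (`full_model_est - simple_model_est`, for reporting).
#' @export
adjusted_prior_mean <- function(historical_est, simple_model_est,
                                full_model_est) {
  change <- full_model_est - simple_model_est
  list(mean = historical_est + change, change = change)
}

#' Historical estimates for the CD4 slope model coefficients
#'
#' Published simple-model estimates, upper confidence limits and study sizes
#' for the coefficients with usable historical information (female sex,
#' baseline log10 viral load, time on treatment and its square), together
#' with the current-study simple-model and full-model estimates used by the
#' change adjustment. These are the inputs of [elicit_priors()].
#'
#' @return data.frame with one row per coefficient.
#' @export
historical_cd4_priors <- function() {
  data.frame(
    coefficient = c("sex", "baseline_log_vl", "time", "time_sq"),
    estimate = c(35.2, 13.9, 65, -6),
    upper_ci = c(66.5, 22.2, 69, -5),
    n = c(459, 459, 12946, 12946),
    simple_est = c(36.17, -10.09, 56.18, -22.97),
    full_est = c(24.1, 7.5, 52.3, -23.0),
    stringsAsFactors = FALSE)
}

#' Prior specification for the fixed-effect coefficients
#'
#' Per-coefficient Gaussian prior means and precisions. Coefficients not
#' named get the vague default (mean 0, precision 1e-6).
#'
#' @param mean named numeric vector of prior means.
#' @param precision named numeric vector of prior precisions (1/variance),
#'   same names as `mean`.
#' @param vague_precision default precision for unnamed coefficients.
#' @return object of class `cd4_priors`.
#' @export
prior_spec <- function(mean = numeric(0), precision = numeric(0),
                       vague_precision = 1e-6) {
  mean <- unlist(mean); precision <- unlist(precision)
  if (length(mean) != length(precision) ||
      !identical(sort(names(mean)), sort(names(precision))))
    stop("mean and precision must be named alike")
  if (any(precision <= 0)) stop("precision must be positive")
  precision <- precision[names(mean)]
  structure(list(mean = mean, precision = precision,
                 vague_precision = vague_precision),
            class = "cd4_priors")
}

#' @export
print.cd4_priors <- function(x, ...) {
  cat("Prior specification (vague precision",
      format(x$vague_precision), "elsewhere)\n")
  if (length(x$mean)) {
    print(data.frame(coefficient = names(x$mean), mean = unname(x$mean),
                     precision = unname(x$precision)), row.names = FALSE)
  } else cat("  (all coefficients vague)\n")
  invisible(x)
}

#' Elicit informative priors from historical estimates
#'
#' Builds a [prior_spec()] for the CD4 slope model: the prior mean is the
#' change-adjusted historical estimate ([adjusted_prior_mean()]) and the
#' precision is the inverse of [variance_from_uci()]. Informative priors are
#' only defined for the Gaussian second-degree-polynomial slope model -- the
#' historical studies reviewed used that form, and asymptote studies used
#' incompatible CD4 thresholds -- so any other model specification is
#' refused.
#'
#' @param table historical-estimates table, as [historical_cd4_priors()].
#' @param model the [cd4_model()] the priors are intended for.
#' @return `cd4_priors` with an `elicitation` data.frame attribute carrying
#'   the intermediate change, variance and precision per coefficient.
#' @export
elicit_priors <- function(table = historical_cd4_priors(), model) {
  if (missing(model) || !inherits(model, "cd4_model_spec"))
    stop("supply the cd4_model() the priors are intended for")
  if (model$outcome != "slope")
    stop("informative priors are not available for asymptote models ",
         "(historical studies used different CD4 thresholds)")
  if (model$time_basis != "poly2" || model$re_dist != "gaussian" ||
      model$error_dist != "gaussian")
    stop("informative priors are only available for the Gaussian ",
         "second-degree polynomial slope model")
  stopifnot(all(c("coefficient", "estimate", "upper_ci", "n",
                  "simple_est", "full_est") %in% names(table)))
  adj <- Map(adjusted_prior_mean, table$estimate, table$simple_est,
             table$full_est)
  mean <- vapply(adj, `[[`, numeric(1), "mean")
  change <- vapply(adj, `[[`, numeric(1), "change")
  s2 <- variance_from_uci(table$estimate, table$upper_ci, table$n)
  prec <- precision_from_variance(s2)
  names(mean) <- names(prec) <- table$coefficient
  out <- prior_spec(mean = mean, precision = prec)
  attr(out, "elicitation") <- data.frame(
    coefficient = table$coefficient, historical = table$estimate,
    change = change, prior_mean = unname(mean), variance = s2,
    precision = unname(prec), stringsAsFactors = FALSE)
  out
}

# align a prior spec with design-matrix column names -> list(mean, prec)
prior_vectors <- function(priors, coef_names) {
  if (is.null(priors)) priors <- prior_spec()
  stopifnot(inherits(priors, "cd4_priors"))
  unknown <- setdiff(names(priors$mean), coef_names)
  if (length(unknown))
    stop("prior given for unknown coefficient(s): ",
         paste(unknown, collapse = ", "))
  mean <- setNames(rep(0, length(coef_names)), coef_names)
  prec <- setNames(rep(priors$vague_precision, length(coef_names)),
                   coef_names)
  mean[names(priors$mean)] <- priors$mean
  prec[names(priors$precision)] <- priors$precision
  list(mean = unname(mean), prec = unname(prec))
}
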