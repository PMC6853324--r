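#' Skew-normal density (convolution representation)
#'
#' Density of `xi + delta * |W| + U` with `W ~ N(0,1)` truncated to the
#' positives and `U ~ N(0, sigma^2)`: a skew-normal with scale
#' `omega = sqrt(sigma^2 + delta^2)` and shape `alpha = delta / sigma`,
#' `f(x) = (2/omega) phi((x-xi)/omega) Phi(alpha (x-xi)/omega)`.
#' At `delta = 0` this is exactly the `N(xi, sigma^2)` density.
#'
#' @param x quantiles.
#' @param xi location.
#' @param sigma Gaussian kernel standard deviation (> 0).
#' @param delta skewness (any sign).
#' @param log return the log density.
#' @export
dsn <- function(x, xi = 0, sigma = 1, delta = 0, log = FALSE) {
  stopifnot(all(sigma > 0))
  omega <- sqrt(sigma^2 + delta^2)
  z <- (x - xi) / omega
  ld <- base::log(2) - base::log(omega) + stats::dnorm(z, log = TRUE) +
    stats::pnorm(delta * z / sigma, log.p = TRUE)
  if (log) ld else exp(ld)
}

#' Conditional log likelihood of a CD4 model
#'
#' Log density of the observed outcomes given the random effects and
#' parameters: Gaussian (or skew-normal, marginalized over its positive
#' latent) measurement error for the slope model, Bernoulli with logit link
#' for the asymptote model. This is the deviance kernel the conditional DIC
#' is built from.
#'
#' @param params list with `beta` (fixed effects, in `design$coef_names`
#'   order), `b` (patients x 2 matrix of random intercepts/slopes; `NULL`
#'   for none), `sigma_eps` (slope models), `delta_eps` (scalar or
#'   per-visit-rank vector; 0 for Gaussian errors), `sn_center` (0 for the
#'   location-zero convention, `sqrt(2/pi)` for the mean-corrected one) and
#'   optionally `X` to override the design matrix (e.g. with imputed
#'   covariate values filled in).
#' @param design a [build_design()] object.
#' @return scalar log likelihood over visits with observed outcome.
#' @export
cd4_log_lik <- function(params, design) {
  stopifnot(inherits(design, "cd4_design"))
  X <- params$X %||% design$X
  if (anyNA(X))
    stop("design matrix contains missing cells; supply params$X with ",
         "imputed values filled in")
  beta <- params$beta
  if (length(beta) != ncol(X)) stop("beta has wrong length")
  eta <- drop(X %*% beta)
  if (!is.null(params$b)) {
    b <- params$b
    eta <- eta + b[design$pat, 1] + b[design$pat, 2] * design$t
  }
  obs <- which(!is.na(design$y))
  y <- design$y[obs]; eta <- eta[obs]
  if (!all(is.finite(eta))) stop("non-finite linear predictor")
  if (design$spec$outcome == "asymptote") {
    return(sum(stats::dbinom(y, 1, stats::plogis(eta), log = TRUE)))
  }
  sigma <- params$sigma_eps
  if (is.null(sigma) || sigma <= 0) stop("sigma_eps must be positive")
  delta <- params$delta_eps %||% 0
  if (all(delta == 0)) {
    sum(stats::dnorm(y, eta, sigma, log = TRUE))
  } else {
    dvis <- if (length(delta) == 1L) rep(delta, length(obs)) else
      delta[design$vnum[obs]]
    cen <- params$sn_center %||% 0
    # residual r = delta*(|W| - cen) + U  =>  r + delta*cen ~ SN(0,...)
    sum(dsn(y - eta + dvis * cen, 0, sigma, dvis, log = TRUE))
  }
}
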