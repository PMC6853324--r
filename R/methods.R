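#' @export
print.cd4_fit <- function(x, ...) {
  print(x$model)
  ctl <- x$control
  cat(sprintf("%d chains x %d iterations (burn-in %d, thin %d)\n",
              ctl$n_chains, ctl$n_iter, ctl$burn_in, ctl$thin))
  cat(sprintf("cDIC %.1f (pD %.1f)\n", x$cdic, x$pD))
  cf <- coef(x)
  cat("posterior mean coefficients:\n")
  print(round(cf, 3))
  invisible(x)
}

#' Summarize a fitted CD4 model
#'
#' Posterior means, sds and 95% equal-tail credible intervals for every
#' scalar parameter, plus convergence (BGR) and Monte Carlo error flags and
#' the conditional DIC. For asymptote models `scale = "odds_ratio"` reports
#' the regression coefficients as posterior mean odds ratios (the draws are
#' exponentiated before summarizing, so the mean is the mean of the
#' exponentiated draws).
#'
#' @param object a `cd4_fit`.
#' @param scale `"identity"` or `"odds_ratio"`.
#' @param ... unused.
#' @return object of class `summary.cd4_fit` with elements `coefficients`
#'   (the summary table), `cdic`, `pD`, `bgr`, `mc_error`, `imputed`.
#' @export
summary.cd4_fit <- function(object, scale = c("identity", "odds_ratio"),
                            ...) {
  scale <- match.arg(scale)
  tab <- object$summaries
  if (scale == "odds_ratio") {
    if (object$model$outcome != "asymptote")
      warning("odds-ratio scale is meant for asymptote models")
    beta_nodes <- names(object$coef_map)
    keep <- tab$parameter %in% object$coef_map
    sub <- object$pooled[, beta_nodes, drop = FALSE]
    es <- exp(sub)
    or <- data.frame(parameter = unname(object$coef_map),
                     mean = colMeans(es), sd = apply(es, 2, stats::sd),
                     `2.5%` = apply(es, 2, stats::quantile, 0.025),
                     `50%` = apply(es, 2, stats::quantile, 0.5),
                     `97.5%` = apply(es, 2, stats::quantile, 0.975),
                     check.names = FALSE, row.names = NULL)
    tab <- rbind(or, tab[!keep, , drop = FALSE])
  }
  structure(list(coefficients = tab, cdic = object$cdic, pD = object$pD,
                 bgr = object$bgr, mc_error = object$mc_error,
                 imputed = object$imputed, model = object$model,
                 scale = scale),
            class = "summary.cd4_fit")
}

#' @export
print.summary.cd4_fit <- function(x, digits = 3, ...) {
  print(x$model)
  if (x$scale == "odds_ratio") cat("(coefficients on the odds-ratio scale)\n")
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("cDIC %.1f (pD %.1f)\n", x$cdic, x$pD))
  conv <- attr(x$bgr, "converged")
  cat(sprintf("BGR < %.2f for %d/%d parameters; MC error rule ok for %d/%d\n",
              attr(x$bgr, "threshold"), sum(conv), length(conv),
              sum(x$mc_error$ok), nrow(x$mc_error)))
  if (!is.null(x$imputed))
    cat(nrow(x$imputed), "missing cells imputed within the sampler\n")
  invisible(x)
}

#' @export
coef.cd4_fit <- function(object, ...) {
  tab <- object$summaries
  idx <- match(unname(object$coef_map), tab$parameter)
  setNames(tab$mean[idx], unname(object$coef_map))
}

#' @export
residuals.cd4_fit <- function(object, ...) {
  design <- object$design
  eta <- fitted_linpred(object)
  if (object$model$outcome == "asymptote")
    design$y - stats::plogis(eta)
  else design$y - eta
}

# posterior-mean linear predictor per analysed visit
fitted_linpred <- function(fit) {
  design <- fit$design
  cm <- colMeans(fit$pooled)
  p <- ncol(design$X)
  X <- design$X
  for (node in list(c("sex", "sex"), c("bcd4_z", "baseline_cd4"),
                    c("blvl_z", "baseline_log_vl"))) {
    key <- switch(node[2], sex = "sex", baseline_cd4 = "baseline_cd4",
                  baseline_log_vl = "baseline_log_vl")
    idx <- design$missing[[key]]
    for (i in idx)
      X[design$pat == i, node[2]] <- cm[sprintf("%s[%d]", node[1], i)]
  }
  beta <- cm[sprintf("beta[%d]", seq_len(p))]
  eta <- drop(X %*% beta)
  if (fit$control$random_effects) {
    P <- length(design$patient_id)
    b1 <- cm[sprintf("b[%d,1]", seq_len(P))]
    b2 <- cm[sprintf("b[%d,2]", seq_len(P))]
    eta <- eta + b1[design$pat] + b2[design$pat] * design$t
  }
  unname(eta)
}

#' Simulate posterior-predictive outcome replicates
#'
#' Each replicate picks one posterior draw (parameters, random effects and
#' imputed covariates) and simulates a new outcome vector for the analysed
#' visits: Gaussian or skew-normal noise around the draw's linear predictor
#' for slope models, Bernoulli draws for asymptote models.
#'
#' @param object a `cd4_fit`.
#' @param nsim number of replicates.
#' @param seed optional seed.
#' @param ... unused.
#' @return matrix, visits x `nsim`.
#' @export
simulate.cd4_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  design <- object$design
  n <- nrow(design$X)
  S <- nrow(object$pooled)
  pick <- sample.int(S, nsim, replace = nsim > S)
  out <- vapply(pick, function(s) {
    eta <- draw_linpred(object, s)
    if (object$model$outcome == "asymptote") {
      stats::rbinom(n, 1, stats::plogis(eta))
    } else {
      sigma <- if (!is.null(object$control$fix_sigma))
        object$control$fix_sigma else object$pooled[s, "sigma_eps"]
      r <- stats::rnorm(n, 0, sigma)
      if (object$model$error_dist == "skew_normal") {
        de <- sn_err_delta(object, s)
        r <- r + de * (abs(stats::rnorm(n)) - object$control$sn_center_value)
      }
      eta + r
    }
  }, numeric(n))
  out
}

# linear predictor (fixed + random effects, no error) for one pooled draw
draw_linpred <- function(fit, s) {
  design <- fit$design
  p <- ncol(design$X)
  row <- fit$pooled[s, ]
  X <- design$X
  for (node in list(c("sex", "sex"), c("bcd4_z", "baseline_cd4"),
                    c("blvl_z", "baseline_log_vl"))) {
    idx <- design$missing[[node[2]]]
    for (i in idx)
      X[design$pat == i, node[2]] <- row[sprintf("%s[%d]", node[1], i)]
  }
  eta <- drop(X %*% row[sprintf("beta[%d]", seq_len(p))])
  if (fit$control$random_effects) {
    P <- length(design$patient_id)
    eta <- eta + row[sprintf("b[%d,1]", design$pat)] +
      row[sprintf("b[%d,2]", design$pat)] * design$t
  }
  unname(eta)
}

sn_err_delta <- function(fit, s, vnum = fit$design$vnum) {
  if (identical(fit$control$delta_structure, "by_visit"))
    fit$pooled[s, sprintf("delta_eps[%d]", vnum)]
  else fit$pooled[s, "delta_eps"]
}

#' Posterior-predictive trajectories (predict method)
#'
#' Delegates to [predict_trajectories()]; see there for details.
#'
#' @param object a `cd4_fit`.
#' @param strata a [strata_spec()] (default strata when `NULL`).
#' @param grid prediction time points (years).
#' @param ndraws posterior draws used.
#' @param type `"prediction"` (new residual noise per draw; slope models) or
#'   `"mean"`.
#' @param ... unused.
#' @export
predict.cd4_fit <- function(object, strata = NULL,
                            grid = seq(0, 5, by = 0.5), ndraws = 200,
                            type = c("prediction", "mean"), ...) {
  predict_trajectories(object, strata = strata, grid = grid,
                       ndraws = ndraws, type = match.arg(type))
}

#' @export
plot.cd4_fit <- function(x, ...) {
  plot(predict(x, ...))
}
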