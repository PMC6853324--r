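#' Stratification scheme for predictive summaries
#'
#' Defines how patients are grouped when summarizing posterior-predictive
#' trajectories. Cutpoints refer to the raw (unstandardized) baseline scale;
#' standardized cohorts are back-transformed using the stored
#' standardization before grouping.
#'
#' @param variable `"baseline_cd4"`, `"sex"`, `"age"`, `"baseline_log_vl"`,
#'   or `"cvl2"` (the patient's realized cumulative log viral load at the
#'   end of follow-up; cVL2-adjusted fits only).
#' @param cutpoints increasing interior cutpoints (ignored for sex;
#'   `numeric(0)` puts every patient in a single stratum).
#' @return object of class `cd4_strata`.
#' @export
strata_spec <- function(variable = c("baseline_cd4", "sex", "age",
                                     "baseline_log_vl", "cvl2"),
                        cutpoints = NULL) {
  variable <- match.arg(variable)
  if (variable == "sex") {
    cutpoints <- NULL
  } else if (is.null(cutpoints)) {
    cutpoints <- switch(variable, baseline_cd4 = c(100, 200), age = 50,
                        baseline_log_vl = 5, cvl2 = c(0.25, 1))
  }
  if (is.unsorted(cutpoints, strictly = TRUE))
    stop("cutpoints must be strictly increasing")
  structure(list(variable = variable, cutpoints = cutpoints),
            class = "cd4_strata")
}

#' Default stratification schemes
#'
#' Baseline CD4 (<=100, 101-200, >200 cells/uL), sex, baseline age
#' (<=50 / >50 years) and baseline log10 VL (<=5 / >5).
#'
#' @return list of [strata_spec()] objects.
#' @export
default_strata <- function() {
  list(strata_spec("baseline_cd4"), strata_spec("sex"),
       strata_spec("age"), strata_spec("baseline_log_vl"))
}

# stratum label per patient for one strata spec, on the raw baseline scale
stratum_of <- function(design, strata) {
  b <- design$baseline
  v <- strata$variable
  if (v == "cvl2") {
    if (!design$spec$cvl_adjusted)
      stop("cvl2 strata need a cVL2-adjusted design")
    raw <- as.vector(tapply(design$X[, "cvl2"], design$pat, max))
  } else {
    raw <- b[[v]]
  }
  info <- design$standardization
  if (!is.null(info) && v %in% info$covariate) {
    i <- match(v, info$covariate)
    raw <- raw * info$sd[i] + info$mean[i]
  }
  if (v == "sex")
    return(factor(ifelse(raw == 1, "female", "male"),
                  levels = c("male", "female")))
  cp <- strata$cutpoints
  if (length(cp) == 0)
    return(factor(rep("all", length(raw)), levels = "all"))
  lab <- character(length(cp) + 1)
  lab[1] <- paste0("<=", cp[1])
  if (length(cp) > 1) {
    # integer cutpoints use the field's "101-200" style, otherwise (a,b]
    lab[2:length(cp)] <- if (all(cp == round(cp)))
      paste0(cp[-length(cp)] + 1, "-", cp[-1])
    else paste0("(", cp[-length(cp)], ",", cp[-1], "]")
  }
  lab[length(cp) + 1] <- paste0(">", cp[length(cp)])
  cut(raw, breaks = c(-Inf, cp, Inf), labels = lab)
}

#' Stratified posterior-predictive trajectories
#'
#' For a sample of posterior draws and every patient, computes the model's
#' predicted outcome on a time grid -- including that draw's random effects
#' and imputed covariates and, for slope models with `type = "prediction"`,
#' fresh residual noise -- then summarizes per stratum and time point the
#' median and 2.5/97.5 percentiles across patients x draws. Asymptote
#' predictions are probabilities of CD4 >= 500.
#'
#' For cVL2-adjusted models each patient's cumulative viral load covariate
#' is carried along the grid using the running value at or before each grid
#' time (the same rule the metric itself uses).
#'
#' @param fit a [fit_cd4()] result.
#' @param strata a [strata_spec()] or list of them; [default_strata()] when
#'   `NULL`.
#' @param grid time points (years).
#' @param ndraws number of posterior draws used.
#' @param type `"prediction"` (default; residual noise added for slope
#'   models) or `"mean"`.
#' @return data.frame of class `cd4_trajectories`: `variable`, `stratum`,
#'   `time`, `median`, `lower`, `upper`, `n_patients`.
#' @export
predict_trajectories <- function(fit, strata = NULL,
                                 grid = seq(0, 5, by = 0.5), ndraws = 200,
                                 type = c("prediction", "mean")) {
  stopifnot(inherits(fit, "cd4_fit"))
  type <- match.arg(type)
  if (is.null(strata)) strata <- default_strata()
  if (inherits(strata, "cd4_strata")) strata <- list(strata)
  design <- fit$design
  spec <- fit$model
  P <- length(design$patient_id)
  S <- nrow(fit$pooled)
  ndraws <- min(ndraws, S)
  pick <- unique(round(seq(1, S, length.out = ndraws)))

  TBg <- time_basis(grid, spec$time_basis, design$horizon)
  G <- length(grid)

  # per-patient baseline covariate matrix, missing cells from posterior means
  cm <- colMeans(fit$pooled)
  bmat <- cbind(1, design$baseline$sex, design$baseline$age,
                design$baseline$baseline_cd4,
                design$baseline$baseline_log_vl)
  fill <- function(col, node, idx) {
    for (i in idx) bmat[i, col] <<- cm[sprintf("%s[%d]", node, i)]
  }
  fill(2, "sex", design$missing$sex)
  fill(4, "bcd4_z", design$missing$baseline_cd4)
  fill(5, "blvl_z", design$missing$baseline_log_vl)

  # cVL2 covariate along the grid: running value at/before each grid time
  cvl_grid <- NULL
  if (spec$cvl_adjusted) {
    p <- ncol(design$X)
    cvl_grid <- matrix(0, P, G)
    for (i in seq_len(P)) {
      rows <- which(design$pat == i)
      idx <- findInterval(grid, design$t[rows])
      vals <- c(0, design$X[rows, p])
      cvl_grid[i, ] <- vals[idx + 1]
    }
  }

  preds <- array(NA_real_, c(P, G, length(pick)))
  p <- ncol(design$X)
  for (d in seq_along(pick)) {
    s <- pick[d]
    row <- fit$pooled[s, ]
    beta <- row[sprintf("beta[%d]", seq_len(p))]
    eta_base <- drop(bmat %*% beta[1:5])            # per patient
    eta_time <- drop(TBg %*% beta[5 + seq_len(design$K)])  # per grid point
    eta <- outer(eta_base, eta_time, `+`)
    if (spec$cvl_adjusted) eta <- eta + beta[p] * cvl_grid
    if (fit$control$random_effects) {
      b1 <- row[sprintf("b[%d,1]", seq_len(P))]
      b2 <- row[sprintf("b[%d,2]", seq_len(P))]
      eta <- eta + b1 + outer(b2, grid)
    }
    if (spec$outcome == "asymptote") {
      preds[, , d] <- stats::plogis(eta)
    } else {
      if (type == "prediction") {
        sigma <- if (!is.null(fit$control$fix_sigma))
          fit$control$fix_sigma else row["sigma_eps"]
        noise <- matrix(stats::rnorm(P * G, 0, sigma), P, G)
        if (spec$error_dist == "skew_normal") {
          de <- if (identical(fit$control$delta_structure, "by_visit"))
            row["delta_eps[1]"] else row["delta_eps"]
          noise <- noise + de * (abs(matrix(stats::rnorm(P * G), P, G)) -
                                   fit$control$sn_center_value)
        }
        eta <- eta + noise
      }
      preds[, , d] <- eta
    }
  }

  out <- do.call(rbind, lapply(strata, function(st) {
    lab <- stratum_of(design, st)
    do.call(rbind, lapply(levels(lab), function(lv) {
      idx <- which(!is.na(lab) & lab == lv)
      if (!length(idx)) stop("empty stratum: ", st$variable, " ", lv)
      vals <- preds[idx, , , drop = FALSE]
      data.frame(variable = st$variable, stratum = lv, time = grid,
                 median = apply(vals, 2, stats::median),
                 lower = apply(vals, 2, stats::quantile, 0.025),
                 upper = apply(vals, 2, stats::quantile, 0.975),
                 n_patients = length(idx), row.names = NULL,
                 stringsAsFactors = FALSE)
    }))
  }))
  class(out) <- c("cd4_trajectories", "data.frame")
  attr(out, "outcome") <- spec$outcome
  attr(out, "type") <- type
  out
}

#' @export
plot.cd4_trajectories <- function(x, variable = NULL, ...) {
  v <- variable %||% x$variable[1]
  d <- x[x$variable == v, , drop = FALSE]
  strata <- unique(d$stratum)
  cols <- grDevices::hcl.colors(max(3, length(strata)), "Dark 2")
  ylab <- if (attr(x, "outcome") == "asymptote")
    "P(CD4 >= 500 cells/uL)" else "CD4 count (cells/uL)"
  plot(range(d$time), range(c(d$lower, d$upper)), type = "n",
       xlab = "years on ART", ylab = ylab, main = v, ...)
  for (i in seq_along(strata)) {
    di <- d[d$stratum == strata[i], ]
    graphics::polygon(c(di$time, rev(di$time)), c(di$lower, rev(di$upper)),
                      col = grDevices::adjustcolor(cols[i], 0.15),
                      border = NA)
    graphics::lines(di$time, di$median, col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = strata, col = cols[seq_along(strata)],
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Conditional-DIC model comparison table
#'
#' Tabulates a set of fits sorted by cDIC, annotating each against the best
#' model with the decision rule: differences below 5 cannot support any
#' choice, and only differences of approximately 10 or more indicate a
#' clear choice.
#'
#' @param fits list of at least two [fit_cd4()] results (named, ideally).
#' @return data.frame sorted by cDIC with columns `model`, `outcome`,
#'   `basis`, `re_dist`, `error_dist`, `adjusted`, `cdic`, `pD`,
#'   `delta_cdic`, `vs_best`.
#' @export
model_comparison_table <- function(fits) {
  if (inherits(fits, "cd4_fit")) fits <- list(fits)
  if (length(fits) < 2L)
    stop("model comparison needs at least two fits")
  stopifnot(all(vapply(fits, inherits, logical(1), "cd4_fit")))
  nm <- names(fits) %||% paste0("fit", seq_along(fits))
  if (is.null(names(fits))) names(fits) <- nm
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(model = names(fits)[i],
               number = model_number(f$model),
               outcome = f$model$outcome, basis = f$model$time_basis,
               re_dist = f$model$re_dist,
               error_dist = if (f$model$outcome == "slope")
                 f$model$error_dist else NA_character_,
               adjusted = f$model$cvl_adjusted,
               cdic = f$cdic, pD = f$pD, stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$cdic), , drop = FALSE]
  tab$delta_cdic <- tab$cdic - tab$cdic[1]
  tab$vs_best <- vapply(tab$delta_cdic, function(d) {
    if (d == 0) "best" else cdic_compare(tab$cdic[1], tab$cdic[1] + d)$label
  }, character(1))
  rownames(tab) <- NULL
  tab
}
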