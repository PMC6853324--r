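#' Log viral-load excess above the detection threshold
#'
#' The per-visit building block of the cumulative log viral-load metric:
#' `log10(viral_load / detection_limit)`, floored at zero for values at or
#' below the threshold. The default threshold of 400 copies/mL excludes
#' transient low-level "blips" (50-400 copies/mL) that do not predict
#' rebound; the assay limit (50) or a less sensitive 1000 copies/mL variant
#' can be selected instead.
#'
#' @param viral_load viral load(s), copies/mL; must be positive. `NA` is
#'   propagated.
#' @param detection_limit threshold in copies/mL (default 400).
#' @return log10 ratio(s), `>= 0`.
#' @export
log_excess <- function(viral_load, detection_limit = 400) {
  if (any(viral_load <= 0, na.rm = TRUE))
    stop("viral_load must be positive")
  pmax(0, log10(viral_load / detection_limit))
}

#' Trapezoidal increment of cumulative log viral load
#'
#' Area contribution of one inter-visit interval:
#' `(t_curr - t_prev) * (log_excess(v_curr) + log_excess(v_prev)) / 2`.
#' When intermediate visits have missing viral load the interval simply
#' spans them (a longer inter-visit duration), which is the metric's
#' bridging rule.
#'
#' @param t_prev,t_curr visit times in years, `t_curr > t_prev`.
#' @param v_prev,v_curr observed viral loads (copies/mL) at the two visits.
#' @param detection_limit threshold in copies/mL.
#' @return increment in log10 copy-year/mL.
#' @export
cvl2_increment <- function(t_prev, t_curr, v_prev, v_curr,
                           detection_limit = 400) {
  if (any(t_curr <= t_prev))
    stop("visit times must be strictly increasing")
  (t_curr - t_prev) *
    (log_excess(v_curr, detection_limit) +
       log_excess(v_prev, detection_limit)) / 2
}

#' Cumulative log viral load (cVL2) per patient-visit
#'
#' Computes the running cumulative log viral load for every visit of every
#' patient: the trapezoid of `log10(VL/detection_limit)`, floored at zero,
#' over time on ART. Visits with missing viral load contribute no node --
#' the trapezoid bridges adjacent observed visits -- but still receive a
#' value, namely the cumulative total at the most recent observed node at or
#' before their time. The baseline value is 0 by definition.
#'
#' @param x a `cd4_cohort` or a visits data.frame with columns `patient_id`,
#'   `time_on_art`, `viral_load`.
#' @param detection_limit threshold in copies/mL (default 400).
#' @return A data.frame of class `cvl_series` with columns `patient_id`,
#'   `time_on_art`, `cvl2` (log10 copy-year/mL), one row per visit, in visit
#'   order.
#' @export
compute_cvl2 <- function(x, detection_limit = 400) {
  visits <- if (inherits(x, "cd4_cohort")) x$visits else as.data.frame(x)
  stopifnot(all(c("patient_id", "time_on_art", "viral_load") %in%
                  names(visits)))
  visits <- visits[order(visits$patient_id, visits$time_on_art), , drop = FALSE]
  out <- do.call(rbind, lapply(split(visits, visits$patient_id), function(v) {
    tt <- v$time_on_art
    if (min(tt) != 0)
      stop("patient ", v$patient_id[1], " has no baseline (t = 0) visit")
    data.frame(patient_id = v$patient_id, time_on_art = tt,
               cvl2 = running_cvl2(tt, v$viral_load, detection_limit),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("cvl_series", "data.frame")
  attr(out, "detection_limit") <- detection_limit
  out
}

# running cumulative for one patient: times tt (sorted), viral loads with NA
# at missing visits; trapezoid over observed nodes, bridged across gaps
running_cvl2 <- function(tt, vl, detection_limit = 400) {
  le <- log_excess(vl, detection_limit)
  obs <- which(!is.na(le))
  cum <- numeric(length(tt))
  if (length(obs) >= 2L) {
    inc <- diff(tt[obs]) * (le[obs][-1] + le[obs][-length(obs)]) / 2
    cum_obs <- cumsum(c(0, inc))
    # value at each visit: cumulative at the last observed node at/before it
    idx <- findInterval(tt, tt[obs])
    cum <- ifelse(idx >= 1, cum_obs[pmax(idx, 1)], 0)
  }
  cum
}
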