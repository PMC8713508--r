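#' Kaplan-Meier estimate with Brookmeyer-Crowley median confidence interval
#'
#' Product-limit estimator of a survival function from right-censored data,
#' with the median (smallest time at which the estimate drops to or below
#' 0.5) and its 95% confidence interval by the Brookmeyer-Crowley
#' construction on the log(-log) scale: the interval collects the times whose
#' pointwise log-log confidence band still covers 0.5.
#'
#' This is the estimator behind [km_backward_onset()]; it is deliberately
#' self-contained so the test suite can compare it against an independent
#' survival implementation.
#'
#' @param time Follow-up times (> 0 allowed to be 0 for degenerate onsets).
#' @param event 1 = event observed, 0 = right-censored.
#' @param conf_level Confidence level for the median interval (default 0.95).
#' @return A list with the step function (`time`, `n_risk`, `n_event`,
#'   `surv`, `lower`, `upper` pointwise band), `median`, and `ci` (lower,
#'   upper; `NA` where the band never reaches 0.5).
#' @export
km_fit <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)),
            length(time) >= 1L, all(time >= 0))
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- sort(unique(time[event == 1]))
  n <- length(time)
  surv <- numeric(length(ut)); d <- integer(length(ut)); r <- integer(length(ut))
  s <- 1
  gw <- 0  # running Greenwood sum: sum d / (n (n - d))
  lower <- upper <- numeric(length(ut))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  for (i in seq_along(ut)) {
    r[i] <- sum(time >= ut[i])
    d[i] <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d[i] / r[i])
    surv[i] <- s
    if (r[i] > d[i]) gw <- gw + d[i] / (r[i] * (r[i] - d[i])) else gw <- Inf
    if (s > 0 && s < 1 && is.finite(gw)) {
      # var of log(-log S) by the delta method
      se_ll <- sqrt(gw) / abs(log(s))
      lower[i] <- s^exp(z * se_ll)
      upper[i] <- s^exp(-z * se_ll)
    } else {
      # S = 0 or 1: log-log band undefined at the boundary
      lower[i] <- NA_real_; upper[i] <- NA_real_
    }
  }
  med_i <- which(surv <= 0.5)
  med <- if (length(med_i)) ut[med_i[1L]] else NA_real_
  # Brookmeyer-Crowley: first time each pointwise band crosses 0.5; the lower
  # band sits below the curve so it crosses first and bounds the median below
  lo_i <- which(!is.na(lower) & lower <= 0.5)
  hi_i <- which(!is.na(upper) & upper <= 0.5)
  ci <- c(lower = if (length(lo_i)) ut[lo_i[1L]] else NA_real_,
          upper = if (length(hi_i)) ut[hi_i[1L]] else NA_real_)
  list(time = ut, n_risk = r, n_event = d, surv = surv,
       lower = lower, upper = upper, median = med, ci = ci,
       conf_level = conf_level)
}
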