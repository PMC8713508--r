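#' Shock index
#'
#' Heart rate divided by systolic blood pressure. Values above 1.0 signal
#' circulatory failure and are used here as a binary predictor event.
#'
#' @param hr Heart rate, beats/min (>= 0). Vectorised.
#' @param sbp Systolic blood pressure, mmHg (> 0). Vectorised.
#' @return `hr / sbp`.
#' @examples
#' shock_index(100, 100)  # 1
#' @export
shock_index <- function(hr, sbp) {
  if (any(!is.na(sbp) & sbp <= 0)) stop("SBP must be > 0", call. = FALSE)
  if (any(!is.na(hr) & hr < 0)) stop("HR must be >= 0", call. = FALSE)
  hr / sbp
}

#' First time the shock index exceeds a threshold
#'
#' Scans a patient's observations in time order and returns the earliest
#' timestamp with shock index strictly greater than `threshold` (strict
#' because the predictor is defined as SI > 1.0). Observations lacking HR or
#' SBP are skipped.
#'
#' @param x A `sid_cohort`.
#' @param patient_id Patient identifier.
#' @param threshold Ratio threshold, default 1.0.
#' @return Time in hours, or `NA_real_` if the index never exceeds the
#'   threshold.
#' @export
si_event_time <- function(x, patient_id, threshold = 1.0) {
  stopifnot(inherits(x, "sid_cohort"))
  if (!patient_id %in% x$patients$patient_id)
    stop("unknown patient id: ", patient_id, call. = FALSE)
  o <- x$observations[x$observations$patient_id == patient_id, , drop = FALSE]
  ok <- !is.na(o$hr) & !is.na(o$sbp)
  si <- shock_index(o$hr[ok], o$sbp[ok])
  hit <- si > threshold
  if (!any(hit)) return(NA_real_)
  min(o$time_h[ok][hit])
}

#' Binned vital-sign trajectory backward from death
#'
#' Summarises a vital (or the derived shock index) over the final week of
#' life, in 12-hour bins counted backward from death. Backward bin `b` covers
#' offsets `(12 b, 12 (b + 1)]` hours before death, with an observation at the
#' death instant (offset 0) assigned to bin 0. Decedents only.
#'
#' @param x A `sid_cohort` (censored patients are ignored).
#' @param vital One of `"sbp"`, `"dbp"`, `"hr"`, `"temp"`, `"rr"`, `"spo2"`,
#'   or `"si"` for the derived shock index.
#' @param bin_h Bin width in hours (default 12).
#' @param span_h Span before death in hours (default 168).
#' @param stat `"mean"` (default) or `"median"` for the per-bin location.
#' @return A data frame with one row per bin: `vital`,
#'   `bin_start_h_before_death`, `mean` (or median, in the same column), `sd`,
#'   `n`, `empty` (`TRUE` when no observation fell in the bin; the location is
#'   `NA` there).
#' @export
binned_trajectory <- function(x, vital, bin_h = 12, span_h = 168,
                              stat = c("mean", "median")) {
  stopifnot(inherits(x, "sid_cohort"))
  stat <- match.arg(stat)
  vitals <- c(.vitals_cols(), "si")
  if (!vital %in% vitals)
    stop("unknown vital name: ", vital, " (expected one of ",
         paste(vitals, collapse = ", "), ")", call. = FALSE)
  p <- x$patients[x$patients$terminal_status == "died", , drop = FALSE]
  o <- x$observations[x$observations$patient_id %in% p$patient_id, , drop = FALSE]
  val <- if (vital == "si") {
    ifelse(!is.na(o$hr) & !is.na(o$sbp), o$hr / o$sbp, NA_real_)
  } else o[[vital]]
  offset <- p$terminal_h[match(o$patient_id, p$patient_id)] - o$time_h
  keep <- !is.na(val) & offset <= span_h
  val <- val[keep]; offset <- offset[keep]
  b <- pmax(ceiling(offset / bin_h) - 1, 0)
  nb <- as.integer(span_h / bin_h)
  out <- data.frame(vital = vital,
                    bin_start_h_before_death = bin_h * seq_len(nb) - bin_h,
                    mean = NA_real_, sd = NA_real_, n = 0L, empty = TRUE,
                    stringsAsFactors = FALSE)
  loc_fun <- if (stat == "mean") mean else stats::median
  for (bi in seq_len(nb) - 1L) {
    v <- val[b == bi]
    if (length(v)) {
      out$mean[bi + 1L] <- loc_fun(v)
      out$sd[bi + 1L] <- stats::sd(v)
      out$n[bi + 1L] <- length(v)
      out$empty[bi + 1L] <- FALSE
    }
  }
  out
}
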