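# Per-sign summary statistics over the decedent population: prevalence inside
# a backward window from death, mortality within a horizon of first
# appearance, and the backward Kaplan-Meier onset distribution.

# internal: first event time for ANY predictor (charted sign or derived SI)
.any_event_time <- function(x, patient_id, predictor) {
  if (predictor == "si_gt1") si_event_time(x, patient_id)
  else first_event_time(x, patient_id, predictor)
}

#' Prevalence of a predictor within a window before death
#'
#' Proportion of decedents exhibiting the predictor inside the final `window`
#' hours of life. Two readings are supported. `"presence"` (default) counts
#' patients with a positive observation (or SI above threshold) at some
#' timestamp inside the window — the natural reading for signs that persist
#' once they appear. `"onset"` counts patients whose *first* event falls
#' inside the window; for decedents this is numerically the same quantity as
#' the within-window mortality after onset, so it is not the default.
#'
#' @param x A `sid_cohort`; must contain at least one decedent. Censored
#'   patients are excluded with a warning.
#' @param predictor A predictor id from [predictor_ids()].
#' @param window_h Window width in hours before death (default 72).
#' @param method `"presence"` or `"onset"` (see above).
#' @return A list with `count`, `n` (all decedents) and `proportion`.
#' @export
prevalence_within_window <- function(x, predictor, window_h = 72,
                                     method = c("presence", "onset")) {
  method <- match.arg(method)
  .predictor_index(predictor)
  x <- decedents(x)
  p <- x$patients
  if (nrow(p) == 0L) stop("cohort contains no decedents", call. = FALSE)
  count <- 0L
  for (i in seq_len(nrow(p))) {
    pid <- p$patient_id[i]
    t_death <- p$terminal_h[i]
    hit <- if (method == "onset") {
      te <- .any_event_time(x, pid, predictor)
      !is.na(te) && (t_death - te) <= window_h
    } else {
      o <- x$observations[x$observations$patient_id == pid, , drop = FALSE]
      o <- o[(t_death - o$time_h) <= window_h, , drop = FALSE]
      if (predictor == "si_gt1") {
        ok <- !is.na(o$hr) & !is.na(o$sbp)
        any(o$hr[ok] / o$sbp[ok] > 1.0)
      } else {
        any(!is.na(o[[predictor]]) & o[[predictor]] == 1)
      }
    }
    if (isTRUE(hit)) count <- count + 1L
  }
  list(count = count, n = nrow(p), proportion = count / nrow(p))
}

#' Mortality within a horizon of a predictor's first appearance
#'
#' Among decedents who ever exhibit the predictor, the proportion who die
#' within `horizon` of its first appearance (inclusive: death exactly at the
#' horizon counts).
#'
#' @param x A `sid_cohort`; censored patients are excluded with a warning.
#' @param predictor A predictor id from [predictor_ids()].
#' @param horizon A [horizon()] object, a label (`"7d"`, `"72h"`, `"24h"`), or
#'   hours.
#' @return A list with `numerator`, `denominator` (exhibitors) and
#'   `proportion`. Stops with an undefined-result error when no decedent
#'   exhibits the predictor (distinct from a proportion of 0).
#' @export
mortality_after_onset <- function(x, predictor, horizon) {
  .predictor_index(predictor)
  h <- .horizon_hours(horizon)
  x <- decedents(x)
  p <- x$patients
  lead <- vapply(seq_len(nrow(p)), function(i) {
    te <- .any_event_time(x, p$patient_id[i], predictor)
    if (is.na(te)) NA_real_ else p$terminal_h[i] - te
  }, numeric(1))
  den <- sum(!is.na(lead))
  if (den == 0L)
    stop("undefined result: no decedent exhibits predictor '", predictor, "'",
         call. = FALSE)
  num <- sum(lead[!is.na(lead)] <= h)
  list(numerator = num, denominator = den, proportion = num / den)
}

#' Backward Kaplan-Meier onset of a predictor
#'
#' Estimates the distribution of the lead time between a predictor's first
#' appearance and death, in days, by the Kaplan-Meier method applied backward
#' from death: each exhibitor contributes an "event" at
#' `(death time - first event time) / 24` days. By default the risk set is
#' exhibitors only (no censoring); with `include_nonexhibitors = TRUE`,
#' decedents who never exhibit the sign enter right-censored at their full
#' observed span `(death time - observation start) / 24`.
#'
#' The median is the smallest lead with survival at or below 0.5; the 95%
#' interval is the Brookmeyer-Crowley construction on the log-log scale (see
#' [km_fit()]).
#'
#' @inheritParams mortality_after_onset
#' @param include_nonexhibitors Pool non-exhibiting decedents as censored
#'   observations (default `FALSE`).
#' @return A list with `median_days`, `ci95` (lower, upper days), `n_event`,
#'   `n` and the underlying `fit`.
#' @export
km_backward_onset <- function(x, predictor, include_nonexhibitors = FALSE) {
  .predictor_index(predictor)
  x <- decedents(x)
  p <- x$patients
  lead_d <- vapply(seq_len(nrow(p)), function(i) {
    te <- .any_event_time(x, p$patient_id[i], predictor)
    if (is.na(te)) NA_real_ else (p$terminal_h[i] - te) / 24
  }, numeric(1))
  span_d <- (p$terminal_h - p$obs_start_h) / 24
  is_ev <- !is.na(lead_d)
  if (!any(is_ev))
    stop("undefined result: no decedent exhibits predictor '", predictor, "'",
         call. = FALSE)
  if (include_nonexhibitors) {
    time <- ifelse(is_ev, lead_d, span_d)
    event <- as.numeric(is_ev)
  } else {
    time <- lead_d[is_ev]
    event <- rep(1, sum(is_ev))
  }
  fit <- km_fit(time, event)
  list(median_days = fit$median,
       ci95 = fit$ci,
       n_event = sum(is_ev), n = length(time), fit = fit)
}

#' Per-sign summary table (prevalence, onset, mortality)
#'
#' Applies [prevalence_within_window()], [mortality_after_onset()] (72-h and
#' 24-h horizons) and [km_backward_onset()] to every predictor in the
#' catalog. Predictors with no exhibitor (e.g. apnea in the source cohort)
#' get `NA` onset and mortality, rendered as "None" in exports.
#'
#' @param x A `sid_cohort`; censored patients are excluded with a warning.
#' @param window_h Prevalence window in hours (default 72).
#' @return A data frame, one row per predictor in catalog order, with columns
#'   `sign`, `km_median_days`, `ci_low`, `ci_high`, `n_within72h`,
#'   `prevalence_pct`, `mort72_num`, `mort72_den`, `mort72_pct`, `mort24_num`,
#'   `mort24_den`, `mort24_pct`.
#' @export
summarize_signs <- function(x, window_h = 72) {
  x <- decedents(x)
  rows <- lapply(predictor_ids(), function(id) {
    prev <- prevalence_within_window(x, id, window_h)
    row <- data.frame(sign = id, km_median_days = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, n_within72h = prev$count,
                      prevalence_pct = 100 * prev$proportion,
                      mort72_num = NA_integer_, mort72_den = NA_integer_,
                      mort72_pct = NA_real_, mort24_num = NA_integer_,
                      mort24_den = NA_integer_, mort24_pct = NA_real_,
                      stringsAsFactors = FALSE)
    has_exhibitor <- tryCatch({
      m72 <- mortality_after_onset(x, id, "72h"); TRUE
    }, error = function(e) FALSE)
    if (has_exhibitor) {
      m24 <- mortality_after_onset(x, id, "24h")
      km <- km_backward_onset(x, id)
      row$km_median_days <- km$median_days
      row$ci_low <- km$ci95[["lower"]]
      row$ci_high <- km$ci95[["upper"]]
      row$mort72_num <- m72$numerator; row$mort72_den <- m72$denominator
      row$mort72_pct <- 100 * m72$proportion
      row$mort24_num <- m24$numerator; row$mort24_den <- m24$denominator
      row$mort24_pct <- 100 * m24$proportion
    }
    row
  })
  do.call(rbind, rows)
}

#' Packaged per-sign count fixture
#'
#' The published per-sign counts for the 50-decedent noncancer cohort:
#' number exhibiting each sign within 72 h of death, and mortality
#' numerators/denominators at the 72-h and 24-h horizons, transcribed from
#' the source table. Used by the acceptance tests for exact arithmetic
#' checks.
#'
#' @return A list with `n_decedents` and a data frame `signs` (columns
#'   `sign`, `n_within72h`, `mort72_num`, `mort72_den`, `mort24_num`,
#'   `mort24_den`, `median_onset_days`).
#' @export
sign_count_reference <- function() {
  path <- system.file("extdata", "sign_count_reference.json", package = "sidmodels")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$signs <- as.data.frame(raw$signs, stringsAsFactors = FALSE)
  raw
}

#' Construct a cohort realising the packaged count fixture
#'
#' Builds a synthetic 50-decedent cohort whose per-sign counts reproduce the
#' packaged fixture exactly: for each sign, `mort24_num` exhibitors get an
#' onset 12 h before death, `mort72_num - mort24_num` get 48 h, and the
#' remaining exhibitors get 96 h (outside the 72-h mortality horizon but
#' still present — signs persist — inside the 72-h prevalence window). All
#' patients are observed every 12 h for 10 days and die at the last
#' observation. Vitals are left missing; the derived shock-index predictor
#' has no events in this cohort.
#'
#' This is a synthetic stand-in for the study's undeposited raw data: it
#' matches the published counts, not the patients.
#'
#' @param counts A fixture as returned by [sign_count_reference()].
#' @return A validated `sid_cohort` of decedents.
#' @export
cohort_from_sign_counts <- function(counts = sign_count_reference()) {
  n <- counts$n_decedents
  span_h <- 240
  times <- seq(0, span_h, by = 12)
  p <- data.frame(patient_id = sprintf("t3_%02d", seq_len(n)),
                  age = 86, sex = "female", diagnosis = "respiratory",
                  charlson = 3, obs_start_h = 0, terminal_h = span_h,
                  terminal_status = "died", censor_reason = NA_character_,
                  stringsAsFactors = FALSE)
  o <- data.frame(patient_id = rep(p$patient_id, each = length(times)),
                  time_h = rep(times, n), stringsAsFactors = FALSE)
  for (s in sign_ids()) o[[s]] <- 0
  for (v in .vitals_cols()) o[[v]] <- NA_real_
  sg <- counts$signs
  for (i in seq_len(nrow(sg))) {
    s <- sg$sign[i]
    n_ex <- sg$n_within72h[i]
    if (is.na(n_ex) || n_ex == 0) next
    stopifnot(sg$mort72_den[i] == n_ex)
    lead <- c(rep(12, sg$mort24_num[i]),
              rep(48, sg$mort72_num[i] - sg$mort24_num[i]),
              rep(96, n_ex - sg$mort72_num[i]))
    onset <- span_h - lead
    for (j in seq_len(n_ex)) {
      rows <- o$patient_id == p$patient_id[j] & o$time_h >= onset[j]
      o[[s]][rows] <- 1
    }
  }
  cohort(p, o)
}
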