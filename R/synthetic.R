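# Synthetic dying-phase cohort generator. Emulates the study design the
# analysis assumes: ~12-hourly standardized observations started after oral
# intake collapses, persistent physical signs whose onsets are anchored a
# random lead before death, and vitals that drift over the final 72 h so
# that the shock index typically crosses 1.0 shortly before death.

#' Generator configuration
#'
#' Defaults encode the published cohort's marginal structure: per-sign
#' occurrence probabilities and median onset leads from the per-sign summary
#' table ([default_config_from_reference()] wires them in), a lognormal
#' observation span with mean 14.1 and sd 15.6 days, a 12-hour observation
#' grid, and a vitals model in which systolic pressure falls and heart rate
#' rises linearly over the final 72 hours.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; mandatory for generation.
#' @param occurrence Named numeric vector: per-sign occurrence probability in
#'   \[0, 1\] for the 11 charted signs.
#' @param onset_median_days Named numeric vector: median onset lead before
#'   death, days (> 0), per charted sign (ignored where occurrence is 0).
#' @param onset_family `"exponential"` (default; rate `log(2) / median`) or
#'   `"lognormal"` (meanlog `log(median)`, sdlog `onset_sdlog`).
#' @param onset_sdlog sdlog of the lognormal onset family (default 0.8).
#' @param interval_h Observation interval in hours (default 12).
#' @param jitter_h Uniform jitter applied to interior observation times
#'   (default 0; must stay below `interval_h / 2`).
#' @param span_mean_days,span_sd_days Mean and sd of the lognormal
#'   observation-span distribution, days before death (defaults 14.1, 15.6).
#' @param span_min_days Lower clip on spans so every patient has at least a
#'   short record (default 1).
#' @param vitals List of vitals-model parameters: baseline mean/sd, terminal
#'   change over the final `ramp_h` hours, and per-observation noise sd, for
#'   `sbp`, `dbp`, `hr`, `temp`, `rr`, `spo2`.
#' @param survivor_fraction Fraction of patients whose observation ends in
#'   discontinuation rather than death (default 0: the analysis population is
#'   decedents).
#' @param censor_reason_mix Named probability weights over [censor_reasons()]
#'   for survivors.
#' @return A `sid_generator_config` list.
#' @export
generator_config <- function(n_patients = 50,
                             seed = 1L,
                             occurrence = NULL,
                             onset_median_days = NULL,
                             onset_family = c("exponential", "lognormal"),
                             onset_sdlog = 0.8,
                             interval_h = 12,
                             jitter_h = 0,
                             span_mean_days = 14.1,
                             span_sd_days = 15.6,
                             span_min_days = 1,
                             vitals = NULL,
                             survivor_fraction = 0,
                             censor_reason_mix = NULL) {
  onset_family <- match.arg(onset_family)
  defaults <- default_config_from_reference()
  if (is.null(occurrence)) occurrence <- defaults$occurrence
  if (is.null(onset_median_days)) onset_median_days <- defaults$onset_median_days
  if (is.null(vitals)) vitals <- .default_vitals_model()
  if (is.null(censor_reason_mix))
    censor_reason_mix <- stats::setNames(rep(1 / 6, 6), censor_reasons())
  cfg <- structure(list(
    n_patients = n_patients, seed = seed, occurrence = occurrence,
    onset_median_days = onset_median_days, onset_family = onset_family,
    onset_sdlog = onset_sdlog, interval_h = interval_h, jitter_h = jitter_h,
    span_mean_days = span_mean_days, span_sd_days = span_sd_days,
    span_min_days = span_min_days, vitals = vitals,
    survivor_fraction = survivor_fraction,
    censor_reason_mix = censor_reason_mix), class = "sid_generator_config")
  validate_generator_config(cfg)
  cfg
}

# Fig-2-style drift: SBP falls ~110 -> ~75 and HR rises ~88 -> ~110 over the
# final 72 h, so the mean shock index crosses 1.0 in the last day or two.
.default_vitals_model <- function() {
  list(ramp_h = 72,
       sbp  = list(base_mean = 110, base_sd = 12, change = -35, noise_sd = 7),
       dbp  = list(base_mean = 65,  base_sd = 8,  change = -15, noise_sd = 5),
       hr   = list(base_mean = 88,  base_sd = 10, change = 22,  noise_sd = 6),
       temp = list(base_mean = 36.8, base_sd = 0.4, change = 0.4, noise_sd = 0.3),
       rr   = list(base_mean = 20,  base_sd = 3,  change = 5,   noise_sd = 2),
       spo2 = list(base_mean = 95,  base_sd = 2,  change = -7,  noise_sd = 2))
}

#' Validate a generator configuration
#' @param cfg A `sid_generator_config`.
#' @return `cfg` invisibly; stops naming each invalid field.
#' @export
validate_generator_config <- function(cfg) {
  bad <- character(0)
  if (!(length(cfg$n_patients) == 1 && cfg$n_patients >= 0 &&
          cfg$n_patients == round(cfg$n_patients))) bad <- c(bad, "n_patients")
  sids <- sign_ids()
  if (!all(sids %in% names(cfg$occurrence)) ||
      any(cfg$occurrence < 0 | cfg$occurrence > 1)) bad <- c(bad, "occurrence")
  med <- cfg$onset_median_days[sids]
  act <- cfg$occurrence[sids] > 0
  if (any(act & (is.na(med) | med <= 0))) bad <- c(bad, "onset_median_days")
  if (!(cfg$interval_h > 0)) bad <- c(bad, "interval_h")
  if (cfg$jitter_h < 0 || cfg$jitter_h >= cfg$interval_h / 2)
    bad <- c(bad, "jitter_h")
  if (!(cfg$span_mean_days > 0 && cfg$span_sd_days >= 0))
    bad <- c(bad, "span_mean_days/span_sd_days")
  if (cfg$survivor_fraction < 0 || cfg$survivor_fraction >= 1)
    bad <- c(bad, "survivor_fraction")
  if (length(bad))
    stop("invalid generator config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(cfg)
}

#' Default configuration matched to the published per-sign summary
#'
#' Occurrence probabilities are the published within-72-h prevalence
#' fractions over 50 decedents (apnea 0, since it was never observed) and
#' onset medians are the published backward Kaplan-Meier medians in days.
#' The shock-index predictor is not configured here: its events emerge from
#' the vitals drift.
#'
#' @return A list with `occurrence` and `onset_median_days` named vectors
#'   (and nothing else; feed them to [generator_config()]).
#' @export
default_config_from_reference <- function() {
  counts <- sign_count_reference()
  sg <- counts$signs
  occ <- stats::setNames(sg$n_within72h / counts$n_decedents, sg$sign)
  med <- stats::setNames(sg$median_onset_days, sg$sign)
  med[is.na(med)] <- 1  # unused when occurrence is 0
  list(occurrence = occ, onset_median_days = med)
}

#' Generate a synthetic dying-phase cohort
#'
#' For each decedent: an observation span is drawn (lognormal, days), death
#' is fixed at the end of the span, and observations are laid on the
#' 12-hourly grid from the start of observation to death. Each charted sign
#' occurs with its configured probability; when it occurs, an onset lead is
#' drawn from the onset distribution, the onset is clipped into the observed
#' span, and the sign is positive at every observation at or after onset
#' (signs persist). Vitals follow patient-level baselines plus a linear
#' terminal ramp over the final 72 h plus Gaussian noise. Survivors, if
#' configured, are censored at the end of their span with a discontinuation
#' reason drawn from the configured mix, and never show signs.
#'
#' @param cfg A [generator_config()].
#' @return A validated `sid_cohort`.
#' @export
generate_cohort <- function(cfg = generator_config()) {
  validate_generator_config(cfg)
  .with_seed(cfg$seed, .generate_cohort_impl(cfg))
}

.generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  if (n == 0L) return(cohort(.empty_patients(), .empty_observations()))
  # lognormal span parameterised by mean/sd on the natural scale
  cv2 <- (cfg$span_sd_days / cfg$span_mean_days)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(cfg$span_mean_days) - sdlog^2 / 2
  span_d <- pmax(cfg$span_min_days, stats::rlnorm(n, meanlog, sdlog))
  span_h <- round(span_d * 24 / cfg$interval_h) * cfg$interval_h
  span_h <- pmax(span_h, cfg$interval_h)
  died <- stats::runif(n) >= cfg$survivor_fraction
  p <- data.frame(
    patient_id = sprintf("p%04d", seq_len(n)),
    age = round(stats::rnorm(n, 85.8, 8.2), 1),
    sex = ifelse(stats::runif(n) < 0.229, "male", "female"),
    diagnosis = sample(c("cerebrovascular", "cardiovascular", "respiratory",
                         "liver", "renal", "other"), n, replace = TRUE,
                       prob = c(0.06, 0.14, 0.54, 0.02, 0.10, 0.14)),
    charlson = pmax(0, round(stats::rnorm(n, 3.12, 1.4))),
    obs_start_h = 0,
    terminal_h = span_h,
    terminal_status = ifelse(died, "died", "censored"),
    censor_reason = NA_character_,
    stringsAsFactors = FALSE)
  if (any(!died))
    p$censor_reason[!died] <- sample(names(cfg$censor_reason_mix), sum(!died),
                                     replace = TRUE,
                                     prob = cfg$censor_reason_mix)
  n_obs <- as.integer(span_h / cfg$interval_h) + 1L
  pat_row <- rep(seq_len(n), n_obs)
  t_idx <- sequence(n_obs) - 1L
  time_h <- t_idx * cfg$interval_h
  if (cfg$jitter_h > 0) {
    interior <- t_idx > 0 & time_h < span_h[pat_row]
    time_h[interior] <- time_h[interior] +
      stats::runif(sum(interior), -cfg$jitter_h, cfg$jitter_h)
  }
  o <- data.frame(patient_id = p$patient_id[pat_row], time_h = time_h,
                  stringsAsFactors = FALSE)
  t_death <- span_h[pat_row]
  # persistent sign flags anchored a random lead before death
  for (s in sign_ids()) {
    occurs <- died & (stats::runif(n) < cfg$occurrence[[s]])
    m <- cfg$onset_median_days[[s]]
    lead_d <- if (cfg$onset_family == "exponential")
      stats::rexp(n, rate = log(2) / m)
    else stats::rlnorm(n, meanlog = log(m), sdlog = cfg$onset_sdlog)
    onset_h <- pmax(0, span_h - lead_d * 24)  # clip into the observed span
    onset_h[!occurs] <- Inf
    o[[s]] <- as.numeric(time_h >= onset_h[pat_row])
  }
  # vitals: baseline + linear terminal ramp over the final ramp_h + noise
  vm <- cfg$vitals
  h_before <- t_death - time_h
  ramp <- ifelse(died[pat_row], pmax(0, 1 - h_before / vm$ramp_h), 0)
  for (v in .vitals_cols()) {
    par <- vm[[v]]
    base <- stats::rnorm(n, par$base_mean, par$base_sd)
    val <- base[pat_row] + par$change * ramp +
      stats::rnorm(length(pat_row), 0, par$noise_sd)
    if (v == "sbp") val <- pmax(val, 40)
    if (v == "dbp") val <- pmax(val, 20)
    if (v == "hr") val <- pmax(val, 20)
    if (v == "rr") val <- pmax(val, 4)
    if (v == "spo2") val <- pmin(pmax(val, 40), 100)
    o[[v]] <- round(val, 1)
  }
  cohort(p, o)
}

#' Calibration report for a generated cohort
#'
#' Compares the empirical per-sign occurrence fraction (among decedents) and
#' the empirical median observed onset lead with the configured targets.
#' Occurrence tolerance is `max(0.02, 3 * sqrt(pi (1 - pi) / n))`; onset
#' tolerance is half an observation interval (grid discretisation) plus an
#' order-statistic allowance `max(0.5, 3 * median / sqrt(n_events))` days.
#'
#' @param x A cohort generated from `cfg`.
#' @param cfg The [generator_config()] that produced it.
#' @return Data frame: `sign`, `target_occurrence`, `empirical_occurrence`,
#'   `occurrence_ok`, `target_median_days`, `empirical_median_days`,
#'   `onset_ok` (NA where no events).
#' @export
calibration_report <- function(x, cfg) {
  xd <- decedents(x, warn = FALSE)
  n <- nrow(xd$patients)
  L <- if (n) lead_matrix(xd) else NULL
  rows <- lapply(sign_ids(), function(s) {
    pi_s <- cfg$occurrence[[s]]
    leads <- if (n) ifelse(is.finite(L[, s]), L[, s] / 24, NA_real_)
             else numeric(0)
    emp_occ <- if (n) mean(!is.na(leads)) else NA_real_
    tol_occ <- max(0.02, 3 * sqrt(pi_s * (1 - pi_s) / max(n, 1)))
    n_ev <- sum(!is.na(leads))
    m_s <- cfg$onset_median_days[[s]]
    emp_med <- if (n_ev) stats::median(leads, na.rm = TRUE) else NA_real_
    tol_med <- cfg$interval_h / 48 + max(0.5, 3 * m_s / sqrt(max(n_ev, 1)))
    data.frame(sign = s,
               target_occurrence = pi_s, empirical_occurrence = emp_occ,
               occurrence_ok = !is.na(emp_occ) && abs(emp_occ - pi_s) <= tol_occ,
               target_median_days = if (pi_s > 0) m_s else NA_real_,
               empirical_median_days = emp_med,
               onset_ok = if (pi_s == 0) NA
                          else n_ev > 0 && abs(emp_med - m_s) <= tol_med,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
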