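# Independent oracles and small cohort builders for the test suite. The
# oracles work directly on the raw data frames with explicit per-patient
# loops, deliberately sharing no code with the package's vectorised paths.

# first time a flag column is 1 (NA skipped) for one patient
oracle_first_event <- function(x, pid, sign) {
  o <- x$observations
  rows <- o[o$patient_id == pid, , drop = FALSE]
  best <- NA_real_
  for (i in seq_len(nrow(rows))) {
    v <- rows[[sign]][i]
    if (!is.na(v) && v == 1 && (is.na(best) || rows$time_h[i] < best))
      best <- rows$time_h[i]
  }
  best
}

oracle_si_event <- function(x, pid, threshold = 1.0) {
  o <- x$observations
  rows <- o[o$patient_id == pid, , drop = FALSE]
  best <- NA_real_
  for (i in seq_len(nrow(rows))) {
    hr <- rows$hr[i]; sbp <- rows$sbp[i]
    if (!is.na(hr) && !is.na(sbp) && hr / sbp > threshold &&
        (is.na(best) || rows$time_h[i] < best))
      best <- rows$time_h[i]
  }
  best
}

oracle_event <- function(x, pid, pred) {
  if (pred == "si_gt1") oracle_si_event(x, pid) else oracle_first_event(x, pid, pred)
}

# per-patient enumeration of the OR-rule prediction probability
oracle_prob <- function(x, subset, horizon_h) {
  p <- x$patients[x$patients$terminal_status == "died", , drop = FALSE]
  succ <- 0L
  for (i in seq_len(nrow(p))) {
    pid <- p$patient_id[i]
    times <- numeric(0)
    for (s in subset) {
      te <- oracle_event(x, pid, s)
      if (!is.na(te)) times <- c(times, te)
    }
    if (length(times) && (p$terminal_h[i] - min(times)) <= horizon_h)
      succ <- succ + 1L
  }
  succ / nrow(p)
}

# per-patient event-time matrix by naive scanning (decedents only)
oracle_event_matrix <- function(x) {
  p <- x$patients[x$patients$terminal_status == "died", , drop = FALSE]
  ids <- sidmodels::predictor_ids()
  ev <- matrix(NA_real_, nrow(p), length(ids), dimnames = list(NULL, ids))
  for (i in seq_len(nrow(p)))
    for (s in ids) ev[i, s] <- oracle_event(x, p$patient_id[i], s)
  ev
}

# naive exhaustive enumerator; first lexicographic argmax over catalog order
oracle_best_subset <- function(x, m, horizon_h, ev = oracle_event_matrix(x)) {
  p <- x$patients[x$patients$terminal_status == "died", , drop = FALSE]
  ids <- sidmodels::predictor_ids()
  combos <- utils::combn(length(ids), m)
  best_p <- -1; best_sub <- NULL
  for (cidx in seq_len(ncol(combos))) {
    sub <- combos[, cidx]
    succ <- 0L
    for (i in seq_len(nrow(p))) {
      times <- ev[i, sub]
      times <- times[!is.na(times)]
      if (length(times) && (p$terminal_h[i] - min(times)) <= horizon_h)
        succ <- succ + 1L
    }
    pr <- succ / nrow(p)
    if (pr > best_p) { best_p <- pr; best_sub <- ids[sub] }
  }
  list(subset = best_sub, prob = best_p)
}

# small random cohort on the 12-h grid, with some missing flags and vitals
random_cohort <- function(n, seed) {
  cfg <- sidmodels::generator_config(
    n_patients = n, seed = seed,
    span_mean_days = 6, span_sd_days = 4, span_min_days = 1)
  x <- sidmodels::generate_cohort(cfg)
  # punch holes: absent flags -> missing, some vitals dropped (seeded)
  o <- x$observations
  set.seed(seed + 10000)
  for (s in sidmodels::sign_ids()) {
    zero <- which(!is.na(o[[s]]) & o[[s]] == 0)
    if (length(zero))
      o[[s]][sample(zero, floor(length(zero) * 0.1))] <- NA
  }
  drop <- sample(nrow(o), floor(nrow(o) * 0.1))
  o$hr[drop] <- NA
  x$observations <- o
  sidmodels::validate_cohort(x)
  x
}

# hand-laid four-patient cohort used for brute-force rule checks:
# patient A: verbal onset 12 h before death (death 96 h)
# patient B: pulseless onset 84 h before death, SI > 1 at 24 h before death
# patient C: no events at all
# patient D: verbal onset exactly 72 h before death (boundary)
toy_cohort <- function() {
  mk_obs <- function(pid, times, death) {
    o <- data.frame(patient_id = pid, time_h = times, stringsAsFactors = FALSE)
    for (s in sidmodels::sign_ids()) o[[s]] <- 0
    for (v in c("sbp", "dbp", "hr", "temp", "rr", "spo2")) o[[v]] <- NA_real_
    o
  }
  death <- c(A = 96, B = 120, C = 48, D = 96)
  p <- data.frame(patient_id = names(death), age = 80, sex = "female",
                  diagnosis = "other", charlson = 2, obs_start_h = 0,
                  terminal_h = unname(death), terminal_status = "died",
                  censor_reason = NA_character_, stringsAsFactors = FALSE)
  obs <- do.call(rbind, lapply(names(death), function(pid)
    mk_obs(pid, seq(0, death[[pid]], by = 12), death[[pid]])))
  set1 <- function(obs, pid, sign, from) {
    sel <- obs$patient_id == pid & obs$time_h >= from
    obs[[sign]][sel] <- 1
    obs
  }
  obs <- set1(obs, "A", "resp_verbal_decreased", 96 - 12)
  obs <- set1(obs, "B", "pulseless_radial", 120 - 84)  # 36 h, on the grid
  obs <- set1(obs, "D", "resp_verbal_decreased", 96 - 72)
  # B: SI crosses 1.0 at 24 h before death (96 h)
  bsel <- obs$patient_id == "B"
  obs$hr[bsel] <- 80; obs$sbp[bsel] <- 100
  obs$hr[bsel & obs$time_h >= 96] <- 110
  sidmodels::cohort(p, obs)
}
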