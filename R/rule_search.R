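# OR-rule prediction probability, exhaustive best-subset search and 10-fold
# cross-validation. The rule fires at the earliest first-event time among the
# chosen predictors; a decedent counts as a success when the rule fires and
# death follows within the horizon (inclusive).

#' Per-patient lead-time matrix
#'
#' For every decedent and every catalog predictor, the lead time
#' `death time - first event time` in hours, or `-Inf` when the predictor
#' never occurs. The OR-rule event time is the *minimum* member event time,
#' i.e. the *maximum* member lead, so all rule evaluations reduce to row-wise
#' maxima over columns of this matrix.
#'
#' @param x A `sid_cohort`; censored patients are excluded with a warning.
#' @return Numeric matrix, decedents x 12 predictors, with patient ids as row
#'   names and predictor ids as column names.
#' @export
lead_matrix <- function(x) {
  x <- decedents(x)
  p <- x$patients
  o <- x$observations
  ids <- predictor_ids()
  L <- matrix(-Inf, nrow = nrow(p), ncol = length(ids),
              dimnames = list(p$patient_id, ids))
  pid_f <- factor(o$patient_id, levels = p$patient_id)
  t_death <- p$terminal_h
  for (s in ids) {
    hit <- if (s == "si_gt1") {
      !is.na(o$hr) & !is.na(o$sbp) & o$hr / o$sbp > 1.0
    } else {
      !is.na(o[[s]]) & o[[s]] == 1
    }
    if (!any(hit)) next
    first <- tapply(o$time_h[hit], pid_f[hit], min)  # NA for event-free levels
    first <- first[!is.na(first)]
    j <- match(names(first), p$patient_id)
    L[j, s] <- t_death[j] - as.numeric(first)
  }
  L
}

#' OR-rule event time for one patient
#'
#' The earliest first-event time among the subset's member predictors;
#' members that never occur are ignored.
#'
#' @param x A `sid_cohort`.
#' @param patient_id Patient identifier.
#' @param subset Character vector of predictor ids (non-empty, no
#'   duplicates).
#' @return Time in hours, or `NA_real_` if no member ever occurs.
#' @export
rule_event_time <- function(x, patient_id, subset) {
  .check_subset(subset)
  times <- vapply(subset, function(s) .any_event_time(x, patient_id, s),
                  numeric(1))
  if (all(is.na(times))) return(NA_real_)
  min(times, na.rm = TRUE)
}

.check_subset <- function(subset) {
  if (length(subset) < 1L) stop("subset must be non-empty", call. = FALSE)
  if (anyDuplicated(subset)) stop("subset contains duplicates", call. = FALSE)
  .predictor_index(subset)
  invisible(subset)
}

# internal: success probability of subset columns `idx` of lead matrix L
# at horizon h (hours); returns the per-patient success vector attribute-free
.subset_success <- function(L, idx, h) {
  m <- L[, idx[1L]]
  for (j in idx[-1L]) m <- pmax(m, L[, j])
  is.finite(m) & m <= h
}

#' Prediction probability of an OR-rule subset
#'
#' The proportion of decedents for whom the rule fires before death *and*
#' death follows within the horizon of the rule event (inclusive at the
#' boundary). Patients for whom no member predictor ever occurs, or whose
#' rule event precedes death by more than the horizon, are failures; the
#' denominator is all decedents.
#'
#' @param x A `sid_cohort` or a precomputed [lead_matrix()].
#' @param subset Character vector of predictor ids.
#' @param horizon A [horizon()], label, or hours.
#' @return A list with `subset`, `horizon_h`, `prob_raw`, `successes`, `n`,
#'   and the per-patient logical `outcome`.
#' @export
prediction_probability <- function(x, subset, horizon) {
  .check_subset(subset)
  h <- .horizon_hours(horizon)
  L <- if (is.matrix(x)) x else lead_matrix(x)
  if (nrow(L) == 0L) stop("empty cohort", call. = FALSE)
  succ <- .subset_success(L, match(subset, colnames(L)), h)
  list(subset = subset, horizon_h = h, prob_raw = mean(succ),
       successes = sum(succ), n = length(succ), outcome = succ)
}

#' Exhaustive best-subset search
#'
#' Evaluates the prediction probability of every one of the `choose(12, m)`
#' subsets of size `m` and returns an argmax. Ties are broken
#' deterministically in favour of the lexicographically smallest catalog
#' index sequence; all tied optima are returned in `ties`.
#'
#' @param x A `sid_cohort` or a precomputed [lead_matrix()].
#' @param m Subset size, 1..12.
#' @param horizon A [horizon()], label, or hours.
#' @return A list with `subset` (character ids), `prob_raw`, `m`,
#'   `horizon_h`, `n`, and `ties` (list of all subsets attaining the
#'   optimum).
#' @export
best_subset <- function(x, m, horizon) {
  if (!(is.numeric(m) && length(m) == 1L && m >= 1 && m <= 12 && m == round(m)))
    stop("m must be an integer in 1..12", call. = FALSE)
  h <- .horizon_hours(horizon)
  L <- if (is.matrix(x)) x else lead_matrix(x)
  if (nrow(L) == 0L) stop("empty cohort", call. = FALSE)
  combos <- utils::combn(ncol(L), m)
  probs <- apply(combos, 2L, function(idx) mean(.subset_success(L, idx, h)))
  best <- max(probs)
  tie_i <- which(probs == best)
  ids <- colnames(L)
  list(subset = ids[combos[, tie_i[1L]]],  # combn order is lexicographic
       prob_raw = best, m = m, horizon_h = h, n = nrow(L),
       ties = lapply(tie_i, function(i) ids[combos[, i]]))
}

# internal: run `expr` under `seed` without clobbering the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!(is.numeric(seed) && length(seed) == 1L && is.finite(seed)))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Cross-validated prediction probability
#'
#' K-fold cross-validation of the best size-`m` OR-rule: patients are
#' randomly partitioned into `k` folds of as-equal-as-possible size; for each
#' fold the exhaustive search is re-run on the other `k - 1` folds
#' (`reselect = TRUE`, default) and the winning subset is scored on the
#' held-out fold. The cross-validated probability pools held-out successes
#' over all folds (micro-average); the fold-mean macro-average is also
#' reported. With `reselect = FALSE` the full-data best subset is scored on
#' each held-out fold instead.
#'
#' @param x A `sid_cohort` or a precomputed [lead_matrix()].
#' @param m Subset size, 1..12.
#' @param horizon A [horizon()], label, or hours.
#' @param k Number of folds (default 10); cohort must have at least `k`
#'   decedents.
#' @param seed Integer seed for the fold assignment (mandatory; echoed in the
#'   result).
#' @param reselect Re-run the subset search inside each training split
#'   (default `TRUE`).
#' @return A list with `m`, `horizon_h`, `k`, `seed`, `prob_10fcv` (pooled),
#'   `prob_foldmean`, and per-fold details (`subset`, `successes`, `n`).
#' @export
cv_probability <- function(x, m, horizon, k = 10, seed, reselect = TRUE) {
  if (missing(seed)) stop("seed is required for cross-validation", call. = FALSE)
  h <- .horizon_hours(horizon)
  L <- if (is.matrix(x)) x else lead_matrix(x)
  n <- nrow(L)
  if (n < k) stop("cohort smaller than the number of folds", call. = FALSE)
  fold <- .with_seed(seed, {
    # uniform random permutation, then round-robin fold labels -> sizes differ
    # by at most one
    lab <- rep(seq_len(k), length.out = n)
    lab[order(sample.int(n))]
  })
  full_best <- if (!reselect) best_subset(L, m, h) else NULL
  folds <- lapply(seq_len(k), function(f) {
    test <- which(fold == f)
    train <- which(fold != f)
    sub <- if (reselect) best_subset(L[train, , drop = FALSE], m, h)$subset
           else full_best$subset
    succ <- .subset_success(L[test, , drop = FALSE],
                            match(sub, colnames(L)), h)
    list(subset = sub, successes = sum(succ), n = length(succ))
  })
  pooled_s <- sum(vapply(folds, `[[`, numeric(1), "successes"))
  pooled_n <- sum(vapply(folds, `[[`, numeric(1), "n"))
  fm <- vapply(folds, function(f) if (f$n) f$successes / f$n else NA_real_,
               numeric(1))
  list(m = m, horizon_h = h, k = k, seed = seed, reselect = reselect,
       prob_10fcv = pooled_s / pooled_n,
       prob_foldmean = mean(fm, na.rm = TRUE),
       folds = folds)
}

#' Model table across subset sizes
#'
#' For each `m`, runs the exhaustive search and the k-fold cross-validation
#' at one horizon and assembles the published model-table layout: one row per
#' `m`, one 0/1 membership indicator column per catalog predictor (in catalog
#' order regardless of subset content), and raw / cross-validated
#' probabilities as percentages.
#'
#' @param x A `sid_cohort` or a precomputed [lead_matrix()].
#' @param horizon A [horizon()], label, or hours.
#' @param m_values Subset sizes (default 1:12).
#' @param k Folds for cross-validation (default 10).
#' @param seed Integer seed (mandatory).
#' @return A data frame with columns `horizon`, `m`, the 12 indicator
#'   columns, `prob_raw_pct`, `prob_10fcv_pct`, `seed`, `k`.
#' @export
model_table <- function(x, horizon, m_values = 1:12, k = 10, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  h <- .horizon_hours(horizon)
  hlab <- if (inherits(horizon, "sid_horizon")) horizon$label
          else if (is.character(horizon)) horizon else paste0(h, "h")
  L <- if (is.matrix(x)) x else lead_matrix(x)
  ids <- predictor_ids()
  rows <- lapply(m_values, function(m) {
    bs <- best_subset(L, m, h)
    cv <- cv_probability(L, m, h, k = k, seed = seed)
    ind <- as.integer(ids %in% bs$subset)
    row <- data.frame(horizon = hlab, m = m, stringsAsFactors = FALSE)
    for (j in seq_along(ids)) row[[ids[j]]] <- ind[j]
    row$prob_raw_pct <- 100 * bs$prob_raw
    row$prob_10fcv_pct <- 100 * cv$prob_10fcv
    row$seed <- seed
    row$k <- k
    row
  })
  do.call(rbind, rows)
}
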