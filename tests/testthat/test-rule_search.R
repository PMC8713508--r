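test_that("rule_event_time is the minimum member event, reducing to first_event_time", {
  x <- toy_cohort()
  # B: pulseless at 36 h, SI event at 96 h -> rule fires at 36 h
  expect_equal(rule_event_time(x, "B", c("pulseless_radial", "si_gt1")), 36)
  # no member event -> NA
  expect_true(is.na(rule_event_time(x, "C", c("death_rattle", "apnea"))))
  # singleton reduction
  expect_equal(rule_event_time(x, "A", "resp_verbal_decreased"),
               first_event_time(x, "A", "resp_verbal_decreased"))
  expect_error(rule_event_time(x, "A", character(0)), "non-empty")
  expect_error(rule_event_time(x, "A", c("apnea", "apnea")), "duplicates")
  expect_error(rule_event_time(x, "A", "bogus"), "unknown predictor")
})

test_that("prediction_probability matches per-patient enumeration on the toy cohort", {
  x <- toy_cohort()
  # hand enumeration: A verbal lead 12 h, D verbal lead 72 h, B SI lead 24 h,
  # B pulseless lead 84 h, C nothing
  expect_equal(prediction_probability(x, "resp_verbal_decreased", "7d")$prob_raw, 2 / 4)
  expect_equal(prediction_probability(x, "resp_verbal_decreased", "72h")$prob_raw, 2 / 4)
  expect_equal(prediction_probability(x, "resp_verbal_decreased", "24h")$prob_raw, 1 / 4)
  expect_equal(prediction_probability(x, "si_gt1", "72h")$prob_raw, 1 / 4)
  # OR with an early long-lead member pushes the rule event outside 72 h
  expect_equal(prediction_probability(x, c("pulseless_radial", "si_gt1"),
                                      "72h")$prob_raw, 0)
  expect_equal(prediction_probability(x, c("resp_verbal_decreased", "si_gt1"),
                                      "72h")$prob_raw, 3 / 4)
  # boundary: event exactly horizon hours before death is a success
  expect_equal(prediction_probability(x, "resp_verbal_decreased", 72)$prob_raw,
               prediction_probability(x, "resp_verbal_decreased", 72.0001)$prob_raw)
  # no member ever occurs -> 0
  expect_equal(prediction_probability(x, "apnea", "7d")$prob_raw, 0)
  # oracle equality on the toy for assorted subsets
  for (sub in list("pulseless_radial", c("resp_verbal_decreased", "pulseless_radial"),
                   c("resp_verbal_decreased", "pulseless_radial", "si_gt1"))) {
    for (h in c(168, 72, 24)) {
      expect_equal(prediction_probability(x, sub, h)$prob_raw,
                   oracle_prob(x, sub, h))
    }
  }
})

test_that("prediction probability never exceeds the any-event fraction", {
  for (seed in c(2, 6)) {
    x <- random_cohort(20, seed)
    L <- lead_matrix(x)
    set.seed(seed)
    for (rep in 1:10) {
      m <- sample(1:4, 1)
      sub <- sample(predictor_ids(), m)
      res <- prediction_probability(L, sub, "72h")
      any_event <- mean(apply(is.finite(L[, sub, drop = FALSE]), 1, any))
      expect_lte(res$prob_raw, any_event)
    }
  }
})

test_that("best_subset is an exhaustive argmax with deterministic ties", {
  x <- toy_cohort()
  # m = 12: single candidate, the full catalog
  full <- best_subset(x, 12, "7d")
  expect_equal(sort(full$subset), sort(predictor_ids()))
  expect_equal(full$prob_raw, prediction_probability(x, predictor_ids(), "7d")$prob_raw)
  expect_error(best_subset(x, 0, "7d"), "1..12")
  expect_error(best_subset(x, 13, "7d"), "1..12")

  # a planted perfect predictor is selected at m = 1
  p <- do.call(rbind, lapply(1:8, function(i) one_patient_table(paste0("q", i), 96)))
  o <- do.call(rbind, lapply(1:8, function(i)
    obs_with_flags(paste0("q", i), seq(0, 96, 12),
                   pulseless_radial = as.numeric(seq(0, 96, 12) >= 84))))
  xp <- cohort(p, o)
  b1 <- best_subset(xp, 1, "72h")
  expect_equal(b1$subset, "pulseless_radial")
  expect_equal(b1$prob_raw, 1.0)

  # tie-breaking: lexicographically smallest catalog index sequence, with all
  # tied optima retrievable
  bt <- best_subset(xp, 2, "72h")
  expect_equal(bt$prob_raw, 1.0)
  expect_equal(bt$subset, c("resp_verbal_decreased", "pulseless_radial"))
  expect_gt(length(bt$ties), 1)
  expect_true(all(vapply(bt$ties, function(s) "pulseless_radial" %in% s ||
                           isTRUE(all.equal(prediction_probability(xp, s, "72h")$prob_raw, 1)),
                         logical(1))))
})

test_that("best_subset equals the naive enumerator on random cohorts", {
  for (seed in c(11, 23, 37)) {
    x <- random_cohort(15, seed)
    for (m in 1:3) {
      bs <- best_subset(x, m, "72h")
      orc <- oracle_best_subset(x, m, 72)
      expect_equal(bs$prob_raw, orc$prob, info = paste(seed, m))
      expect_equal(bs$subset, orc$subset, info = paste(seed, m))
    }
  }
})

test_that("cv_probability: determinism, fold structure, leave-one-out", {
  x <- random_cohort(30, 4)
  L <- lead_matrix(x)
  cv1 <- cv_probability(L, 2, "72h", k = 10, seed = 99)
  cv2 <- cv_probability(L, 2, "72h", k = 10, seed = 99)
  expect_identical(cv1, cv2)
  # folds partition the cohort into near-equal parts
  sizes <- vapply(cv1$folds, `[[`, numeric(1), "n")
  expect_equal(sum(sizes), nrow(L))
  expect_lte(diff(range(sizes)), 1)
  # pooled aggregation identity
  expect_equal(cv1$prob_10fcv,
               sum(vapply(cv1$folds, `[[`, numeric(1), "successes")) / nrow(L))
  expect_error(cv_probability(L, 2, "72h", k = 40, seed = 1), "smaller")
  expect_error(cv_probability(L, 2, "72h", k = 10), "seed")

  # seed is required and echoed
  expect_equal(cv1$seed, 99)

  # n identical patients: held-out performance equals full-data prob_raw
  p <- do.call(rbind, lapply(1:10, function(i) one_patient_table(paste0("s", i), 60)))
  o <- do.call(rbind, lapply(1:10, function(i)
    obs_with_flags(paste0("s", i), seq(0, 60, 12),
                   death_rattle = as.numeric(seq(0, 60, 12) >= 36))))
  xid <- cohort(p, o)
  cvi <- cv_probability(xid, 1, "72h", k = 10, seed = 5)
  expect_equal(cvi$prob_10fcv, best_subset(xid, 1, "72h")$prob_raw)

  # leave-one-out on the identical cohort: every fold holds out one success
  expect_true(all(vapply(cvi$folds, `[[`, numeric(1), "n") == 1))
  expect_true(all(vapply(cvi$folds, `[[`, numeric(1), "successes") == 1))

  # leave-one-out against hand enumeration on a mixed hand-laid cohort:
  # 6 patients with a 12-h-lead rattle event, 4 with none
  p2 <- do.call(rbind, lapply(1:10, function(i) one_patient_table(paste0("u", i), 48)))
  o2 <- do.call(rbind, lapply(1:10, function(i) {
    times <- seq(0, 48, 12)
    obs_with_flags(paste0("u", i), times,
                   death_rattle = if (i <= 6) as.numeric(times >= 36) else 0)
  }))
  xm <- cohort(p2, o2)
  cvm <- cv_probability(xm, 1, "72h", k = 10, seed = 3)
  # in every training split of 9, death_rattle (6 or 5 successes) beats all
  # other predictors (0 successes; ties broken away only by lex order, and
  # death_rattle is the only non-zero column) -> held-out success iff the
  # held-out patient has the event: pooled 6/10
  expect_equal(cvm$prob_10fcv, 6 / 10)
  # fixed-subset variant scores the full-data best subset on every fold
  cvf <- cv_probability(xm, 1, "72h", k = 10, seed = 3, reselect = FALSE)
  expect_equal(cvf$prob_10fcv, 6 / 10)
})

test_that("model_table composes search and CV in the published layout", {
  x <- random_cohort(20, 8)
  L <- lead_matrix(x)
  tab <- model_table(L, horizon("72h"), m_values = 1:4, k = 5, seed = 17)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$m, 1:4)
  # indicator columns appear in catalog order regardless of subset content
  expect_equal(names(tab)[3:14], predictor_ids())
  expect_equal(rowSums(tab[, predictor_ids()]), 1:4, ignore_attr = TRUE)
  # rows equal per-m calls
  for (m in 1:4) {
    bs <- best_subset(L, m, "72h")
    cv <- cv_probability(L, m, "72h", k = 5, seed = 17)
    expect_equal(tab$prob_raw_pct[m], 100 * bs$prob_raw)
    expect_equal(tab$prob_10fcv_pct[m], 100 * cv$prob_10fcv)
    expect_equal(as.integer(tab[m, predictor_ids()]),
                 as.integer(predictor_ids() %in% bs$subset))
  }
  expect_equal(unique(tab$seed), 17)
  expect_error(model_table(L, "72h", m_values = 1:2, k = 5), "seed")
})
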