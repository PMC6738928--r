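test_that("summarize_scores computes mean and high-score fraction", {
  s <- summarize_scores(rep(4L, 9))
  expect_equal(s$mean_score, 4)
  expect_equal(s$frac_high, 1)
  expect_equal(s$n, 9)

  s <- summarize_scores(c(5, 5, 5, 5, 4, 4, 4, 3, 3))
  expect_equal(s$mean_score, 38 / 9)  # hand arithmetic: sum 38 over 9 panellists
  expect_equal(s$frac_high, 7 / 9)

  s <- summarize_scores(rep(1L, 9))
  expect_equal(s$mean_score, 1)
  expect_equal(s$frac_high, 0)
})

test_that("summarize_scores rejects invalid input", {
  expect_error(summarize_scores(integer(0)), "empty")
  expect_error(summarize_scores(c(4, 6)), "1-5")
  expect_error(summarize_scores(c(4, 0)), "1-5")
  expect_error(summarize_scores(c(4, 3.5)), "1-5")
  expect_error(summarize_scores(c(4, NA)), "NA")
})

test_that("classify_aspect applies the agreement bands, acceptable first", {
  expect_equal(classify_aspect(list(mean_score = 4.44, frac_high = 1, n = 9)),
               "acceptable")
  expect_equal(classify_aspect(list(mean_score = 3.5, frac_high = 6 / 9, n = 9)),
               "moderate")
  expect_equal(classify_aspect(list(mean_score = 2, frac_high = 0, n = 9)),
               "unacceptable")
  # high mean but insufficient consensus falls into the moderate band
  expect_equal(classify_aspect(list(mean_score = 4.2, frac_high = 0.7, n = 9)),
               "moderate")
  # band boundaries are inclusive
  expect_equal(classify_aspect(list(mean_score = 4, frac_high = 0.8, n = 9)),
               "acceptable")
  expect_equal(classify_aspect(list(mean_score = 3, frac_high = 0.6, n = 9)),
               "moderate")
})

test_that("health-event and attribute decision rules follow the round logic", {
  expect_equal(classify_health_event("acceptable", "acceptable"), "included")
  expect_equal(classify_health_event("moderate", "acceptable"), "round3")
  expect_equal(classify_health_event("acceptable", "moderate"), "round3")
  expect_equal(classify_health_event("moderate", "moderate"), "round3")
  expect_equal(classify_health_event("unacceptable", "acceptable"), "rejected")
  expect_equal(classify_health_event("moderate", "unacceptable"), "rejected")
  expect_error(classify_health_event("acceptable", "fine"), "must be one of")

  expect_equal(classify_attribute("acceptable"), "included")
  expect_equal(classify_attribute("moderate"), "round3")
  expect_equal(classify_attribute("unacceptable"), "rejected")
})

test_that("round 3 re-classification includes only newly-acceptable choices", {
  prior <- classify_choice("delirium", "health_event",
                           strength_scores = scores_moderate,
                           impact_scores = scores_acceptable)
  expect_equal(prior$decision, "round3")
  upgraded <- apply_round3(prior, scores_acceptable, scores_acceptable)
  expect_equal(upgraded$round3_final, "included")
  expect_equal(final_decision(upgraded), "included")

  stuck <- apply_round3(prior, scores_moderate, scores_acceptable)
  expect_equal(stuck$round3_final, "rejected")

  # unchanged moderate scores stay moderate, hence rejected
  attr_prior <- classify_choice("smoking_status", "patient_attribute",
                                strength_scores = scores_moderate)
  expect_equal(apply_round3(attr_prior, scores_moderate)$round3_final, "rejected")

  included <- classify_choice("hip_fracture", "health_event",
                              scores_acceptable, scores_acceptable)
  expect_error(apply_round3(included, scores_acceptable, scores_acceptable),
               "not fed back")
})

test_that("classify_choice validates the aspect/kind contract", {
  expect_error(classify_choice("x", "health_event", scores_acceptable),
               "require impact scores")
  expect_error(classify_choice("x", "patient_attribute", scores_acceptable,
                               scores_acceptable), "single aspect")
})

test_that("full response-table workflow reproduces the round outcomes", {
  responses <- make_responses(
    list(name = "hip_fracture", kind = "health_event",
         scores = list(strength_r1 = scores_acceptable,
                       impact_r2 = scores_acceptable)),
    list(name = "delirium", kind = "health_event",
         scores = list(strength_r1 = scores_moderate,
                       impact_r2 = scores_acceptable,
                       strength_r3 = scores_acceptable)),
    list(name = "incontinence", kind = "health_event",
         scores = list(strength_r1 = scores_moderate,
                       impact_r2 = scores_moderate,
                       strength_r3 = scores_moderate,
                       impact_r3 = scores_moderate)),
    list(name = "heart_failure", kind = "health_event",
         scores = list(strength_r1 = scores_unacceptable,
                       impact_r2 = scores_acceptable)),
    list(name = "age", kind = "patient_attribute",
         scores = list(strength_r1 = scores_acceptable)),
    list(name = "depression", kind = "patient_attribute",
         scores = list(strength_r1 = scores_moderate,
                       strength_r3 = scores_acceptable)),
    list(name = "smoking_status", kind = "patient_attribute",
         scores = list(strength_r1 = scores_moderate,
                       strength_r3 = scores_moderate)))
  report <- classify_delphi_responses(responses)
  final <- setNames(report$final, report$choice_name)
  expect_equal(final[["hip_fracture"]], "included")
  expect_equal(final[["delirium"]], "included")      # upgraded in round 3
  expect_equal(final[["incontinence"]], "rejected")  # stayed moderate
  expect_equal(final[["heart_failure"]], "rejected") # unacceptable strength
  expect_equal(final[["age"]], "included")
  expect_equal(final[["depression"]], "included")
  expect_equal(final[["smoking_status"]], "rejected")
  # round-3 aspect not re-scored (impact of delirium) reuses earlier scores
  expect_equal(report$impact_level[report$choice_name == "delirium"], "acceptable")
})

test_that("every score vector maps to exactly one band (exhaustive, 5 panellists)", {
  enum <- enumerate_score_vectors(5)
  expect_equal(sum(enum$n_vectors), 5^5)
  expect_true(all(enum$level %in% c("acceptable", "moderate", "unacceptable")))
  # the classifier's guarantees, by brute force
  acc <- enum[enum$level == "acceptable", ]
  mod <- enum[enum$level == "moderate", ]
  expect_true(all(acc$frac_high >= 0.8 & acc$mean_score >= 4))
  expect_true(all(mod$frac_high >= 0.6 & mod$mean_score >= 3))
})

test_that("degenerate thresholds make everything acceptable", {
  lax <- delphi_thresholds(acceptable_mean = 1, acceptable_frac = 0)
  enum <- enumerate_score_vectors(5, lax)
  expect_true(all(enum$level == "acceptable"))
})

test_that("raising a single score never downgrades the classification", {
  rank <- c(unacceptable = 1, moderate = 2, acceptable = 3)
  set.seed(42)
  for (rep in 1:200) {
    v <- sample(1:5, 9, replace = TRUE)
    lv <- rank[[classify_aspect(v)]]
    i <- sample(9, 1)
    if (v[i] < 5) {
      v[i] <- v[i] + 1L
      expect_gte(rank[[classify_aspect(v)]], lv)
    }
  }
})
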