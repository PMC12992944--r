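# The department rule set: itemized scores, markup, recommendations.

test_that("bundled case series reproduces the factor-list-derived scores", {
  cases <- vte_example_cases()
  sc <- score_cohort(cases)
  computed <- sc$scores$final_score

  # expected scores derived from each case's tabulated factor list; the
  # protocol-period case 5 prints a total (1) that contradicts its own
  # factor list (age 40 + BMI 28 -> 2), so the factor list wins there
  expected <- cases$reported_score
  expected[cases$period == "protocol" & cases$case_id == 5] <- 2L
  expect_identical(computed, as.integer(expected))

  # 15 of 16 printed totals agree; the one disagreement is that case
  agree <- computed == cases$reported_score
  expect_identical(sum(agree), 15L)
  expect_false(agree[cases$period == "protocol" & cases$case_id == 5])

  # hand-count of high-tier cases across the series
  expect_identical(sum(computed >= 3), 8L)
})

test_that("single-profile scoring itemizes components that sum to the total", {
  s <- compute_vte_score(risk_profile(age = 45, bmi = 31,
                                      cs_urgency = "elective"))
  expect_s3_class(s, "vte_score")
  expect_identical(s$final_score, 3L)
  expect_setequal(s$components$factor, c("age_40", "bmi_30"))
  expect_identical(sum(s$components$points), s$final_score)
  expect_identical(s$risk_tier, "high")

  s0 <- compute_vte_score(base_profile())
  expect_identical(s0$final_score, 0L)
  expect_identical(nrow(s0$components), 0L)
  expect_identical(s0$risk_tier, "low")
})

test_that("scoring cutoffs fall on the inclusive side stated by the protocol", {
  score_of <- function(...) compute_vte_score(base_profile(...))$final_score
  expect_identical(score_of(age = 40), 1L)
  expect_identical(score_of(age = 39.9), 0L)
  expect_identical(score_of(bmi = 25), 1L)
  expect_identical(score_of(bmi = 24.9), 0L)
  expect_identical(score_of(bmi = 30), 2L)   # obese band replaces overweight
  expect_identical(score_of(bmi = 29.9), 1L)
  expect_identical(score_of(parity = 3), 1L)
  expect_identical(score_of(gestational_age_at_delivery = 33.9), 1L)
  expect_identical(score_of(gestational_age_at_delivery = 34), 0L)
  expect_identical(score_of(pph_ml = 1000), 1L)
  expect_identical(score_of(pph_ml = 999), 0L)
  expect_identical(score_of(transfusion = TRUE), 1L)
})

test_that("BMI components are mutually exclusive", {
  for (bmi in c(18, 24.9, 25, 27, 29.9, 30, 35, 44)) {
    s <- compute_vte_score(base_profile(bmi = bmi))
    bmi_pts <- sum(s$components$points[grepl("^bmi", s$components$factor)])
    expect_lte(sum(grepl("^bmi", s$components$factor)), 1)
    expect_true(bmi_pts %in% 0:2)
  }
})

test_that("markup raises the final score but not the intraoperative cuff", {
  p <- risk_profile(age = 30, bmi = 27, cs_urgency = "emergency",
                    gestational_age_at_delivery = 39)
  s <- compute_vte_score(p, markup = "defer")
  expect_identical(s$pre_op_score, 1L)
  expect_false(s$markup_applied)

  s2 <- apply_postpartum_markup(s, pph_ml = 1200)
  expect_identical(s2$final_score, 2L)
  expect_identical(s2$risk_tier, "moderate")
  expect_false(s2$mechanical_during_op)   # not retroactive

  s3 <- apply_postpartum_markup(s, pph_ml = 400)
  expect_identical(s3$final_score, 1L)

  # transfusion alone triggers it
  s4 <- apply_postpartum_markup(s, pph_ml = 0, transfusion = TRUE)
  expect_identical(s4$final_score, 2L)

  expect_error(apply_postpartum_markup(s2, 500), "already applied")
  expect_error(apply_postpartum_markup(s, -5), "non-negative")
})

test_that("deferred + markup equals one-shot scoring on the full profile", {
  set.seed(71)
  for (i in 1:40) {
    p <- random_profile()
    one <- compute_vte_score(p)
    two <- apply_postpartum_markup(
      compute_vte_score(p, markup = "defer"),
      pph_ml = p$pph_ml, transfusion = p$transfusion)
    expect_identical(one$final_score, two$final_score)
    expect_identical(one$pre_op_score, two$pre_op_score)
  }
})

test_that("antenatal LMWH patients are not scored", {
  p <- risk_profile(age = 35, bmi = 28, cs_urgency = "elective",
                    on_antenatal_lmwh = TRUE)
  s <- compute_vte_score(p)
  expect_true(s$excluded_antenatal_lmwh)
  expect_true(is.na(s$final_score))
  expect_error(apply_postpartum_markup(s, 1500), "antenatal")
  plan <- recommend_prophylaxis(s)
  expect_identical(plan$tier, "antenatal_lmwh_continued")
})

test_that("recommendations follow the tier thresholds and dosing table", {
  mk <- function(score) {
    s <- compute_vte_score(base_profile())
    s$final_score <- as.integer(score)
    s$risk_tier <- if (score >= 3) "high" else if (score == 2) "moderate"
      else "low"
    s
  }
  expect_identical(recommend_prophylaxis(mk(0))$tier,
                   "early_mobilization_only")
  expect_identical(recommend_prophylaxis(mk(1))$tier,
                   "early_mobilization_only")
  p2 <- recommend_prophylaxis(mk(2), weight = 60)
  expect_identical(p2$tier, "mechanical")
  expect_true(is.na(p2$dose_mg))
  p3 <- recommend_prophylaxis(mk(3), weight = 70)
  expect_identical(p3$tier, "mechanical_plus_pharmacologic")
  expect_identical(p3$drug, "enoxaparin")
  expect_identical(p3$dose_mg, 40L)
  expect_identical(p3$duration_days, 10L)
  expect_identical(recommend_prophylaxis(mk(4), weight = 105)$dose_mg, 60L)
  expect_identical(recommend_prophylaxis(mk(3), weight = 100)$dose_mg, 60L)
  expect_identical(recommend_prophylaxis(mk(3), weight = 99.9)$dose_mg, 40L)
  expect_error(recommend_prophylaxis(mk(3)), "weight")
})

test_that("adding factors or crossing cutoffs never lowers the score", {
  set.seed(99)
  flags <- c("pre_eclampsia", "multiple_pregnancy", "prolonged_labor_gt24h",
             "stillbirth", "medical_comorbidity", "low_risk_thrombophilia",
             "current_smoker", "gross_varicose_veins",
             "current_systemic_infection", "immobility",
             "family_history_vte")
  for (i in 1:25) {
    p <- random_profile()
    s <- compute_vte_score(p)$final_score
    for (f in sample(flags, 3)) {
      q <- p; q[[f]] <- TRUE
      expect_gte(compute_vte_score(q)$final_score, s)
    }
    for (f in c("age", "bmi", "pph_ml")) {
      q <- p
      q[[f]] <- min(p[[f]] + c(age = 15, bmi = 10, pph_ml = 1500)[[f]],
                    c(age = 60, bmi = 45, pph_ml = 4000)[[f]])
      expect_gte(compute_vte_score(q)$final_score, s)
    }
  }
})

test_that("final score always equals the sum of component points", {
  set.seed(7)
  for (i in 1:60) {
    s <- compute_vte_score(random_profile())
    expect_identical(s$final_score, as.integer(sum(s$components$points)))
    expect_true((s$final_score - s$pre_op_score) %in% c(0L, 1L))
  }
})

test_that("cohort scoring is order-preserving, summarized, and strict", {
  cases <- vte_example_cases()
  sc <- score_cohort(cases)
  expect_identical(sum(sc$summary$score_counts) +
                     sc$summary$excluded_antenatal_lmwh,
                   nrow(cases))
  singly <- vapply(seq_len(nrow(cases)), function(i)
    compute_vte_score(cases[i, ])$final_score, integer(1))
  expect_identical(sc$scores$final_score, singly)

  # empty input
  empty <- score_cohort(cases[0, ])
  expect_identical(sum(empty$summary$score_counts), 0L)
  expect_identical(nrow(empty$scores), 0L)

  # antenatal-LMWH-only cohort: excluded from tier breakdown
  lm <- risk_profile(age = 33, bmi = 24, cs_urgency = "elective",
                     on_antenatal_lmwh = TRUE)
  sc_lm <- score_cohort(lm)
  expect_identical(sc_lm$summary$excluded_antenatal_lmwh, 1L)
  expect_identical(sum(sc_lm$summary$score_counts), 0L)

  # invalid record is reported by index
  bad <- cases
  bad$bmi[3] <- -1
  expect_error(score_cohort(bad), "record\\(s\\) 3")
})

test_that("profile validation catches bad and missing fields", {
  expect_error(risk_profile(bmi = 25, cs_urgency = "elective"),
               "age")
  expect_error(risk_profile(age = 30, bmi = -2, cs_urgency = "elective"),
               "bmi")
  expect_error(risk_profile(age = 30, bmi = 22, cs_urgency = "urgentish"),
               "cs_urgency")
  expect_error(risk_profile(age = 30, bmi = 22, cs_urgency = "elective",
                            gestational_age_at_delivery = 18),
               "gestational")
  expect_error(risk_profile(age = 8, bmi = 22, cs_urgency = "elective"),
               "age")
  # defaulted optional columns warn
  expect_warning(validate_profiles(data.frame(age = 30, bmi = 22,
                                              cs_urgency = "elective")),
                 "defaulted")
})

test_that("alternative cutoffs are expressible as rule-set configuration", {
  rcog_like <- vte_protocol(age_cutoff = 35, preterm_cutoff = 37,
                            pharmacologic_threshold = 2,
                            name = "rcog-like")
  p <- base_profile(age = 36, gestational_age_at_delivery = 35)
  expect_identical(compute_vte_score(p)$final_score, 0L)
  s <- compute_vte_score(p, protocol = rcog_like)
  expect_identical(s$final_score, 2L)
  expect_identical(s$risk_tier, "high")
})

test_that("rule sets round-trip through the YAML configuration", {
  proto <- vte_protocol(preterm_cutoff = 36, pph_threshold = 500)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_protocol_config(proto, path)
  back <- read_protocol_config(path)
  expect_identical(back$thresholds, proto$thresholds)
  expect_equal(back$factors, proto$factors)
  set.seed(3)
  for (i in 1:10) {
    p <- random_profile()
    expect_identical(compute_vte_score(p, back)$final_score,
                     compute_vte_score(p, proto)$final_score)
  }
})
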