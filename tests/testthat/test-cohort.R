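# Synthetic cohorts and the exact score distribution.

test_that("parameter validation rejects impossible probabilities", {
  expect_error(cohort_params(factor_prevalences = c(age_40 = 1.2)),
               "probabilities")
  expect_error(cohort_params(factor_prevalences = c(bmi_25_30 = 0.7,
                                                    bmi_30 = 0.5)),
               "BMI band")
  expect_error(cohort_params(factor_prevalences = c(nonsense = 0.1)),
               "unknown")
  expect_error(cohort_params(n = -1), "n must be")
})

test_that("degenerate generators behave", {
  expect_identical(nrow(generate_cohort(cohort_params(n = 0, seed = 1))), 0L)

  zeros <- cohort_params(n = 50, seed = 2)
  zeros$factor_prevalences[] <- 0
  cohort <- generate_cohort(zeros)
  sc <- score_cohort(cohort)
  expect_true(all(sc$scores$final_score == 0))
  expect_true(all(sc$scores$risk_tier == "low"))
})

test_that("sampled factor prevalences hit their targets within 3 SE", {
  n <- 100000
  params <- cohort_params(n = n, seed = 31)
  cohort <- generate_cohort(params)
  pv <- params$factor_prevalences
  got <- c(
    age_40 = mean(cohort$age >= 40),
    bmi_25_30 = mean(cohort$bmi >= 25 & cohort$bmi < 30),
    bmi_30 = mean(cohort$bmi >= 30),
    parity_3 = mean(cohort$parity >= 3),
    pre_eclampsia = mean(cohort$pre_eclampsia),
    multiple_pregnancy = mean(cohort$multiple_pregnancy),
    preterm = mean(cohort$gestational_age_at_delivery < 34),
    prolonged_labor = mean(cohort$prolonged_labor_gt24h),
    stillbirth = mean(cohort$stillbirth),
    medical_comorbidity = mean(cohort$medical_comorbidity),
    low_risk_thrombophilia = mean(cohort$low_risk_thrombophilia),
    current_smoker = mean(cohort$current_smoker),
    gross_varicose_veins = mean(cohort$gross_varicose_veins),
    current_systemic_infection = mean(cohort$current_systemic_infection),
    immobility = mean(cohort$immobility),
    family_history_vte = mean(cohort$family_history_vte),
    pph_or_transfusion = mean(cohort$pph_ml >= 1000 | cohort$transfusion),
    emergency_cs = mean(cohort$cs_urgency == "emergency")
  )
  for (f in names(got)) {
    se <- sqrt(pv[[f]] * (1 - pv[[f]]) / n)
    expect_lt(abs(got[[f]] - pv[[f]]), 3 * se + 1e-12, label = f)
  }
})

test_that("generation is seed-deterministic down to the written file", {
  params <- cohort_params(n = 300, seed = 77)
  a <- generate_cohort(params)
  b <- generate_cohort(params)
  expect_identical(a, b)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_patient_csv(a, fa)
  write_patient_csv(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  # a different seed gives a different cohort
  params$seed <- 78
  expect_false(identical(generate_cohort(params), a))
})

test_that("seeded generation does not disturb the global RNG stream", {
  set.seed(11)
  before <- .Random.seed
  invisible(generate_cohort(cohort_params(n = 50, seed = 9)))
  expect_identical(.Random.seed, before)
})

test_that("exact pmf matches trivial closed forms", {
  params <- cohort_params()
  params$factor_prevalences[] <- 0

  # single weight-2 factor at prevalence 1
  p1 <- params
  p1$factor_prevalences[["bmi_30"]] <- 1
  d <- exact_score_distribution(p1)
  expect_equal(unname(d$pmf[["2"]]), 1)
  expect_equal(sum(d$pmf), 1, tolerance = 1e-12)

  # two weight-1 factors at 1/2: Binomial(2, 1/2)
  p2 <- params
  p2$factor_prevalences[c("pre_eclampsia", "current_smoker")] <- 0.5
  d2 <- exact_score_distribution(p2)
  expect_equal(unname(d2$pmf[c("0", "1", "2")]), c(0.25, 0.5, 0.25),
               tolerance = 1e-12)
})

test_that("exact pmf equals brute-force enumeration at default prevalences", {
  params <- cohort_params()
  proto <- vte_protocol()
  d <- exact_score_distribution(params, proto)
  oracle <- protocol_factor_list(params, proto)
  # enumeration over every factor combination is infeasible at 16 factors;
  # collapse the zero-prevalence factor and enumerate the rest in two halves
  # by convolving two exhaustive enumerations
  k <- length(oracle$outcomes)
  half <- seq_len(ceiling(k / 2))
  pmf_a <- enum_score_pmf(oracle$outcomes[half], oracle$probs[half])
  pmf_b <- enum_score_pmf(oracle$outcomes[-half], oracle$probs[-half])
  pmf <- conv_open(pmf_a, pmf_b)
  expect_equal(unname(d$pmf), pmf[seq_along(d$pmf)], tolerance = 1e-12)
  expect_equal(sum(d$pmf), 1, tolerance = 1e-12)
  expect_true(all(d$pmf >= 0))
})

test_that("exact pmf equals full enumeration for a 12-factor rule set", {
  params <- cohort_params(seed = 1)
  set.seed(42)
  pv <- params$factor_prevalences
  # random prevalences over a reduced rule set: drop five weight-1 flags
  proto <- vte_protocol()
  drop <- c("prolonged_labor", "stillbirth", "gross_varicose_veins",
            "immobility", "family_history_vte")
  proto$factors <- proto$factors[!proto$factors$factor %in% drop, ]
  keep_names <- setdiff(names(pv), c(drop, "emergency_cs"))
  pv[keep_names] <- runif(length(keep_names), 0.05, 0.6)
  pv[["bmi_30"]] <- min(pv[["bmi_30"]], 1 - pv[["bmi_25_30"]])
  params$factor_prevalences <- pv

  d <- exact_score_distribution(params, proto)
  oracle <- protocol_factor_list(params, proto)
  pmf <- enum_score_pmf(oracle$outcomes, oracle$probs)
  expect_equal(unname(d$pmf), pmf[seq_along(d$pmf)], tolerance = 1e-12)
})

test_that("exact pmf mean obeys linearity of expectation", {
  params <- cohort_params()
  d <- exact_score_distribution(params)
  pv <- params$factor_prevalences
  w1 <- c("age_40", "parity_3", "pre_eclampsia", "multiple_pregnancy",
          "preterm", "prolonged_labor", "stillbirth", "medical_comorbidity",
          "low_risk_thrombophilia", "current_smoker", "gross_varicose_veins",
          "current_systemic_infection", "immobility", "family_history_vte",
          "pph_or_transfusion")
  mu <- sum(pv[w1]) + pv[["bmi_25_30"]] + 2 * pv[["bmi_30"]]
  expect_equal(d$mean, mu, tolerance = 1e-12)
})

test_that("exact high-tier probability matches Monte Carlo", {
  params <- cohort_params(n = 200000, seed = 404)
  d <- exact_score_distribution(params)
  p3 <- sum(d$pmf[d$support >= 3])
  cohort <- generate_cohort(params)
  sc <- score_cohort(cohort)
  phat <- mean(sc$scores$final_score >= 3)
  se <- sqrt(p3 * (1 - p3) / params$n)
  expect_lt(abs(phat - p3), 3 * se)
})

test_that("expected prophylaxis rates come from the right stages", {
  # one weight-2 factor at 0.2 and nothing else: mechanical 20%, pharm 0%
  params <- cohort_params()
  params$factor_prevalences[] <- 0
  params$factor_prevalences[["bmi_30"]] <- 0.2
  r <- expected_prophylaxis_rates(params)
  expect_equal(unname(r[["mechanical"]]), 20, tolerance = 1e-12)
  expect_equal(unname(r[["pharmacologic"]]), 0, tolerance = 1e-12)

  z <- params; z$factor_prevalences[] <- 0
  expect_equal(unname(expected_prophylaxis_rates(z)), c(0, 0))

  # defaults: pharmacologic rate in the low single digits, like the
  # audited 3.25% (independence is only an approximation)
  r0 <- expected_prophylaxis_rates(cohort_params())
  expect_gt(r0[["pharmacologic"]], 0.5)
  expect_lt(r0[["pharmacologic"]], 10)
  # markup can only help reach the pharmacologic threshold
  expect_gte(r0[["mechanical"]], 0)
  fin <- exact_score_distribution(cohort_params(), stage = "final")
  pre <- exact_score_distribution(cohort_params(), stage = "pre_op")
  expect_gte(sum(fin$pmf[fin$support >= 3]), sum(pre$pmf[pre$support >= 3]))
})

test_that("stratum event risks are recovered from large simulations", {
  params <- cohort_params(n = 200000, seed = 900)
  cohort <- generate_cohort(params)
  sc <- score_cohort(cohort)
  tier <- sc$scores$risk_tier
  for (t in c("low", "moderate", "high")) {
    p <- params$event_risk_by_stratum[[t]]
    n_t <- sum(tier == t)
    phat <- mean(cohort$vte_event[tier == t])
    se <- sqrt(p * (1 - p) / n_t)
    expect_lt(abs(phat - p), 3 * se, label = t)
  }
})

test_that("treatment relative risk scales only the treated stratum", {
  params <- cohort_params(n = 150000, seed = 55, treatment_effect_rr = 0.3)
  cohort <- generate_cohort(params)
  sc <- score_cohort(cohort)
  high <- sc$scores$final_score >= 3
  p_high <- params$event_risk_by_stratum[["high"]] * 0.3
  phat <- mean(cohort$vte_event[high])
  se <- sqrt(p_high * (1 - p_high) / sum(high))
  expect_lt(abs(phat - p_high), 3 * se)
  p_low <- params$event_risk_by_stratum[["low"]]
  low <- sc$scores$final_score < 2
  expect_lt(abs(mean(cohort$vte_event[low]) - p_low),
            3 * sqrt(p_low * (1 - p_low) / sum(low)))
})

test_that("simulate() draws reproducible replicate cohorts", {
  proto <- vte_protocol()
  two <- simulate(proto, nsim = 2, seed = 10, params = cohort_params(n = 80))
  expect_length(two, 2)
  expect_false(identical(two[[1]], two[[2]]))
  again <- simulate(proto, nsim = 2, seed = 10,
                    params = cohort_params(n = 80))
  expect_identical(two, again)
})
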