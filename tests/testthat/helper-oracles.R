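# Independent oracles used against the package's own implementations.

# Brute-force score distribution: exhaustive enumeration over all factor
# combinations. `outcomes` is a list of integer outcome vectors, `probs` a
# list of matching probability vectors (one entry per factor). Feasible for
# small k only.
enum_score_pmf <- function(outcomes, probs) {
  grid <- expand.grid(lapply(outcomes, seq_along))
  kmax <- sum(vapply(outcomes, max, numeric(1)))
  pmf <- numeric(kmax + 1)
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    s <- sum(mapply(function(o, i) o[i], outcomes, idx))
    p <- prod(mapply(function(pr, i) pr[i], probs, idx))
    pmf[s + 1] <- pmf[s + 1] + p
  }
  pmf
}

# Turn a protocol + prevalence vector into the oracle's factor list
# (BMI as one 3-way categorical, everything else Bernoulli).
protocol_factor_list <- function(params, protocol, include_markup = TRUE) {
  pv <- params$factor_prevalences
  fs <- protocol$factors
  if (!include_markup) fs <- fs[fs$stage == "pre_operative", , drop = FALSE]
  outcomes <- list()
  probs <- list()
  bmi_done <- FALSE
  for (i in seq_len(nrow(fs))) {
    f <- fs[i, ]
    if (f$field == "bmi") {
      if (bmi_done) next
      bmi_done <- TRUE
      p1 <- pv[["bmi_25_30"]]; p2 <- pv[["bmi_30"]]
      outcomes <- c(outcomes, list(c(0L, 1L, 2L)))
      probs <- c(probs, list(c(1 - p1 - p2, p1, p2)))
    } else {
      p <- pv[[f$factor]]
      outcomes <- c(outcomes, list(c(0L, f$points)))
      probs <- c(probs, list(c(1 - p, p)))
    }
  }
  list(outcomes = outcomes, probs = probs)
}

# Direct open convolution of two pmfs on 0..k (no FFT round-off).
conv_open <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Exact conditional two-sided Fisher p by exhaustive hypergeometric
# enumeration (sum of tables with point probability <= observed, with the
# customary relative tolerance for ties).
fisher_enum_p <- function(a, na, b, nb) {
  m <- a + b
  xs <- max(0, m - nb):min(m, na)
  pr <- stats::dhyper(xs, na, nb, m)
  obs <- stats::dhyper(a, na, nb, m)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Binomial tail sums for checking the Clopper-Pearson defining equations.
upper_tail <- function(x, n, p) sum(stats::dbinom(x:n, n, p))   # P(X >= x)
lower_tail <- function(x, n, p) sum(stats::dbinom(0:x, n, p))   # P(X <= x)

# A small all-factors-off profile to perturb in property tests; any field
# can be overridden by name.
base_profile <- function(...) {
  args <- list(age = 30, bmi = 22, cs_urgency = "elective", weight = 60,
               parity = 1, gestational_age_at_delivery = 39, pph_ml = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(risk_profile, args)
}

# Random profile generator for property-style tests (uniform over a wide
# box, all flags independent fair-ish coins).
random_profile <- function() {
  flags <- stats::setNames(
    as.list(stats::runif(11) < 0.3),
    c("pre_eclampsia", "multiple_pregnancy", "prolonged_labor_gt24h",
      "stillbirth", "medical_comorbidity", "low_risk_thrombophilia",
      "current_smoker", "gross_varicose_veins",
      "current_systemic_infection", "immobility", "family_history_vte"))
  do.call(risk_profile, c(list(
    age = stats::runif(1, 18, 55),
    bmi = stats::runif(1, 17, 45),
    weight = stats::runif(1, 45, 120),
    parity = sample(0:5, 1),
    gestational_age_at_delivery = stats::runif(1, 24, 42),
    cs_urgency = sample(c("elective", "emergency"), 1),
    pph_ml = stats::runif(1, 0, 2500),
    transfusion = stats::runif(1) < 0.1), flags))
}
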