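# Seeded synthetic cesarean cohorts with independent Bernoulli risk factors,
# plus the exact (weighted Poisson-binomial) score distribution implied by
# the independence model.

# Audited per-factor prevalences for the two study-like periods (counts over
# cohort sizes 4803 and 3309). Keys match the protocol factor labels;
# emergency_cs is sampled but not scored.
.prevalences_protocol <- c(
  age_40 = 537 / 4803, bmi_25_30 = 624 / 4803, bmi_30 = 239 / 4803,
  parity_3 = 8 / 4803, pre_eclampsia = 161 / 4803,
  multiple_pregnancy = 226 / 4803, preterm = 480 / 4803,
  prolonged_labor = 38 / 4803, stillbirth = 2 / 4803,
  medical_comorbidity = 55 / 4803, low_risk_thrombophilia = 11 / 4803,
  current_smoker = 30 / 4803, gross_varicose_veins = 3 / 4803,
  current_systemic_infection = 16 / 4803, immobility = 0,
  family_history_vte = 4 / 4803, pph_or_transfusion = 291 / 4803,
  emergency_cs = 2816 / 4803
)

.prevalences_preprotocol <- c(
  age_40 = 333 / 3309, bmi_25_30 = 361 / 3309, bmi_30 = 123 / 3309,
  parity_3 = 1 / 3309, pre_eclampsia = 99 / 3309,
  multiple_pregnancy = 199 / 3309, preterm = 335 / 3309,
  prolonged_labor = 36 / 3309, stillbirth = 3 / 3309,
  medical_comorbidity = 34 / 3309, low_risk_thrombophilia = 5 / 3309,
  current_smoker = 29 / 3309, gross_varicose_veins = 2 / 3309,
  current_systemic_infection = 2 / 3309, immobility = 0,
  family_history_vte = 6 / 3309, pph_or_transfusion = 133 / 3309,
  emergency_cs = 1901 / 3309
)

#' Parameters for a synthetic cesarean cohort
#'
#' Bundles everything the generator needs: cohort size, per-factor Bernoulli
#' prevalences (defaults: the audited protocol-period or preprotocol-period
#' marginals), score-stratified VTE event risks (defaults 1/4064 for final
#' score < 2, 1/583 at 2, 3/156 at >= 3), a relative-risk multiplier applied
#' to the event probability of patients modelled as receiving pharmacologic
#' prophylaxis (1 = no treatment effect), a score-independent bleeding
#' complication rate, and the seed.
#'
#' Factors are sampled independently: the generator reproduces the marginal
#' prevalences, not any real-world correlation structure.
#'
#' @param n cohort size (>= 0).
#' @param period \code{"protocol"} or \code{"preprotocol"}: selects the
#'   default prevalence set and bleeding rate.
#' @param factor_prevalences named probability vector overriding the period
#'   defaults (names as in the rule-set factor labels plus
#'   \code{emergency_cs}).
#' @param event_risk_by_stratum named probabilities \code{c(low=, moderate=,
#'   high=)} of a postpartum VTE event by final-score tier.
#' @param treatment_effect_rr relative risk multiplying the event probability
#'   when the patient reaches the pharmacologic tier.
#' @param bleeding_rate probability of a bleeding complication (independent
#'   of the score).
#' @param seed integer seed; every draw in [generate_cohort()] flows from it.
#' @return An object of class \code{"cohort_params"}.
#' @export
cohort_params <- function(n = 4803,
                          period = c("protocol", "preprotocol"),
                          factor_prevalences = NULL,
                          event_risk_by_stratum = c(low = 1 / 4064,
                                                    moderate = 1 / 583,
                                                    high = 3 / 156),
                          treatment_effect_rr = 1,
                          bleeding_rate = NULL,
                          seed = NULL) {
  period <- match.arg(period)
  prev <- if (period == "protocol") .prevalences_protocol else
    .prevalences_preprotocol
  if (!is.null(factor_prevalences)) {
    unknown <- setdiff(names(factor_prevalences), names(prev))
    if (length(unknown) > 0) {
      stop("unknown factor prevalence name(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    prev[names(factor_prevalences)] <- factor_prevalences
  }
  if (is.null(bleeding_rate)) {
    bleeding_rate <- if (period == "protocol") 37 / 4803 else 32 / 3309
  }
  p <- list(n = n, period = period, factor_prevalences = prev,
            event_risk_by_stratum = event_risk_by_stratum,
            treatment_effect_rr = treatment_effect_rr,
            bleeding_rate = bleeding_rate, seed = seed)
  class(p) <- "cohort_params"
  validate_cohort_params(p)
  p
}

#' @rdname cohort_params
#' @param params object to validate.
#' @export
validate_cohort_params <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  probs <- c(params$factor_prevalences, params$event_risk_by_stratum,
             params$bleeding_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all prevalences/risks must be probabilities in [0, 1]",
         call. = FALSE)
  }
  pv <- params$factor_prevalences
  if (pv[["bmi_25_30"]] + pv[["bmi_30"]] > 1) {
    stop("BMI band prevalences sum above 1", call. = FALSE)
  }
  if (!all(c("low", "moderate", "high") %in%
             names(params$event_risk_by_stratum))) {
    stop("event_risk_by_stratum needs low/moderate/high entries",
         call. = FALSE)
  }
  if (is.na(params$n) || params$n < 0) stop("n must be >= 0", call. = FALSE)
  if (params$treatment_effect_rr < 0) {
    stop("treatment_effect_rr must be >= 0", call. = FALSE)
  }
  invisible(params)
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic cohort parameters (", x$period, "-period defaults)\n",
      sep = "")
  cat("  n = ", x$n, ", seed = ",
      if (is.null(x$seed)) "<none>" else x$seed, "\n", sep = "")
  cat("  event risk by stratum: ",
      paste(sprintf("%s %.4g", names(x$event_risk_by_stratum),
                    x$event_risk_by_stratum), collapse = ", "), "\n",
      sep = "")
  cat("  treatment effect RR = ", x$treatment_effect_rr,
      ", bleeding rate = ", signif(x$bleeding_rate, 3), "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic cesarean cohort
#'
#' Draws each boolean risk factor independently at its prevalence, samples
#' the continuous covariates (age, BMI, gestational age, blood loss) within
#' the band implied by the drawn factor so that the scoring cutoffs are
#' exercised, scores every patient under \code{protocol}, and draws the
#' outcomes: a VTE event from the final-score stratum risk (scaled by the
#' treatment relative risk for pharmacologic-tier patients) and a bleeding
#' complication at the score-independent bleeding rate.
#'
#' @param params a [cohort_params()] object.
#' @param protocol the [vte_protocol()] used to stratify event risk.
#' @return Data frame in the patient CSV schema: one row per patient with
#'   the profile fields plus \code{vte_event} and \code{bleeding_event}
#'   (0/1). Reproducible given \code{params$seed}.
#' @examples
#' cohort <- generate_cohort(cohort_params(n = 200, seed = 42))
#' table(score_cohort(cohort)$scores$final_score)
#' @export
generate_cohort <- function(params, protocol = vte_protocol()) {
  validate_cohort_params(params)
  n <- as.integer(params$n)
  pv <- params$factor_prevalences
  .with_seed(params$seed, {
    if (n == 0) {
      prof <- validate_profiles(
        stats::setNames(
          data.frame(matrix(nrow = 0, ncol = length(.profile_fields()))),
          .profile_fields()), quiet = TRUE)
      prof$vte_event <- integer(0)
      prof$bleeding_event <- integer(0)
      return(prof)
    }
    draw <- function(p) stats::rbinom(n, 1L, p) == 1L

    # band upper edges leave headroom so rounding to 1 dp cannot push a
    # sampled value across a scoring cutoff
    age_hit <- draw(pv[["age_40"]])
    age <- ifelse(age_hit, stats::runif(n, 40, 50),
                  stats::runif(n, 19, 39.94))
    bmi_cat <- sample.int(3L, n, replace = TRUE,
                          prob = c(1 - pv[["bmi_25_30"]] - pv[["bmi_30"]],
                                   pv[["bmi_25_30"]], pv[["bmi_30"]]))
    bmi <- c(stats::runif(n, 19, 24.94), stats::runif(n, 25, 29.94),
             stats::runif(n, 30, 42))[(bmi_cat - 1L) * n + seq_len(n)]
    height <- pmax(stats::rnorm(n, 1.60, 0.055), 1.40)
    weight <- round(bmi * height^2, 1)
    par_hit <- draw(pv[["parity_3"]])
    parity <- ifelse(par_hit, sample(3:4, n, replace = TRUE),
                     sample(0:2, n, replace = TRUE,
                            prob = c(0.5, 0.35, 0.15)))
    preterm_hit <- draw(pv[["preterm"]])
    gest <- ifelse(preterm_hit, stats::runif(n, 26, 33.94),
                   stats::runif(n, 37, 41))
    pph_hit <- draw(pv[["pph_or_transfusion"]])
    pph_ml <- round(ifelse(pph_hit, stats::runif(n, 1000, 2500),
                           stats::runif(n, 50, 900)))
    urgency <- ifelse(draw(pv[["emergency_cs"]]), "emergency", "elective")

    prof <- data.frame(
      age = round(age, 1), bmi = round(bmi, 1), weight = weight,
      parity = parity, gestational_age_at_delivery = round(gest, 1),
      cs_urgency = urgency, pph_ml = pph_ml, transfusion = FALSE,
      on_antenatal_lmwh = FALSE,
      prior_vte_or_high_risk_thrombophilia = FALSE,
      pre_eclampsia = draw(pv[["pre_eclampsia"]]),
      multiple_pregnancy = draw(pv[["multiple_pregnancy"]]),
      prolonged_labor_gt24h = draw(pv[["prolonged_labor"]]),
      stillbirth = draw(pv[["stillbirth"]]),
      medical_comorbidity = draw(pv[["medical_comorbidity"]]),
      low_risk_thrombophilia = draw(pv[["low_risk_thrombophilia"]]),
      current_smoker = draw(pv[["current_smoker"]]),
      gross_varicose_veins = draw(pv[["gross_varicose_veins"]]),
      current_systemic_infection = draw(pv[["current_systemic_infection"]]),
      immobility = draw(pv[["immobility"]]),
      family_history_vte = draw(pv[["family_history_vte"]]),
      stringsAsFactors = FALSE
    )

    pts <- .factor_points(prof, protocol)
    pre_idx <- protocol$factors$stage == "pre_operative"
    final <- as.integer(rowSums(pts))
    tier <- .risk_tier(final, protocol$thresholds)
    risk <- unname(params$event_risk_by_stratum[tier])
    treated <- final >= protocol$thresholds[["pharmacologic"]]
    risk[treated] <- pmin(risk[treated] * params$treatment_effect_rr, 1)
    prof$vte_event <- stats::rbinom(n, 1L, risk)
    prof$bleeding_event <- stats::rbinom(n, 1L, params$bleeding_rate)
    prof
  })
}

#' Simulate synthetic cohorts from a protocol rule set
#'
#' \code{simulate} method sugar over [generate_cohort()]: draws \code{nsim}
#' cohorts under \code{params}, stratifying event risk by the protocol's
#' scoring.
#'
#' @param object a [vte_protocol()].
#' @param nsim number of cohorts.
#' @param seed integer; overrides \code{params$seed}. Replicate \code{i}
#'   uses \code{seed + i - 1}.
#' @param params a [cohort_params()].
#' @param ... unused.
#' @return A data frame (\code{nsim = 1}) or a list of data frames.
#' @export
simulate.vte_protocol <- function(object, nsim = 1, seed = NULL,
                                  params = cohort_params(), ...) {
  base_seed <- if (!is.null(seed)) seed else params$seed
  out <- lapply(seq_len(nsim), function(i) {
    params$seed <- if (is.null(base_seed)) NULL else base_seed + i - 1
    generate_cohort(params, protocol = object)
  })
  if (nsim == 1) out[[1]] else out
}

#' Exact score distribution under the independence model
#'
#' Computes the exact probability mass function of the VTE score when every
#' factor is an independent Bernoulli draw at its prevalence: a weighted
#' Poisson-binomial with fourteen weight-1 flags, one three-way BMI
#' categorical contributing 0/1/2 points, and (for the final score) the
#' weight-1 hemorrhage markup. The pmf is built by sequential convolution
#' over factors.
#'
#' @param params a [cohort_params()] (only the prevalences are used).
#' @param protocol the rule set supplying factor weights and stages.
#' @param stage \code{"final"} includes the postpartum markup,
#'   \code{"pre_op"} excludes it.
#' @return An object of class \code{"score_distribution"}: list with
#'   \code{pmf} (named numeric, names \code{"0"}..\code{"K"}),
#'   \code{support} and \code{mean}.
#' @examples
#' d <- exact_score_distribution(cohort_params())
#' sum(d$pmf)            # 1
#' sum(d$pmf[as.integer(names(d$pmf)) >= 3])   # P(high tier)
#' @export
exact_score_distribution <- function(params = cohort_params(),
                                     protocol = vte_protocol(),
                                     stage = c("final", "pre_op")) {
  stage <- match.arg(stage)
  validate_cohort_params(params)
  pv <- params$factor_prevalences
  fs <- protocol$factors
  if (stage == "pre_op") fs <- fs[fs$stage == "pre_operative", , drop = FALSE]

  pmf <- 1
  bmi_done <- FALSE
  for (i in seq_len(nrow(fs))) {
    f <- fs[i, ]
    if (f$field == "bmi") {
      if (bmi_done) next
      bmi_done <- TRUE
      # three-way categorical: 0 / 1 (overweight band) / 2 (obese)
      p1 <- pv[["bmi_25_30"]]; p2 <- pv[["bmi_30"]]
      pmf <- .convolve_pmf(pmf, outcomes = c(0L, 1L, 2L),
                           probs = c(1 - p1 - p2, p1, p2))
    } else {
      p <- pv[[f$factor]]
      if (is.null(p)) {
        stop("no prevalence supplied for factor '", f$factor, "'",
             call. = FALSE)
      }
      pmf <- .convolve_pmf(pmf, outcomes = c(0L, f$points),
                           probs = c(1 - p, p))
    }
  }
  support <- 0:(length(pmf) - 1)
  out <- list(pmf = stats::setNames(pmf, as.character(support)),
              support = support,
              mean = sum(support * pmf),
              stage = stage)
  class(out) <- "score_distribution"
  out
}

# Convolve a pmf on 0..K with an independent discrete factor taking
# `outcomes` (non-negative integers) with `probs`.
.convolve_pmf <- function(pmf, outcomes, probs) {
  new_len <- length(pmf) + max(outcomes)
  out <- numeric(new_len)
  for (j in seq_along(outcomes)) {
    if (probs[j] == 0) next
    k <- outcomes[j]
    out[(1 + k):(length(pmf) + k)] <-
      out[(1 + k):(length(pmf) + k)] + pmf * probs[j]
  }
  out
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("Exact VTE score distribution (", x$stage, " score), mean = ",
      signif(x$mean, 4), "\n", sep = "")
  show <- x$pmf[x$pmf > 1e-6 | x$support <= 4]
  for (k in names(show)) {
    cat(sprintf("  P(score = %-2s) = %.6f\n", k, show[[k]]))
  }
  invisible(x)
}

#' Expected prophylaxis rates under the independence model
#'
#' Derived from the exact score distribution: the mechanical rate is the
#' probability that the pre-operative score reaches the mechanical
#' threshold (cuff attribution is decided before the cesarean), and the
#' pharmacologic rate is the probability that the final score (including
#' markup) reaches the pharmacologic threshold.
#'
#' @param params a [cohort_params()].
#' @param protocol a [vte_protocol()].
#' @return Named numeric: \code{mechanical} and \code{pharmacologic}, in
#'   percent.
#' @export
expected_prophylaxis_rates <- function(params = cohort_params(),
                                       protocol = vte_protocol()) {
  pre <- exact_score_distribution(params, protocol, stage = "pre_op")
  fin <- exact_score_distribution(params, protocol, stage = "final")
  th <- protocol$thresholds
  c(mechanical = 100 * sum(pre$pmf[pre$support >= th[["mechanical"]]]),
    pharmacologic = 100 * sum(fin$pmf[fin$support >= th[["pharmacologic"]]]))
}
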