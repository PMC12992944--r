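# The department VTE prophylaxis rule set as a declarative, data-driven object.

#' Department cesarean-section VTE prophylaxis protocol
#'
#' Constructs the department scoring rule set as a first-class object. The
#' rule set is declarative: a table of factors (field, predicate, points,
#' stage), decision thresholds, and an enoxaparin dosing table. The default
#' is the department protocol: one point per risk factor, two points for
#' BMI >= 30 kg/m^2, a +1 postpartum markup for major hemorrhage (>= 1000 mL)
#' or transfusion; a final score of 2 triggers mechanical prophylaxis
#' (pneumatic cuff) and >= 3 adds at least 10 days of postnatal enoxaparin
#' (40 mg daily under 100 kg booking weight, 60 mg at or above).
#'
#' All cutoffs are configurable so that guideline-style variants (e.g. age 35
#' instead of 40, preterm 37 instead of 34 weeks, a pharmacologic threshold
#' of 2) can be expressed as alternative rule sets.
#'
#' @param age_cutoff minimum age (years, inclusive) scoring one point.
#' @param bmi_overweight,bmi_obese BMI band edges: one point for
#'   [\code{bmi_overweight}, \code{bmi_obese}), two points at or above
#'   \code{bmi_obese} (mutually exclusive).
#' @param parity_cutoff minimum parity (inclusive) scoring one point.
#' @param preterm_cutoff delivery strictly before this many completed weeks
#'   scores one point.
#' @param pph_threshold_ml blood loss (mL, inclusive) triggering the +1
#'   postpartum markup; transfusion always triggers it.
#' @param mechanical_threshold final score (inclusive) prescribing the
#'   pneumatic cuff.
#' @param pharmacologic_threshold final score (inclusive) adding postnatal
#'   low-molecular-weight heparin.
#' @param lmwh_duration_days minimum duration of postnatal enoxaparin.
#' @param dose_weight_cutoff_kg booking weight at/above which the higher
#'   enoxaparin dose is used.
#' @param dose_low_mg,dose_high_mg daily enoxaparin doses below / at-or-above
#'   the weight cutoff.
#' @param name label carried through printed output.
#'
#' @return An object of class \code{"vte_protocol"}.
#' @seealso [compute_vte_score()], [score_cohort()], [predict.vte_protocol()]
#' @examples
#' proto <- vte_protocol()
#' proto
#' predict(proto, data.frame(age = 45, bmi = 31, cs_urgency = "elective"))
#' @export
vte_protocol <- function(age_cutoff = 40,
                         bmi_overweight = 25, bmi_obese = 30,
                         parity_cutoff = 3, preterm_cutoff = 34,
                         pph_threshold_ml = 1000,
                         mechanical_threshold = 2,
                         pharmacologic_threshold = 3,
                         lmwh_duration_days = 10,
                         dose_weight_cutoff_kg = 100,
                         dose_low_mg = 40, dose_high_mg = 60,
                         name = "department") {
  stopifnot(bmi_overweight < bmi_obese,
            mechanical_threshold <= pharmacologic_threshold,
            pph_threshold_ml >= 0, preterm_cutoff > 20)
  factors <- rbind(
    .factor_row("age_40", "age", "ge", age_cutoff, 1),
    .factor_row("bmi_25_30", "bmi", "band", c(bmi_overweight, bmi_obese), 1),
    .factor_row("bmi_30", "bmi", "ge", bmi_obese, 2),
    .factor_row("parity_3", "parity", "ge", parity_cutoff, 1),
    .factor_row("pre_eclampsia", "pre_eclampsia", "flag", NA, 1),
    .factor_row("multiple_pregnancy", "multiple_pregnancy", "flag", NA, 1),
    .factor_row("preterm", "gestational_age_at_delivery", "lt",
                preterm_cutoff, 1),
    .factor_row("prolonged_labor", "prolonged_labor_gt24h", "flag", NA, 1),
    .factor_row("stillbirth", "stillbirth", "flag", NA, 1),
    .factor_row("medical_comorbidity", "medical_comorbidity", "flag", NA, 1),
    .factor_row("low_risk_thrombophilia", "low_risk_thrombophilia", "flag",
                NA, 1),
    .factor_row("current_smoker", "current_smoker", "flag", NA, 1),
    .factor_row("gross_varicose_veins", "gross_varicose_veins", "flag", NA, 1),
    .factor_row("current_systemic_infection", "current_systemic_infection",
                "flag", NA, 1),
    .factor_row("immobility", "immobility", "flag", NA, 1),
    .factor_row("family_history_vte", "family_history_vte", "flag", NA, 1),
    .factor_row("pph_or_transfusion", "pph_ml", "pph", pph_threshold_ml, 1,
                stage = "post_operative_markup")
  )
  obj <- list(
    name = name,
    factors = factors,
    thresholds = c(mechanical = mechanical_threshold,
                   pharmacologic = pharmacologic_threshold),
    dosing = list(weight_cutoff_kg = dose_weight_cutoff_kg,
                  dose_low_mg = dose_low_mg, dose_high_mg = dose_high_mg,
                  duration_days = lmwh_duration_days)
  )
  class(obj) <- "vte_protocol"
  obj
}

.factor_row <- function(factor, field, op, cutoff, points,
                        stage = "pre_operative") {
  data.frame(factor = factor, field = field, op = op,
             cutoff = cutoff[1],
             cutoff2 = if (length(cutoff) > 1) cutoff[2] else NA_real_,
             points = as.integer(points), stage = stage,
             stringsAsFactors = FALSE)
}

# Evaluate every factor predicate column-wise over a validated profile table.
# Returns an n x n_factors integer matrix of awarded points.
.factor_points <- function(profiles, protocol) {
  fs <- protocol$factors
  n <- nrow(profiles)
  pts <- matrix(0L, nrow = n, ncol = nrow(fs),
                dimnames = list(NULL, fs$factor))
  for (i in seq_len(nrow(fs))) {
    f <- fs[i, ]
    x <- profiles[[f$field]]
    hit <- switch(f$op,
      ge   = x >= f$cutoff,
      lt   = x < f$cutoff,
      band = x >= f$cutoff & x < f$cutoff2,
      flag = as.logical(x),
      pph  = (x >= f$cutoff) | profiles$transfusion,
      stop("unknown predicate op: ", f$op)
    )
    hit[is.na(hit)] <- FALSE
    pts[, i] <- as.integer(hit) * f$points
  }
  pts
}

#' @export
print.vte_protocol <- function(x, ...) {
  cat("VTE prophylaxis rule set: ", x$name, "\n", sep = "")
  cat("  factors: ", nrow(x$factors), " (",
      sum(x$factors$stage == "post_operative_markup"),
      " postpartum markup)\n", sep = "")
  cat("  thresholds: mechanical >= ", x$thresholds[["mechanical"]],
      ", pharmacologic >= ", x$thresholds[["pharmacologic"]], "\n", sep = "")
  cat("  enoxaparin: ", x$dosing$dose_low_mg, " mg (< ",
      x$dosing$weight_cutoff_kg, " kg) / ", x$dosing$dose_high_mg,
      " mg daily, >= ", x$dosing$duration_days, " days\n", sep = "")
  invisible(x)
}

#' @export
summary.vte_protocol <- function(object, ...) {
  cat("Rule set '", object$name, "'\n\n", sep = "")
  fs <- object$factors
  desc <- ifelse(fs$op == "flag", fs$field,
          ifelse(fs$op == "ge", paste0(fs$field, " >= ", fs$cutoff),
          ifelse(fs$op == "lt", paste0(fs$field, " < ", fs$cutoff),
          ifelse(fs$op == "band",
                 paste0(fs$field, " in [", fs$cutoff, ", ", fs$cutoff2, ")"),
                 paste0(fs$field, " >= ", fs$cutoff, " or transfusion")))))
  print(data.frame(factor = fs$factor, rule = desc, points = fs$points,
                   stage = fs$stage), row.names = FALSE)
  invisible(object)
}

#' Read / write a rule set as a YAML configuration file
#'
#' The rule set is serialized as a plain list of factor rows plus thresholds
#' and dosing, so institutions can version and adapt their own cutoffs.
#'
#' @param protocol a [vte_protocol()] object.
#' @param path file path of the YAML configuration.
#' @return \code{write_protocol_config} returns \code{path} invisibly;
#'   \code{read_protocol_config} returns a \code{vte_protocol}.
#' @export
write_protocol_config <- function(protocol, path) {
  stopifnot(inherits(protocol, "vte_protocol"))
  cfg <- list(
    name = protocol$name,
    factors = lapply(seq_len(nrow(protocol$factors)), function(i) {
      r <- as.list(protocol$factors[i, ])
      r[!vapply(r, function(v) length(v) == 1 && is.na(v), logical(1))]
    }),
    thresholds = as.list(protocol$thresholds),
    dosing = protocol$dosing
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_protocol_config
#' @export
read_protocol_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  factors <- do.call(rbind, lapply(cfg$factors, function(r) {
    .factor_row(r$factor, r$field, r$op,
                c(r$cutoff %||% NA_real_, r$cutoff2 %||% NA_real_),
                r$points, r$stage %||% "pre_operative")
  }))
  obj <- list(
    name = cfg$name %||% "custom",
    factors = factors,
    thresholds = c(mechanical = cfg$thresholds$mechanical,
                   pharmacologic = cfg$thresholds$pharmacologic),
    dosing = cfg$dosing
  )
  class(obj) <- "vte_protocol"
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a
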