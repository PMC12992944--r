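# Patient risk-factor profiles: schema, constructors, validation.

# Boolean risk-factor flags scored 1 point each by the department protocol.
.flag_fields <- c(
  "pre_eclampsia", "multiple_pregnancy", "prolonged_labor_gt24h", "stillbirth",
  "medical_comorbidity", "low_risk_thrombophilia", "current_smoker",
  "gross_varicose_veins", "current_systemic_infection", "immobility",
  "family_history_vte"
)

# Flags that gate exclusion / comparator logic rather than the score itself.
.aux_flag_fields <- c("transfusion", "on_antenatal_lmwh",
                      "prior_vte_or_high_risk_thrombophilia")

.numeric_fields <- c("age", "bmi", "weight", "parity",
                     "gestational_age_at_delivery", "pph_ml")

# Fields that must be present and non-missing; everything else defaults.
.mandatory_fields <- c("age", "bmi", "cs_urgency")

.profile_fields <- function() {
  c(.numeric_fields, "cs_urgency", .flag_fields, .aux_flag_fields)
}

#' Construct a single patient risk-factor profile
#'
#' Builds a one-row data frame holding the demographic, obstetric and medical
#' risk factors used by the cesarean-section VTE scoring protocol and by the
#' guideline comparators. Unspecified boolean factors default to \code{FALSE};
#' \code{age}, \code{bmi} and \code{cs_urgency} are mandatory.
#'
#' @param age maternal age in completed years (12--60).
#' @param bmi prepregnancy or early-pregnancy body mass index, kg/m^2.
#' @param cs_urgency \code{"elective"} or \code{"emergency"}.
#' @param weight booking or early-pregnancy body weight in kg (needed only to
#'   choose the enoxaparin dose); \code{NA} allowed otherwise.
#' @param parity number of previous births (>= 0).
#' @param gestational_age_at_delivery completed weeks at delivery (20--43).
#' @param pph_ml intra/immediately-postoperative blood loss in mL.
#' @param transfusion did the patient receive blood transfusion during or
#'   immediately after the cesarean?
#' @param on_antenatal_lmwh already on antenatal low-molecular-weight heparin
#'   (these patients continue LMWH and are not scored).
#' @param prior_vte_or_high_risk_thrombophilia history of VTE or a high-risk
#'   thrombophilia (drives the ACOG-style comparator).
#' @param pre_eclampsia,multiple_pregnancy,prolonged_labor_gt24h,stillbirth,medical_comorbidity,low_risk_thrombophilia,current_smoker,gross_varicose_veins,current_systemic_infection,immobility,family_history_vte
#'   logical risk-factor flags, each worth one point in the department score.
#'
#' @return A one-row data frame with class \code{"risk_profile"} prepended.
#' @examples
#' p <- risk_profile(age = 45, bmi = 31, cs_urgency = "elective")
#' compute_vte_score(p)
#' @export
risk_profile <- function(age, bmi, cs_urgency,
                         weight = NA_real_, parity = 0,
                         gestational_age_at_delivery = 39,
                         pph_ml = 0, transfusion = FALSE,
                         on_antenatal_lmwh = FALSE,
                         prior_vte_or_high_risk_thrombophilia = FALSE,
                         pre_eclampsia = FALSE, multiple_pregnancy = FALSE,
                         prolonged_labor_gt24h = FALSE, stillbirth = FALSE,
                         medical_comorbidity = FALSE,
                         low_risk_thrombophilia = FALSE,
                         current_smoker = FALSE, gross_varicose_veins = FALSE,
                         current_systemic_infection = FALSE,
                         immobility = FALSE, family_history_vte = FALSE) {
  if (missing(age) || missing(bmi) || missing(cs_urgency)) {
    miss <- c("age", "bmi", "cs_urgency")[c(missing(age), missing(bmi),
                                            missing(cs_urgency))]
    stop("missing mandatory profile field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  prof <- data.frame(
    age = age, bmi = bmi, weight = weight, parity = parity,
    gestational_age_at_delivery = gestational_age_at_delivery,
    cs_urgency = cs_urgency, pph_ml = pph_ml, transfusion = transfusion,
    on_antenatal_lmwh = on_antenatal_lmwh,
    prior_vte_or_high_risk_thrombophilia = prior_vte_or_high_risk_thrombophilia,
    pre_eclampsia = pre_eclampsia, multiple_pregnancy = multiple_pregnancy,
    prolonged_labor_gt24h = prolonged_labor_gt24h, stillbirth = stillbirth,
    medical_comorbidity = medical_comorbidity,
    low_risk_thrombophilia = low_risk_thrombophilia,
    current_smoker = current_smoker,
    gross_varicose_veins = gross_varicose_veins,
    current_systemic_infection = current_systemic_infection,
    immobility = immobility, family_history_vte = family_history_vte,
    stringsAsFactors = FALSE
  )
  prof <- validate_profiles(prof)
  class(prof) <- c("risk_profile", class(prof))
  prof
}

#' Validate a table of patient profiles
#'
#' Checks mandatory fields, fills defaulted optional fields (with a warning),
#' coerces booleans (accepting 0/1 and true/false spellings) and enforces the
#' field invariants: positive \code{bmi}/\code{weight}, \code{age} in
#' [12, 60], \code{parity >= 0}, gestational age in [20, 43] weeks,
#' \code{pph_ml >= 0}, and \code{cs_urgency} in \{elective, emergency\}.
#'
#' @param profiles data frame, one row per patient, columns named as in
#'   [risk_profile()].
#' @param quiet suppress the defaulting warnings.
#' @return The validated, type-normalized data frame.
#' @export
validate_profiles <- function(profiles, quiet = FALSE) {
  if (!is.data.frame(profiles)) {
    stop("profiles must be a data frame", call. = FALSE)
  }
  profiles <- as.data.frame(profiles, stringsAsFactors = FALSE)

  miss <- setdiff(.mandatory_fields, names(profiles))
  if (length(miss) > 0) {
    stop("missing mandatory profile field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(profiles)

  # fill defaulted optional fields
  defaults <- c(
    stats::setNames(as.list(rep(FALSE, length(c(.flag_fields, .aux_flag_fields)))),
                    c(.flag_fields, .aux_flag_fields)),
    list(parity = 0, gestational_age_at_delivery = 39, pph_ml = 0,
         weight = NA_real_)
  )
  filled <- character(0)
  for (f in names(defaults)) {
    if (!f %in% names(profiles)) {
      profiles[[f]] <- rep(defaults[[f]], length.out = max(n, 1L))[seq_len(n)]
      filled <- c(filled, f)
    }
  }
  if (length(filled) > 0 && !quiet) {
    warning("profile field(s) absent, defaulted: ",
            paste(filled, collapse = ", "), call. = FALSE)
  }

  for (f in c(.flag_fields, .aux_flag_fields)) {
    profiles[[f]] <- .as_flag(profiles[[f]], f)
  }
  for (f in .numeric_fields) {
    if (!is.numeric(profiles[[f]])) {
      v <- suppressWarnings(as.numeric(profiles[[f]]))
      if (n > 0 && anyNA(v) && !all(is.na(profiles[[f]])))
        stop("field '", f, "' is not numeric", call. = FALSE)
      profiles[[f]] <- v
    }
  }
  profiles$cs_urgency <- tolower(as.character(profiles$cs_urgency))

  if (n == 0) return(profiles)

  .check_field(is.na(profiles$age), "age", "missing", profiles)
  .check_field(is.na(profiles$bmi), "bmi", "missing", profiles)
  .check_field(!profiles$cs_urgency %in% c("elective", "emergency"),
               "cs_urgency", "must be 'elective' or 'emergency'", profiles)
  .check_field(profiles$age < 12 | profiles$age > 60, "age",
               "outside [12, 60] years", profiles)
  .check_field(profiles$bmi <= 0, "bmi", "must be strictly positive", profiles)
  .check_field(!is.na(profiles$weight) & profiles$weight <= 0, "weight",
               "must be strictly positive", profiles)
  .check_field(profiles$parity < 0, "parity", "must be non-negative", profiles)
  .check_field(profiles$gestational_age_at_delivery < 20 |
                 profiles$gestational_age_at_delivery > 43,
               "gestational_age_at_delivery", "outside [20, 43] weeks",
               profiles)
  .check_field(profiles$pph_ml < 0, "pph_ml", "must be non-negative", profiles)
  profiles
}

.check_field <- function(bad, field, what, profiles) {
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    stop("invalid field '", field, "' (", what, ") at record(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
}

.as_flag <- function(x, field) {
  if (is.logical(x)) { x[is.na(x)] <- FALSE; return(x) }
  if (is.numeric(x)) {
    if (any(!x %in% c(0, 1, NA)))
      stop("field '", field, "' must be 0/1 or logical", call. = FALSE)
    x[is.na(x)] <- 0
    return(x == 1)
  }
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "t", "yes")] <- TRUE
  out[v %in% c("0", "false", "f", "no", "", "na")] <- FALSE
  if (anyNA(out))
    stop("field '", field, "' has unparseable boolean value(s): ",
         paste(unique(v[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}
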