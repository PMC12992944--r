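# Comparator rule sets in the style of the RCOG, ACCP and ACOG guidance,
# operationalized for post-cesarean prophylaxis recoding.
#
# The published guidelines do not pin down a single machine-readable factor
# list; these comparators ship documented defaults (configurable) and are
# meant for rate comparisons/orderings, not for exact reproduction of any
# particular institution's recoding.

#' Comparator guideline rule sets
#'
#' Constructors for three guideline-style rule sets used to recode a cesarean
#' cohort and compare prophylaxis rates against the department protocol.
#' All three prescribe mechanical prophylaxis universally for cesarean
#' delivery; they differ in when pharmacologic prophylaxis (LMWH) is added:
#' \describe{
#'   \item{RCOG-style}{any emergency (intrapartum/urgent) cesarean, or an
#'     elective cesarean with at least one listed risk factor (age >= 35,
#'     BMI >= 30, parity >= 3, preterm < 37 weeks, major hemorrhage, or any
#'     of the boolean factors).}
#'   \item{ACCP-style}{one major factor, or two or more minor factors, or one
#'     minor factor with an emergency cesarean.}
#'   \item{ACOG-style}{pneumatic compression for all; LMWH only for prior
#'     VTE / high-risk thrombophilia.}
#' }
#'
#' @param age_cutoff,bmi_cutoff,parity_cutoff,preterm_cutoff,pph_threshold_ml
#'   factor cutoffs for the guideline's derived indicators.
#' @param extra_factors boolean profile fields counted as risk factors
#'   (RCOG-style list).
#' @param major,minor factor labels designated major/minor (ACCP-style);
#'   labels refer to the derived indicator set: the boolean profile fields
#'   plus \code{age_35}, \code{bmi_30}, \code{parity_3}, \code{preterm},
#'   \code{pph_or_transfusion}, \code{prior_vte_or_high_risk_thrombophilia}.
#' @return An object of class \code{"vte_guideline"}.
#' @seealso [recode_guideline()], [compare_guidelines()]
#' @export
guideline_rcog <- function(age_cutoff = 35, bmi_cutoff = 30,
                           parity_cutoff = 3, preterm_cutoff = 37,
                           pph_threshold_ml = 1000,
                           extra_factors = .flag_fields) {
  obj <- list(name = "RCOG-style", mechanical_policy = "universal",
              type = "rcog",
              cutoffs = list(age = age_cutoff, bmi = bmi_cutoff,
                             parity = parity_cutoff, preterm = preterm_cutoff,
                             pph = pph_threshold_ml),
              factors = extra_factors)
  class(obj) <- "vte_guideline"
  obj
}

.accp_default_major <- c("prior_vte_or_high_risk_thrombophilia",
                         "immobility", "pre_eclampsia")

#' @rdname guideline_rcog
#' @export
guideline_accp <- function(age_cutoff = 35, bmi_cutoff = 30,
                           parity_cutoff = 3, preterm_cutoff = 37,
                           pph_threshold_ml = 1000,
                           major = .accp_default_major,
                           minor = NULL) {
  all_ind <- c(.flag_fields, "age_35", "bmi_30", "parity_3", "preterm",
               "pph_or_transfusion", "prior_vte_or_high_risk_thrombophilia")
  if (is.null(minor)) minor <- setdiff(all_ind, major)
  unknown <- setdiff(c(major, minor), all_ind)
  if (length(unknown) > 0) {
    stop("unknown factor designation(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  obj <- list(name = "ACCP-style", mechanical_policy = "universal",
              type = "accp",
              cutoffs = list(age = age_cutoff, bmi = bmi_cutoff,
                             parity = parity_cutoff, preterm = preterm_cutoff,
                             pph = pph_threshold_ml),
              major = major, minor = minor)
  class(obj) <- "vte_guideline"
  obj
}

#' @rdname guideline_rcog
#' @export
guideline_acog <- function() {
  obj <- list(name = "ACOG-style", mechanical_policy = "universal",
              type = "acog")
  class(obj) <- "vte_guideline"
  obj
}

#' @export
print.vte_guideline <- function(x, ...) {
  cat("Guideline comparator: ", x$name, "\n", sep = "")
  cat("  mechanical prophylaxis: ", x$mechanical_policy, "\n", sep = "")
  cat("  pharmacologic rule: ",
      switch(x$type,
             rcog = "emergency CS, or elective CS with >= 1 risk factor",
             accp = ">= 1 major, or >= 2 minor, or 1 minor + emergency CS",
             acog = "prior VTE / high-risk thrombophilia only"),
      "\n", sep = "")
  invisible(x)
}

# Derived per-patient guideline indicators (logical matrix, one column per
# indicator label used in major/minor designations).
.guideline_indicators <- function(profiles, cutoffs) {
  ind <- cbind(
    as.matrix(profiles[, .flag_fields, drop = FALSE]),
    age_35 = profiles$age >= cutoffs$age,
    bmi_30 = profiles$bmi >= cutoffs$bmi,
    parity_3 = profiles$parity >= cutoffs$parity,
    preterm = profiles$gestational_age_at_delivery < cutoffs$preterm,
    pph_or_transfusion = profiles$pph_ml >= cutoffs$pph |
      profiles$transfusion,
    prior_vte_or_high_risk_thrombophilia =
      profiles$prior_vte_or_high_risk_thrombophilia
  )
  ind[is.na(ind)] <- FALSE
  ind
}

#' Recode a cohort under a comparator guideline
#'
#' Evaluates a guideline comparator over a patient table and returns, per
#' patient, whether mechanical and pharmacologic prophylaxis would be
#' recommended, with the triggering factors.
#'
#' @param profiles data frame of patient profiles (validated as in
#'   [validate_profiles()]).
#' @param guideline a \code{"vte_guideline"} object.
#' @return Data frame with columns \code{guideline}, \code{mechanical},
#'   \code{pharmacologic} and \code{rationale} (comma-separated triggering
#'   factors).
#' @examples
#' p <- risk_profile(age = 30, bmi = 22, cs_urgency = "emergency")
#' recode_guideline(p, guideline_rcog())
#' @export
recode_guideline <- function(profiles, guideline) {
  stopifnot(inherits(guideline, "vte_guideline"))
  profiles <- validate_profiles(as.data.frame(profiles), quiet = TRUE)
  n <- nrow(profiles)
  emergency <- profiles$cs_urgency == "emergency"

  if (guideline$type == "acog") {
    pharm <- profiles$prior_vte_or_high_risk_thrombophilia
    rationale <- ifelse(pharm, "prior_vte_or_high_risk_thrombophilia", "")
  } else {
    ind <- .guideline_indicators(profiles, guideline$cutoffs)
    if (guideline$type == "rcog") {
      use <- c(guideline$factors, "age_35", "bmi_30", "parity_3", "preterm",
               "pph_or_transfusion")
      use <- intersect(use, colnames(ind))
      any_factor <- rowSums(ind[, use, drop = FALSE]) > 0
      pharm <- emergency | any_factor
      rationale <- vapply(seq_len(n), function(i) {
        r <- colnames(ind[, use, drop = FALSE])[ind[i, use]]
        if (emergency[i]) r <- c("emergency_cs", r)
        paste(r, collapse = ",")
      }, character(1))
    } else { # accp
      n_major <- rowSums(ind[, intersect(guideline$major, colnames(ind)),
                             drop = FALSE])
      n_minor <- rowSums(ind[, intersect(guideline$minor, colnames(ind)),
                             drop = FALSE])
      pharm <- n_major >= 1 | n_minor >= 2 | (n_minor >= 1 & emergency)
      rationale <- vapply(seq_len(n), function(i) {
        r <- colnames(ind)[ind[i, ] &
                             colnames(ind) %in% c(guideline$major,
                                                  guideline$minor)]
        if (emergency[i]) r <- c(r, "emergency_cs")
        paste(r, collapse = ",")
      }, character(1))
    }
  }
  data.frame(guideline = rep(guideline$name, n),
             mechanical = rep(TRUE, n),
             pharmacologic = as.logical(pharm),
             rationale = rationale, stringsAsFactors = FALSE)
}

#' @rdname recode_guideline
#' @param object a \code{"vte_guideline"}.
#' @param newdata data frame of patient profiles.
#' @param ... unused.
#' @export
predict.vte_guideline <- function(object, newdata, ...) {
  recode_guideline(newdata, object)
}

#' @rdname recode_guideline
#' @param profile a single profile (one-row data frame or [risk_profile()]).
#' @export
recode_rcog <- function(profile, guideline = guideline_rcog()) {
  recode_guideline(profile, guideline)
}

#' @rdname recode_guideline
#' @export
recode_accp <- function(profile, guideline = guideline_accp()) {
  recode_guideline(profile, guideline)
}

#' @rdname recode_guideline
#' @export
recode_acog <- function(profile, guideline = guideline_acog()) {
  recode_guideline(profile, guideline)
}

#' Read / write a guideline comparator as a YAML configuration file
#'
#' Serializes the comparator's name, type, cutoffs and factor designations
#' so institutions can pin the exact lists they recode with. Three presets
#' ship with the package under
#' \code{system.file("extdata", "guidelines", package = "vtecs")}.
#'
#' @param guideline a \code{"vte_guideline"}.
#' @param path YAML file path.
#' @return \code{write_guideline_config} returns \code{path} invisibly;
#'   \code{read_guideline_config} returns a \code{vte_guideline}.
#' @examples
#' g <- read_guideline_config(system.file("extdata", "guidelines",
#'                                        "accp.yaml", package = "vtecs"))
#' g
#' @export
write_guideline_config <- function(guideline, path) {
  stopifnot(inherits(guideline, "vte_guideline"))
  yaml::write_yaml(unclass(guideline), path)
  invisible(path)
}

#' @rdname write_guideline_config
#' @export
read_guideline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!cfg$type %in% c("rcog", "accp", "acog")) {
    stop("unknown guideline type: ", cfg$type, call. = FALSE)
  }
  obj <- switch(cfg$type,
    rcog = guideline_rcog(age_cutoff = cfg$cutoffs$age,
                          bmi_cutoff = cfg$cutoffs$bmi,
                          parity_cutoff = cfg$cutoffs$parity,
                          preterm_cutoff = cfg$cutoffs$preterm,
                          pph_threshold_ml = cfg$cutoffs$pph,
                          extra_factors = unlist(cfg$factors)),
    accp = guideline_accp(age_cutoff = cfg$cutoffs$age,
                          bmi_cutoff = cfg$cutoffs$bmi,
                          parity_cutoff = cfg$cutoffs$parity,
                          preterm_cutoff = cfg$cutoffs$preterm,
                          pph_threshold_ml = cfg$cutoffs$pph,
                          major = unlist(cfg$major),
                          minor = unlist(cfg$minor)),
    acog = guideline_acog())
  if (!is.null(cfg$name)) obj$name <- cfg$name
  obj
}

#' Compare prophylaxis rates across rule sets
#'
#' Scores a cohort under the department protocol and recodes it under each
#' comparator guideline, returning counts and percentages of mechanical and
#' pharmacologic prophylaxis against a common denominator (patients on
#' antenatal LMWH are excluded throughout, as in the department audit).
#'
#' @param profiles nonempty data frame of patient profiles.
#' @param guidelines list of \code{"vte_guideline"} objects.
#' @param protocol the department [vte_protocol()].
#' @return Data frame, one row per rule set and prophylaxis type, with
#'   \code{count}, \code{denominator} and \code{percent} (unrounded).
#' @examples
#' cohort <- generate_cohort(cohort_params(n = 500, seed = 1))
#' compare_guidelines(cohort)
#' @export
compare_guidelines <- function(profiles,
                               guidelines = list(guideline_rcog(),
                                                 guideline_accp(),
                                                 guideline_acog()),
                               protocol = vte_protocol()) {
  profiles <- validate_profiles(as.data.frame(profiles), quiet = TRUE)
  if (nrow(profiles) == 0) stop("empty cohort", call. = FALSE)
  keep <- !profiles$on_antenatal_lmwh
  profiles <- profiles[keep, , drop = FALSE]
  if (nrow(profiles) == 0) {
    stop("no scoreable patients (all on antenatal LMWH)", call. = FALSE)
  }
  n <- nrow(profiles)

  sc <- score_cohort(profiles, protocol = protocol)
  rows <- list(
    data.frame(ruleset = protocol$name,
               prophylaxis = c("mechanical", "pharmacologic"),
               count = c(sc$summary$mechanical, sc$summary$pharmacologic),
               stringsAsFactors = FALSE)
  )
  for (g in guidelines) {
    rec <- recode_guideline(profiles, g)
    rows <- c(rows, list(
      data.frame(ruleset = g$name,
                 prophylaxis = c("mechanical", "pharmacologic"),
                 count = c(sum(rec$mechanical), sum(rec$pharmacologic)),
                 stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  out$denominator <- n
  out$percent <- 100 * out$count / n
  out
}
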