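# Scoring a patient or a cohort under a vte_protocol rule set.

#' Compute the itemized VTE score for one patient
#'
#' Evaluates every rule-set factor against the profile and returns an
#' itemized result: the triggered components, the pre-operative score, the
#' final score after the postpartum-hemorrhage markup, the risk tier, and
#' whether a pneumatic cuff is indicated during the cesarean. Patients
#' already on antenatal LMWH are not scored: they continue LMWH and the
#' result carries \code{excluded_antenatal_lmwh = TRUE}.
#'
#' The intraoperative cuff decision (\code{mechanical_during_op}) is made
#' from the pre-operative score only; a patient whose score reaches the
#' mechanical threshold only through the postpartum markup is not counted as
#' having had intraoperative mechanical prophylaxis.
#'
#' @param profile a [risk_profile()] or one-row data frame of profile fields.
#' @param protocol a [vte_protocol()] rule set.
#' @param markup \code{"auto"} evaluates the postpartum markup from the
#'   profile's \code{pph_ml}/\code{transfusion}; \code{"defer"} returns the
#'   pre-operative score only, leaving the markup to
#'   [apply_postpartum_markup()] once blood loss is known.
#' @return An object of class \code{"vte_score"} with elements
#'   \code{components} (data frame: factor, points, stage),
#'   \code{pre_op_score}, \code{final_score}, \code{risk_tier}
#'   (\code{low}/\code{moderate}/\code{high}), \code{mechanical_during_op},
#'   \code{excluded_antenatal_lmwh} and \code{markup_applied}.
#' @examples
#' compute_vte_score(risk_profile(age = 45, bmi = 31, cs_urgency = "elective"))
#' @export
compute_vte_score <- function(profile, protocol = vte_protocol(),
                              markup = c("auto", "defer")) {
  markup <- match.arg(markup)
  stopifnot(inherits(protocol, "vte_protocol"))
  profile <- validate_profiles(as.data.frame(profile), quiet = TRUE)
  if (nrow(profile) != 1) {
    stop("compute_vte_score expects a single profile; use score_cohort() ",
         "for a table", call. = FALSE)
  }

  if (isTRUE(profile$on_antenatal_lmwh)) {
    res <- list(components = .empty_components(), pre_op_score = NA_integer_,
                final_score = NA_integer_, risk_tier = NA_character_,
                mechanical_during_op = TRUE, excluded_antenatal_lmwh = TRUE,
                markup_applied = FALSE, protocol = protocol$name,
                thresholds = protocol$thresholds)
    class(res) <- "vte_score"
    return(res)
  }

  pts <- .factor_points(profile, protocol)[1, ]
  fs <- protocol$factors
  pre_idx <- fs$stage == "pre_operative"
  use <- if (markup == "auto") rep(TRUE, nrow(fs)) else pre_idx
  hit <- pts > 0 & use
  components <- data.frame(factor = fs$factor[hit],
                           points = as.integer(pts[hit]),
                           stage = fs$stage[hit], stringsAsFactors = FALSE)
  pre_op <- as.integer(sum(pts[pre_idx]))
  final <- as.integer(sum(pts[use]))
  res <- list(
    components = components,
    pre_op_score = pre_op,
    final_score = final,
    risk_tier = .risk_tier(final, protocol$thresholds),
    mechanical_during_op = pre_op >= protocol$thresholds[["mechanical"]],
    excluded_antenatal_lmwh = FALSE,
    markup_applied = markup == "auto",
    protocol = protocol$name,
    thresholds = protocol$thresholds
  )
  class(res) <- "vte_score"
  res
}

.empty_components <- function() {
  data.frame(factor = character(0), points = integer(0),
             stage = character(0), stringsAsFactors = FALSE)
}

.risk_tier <- function(score, thresholds) {
  ifelse(score >= thresholds[["pharmacologic"]], "high",
         ifelse(score >= thresholds[["mechanical"]], "moderate", "low"))
}

#' Apply the postpartum hemorrhage / transfusion markup
#'
#' Adds one point to a deferred-markup score when blood loss meets the
#' protocol threshold (1000 mL by default, inclusive) or a transfusion was
#' given. The markup raises the final score and risk tier (possibly
#' triggering postnatal LMWH) but never retroactively changes the
#' intraoperative cuff attribution, which was decided before the cesarean.
#'
#' @param result a \code{"vte_score"} from
#'   \code{compute_vte_score(..., markup = "defer")}.
#' @param pph_ml postpartum blood loss in mL (>= 0).
#' @param transfusion logical; blood transfusion during or immediately after
#'   the cesarean.
#' @param protocol the rule set supplying the threshold.
#' @return The updated \code{"vte_score"}.
#' @examples
#' p <- risk_profile(age = 39, bmi = 31, cs_urgency = "emergency",
#'                   gestational_age_at_delivery = 33)
#' s <- compute_vte_score(p, markup = "defer")
#' apply_postpartum_markup(s, pph_ml = 3000)
#' @export
apply_postpartum_markup <- function(result, pph_ml, transfusion = FALSE,
                                    protocol = vte_protocol()) {
  stopifnot(inherits(result, "vte_score"))
  if (isTRUE(result$excluded_antenatal_lmwh)) {
    stop("patient on antenatal LMWH is not scored; markup not applicable",
         call. = FALSE)
  }
  if (isTRUE(result$markup_applied)) {
    stop("postpartum markup already applied to this score", call. = FALSE)
  }
  if (!is.numeric(pph_ml) || is.na(pph_ml) || pph_ml < 0) {
    stop("pph_ml must be a non-negative volume in mL", call. = FALSE)
  }
  fs <- protocol$factors
  mk <- fs[fs$stage == "post_operative_markup", , drop = FALSE]
  triggered <- nrow(mk) > 0 &&
    (pph_ml >= mk$cutoff[1] || isTRUE(as.logical(transfusion)))
  if (triggered) {
    result$components <- rbind(result$components,
      data.frame(factor = mk$factor[1], points = as.integer(mk$points[1]),
                 stage = mk$stage[1], stringsAsFactors = FALSE))
    result$final_score <- result$pre_op_score + as.integer(mk$points[1])
  } else {
    result$final_score <- result$pre_op_score
  }
  result$risk_tier <- .risk_tier(result$final_score, result$thresholds)
  result$markup_applied <- TRUE
  result
}

#' Turn a VTE score into a prophylaxis recommendation
#'
#' Maps the scored result onto the protocol's tiers: below the mechanical
#' threshold, early mobilization only; at it, pneumatic cuff; at or above the
#' pharmacologic threshold, pneumatic cuff plus postnatal enoxaparin for at
#' least the protocol duration, dosed by booking weight. Patients on
#' antenatal LMWH simply continue their planned LMWH (with cuff during the
#' cesarean).
#'
#' @param result a \code{"vte_score"}.
#' @param weight booking/early-pregnancy body weight in kg; required only
#'   when the pharmacologic tier is reached.
#' @param protocol the rule set supplying thresholds and the dosing table.
#' @return An object of class \code{"prophylaxis_plan"}: list with
#'   \code{tier}, \code{drug}, \code{dose_mg}, \code{duration_days}.
#' @examples
#' s <- compute_vte_score(risk_profile(age = 45, bmi = 31,
#'                                     cs_urgency = "elective"))
#' recommend_prophylaxis(s, weight = 70)
#' @export
recommend_prophylaxis <- function(result, weight = NULL,
                                  protocol = vte_protocol()) {
  stopifnot(inherits(result, "vte_score"))
  d <- protocol$dosing
  if (isTRUE(result$excluded_antenatal_lmwh)) {
    plan <- list(tier = "antenatal_lmwh_continued", drug = "LMWH (as planned)",
                 dose_mg = NA_integer_, duration_days = NA_integer_)
  } else if (result$final_score >= result$thresholds[["pharmacologic"]]) {
    if (is.null(weight) || is.na(weight)) {
      stop("booking weight required to dose enoxaparin at the ",
           "pharmacologic tier", call. = FALSE)
    }
    dose <- if (weight >= d$weight_cutoff_kg) d$dose_high_mg else d$dose_low_mg
    plan <- list(tier = "mechanical_plus_pharmacologic", drug = "enoxaparin",
                 dose_mg = as.integer(dose),
                 duration_days = as.integer(d$duration_days))
  } else if (result$final_score >= result$thresholds[["mechanical"]]) {
    plan <- list(tier = "mechanical", drug = NA_character_,
                 dose_mg = NA_integer_, duration_days = NA_integer_)
  } else {
    plan <- list(tier = "early_mobilization_only", drug = NA_character_,
                 dose_mg = NA_integer_, duration_days = NA_integer_)
  }
  class(plan) <- "prophylaxis_plan"
  plan
}

#' Score a whole cohort and summarize by risk tier
#'
#' Vectorized scoring of a patient table. Patients on antenatal LMWH are set
#' aside (they continue LMWH and are excluded from the tier breakdown, as in
#' the department audit); all others receive a pre-operative score, a final
#' score including the hemorrhage markup, a risk tier and prophylaxis flags.
#'
#' @param profiles data frame of patient profiles.
#' @param protocol a [vte_protocol()] rule set.
#' @return An object of class \code{"vte_cohort_scores"}: list with
#'   \code{scores} (the input plus \code{pre_op_score}, \code{final_score},
#'   \code{risk_tier}, \code{mechanical_during_op}, \code{mechanical},
#'   \code{pharmacologic}, \code{excluded_antenatal_lmwh}) and
#'   \code{summary} (counts by final score band 0/1/2/3/>=4 plus the
#'   excluded count).
#' @examples
#' cohort <- vte_example_cases()
#' score_cohort(cohort)$summary
#' @export
score_cohort <- function(profiles, protocol = vte_protocol()) {
  stopifnot(inherits(protocol, "vte_protocol"))
  profiles <- tryCatch(validate_profiles(as.data.frame(profiles),
                                         quiet = TRUE),
                       error = function(e) stop(conditionMessage(e),
                                                call. = FALSE))
  n <- nrow(profiles)
  out <- profiles
  out$pre_op_score <- rep(NA_integer_, n)
  out$final_score <- rep(NA_integer_, n)
  out$risk_tier <- rep(NA_character_, n)
  out$mechanical_during_op <- rep(FALSE, n)
  out$excluded_antenatal_lmwh <- profiles$on_antenatal_lmwh

  keep <- !profiles$on_antenatal_lmwh
  if (any(keep)) {
    pts <- .factor_points(profiles[keep, , drop = FALSE], protocol)
    pre_idx <- protocol$factors$stage == "pre_operative"
    pre <- as.integer(rowSums(pts[, pre_idx, drop = FALSE]))
    fin <- as.integer(rowSums(pts))
    out$pre_op_score[keep] <- pre
    out$final_score[keep] <- fin
    out$risk_tier[keep] <- .risk_tier(fin, protocol$thresholds)
    out$mechanical_during_op[keep] <-
      pre >= protocol$thresholds[["mechanical"]]
  }
  # mechanical prophylaxis as audited: cuff from the pre-op score, plus all
  # high-tier patients (cuffed during and after CS); markup-only moderates
  # are not attributed mechanical prophylaxis.
  out$pharmacologic <- !is.na(out$final_score) &
    out$final_score >= protocol$thresholds[["pharmacologic"]]
  out$mechanical <- out$mechanical_during_op | out$pharmacologic

  fin_scored <- out$final_score[keep]
  bands <- c("0", "1", "2", "3", ">=4")
  band_of <- pmin(fin_scored, 4)
  counts <- stats::setNames(
    vapply(0:4, function(b) sum(band_of == b), integer(1)), bands)
  res <- list(
    scores = out,
    summary = list(
      n = n,
      excluded_antenatal_lmwh = sum(!keep),
      score_counts = counts,
      mechanical = sum(out$mechanical, na.rm = TRUE),
      pharmacologic = sum(out$pharmacologic, na.rm = TRUE)
    ),
    protocol = protocol$name
  )
  class(res) <- "vte_cohort_scores"
  res
}

#' Predict method for a VTE protocol rule set
#'
#' Applies the rule set to new patient data. \code{type = "score"} returns
#' the scored table; \code{type = "plan"} adds the recommendation tier and
#' enoxaparin dose per patient.
#'
#' @param object a [vte_protocol()].
#' @param newdata data frame of patient profiles.
#' @param type \code{"score"} or \code{"plan"}.
#' @param ... unused.
#' @return A data frame (see [score_cohort()]).
#' @export
predict.vte_protocol <- function(object, newdata, type = c("score", "plan"),
                                 ...) {
  type <- match.arg(type)
  sc <- score_cohort(newdata, protocol = object)
  out <- sc$scores
  if (type == "plan") {
    d <- object$dosing
    tier <- ifelse(out$excluded_antenatal_lmwh, "antenatal_lmwh_continued",
            ifelse(out$pharmacologic, "mechanical_plus_pharmacologic",
            ifelse(out$final_score >= object$thresholds[["mechanical"]],
                   "mechanical", "early_mobilization_only")))
    dose <- ifelse(tier == "mechanical_plus_pharmacologic",
                   ifelse(!is.na(out$weight) &
                            out$weight >= d$weight_cutoff_kg,
                          d$dose_high_mg, d$dose_low_mg), NA_integer_)
    if (any(tier == "mechanical_plus_pharmacologic" & is.na(out$weight))) {
      stop("booking weight required to dose enoxaparin at the ",
           "pharmacologic tier", call. = FALSE)
    }
    out$tier <- tier
    out$drug <- ifelse(tier == "mechanical_plus_pharmacologic", "enoxaparin",
                       NA_character_)
    out$dose_mg <- as.integer(dose)
    out$duration_days <- ifelse(tier == "mechanical_plus_pharmacologic",
                                as.integer(d$duration_days), NA_integer_)
  }
  out
}

#' @export
print.vte_score <- function(x, ...) {
  if (isTRUE(x$excluded_antenatal_lmwh)) {
    cat("VTE score: not computed (antenatal LMWH continued; cuff during CS)\n")
    return(invisible(x))
  }
  cat("VTE score (", x$protocol, " rule set)\n", sep = "")
  if (nrow(x$components) == 0) {
    cat("  no scoring factors present\n")
  } else {
    for (i in seq_len(nrow(x$components))) {
      cat(sprintf("  %-28s +%d%s\n", x$components$factor[i],
                  x$components$points[i],
                  if (x$components$stage[i] == "post_operative_markup")
                    "  (postpartum markup)" else ""))
    }
  }
  cat("  pre-operative score: ", x$pre_op_score, "\n", sep = "")
  cat("  final score:         ", x$final_score,
      if (!x$markup_applied) "  (markup pending)" else "", "\n", sep = "")
  cat("  risk tier:           ", x$risk_tier, "\n", sep = "")
  invisible(x)
}

#' @export
print.prophylaxis_plan <- function(x, ...) {
  lab <- c(early_mobilization_only = "early mobilization only",
           mechanical = "pneumatic cuff during/after CS",
           mechanical_plus_pharmacologic =
             "pneumatic cuff + postnatal LMWH",
           antenatal_lmwh_continued = "continue antenatal LMWH (+ cuff)")
  cat("Prophylaxis plan: ", lab[[x$tier]], "\n", sep = "")
  if (!is.na(x$dose_mg)) {
    cat("  ", x$drug, " ", x$dose_mg, " mg subcutaneous daily, >= ",
        x$duration_days, " days\n", sep = "")
  }
  invisible(x)
}

#' @export
print.vte_cohort_scores <- function(x, ...) {
  s <- x$summary
  cat("Scored cohort (", x$protocol, " rule set): n = ", s$n, "\n", sep = "")
  if (s$excluded_antenatal_lmwh > 0) {
    cat("  on antenatal LMWH (not scored): ", s$excluded_antenatal_lmwh,
        "\n", sep = "")
  }
  n_scored <- s$n - s$excluded_antenatal_lmwh
  for (b in names(s$score_counts)) {
    cat(sprintf("  score %-3s %6d (%s%%)\n", b, s$score_counts[[b]],
                round_half_up(100 * s$score_counts[[b]] / max(n_scored, 1),
                              1)))
  }
  cat("  mechanical prophylaxis:    ", s$mechanical, "\n", sep = "")
  cat("  pharmacologic prophylaxis: ", s$pharmacologic, "\n", sep = "")
  invisible(x)
}
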