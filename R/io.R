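# Patient CSV plumbing and report writing.

.schema_version <- "1"
.outcome_fields <- c("vte_event", "bleeding_event")

#' Read a patient CSV
#'
#' Strict-by-default reader for the shared patient schema: one row per
#' patient, columns named as the [risk_profile()] fields, booleans encoded
#' 0/1 or true/false; optional outcome columns \code{vte_event} and
#' \code{bleeding_event}. Unknown columns are dropped with a warning;
#' missing mandatory columns are a schema error naming the column; invalid
#' cells error with the offending record.
#'
#' @param path CSV file path (header row required).
#' @param quiet suppress defaulting/unknown-column warnings.
#' @return Validated data frame of profiles (plus outcome columns when
#'   present), with attribute \code{"source"} recording the path.
#' @export
read_patient_csv <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         comment.char = "#")
  known <- c(.profile_fields(), .outcome_fields)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    if (!quiet) {
      warning("ignoring unknown column(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  miss <- setdiff(.mandatory_fields, names(raw))
  if (length(miss) > 0) {
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  outcomes <- raw[, intersect(.outcome_fields, names(raw)), drop = FALSE]
  prof <- validate_profiles(
    raw[, setdiff(names(raw), .outcome_fields), drop = FALSE],
    quiet = quiet)
  for (f in names(outcomes)) {
    v <- outcomes[[f]]
    if (!all(v %in% c(0, 1, NA))) {
      stop("outcome column '", f, "' must be 0/1", call. = FALSE)
    }
    prof[[f]] <- as.integer(v)
  }
  attr(prof, "source") <- path
  attr(prof, "schema_version") <- .schema_version
  prof
}

#' Write a patient table to CSV
#'
#' Deterministic, round-trip-stable writer for the shared schema: booleans
#' are encoded 0/1, a schema-version comment line precedes the header.
#'
#' @param cohort data frame of profiles (e.g. from [generate_cohort()]).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_patient_csv <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (f in names(out)) {
    if (is.logical(out[[f]])) out[[f]] <- as.integer(out[[f]])
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# vtecs patient schema v", .schema_version), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write analysis results as CSV plus a text report
#'
#' The machine CSV carries unrounded values; the text report prints at the
#' reporting precision (round-half-up). Accepts any results data frame, e.g.
#' from [compare_guidelines()] or [screening_metrics()].
#'
#' @param results data frame of results.
#' @param path output CSV path; the text report goes to the same path with
#'   extension \code{.txt}.
#' @param digits printed decimal places in the text report.
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(results, path, digits = 2) {
  results <- as.data.frame(results)
  txt_path <- sub("\\.csv$", "", path)
  txt_path <- paste0(txt_path, ".txt")
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  if (nrow(results) == 0) {
    warning("empty results: header-only file written", call. = FALSE)
    writeLines(paste(names(results), collapse = "  "), txt_path)
  } else {
    disp <- results
    for (f in names(disp)) {
      if (is.numeric(disp[[f]]) && !all(disp[[f]] == round(disp[[f]]),
                                        na.rm = TRUE)) {
        disp[[f]] <- round_half_up(disp[[f]], digits)
      }
    }
    lines <- utils::capture.output(print(disp, row.names = FALSE))
    writeLines(lines, txt_path)
  }
  invisible(c(csv = path, txt = txt_path))
}

#' Bundled worked-example VTE case series
#'
#' Sixteen illustrative postpartum VTE cases (eleven from a period without
#' prophylaxis, five from a period under the scoring protocol) with their
#' tabulated risk factors and the reference scores reported for them. Used
#' as a worked example and as the fixture behind the screening-evaluation
#' arithmetic.
#'
#' Note: in the protocol-period Case 5 the reference total (1) disagrees
#' with the case's own tabulated factor list (age 40 and BMI 28 kg/m^2,
#' which score 2 under the rule set); the engine scores from the factor
#' list. See the package vignette.
#'
#' @return Data frame of 16 profiles with \code{period}, \code{case_id},
#'   \code{reported_score} and \code{event_type} columns alongside the
#'   profile fields.
#' @examples
#' cases <- vte_example_cases()
#' cbind(cases$reported_score,
#'       score_cohort(cases)$scores$final_score)
#' @export
vte_example_cases <- function() {
  path <- system.file("extdata", "vte_case_series.csv", package = "vtecs",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- raw[, c("period", "case_id", "reported_score", "event_type")]
  prof <- validate_profiles(
    raw[, setdiff(names(raw),
                  c("period", "case_id", "reported_score", "event_type")),
        drop = FALSE],
    quiet = TRUE)
  cbind(meta, prof)
}
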