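# Statistical evaluation: incidences with exact intervals, two-proportion
# tests, screening-test metrics, and number needed to screen / treat.

#' Incidence with exact binomial confidence interval
#'
#' @param events event count.
#' @param n denominator (> 0).
#' @param level confidence level.
#' @return List with \code{events}, \code{n}, \code{proportion},
#'   \code{percent} (unrounded), and \code{ci_percent}
#'   (Clopper-Pearson, percent scale).
#' @examples
#' incidence(11, 3309)   # 0.33\%
#' @export
incidence <- function(events, n, level = 0.95) {
  if (length(n) != 1 || is.na(n) || n <= 0) {
    stop("n must be a positive count", call. = FALSE)
  }
  if (events < 0 || events > n) {
    stop("events must lie in [0, n]", call. = FALSE)
  }
  ci <- clopper_pearson_ci(events, n, level)
  list(events = events, n = n, proportion = events / n,
       percent = 100 * events / n, ci_percent = 100 * ci,
       ci_method = "clopper-pearson", level = level)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Inverts the binomial tail probabilities: the lower bound solves
#' \eqn{P(X \ge x \mid p) = \alpha/2} and the upper bound
#' \eqn{P(X \le x \mid p) = \alpha/2}, via the beta-quantile closed form.
#' The lower bound is 0 when \code{successes = 0} and the upper bound 1 when
#' \code{successes = n}.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials.
#' @param level confidence level in (0, 1).
#' @return Numeric vector \code{c(lower, upper)} on the proportion scale.
#' @examples
#' clopper_pearson_ci(5, 11)   # c(0.167..., 0.766...)
#' @export
clopper_pearson_ci <- function(successes, n, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || is.na(level) ||
        level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  }
  if (successes < 0 || successes > n || n < 1) {
    stop("successes must lie in [0, n], n >= 1", call. = FALSE)
  }
  a <- (1 - level) / 2
  lower <- if (successes == 0) 0 else stats::qbeta(a, successes,
                                                  n - successes + 1)
  upper <- if (successes == n) 1 else stats::qbeta(1 - a, successes + 1,
                                                   n - successes)
  c(lower = lower, upper = upper)
}

#' Two-proportion test on a 2x2 table
#'
#' Compares event proportions between two groups (by convention A =
#' preprotocol, B = protocol). \code{"yates_chi2"} is the continuity-
#' corrected chi-squared test; \code{"fisher"} the exact conditional test,
#' two-sided by summing all tables with point probability at most that of
#' the observed table; \code{"auto"} picks Fisher when any expected cell
#' count is below 5, the corrected chi-squared otherwise.
#'
#' @param events_a,n_a,events_b,n_b counts of the 2x2 table.
#' @param method \code{"auto"}, \code{"yates_chi2"} or \code{"fisher"}.
#' @return List with \code{p_value}, \code{statistic} (chi-squared statistic
#'   or \code{NA} for Fisher), \code{method} (the method actually used),
#'   \code{proportions} and the underlying \code{table}.
#' @examples
#' two_proportion_test(11, 3309, 5, 4803, method = "yates_chi2")$p_value
#' @export
two_proportion_test <- function(events_a, n_a, events_b, n_b,
                                method = c("auto", "yates_chi2", "fisher")) {
  method <- match.arg(method)
  counts <- c(events_a, n_a, events_b, n_b)
  if (any(is.na(counts)) || any(counts < 0) || events_a > n_a ||
        events_b > n_b || n_a == 0 || n_b == 0) {
    stop("invalid 2x2 counts", call. = FALSE)
  }
  tab <- matrix(c(events_a, n_a - events_a, events_b, n_b - events_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("A", "B"),
                                outcome = c("event", "no_event")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin (zero row/column total); p = 1",
            call. = FALSE)
    return(list(p_value = 1, statistic = NA_real_, method = "degenerate",
                proportions = c(a = events_a / n_a, b = events_b / n_b),
                table = tab))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto") {
    method <- if (any(expected < 5)) "fisher" else "yates_chi2"
  }
  if (method == "fisher") {
    ht <- stats::fisher.test(tab)
    p <- ht$p.value
    stat <- NA_real_
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    p <- ht$p.value
    stat <- unname(ht$statistic)
  }
  list(p_value = p, statistic = stat, method = method,
       proportions = c(a = events_a / n_a, b = events_b / n_b),
       table = tab)
}

#' Compare incidences between two periods
#'
#' Convenience wrapper producing both period incidences (with exact
#' intervals) and the two-proportion test between them.
#'
#' @inheritParams two_proportion_test
#' @param level confidence level for the incidence intervals.
#' @return List with \code{incidence_a}, \code{incidence_b}, \code{test}.
#' @examples
#' cmp <- compare_incidence(11, 3309, 5, 4803)
#' cmp$test$p_value
#' @export
compare_incidence <- function(events_a, n_a, events_b, n_b,
                              method = c("auto", "yates_chi2", "fisher"),
                              level = 0.95) {
  list(incidence_a = incidence(events_a, n_a, level),
       incidence_b = incidence(events_b, n_b, level),
       test = two_proportion_test(events_a, n_a, events_b, n_b,
                                  method = match.arg(method)))
}

#' Build a screening confusion matrix from score counts
#'
#' Treats "final score at or above \code{threshold}" as a positive screen
#' and observed postpartum VTE events as the condition. \code{score_counts}
#' is the whole-cohort score tally (events included); \code{event_scores}
#' the final scores of the event cases.
#'
#' @param score_counts named vector of patient counts by final score (names
#'   are scores, e.g. \code{c("0" = 2026, ...)}; a name like \code{">=4"} is
#'   taken at its lower bound).
#' @param event_scores integer vector of final scores of the VTE cases.
#' @param threshold screening threshold (score >= threshold is positive).
#' @return Object of class \code{"confusion_matrix"}: list with \code{tp},
#'   \code{fp}, \code{fn}, \code{tn}, \code{threshold}.
#' @examples
#' cm <- build_confusion(c("0" = 2026, "1" = 857, "2" = 322, "3" = 88,
#'                         ">=4" = 16),
#'                       event_scores = c(2, 3, 2, 0, 2, 3, 3, 3, 1, 3, 1),
#'                       threshold = 3)
#' cm
#' @export
build_confusion <- function(score_counts, event_scores, threshold = 3) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  scores <- as.integer(gsub("[^0-9]", "", names(score_counts)))
  if (anyNA(scores)) {
    stop("score_counts names must encode integer scores", call. = FALSE)
  }
  total <- sum(score_counts)
  n_events <- length(event_scores)
  if (n_events > total) {
    stop("more events than patients in score_counts", call. = FALSE)
  }
  positives <- sum(score_counts[scores >= threshold])
  tp <- sum(event_scores >= threshold)
  if (tp > positives) {
    stop("event scores inconsistent with score_counts (more positive ",
         "events than positive screens)", call. = FALSE)
  }
  cm <- list(tp = as.integer(tp), fp = as.integer(positives - tp),
             fn = as.integer(n_events - tp),
             tn = as.integer(total - positives - (n_events - tp)),
             threshold = threshold)
  if (cm$tn < 0) stop("inconsistent totals", call. = FALSE)
  class(cm) <- "confusion_matrix"
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Screening confusion matrix (positive: score >= ", x$threshold,
      ")\n", sep = "")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(screen = c("positive", "negative"),
                              VTE = c("event", "no event")))
  print(t(m))
  invisible(x)
}

#' Screening-test metrics with exact confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive values and
#' accuracy from a confusion matrix, each with a Clopper-Pearson interval.
#' A metric whose denominator is zero is reported as \code{NA} (undefined),
#' never as 0.
#'
#' @param cm a [build_confusion()] result, or a list with \code{tp},
#'   \code{fp}, \code{fn}, \code{tn}.
#' @param level confidence level.
#' @return Object of class \code{"screening_evaluation"}: data frame with
#'   one row per metric (\code{percent}, \code{lower}, \code{upper} on the
#'   percent scale, unrounded, plus the defining counts).
#' @examples
#' screening_metrics(list(tp = 5, fp = 99, fn = 6, tn = 3199))
#' @export
screening_metrics <- function(cm, level = 0.95) {
  counts <- c(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all-zero confusion matrix", call. = FALSE)
  num <- c(sensitivity = cm$tp, specificity = cm$tn, ppv = cm$tp,
           npv = cm$tn, accuracy = cm$tp + cm$tn)
  den <- c(sensitivity = cm$tp + cm$fn, specificity = cm$tn + cm$fp,
           ppv = cm$tp + cm$fp, npv = cm$tn + cm$fn,
           accuracy = sum(counts))
  rows <- lapply(names(num), function(m) {
    if (den[[m]] == 0) {
      data.frame(metric = m, numerator = num[[m]], denominator = 0,
                 percent = NA_real_, lower = NA_real_, upper = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      ci <- clopper_pearson_ci(num[[m]], den[[m]], level)
      data.frame(metric = m, numerator = num[[m]],
                 denominator = den[[m]],
                 percent = 100 * num[[m]] / den[[m]],
                 lower = 100 * ci[["lower"]], upper = 100 * ci[["upper"]],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  attr(out, "ci_method") <- "clopper-pearson"
  class(out) <- c("screening_evaluation", class(out))
  out
}

#' @export
print.screening_evaluation <- function(x, digits = 1, ...) {
  lvl <- attr(x, "level")
  cat("Screening performance (", attr(x, "ci_method"), " ",
      100 * lvl, "% CI)\n", sep = "")
  for (i in seq_len(nrow(x))) {
    if (is.na(x$percent[i])) {
      cat(sprintf("  %-12s undefined (denominator 0)\n", x$metric[i]))
    } else {
      cat(sprintf("  %-12s %s%% (%s%%-%s%%)  [%d/%d]\n", x$metric[i],
                  round_half_up(x$percent[i], digits),
                  round_half_up(x$lower[i], digits),
                  round_half_up(x$upper[i], digits),
                  x$numerator[i], x$denominator[i]))
    }
  }
  invisible(x)
}

#' Number needed to screen / treat
#'
#' \code{nns = 1 / arr} is the number of patients that must be screened to
#' prevent one event, where \code{arr} is the absolute risk reduction
#' attributable to the screening programme; \code{nnt = nns *
#' treated_fraction} scales by the fraction of screened patients actually
#' treated.
#'
#' @param arr absolute risk reduction, a proportion in (0, 1].
#' @param treated_fraction fraction of the screened population treated,
#'   in (0, 1].
#' @return Named numeric \code{c(nns =, nnt =)}.
#' @examples
#' nns_nnt(0.002, 0.03)   # c(nns = 500, nnt = 15)
#' @export
nns_nnt <- function(arr, treated_fraction) {
  if (!is.numeric(arr) || is.na(arr) || arr <= 0 || arr > 1) {
    stop("arr must lie in (0, 1]: no effect or harm leaves NNS undefined",
         call. = FALSE)
  }
  if (!is.numeric(treated_fraction) || is.na(treated_fraction) ||
        treated_fraction <= 0 || treated_fraction > 1) {
    stop("treated_fraction must lie in (0, 1]", call. = FALSE)
  }
  nns <- 1 / arr
  c(nns = nns, nnt = nns * treated_fraction)
}
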