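#' Construct a follow-up period
#'
#' A follow-up period is one eligible observation window for one patient:
#' an ordered series of EDSS assessments (integer days since period start)
#' plus the days of clinical relapses. Relapse days may lie before day 0 or
#' after the last assessment; such relapses are kept as context because
#' their proximity windows can cover early or late assessments.
#'
#' Duplicate assessment days are resolved by keeping the last record for
#' that day, with a warning.
#'
#' @param patient_id Scalar identifier (coerced to character).
#' @param days Integer vector of assessment days (>= 0, strictly increasing
#'   after duplicate resolution).
#' @param edss Numeric vector of EDSS scores, same length as `days`.
#' @param relapse_days Integer vector of relapse days (any order; sorted).
#' @param period_index Integer >= 1; which eligible window of this patient.
#' @param dmt_label Optional baseline disease-modifying-treatment label.
#' @return An object of class `msfollowup`: a list with elements
#'   `patient_id`, `period_index`, `assessments` (data.frame `day`, `edss`),
#'   `relapses` (integer vector) and `dmt_label`.
#' @export
#' @examples
#' fp <- followup_period("p1", days = c(0, 180, 370, 740),
#'                       edss = c(2, 2, 3, 3), relapse_days = 150)
#' fp
followup_period <- function(patient_id, days, edss, relapse_days = integer(),
                            period_index = 1L, dmt_label = NA_character_) {
  stopifnot(length(days) == length(edss))
  days <- as.integer(days)
  o <- order(days)
  days <- days[o]
  edss <- as.numeric(edss)[o]
  if (anyDuplicated(days)) {
    warning("duplicate assessment days for patient ", patient_id,
            ": keeping the last record per day")
    keep <- !duplicated(days, fromLast = TRUE)
    days <- days[keep]
    edss <- edss[keep]
  }
  structure(
    list(
      patient_id = as.character(patient_id),
      period_index = as.integer(period_index),
      assessments = data.frame(day = days, edss = edss),
      relapses = sort(as.integer(relapse_days)),
      dmt_label = as.character(dmt_label)
    ),
    class = "msfollowup"
  )
}

#' @export
print.msfollowup <- function(x, ...) {
  a <- x$assessments
  cat(sprintf("Follow-up period: patient %s, period %d\n",
              x$patient_id, x$period_index))
  cat(sprintf("  %d assessments over %d days, EDSS %.1f-%.1f\n",
              nrow(a), if (nrow(a)) max(a$day) - min(a$day) else 0L,
              if (nrow(a)) min(a$edss) else NA, if (nrow(a)) max(a$edss) else NA))
  cat(sprintf("  %d relapse(s)%s\n", length(x$relapses),
              if (length(x$relapses))
                paste0(" at day ", paste(x$relapses, collapse = ", "))
              else ""))
  if (!is.na(x$dmt_label)) cat("  DMT at baseline:", x$dmt_label, "\n")
  invisible(x)
}

#' Validate a follow-up period
#'
#' Checks the structural invariants a period must satisfy before
#' annotation: at least three assessments, non-negative strictly increasing
#' days, and EDSS scores on the valid grid (in permissive mode, off-grid
#' 0.5 scores are downgraded from error to warning).
#'
#' @param period An `msfollowup` object.
#' @param permissive Logical; if `TRUE`, EDSS 0.5 yields a warning finding
#'   instead of an error finding.
#' @return A data.frame of findings with columns `severity`
#'   (`"error"`/`"warning"`) and `message`; zero rows when all invariants
#'   hold.
#' @export
validate_period <- function(period, permissive = FALSE) {
  findings <- list()
  add <- function(severity, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, message = message, stringsAsFactors = FALSE)
  }
  a <- period$assessments
  if (nrow(a) < 3) {
    add("error", sprintf("fewer than 3 EDSS scores (%d)", nrow(a)))
  }
  if (nrow(a) && any(a$day < 0)) add("error", "assessment day < 0")
  if (nrow(a) > 1 && any(diff(a$day) <= 0)) {
    add("error", "assessment days not strictly increasing")
  }
  bad <- !is_valid_edss(a$edss, strict = FALSE)
  if (any(bad)) {
    add("error", sprintf("EDSS value(s) off the 0.5 grid: %s",
                         paste(unique(a$edss[bad]), collapse = ", ")))
  }
  half <- !bad & a$edss == 0.5
  if (any(half)) {
    add(if (permissive) "warning" else "error",
        "EDSS 0.5 is not a standard scale level")
  }
  if (length(period$relapses) > 1 && is.unsorted(period$relapses)) {
    add("error", "relapse days not sorted")
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(severity = character(), message = character(),
                  stringsAsFactors = FALSE)
}

# span of a period in days (last - first assessment)
period_span <- function(period) {
  d <- period$assessments$day
  if (length(d) < 2) 0L else max(d) - min(d)
}

#' Bundle follow-up periods into a cohort
#'
#' @param periods A list of `msfollowup` objects.
#' @return The list, classed `msaccrual_cohort`.
#' @export
as_cohort <- function(periods) {
  if (inherits(periods, "msfollowup")) periods <- list(periods)
  stopifnot(all(vapply(periods, inherits, logical(1), "msfollowup")))
  structure(periods, class = "msaccrual_cohort")
}

#' @export
print.msaccrual_cohort <- function(x, ...) {
  n <- length(x)
  nr <- sum(vapply(x, function(p) length(p$relapses) > 0, logical(1)))
  na <- vapply(x, function(p) nrow(p$assessments), integer(1))
  cat(sprintf("EDSS cohort: %d follow-up period(s), %d with >=1 relapse\n",
              n, nr))
  if (n) cat(sprintf("  assessments per period: median %s (range %d-%d)\n",
                     format(stats::median(na)), min(na), max(na)))
  invisible(x)
}

#' Plot a follow-up period trajectory
#'
#' Draws the EDSS step trajectory with relapse days as vertical lines and,
#' optionally, annotated events marked at their detection day.
#'
#' @param x An `msfollowup` object.
#' @param events Optional annotation data.frame from [annotate_followup()].
#' @param raw_window Length-2 window (pre, post) to shade around relapses.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.msfollowup <- function(x, events = NULL, raw_window = c(30, 90), ...) {
  a <- x$assessments
  graphics::plot(a$day, a$edss, type = "s", pch = 16,
                 xlab = "Day", ylab = "EDSS",
                 ylim = c(0, max(10, a$edss)), ...)
  graphics::points(a$day, a$edss, pch = 16)
  for (r in x$relapses) {
    graphics::rect(r - raw_window[1], -0.5, r + raw_window[2], 10.5,
                   col = grDevices::adjustcolor("pink", 0.4), border = NA)
    graphics::abline(v = r, col = "deeppink")
  }
  if (!is.null(events) && nrow(events)) {
    cols <- c(RAW = "red", PIRA = "blue",
              PIRA_RELAPSE_DURING_CONFIRMATION = "purple",
              UNDEFINED = "orange")
    graphics::points(events$detection_day,
                     a$edss[match(events$detection_day, a$day)],
                     col = cols[events$event_type], pch = 8, cex = 1.6)
  }
  invisible(x)
}
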