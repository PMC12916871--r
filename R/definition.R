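# Enum values for each configurable axis. Order matters: grid enumeration
# is lexicographic over these vectors.
.def_axes <- list(
  event_merging = c(FALSE, TRUE),
  undefined_mode = c("rebaselining_only", "never", "all", "end"),
  undefined_constraint = c("greater_only", "equal_or_greater", "unconstrained"),
  baseline_mode = c("fixed", "roving_next_confirmed"),
  confirmation_mode = c("none", "w12_all", "w12_last", "w24_all", "w24_last",
                        "sustained", "sustained_min12", "sustained_min24"),
  confirmation_score_handling = c("use_all", "skip_relapse_proximal")
)

# confirmation modes in which only the last (first at/after the minimal
# distance) score is checked — the only modes in which relapses may be
# allowed inside the confirmation interval
.last_confirmed_modes <- c("w12_last", "w24_last")

DAYS_PER_WEEK12 <- 84L
DAYS_PER_WEEK24 <- 168L
DAYS_PER_YEAR <- 365L

#' Define one disability-accrual annotation variant
#'
#' A definition is one point in the space of definitional choices for
#' confirmed EDSS worsening and its RAW/PIRA classification. The axes and
#' their levels:
#'
#' \describe{
#'   \item{baseline_mode}{`"fixed"` (reference set at period start, raised
#'     only by events and post-relapse residual disability) or
#'     `"roving_next_confirmed"` (in addition, a score below the current
#'     reference becomes the new reference once the immediately following
#'     assessment does not exceed it).}
#'   \item{confirmation_mode}{`"none"`, `"w12_all"`/`"w24_all"` (every score
#'     from the candidate up to and including the first score at >= 84/168
#'     days must stay at or above reference + minimal increase),
#'     `"w12_last"`/`"w24_last"` (only that first score at >= 84/168 days is
#'     checked), `"sustained"` (every later score until end of follow-up),
#'     `"sustained_min12"`/`"sustained_min24"` (sustained, plus at least
#'     84/168 days of post-candidate follow-up).}
#'   \item{raw_window}{Days (pre, post) around a relapse within which
#'     worsening counts as relapse-associated; the tested grid uses
#'     (30,30), (30,90), (90,90).}
#'   \item{undefined_mode}{Who may yield undefined worsening:
#'     `"rebaselining_only"` (post-relapse re-baselining assessments),
#'     `"never"` (re-baselining assessments are not checked for worsening),
#'     `"all"` (any assessment, after RAW/PIRA take precedence), `"end"`
#'     (re-baselining assessments plus assessments after the last RAW/PIRA
#'     event).}
#'   \item{undefined_constraint}{Extra gate for undefined candidates
#'     relative to the previous reference: `"greater_only"`,
#'     `"equal_or_greater"`, or `"unconstrained"` (magnitude rule alone).}
#'   \item{allow_relapse_in_confirmation}{If `TRUE` (legal only for
#'     last-confirmed modes), events whose confirmation score lies inside a
#'     relapse window are still labelled PIRA; if `FALSE` they are labelled
#'     PIRA with relapse during confirmation.}
#'   \item{confirmation_score_handling}{`"use_all"` keeps every assessment
#'     in the confirmation set; `"skip_relapse_proximal"` removes
#'     relapse-proximal assessments from the confirmation set before the
#'     checks (the confirmation implementation of the standardized
#'     proposal). Not an axis of the 1440 grid.}
#'   \item{event_merging}{If `TRUE`, consecutive events of the same type
#'     with no intervening stabilization are merged into one event with the
#'     combined EDSS change; repeated identical scores within
#'     `max_repetition_time` days (defaults to the post-relapse window
#'     size) continue a merge.}
#' }
#'
#' Fixed (non-axis) aspects: the minimal required increase follows
#' [minimal_required_increase()]; the confirmed event score is the minimum
#' over the candidate and all confirmation scores; confirmation is required
#' for candidates at the last visit (whenever a confirmation is required at
#' all); the earliest admissible confirmation assessment is exactly at the
#' confirmation distance and there is no upper limit; no minimal distance
#' to the reference is required.
#'
#' @param event_merging Logical.
#' @param undefined_mode One of `"rebaselining_only"`, `"never"`, `"all"`,
#'   `"end"`.
#' @param undefined_constraint One of `"greater_only"`, `"equal_or_greater"`,
#'   `"unconstrained"`.
#' @param baseline_mode One of `"fixed"`, `"roving_next_confirmed"`.
#' @param confirmation_mode See Details.
#' @param raw_window Integer length-2 vector `c(pre, post)` in days.
#' @param allow_relapse_in_confirmation Logical.
#' @param confirmation_score_handling One of `"use_all"`,
#'   `"skip_relapse_proximal"`.
#' @param max_repetition_time Days within which a repeated identical score
#'   continues an event merge; `NULL` (default) uses `raw_window[2]`.
#' @return An object of class `accrual_definition`.
#' @export
#' @examples
#' accrual_definition()
#' accrual_definition(baseline_mode = "roving_next_confirmed",
#'                    confirmation_mode = "w24_last")
accrual_definition <- function(event_merging = FALSE,
                               undefined_mode = "rebaselining_only",
                               undefined_constraint = "greater_only",
                               baseline_mode = "fixed",
                               confirmation_mode = "w12_last",
                               raw_window = c(30L, 90L),
                               allow_relapse_in_confirmation = FALSE,
                               confirmation_score_handling = "use_all",
                               max_repetition_time = NULL) {
  def <- structure(
    list(
      event_merging = isTRUE(event_merging),
      undefined_mode = match.arg(undefined_mode, .def_axes$undefined_mode),
      undefined_constraint = match.arg(undefined_constraint,
                                       .def_axes$undefined_constraint),
      baseline_mode = match.arg(baseline_mode, .def_axes$baseline_mode),
      confirmation_mode = match.arg(confirmation_mode,
                                    .def_axes$confirmation_mode),
      raw_window = as.integer(raw_window),
      allow_relapse_in_confirmation = isTRUE(allow_relapse_in_confirmation),
      confirmation_score_handling = match.arg(
        confirmation_score_handling, .def_axes$confirmation_score_handling),
      max_repetition_time = if (is.null(max_repetition_time))
        as.integer(raw_window[2]) else as.integer(max_repetition_time)
    ),
    class = "accrual_definition"
  )
  f <- validate_definition(def)
  err <- f$message[f$severity == "error"]
  if (length(err)) stop("invalid definition: ", paste(err, collapse = "; "))
  def
}

#' Validate a definition
#'
#' Checks enum spellings and the cross-field constraint that relapses may
#' only be allowed inside the confirmation interval when a last-confirmed
#' confirmation mode is used.
#'
#' @param def An `accrual_definition` (or bare list with the same fields).
#' @return A data.frame of findings (`severity`, `message`); zero rows when
#'   the definition is consistent.
#' @export
validate_definition <- function(def) {
  findings <- list()
  add <- function(severity, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, message = message, stringsAsFactors = FALSE)
  }
  for (ax in c("undefined_mode", "undefined_constraint", "baseline_mode",
               "confirmation_mode", "confirmation_score_handling")) {
    if (!is.character(def[[ax]]) || length(def[[ax]]) != 1 ||
        !(def[[ax]] %in% .def_axes[[ax]])) {
      add("error", sprintf("%s must be one of: %s", ax,
                           paste(.def_axes[[ax]], collapse = ", ")))
    }
  }
  if (!is.logical(def$event_merging) ||
      !is.logical(def$allow_relapse_in_confirmation)) {
    add("error", "event_merging and allow_relapse_in_confirmation must be logical")
  }
  w <- def$raw_window
  if (length(w) != 2 || any(is.na(w)) || any(w < 0)) {
    add("error", "raw_window must be two non-negative day counts (pre, post)")
  }
  if (isTRUE(def$allow_relapse_in_confirmation) &&
      !(def$confirmation_mode %in% .last_confirmed_modes)) {
    add("error", paste("allow_relapse_in_confirmation = TRUE requires a",
                       "last-confirmed confirmation mode (w12_last, w24_last)"))
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(severity = character(), message = character(),
                  stringsAsFactors = FALSE)
}

#' @export
print.accrual_definition <- function(x, ...) {
  cat("Disability-accrual definition\n")
  cat(sprintf("  baseline: %s | confirmation: %s (%s)%s\n",
              x$baseline_mode, x$confirmation_mode,
              x$confirmation_score_handling,
              if (x$allow_relapse_in_confirmation)
                " | relapse in confirmation allowed" else ""))
  cat(sprintf("  RAW window: %d days pre / %d days post relapse\n",
              x$raw_window[1], x$raw_window[2]))
  cat(sprintf("  undefined events: %s (%s)\n",
              x$undefined_mode, x$undefined_constraint))
  cat(sprintf("  event merging: %s%s\n",
              if (x$event_merging) "on" else "off",
              if (x$event_merging)
                sprintf(" (max repetition time %d days)", x$max_repetition_time)
              else ""))
  invisible(x)
}

# days required by a confirmation mode (0 when no fixed distance applies)
confirmation_distance <- function(mode) {
  switch(mode,
         w12_all = , w12_last = , sustained_min12 = DAYS_PER_WEEK12,
         w24_all = , w24_last = , sustained_min24 = DAYS_PER_WEEK24,
         0L)
}

#' Read / write a definition configuration
#'
#' Definitions serialize to YAML or JSON (chosen by file extension) using
#' the exact field names and enum spellings of [accrual_definition()].
#' A serialize-then-parse round trip is the identity.
#'
#' @param def An `accrual_definition`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_definition()` returns an `accrual_definition`;
#'   `write_definition()` returns `path` invisibly.
#' @export
write_definition <- function(def, path) {
  x <- unclass(def)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_definition
#' @export
read_definition <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  accrual_definition(
    event_merging = x$event_merging,
    undefined_mode = x$undefined_mode,
    undefined_constraint = x$undefined_constraint,
    baseline_mode = x$baseline_mode,
    confirmation_mode = x$confirmation_mode,
    raw_window = unlist(x$raw_window),
    allow_relapse_in_confirmation = x$allow_relapse_in_confirmation,
    confirmation_score_handling = x$confirmation_score_handling,
    max_repetition_time = x$max_repetition_time
  )
}
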