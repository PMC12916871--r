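#' Eligibility criteria for follow-up periods
#'
#' Defaults mirror typical registry inclusion rules: at least 24 months of
#' follow-up (730 days), at least 3 EDSS scores, and at least one
#' assessment per year implemented as a rolling rule (no inter-assessment
#' gap above 365 days).
#'
#' @param min_span_days Minimum distance between first and last assessment.
#' @param min_assessments Minimum number of assessments.
#' @param max_gap_days Maximum allowed gap between consecutive assessments.
#' @param subgroup One of `"all"`, `"with_relapse"` (periods with at least
#'   one relapse inside the period span), `"dense"` (at least 4 assessments
#'   and every gap at most 183 days).
#' @return A list of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(min_span_days = 730L,
                                 min_assessments = 3L,
                                 max_gap_days = 365L,
                                 subgroup = "all") {
  stopifnot(min_span_days > 0, min_assessments > 0, max_gap_days > 0)
  structure(list(
    min_span_days = as.integer(min_span_days),
    min_assessments = as.integer(min_assessments),
    max_gap_days = as.integer(max_gap_days),
    subgroup = match.arg(subgroup, c("all", "with_relapse", "dense"))
  ), class = "eligibility_criteria")
}

# margin (days) by which relapses outside the assessment span are retained:
# the largest pre/post relapse window in the tested definition grid, so that
# window membership of edge assessments is computable for every definition
RELAPSE_CONTEXT_DAYS <- 90L

#' Segment raw records into eligible follow-up periods
#'
#' Splits each patient's assessment stream into maximal windows whose
#' consecutive gaps all stay within `max_gap_days`, then keeps windows with
#' at least `min_assessments` assessments spanning at least
#' `min_span_days`. A patient can contribute several periods. Days are
#' re-based so each period starts at day 0. Relapses within 90 days of
#' either period edge are retained (with possibly negative days) because
#' their proximity windows can cover edge assessments; segmentation is
#' idempotent.
#'
#' @param assessments data.frame with columns `patient_id`, `day`, `edss`
#'   (days on a common per-patient clock).
#' @param relapses Optional data.frame with columns `patient_id`, `day`.
#' @param criteria An [eligibility_criteria()] object.
#' @param dmt Optional data.frame `patient_id`, `dmt_label`.
#' @return An `msaccrual_cohort` (possibly empty list).
#' @export
#' @examples
#' a <- data.frame(patient_id = "p1",
#'                 day = c(0, 200, 400, 600, 800),
#'                 edss = c(2, 2, 3, 3, 3))
#' segment_followups(a)
segment_followups <- function(assessments, relapses = NULL,
                              criteria = eligibility_criteria(),
                              dmt = NULL) {
  stopifnot(all(c("patient_id", "day", "edss") %in% names(assessments)))
  if (!is.null(relapses) && nrow(relapses)) {
    stopifnot(all(c("patient_id", "day") %in% names(relapses)))
  }
  periods <- list()
  for (pid in unique(assessments$patient_id)) {
    a <- assessments[assessments$patient_id == pid, , drop = FALSE]
    a <- a[order(a$day), , drop = FALSE]
    if (anyDuplicated(a$day)) {
      warning("duplicate assessment days for patient ", pid,
              ": keeping the last record per day")
      a <- a[!duplicated(a$day, fromLast = TRUE), , drop = FALSE]
    }
    rl <- if (is.null(relapses)) integer() else
      sort(relapses$day[relapses$patient_id == pid])
    lab <- if (is.null(dmt)) NA_character_ else {
      m <- dmt$dmt_label[dmt$patient_id == pid]
      if (length(m)) m[1] else NA_character_
    }
    # maximal runs: split where the gap exceeds the limit
    gaps <- diff(a$day)
    run_id <- cumsum(c(0L, as.integer(gaps > criteria$max_gap_days)))
    idx <- 0L
    for (r in split(seq_len(nrow(a)), run_id)) {
      w <- a[r, , drop = FALSE]
      span <- max(w$day) - min(w$day)
      if (nrow(w) < criteria$min_assessments ||
          span < criteria$min_span_days) next
      idx <- idx + 1L
      start <- min(w$day)
      end <- max(w$day)
      keep_rl <- rl[rl >= start - RELAPSE_CONTEXT_DAYS &
                      rl <= end + RELAPSE_CONTEXT_DAYS]
      periods[[length(periods) + 1L]] <- followup_period(
        patient_id = pid,
        days = w$day - start,
        edss = w$edss,
        relapse_days = keep_rl - start,
        period_index = idx,
        dmt_label = lab
      )
    }
  }
  subgroup_filter(as_cohort(periods), criteria$subgroup)
}

#' Filter periods into an analysis subgroup
#'
#' @param periods An `msaccrual_cohort` or list of `msfollowup`.
#' @param subgroup `"all"` (identity), `"with_relapse"` (at least one
#'   relapse with day inside `[0, span]`), or `"dense"` (at least 4
#'   assessments, all gaps at most 183 days).
#' @return The filtered `msaccrual_cohort`.
#' @export
subgroup_filter <- function(periods, subgroup = "all") {
  subgroup <- match.arg(subgroup, c("all", "with_relapse", "dense"))
  keep <- vapply(periods, function(p) {
    switch(subgroup,
           all = TRUE,
           with_relapse = any(p$relapses >= 0 &
                                p$relapses <= period_span(p)),
           dense = nrow(p$assessments) >= 4 &&
             all(diff(p$assessments$day) <= 183))
  }, logical(1))
  as_cohort(unclass(periods)[keep])
}
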