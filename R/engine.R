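#' Relapse-proximity (RAW) window membership
#'
#' A day lies in the RAW window of a relapse at day r when
#' r - pre <= day <= r + post, boundaries inclusive; the windows of all
#' relapses are unioned. An assessment on the same day as a relapse is
#' inside the window.
#'
#' @param day Integer vector of days to test.
#' @param relapse_days Integer vector of relapse days.
#' @param window Integer length-2 vector `c(pre, post)` in days.
#' @return Logical vector parallel to `day`.
#' @export
#' @examples
#' in_raw_window(75, 100, c(30, 90))   # TRUE: inside [70, 190]
#' in_raw_window(69, 100, c(30, 90))   # FALSE
in_raw_window <- function(day, relapse_days, window) {
  if (!length(relapse_days)) return(rep(FALSE, length(day)))
  vapply(day, function(d) {
    any(d >= relapse_days - window[1] & d <= relapse_days + window[2])
  }, logical(1))
}

#' Post-relapse re-baselining assessments
#'
#' After a relapse, residual disability is read off at the first
#' assessment past the relapse's post-window that is not itself inside any
#' relapse's window (overlapping windows from successive relapses defer the
#' re-baselining assessment until outside all of them). Returns `NA` when
#' follow-up ends first.
#'
#' @param relapse_day A single relapse day.
#' @param assessment_days Sorted integer vector of assessment days.
#' @param relapse_days All relapse days of the period (for window unions).
#' @param window Integer `c(pre, post)` window in days.
#' @return The re-baselining assessment day, or `NA_integer_`.
#' @export
post_relapse_rebaseline_day <- function(relapse_day, assessment_days,
                                        relapse_days, window) {
  assessment_days <- as.integer(assessment_days)
  cand <- assessment_days[assessment_days > relapse_day + window[2]]
  cand <- cand[!in_raw_window(cand, relapse_days, window)]
  if (length(cand)) cand[1] else NA_integer_
}

# all distinct post-relapse re-baselining assessment days of a period
rebaseline_days <- function(period, window) {
  days <- period$assessments$day
  rl <- period$relapses
  if (!length(rl)) return(integer())
  rb <- vapply(rl, post_relapse_rebaseline_day, integer(1),
               assessment_days = days, relapse_days = rl, window = window)
  sort(unique(rb[!is.na(rb)]))
}

#' Confirm a worsening candidate
#'
#' Given a candidate assessment whose score reaches
#' reference + [minimal_required_increase()], applies the definition's
#' confirmation requirement. All confirmation checks use the condition
#' score >= reference + minimal increase. The confirmed event score is the
#' minimum over the candidate score and every score that entered the
#' confirmation check.
#'
#' @param period An `msfollowup`.
#' @param index Position of the candidate assessment in
#'   `period$assessments`.
#' @param reference The reference EDSS score in force at the candidate.
#' @param def An `accrual_definition`.
#' @return A list: `confirmed` (logical), `event_score` (NA when not
#'   confirmed), `confirmation_days` (integer vector), and
#'   `relapse_in_confirmation` (logical: any confirmation assessment inside
#'   a RAW window).
#' @export
#' @examples
#' fp <- followup_period("p", days = c(0, 60, 150),
#'                       edss = c(3.0, 4.5, 4.0))
#' confirm_event(fp, 2, 3.0, accrual_definition(confirmation_mode = "w12_last"))
confirm_event <- function(period, index, reference, def) {
  days <- period$assessments$day
  scores <- period$assessments$edss
  d <- days[index]
  thr <- reference + minimal_required_increase(reference)
  stopifnot(scores[index] >= thr)

  later <- which(days > d)
  if (def$confirmation_score_handling == "skip_relapse_proximal") {
    later <- later[!in_raw_window(days[later], period$relapses,
                                  def$raw_window)]
  }

  not_confirmed <- list(confirmed = FALSE, event_score = NA_real_,
                        confirmation_days = integer(),
                        relapse_in_confirmation = FALSE)
  mode <- def$confirmation_mode
  W <- confirmation_distance(mode)

  set <- integer()
  ok <- FALSE
  if (mode == "none") {
    ok <- TRUE
  } else if (mode %in% c("w12_all", "w24_all")) {
    at_dist <- later[days[later] >= d + W]
    if (length(at_dist)) {
      set <- later[days[later] <= days[at_dist[1]]]
      ok <- all(scores[set] >= thr)
    }
  } else if (mode %in% c("w12_last", "w24_last")) {
    at_dist <- later[days[later] >= d + W]
    if (length(at_dist)) {
      set <- at_dist[1]
      ok <- scores[set] >= thr
    }
  } else { # sustained family
    if (length(later)) {
      set <- later
      ok <- all(scores[set] >= thr) &&
        (W == 0L || days[later[length(later)]] >= d + W)
    }
  }
  if (!ok) return(not_confirmed)

  list(
    confirmed = TRUE,
    event_score = min(c(scores[index], scores[set])),
    confirmation_days = days[set],
    relapse_in_confirmation =
      length(set) > 0 && any(in_raw_window(days[set], period$relapses,
                                           def$raw_window))
  )
}

#' Classify a confirmed worsening event
#'
#' A confirmed candidate at a post-relapse re-baselining assessment is an
#' undefined-worsening candidate (its fate depends on the definition's
#' undefined handling). Otherwise a candidate inside a RAW window is RAW; a
#' candidate outside with a relapse-proximal confirmation assessment is
#' PIRA with relapse during confirmation (unless such relapses are allowed,
#' or relapse-proximal scores were skipped from the confirmation set); all
#' remaining events are PIRA.
#'
#' @param candidate_day Day of the confirmed candidate.
#' @param confirmation Result of [confirm_event()] with `confirmed = TRUE`.
#' @param period An `msfollowup`.
#' @param def An `accrual_definition`.
#' @param rebaseline_days Integer vector of the period's post-relapse
#'   re-baselining assessment days (see
#'   [post_relapse_rebaseline_day()]).
#' @return One of `"RAW"`, `"PIRA"`, `"PIRA_RELAPSE_DURING_CONFIRMATION"`,
#'   `"UNDEFINED"`.
#' @export
classify_event <- function(candidate_day, confirmation, period, def,
                           rebaseline_days) {
  stopifnot(isTRUE(confirmation$confirmed))
  if (candidate_day %in% rebaseline_days) return("UNDEFINED")
  if (in_raw_window(candidate_day, period$relapses, def$raw_window)) {
    return("RAW")
  }
  if (confirmation$relapse_in_confirmation &&
      !def$allow_relapse_in_confirmation &&
      def$confirmation_score_handling == "use_all") {
    return("PIRA_RELAPSE_DURING_CONFIRMATION")
  }
  "PIRA"
}

# gate for undefined candidates relative to the previous reference;
# isolated here because the comparison semantics are the least pinned-down
# aspect of the definition space (see the methods vignette)
undefined_gate <- function(score, previous_reference, constraint) {
  switch(constraint,
         greater_only = score > previous_reference,
         equal_or_greater = score >= previous_reference,
         unconstrained = TRUE)
}

empty_events <- function() {
  data.frame(
    detection_day = integer(), event_type = character(),
    reference_score = numeric(), event_score = numeric(),
    delta_edss = numeric(), confirmation_days = character(),
    merged_from = integer(), stringsAsFactors = FALSE
  )
}

#' Annotate one follow-up period
#'
#' The core scan: walk the assessments left to right maintaining a
#' reference score; at each assessment test the magnitude rule against the
#' current reference, confirm per the definition, classify, and re-baseline.
#' The reference starts at the first assessment's score, is raised to the
#' confirmed event score after each RAW/PIRA event, is raised without
#' confirmation to residual disability at post-relapse re-baselining
#' assessments, and (under a roving baseline) is lowered to an improved
#' score once the immediately following assessment does not exceed it.
#'
#' Post-relapse re-baselining assessments are handled by the definition's
#' undefined-event mode: under `"never"` they are not checked for worsening
#' at all; under the other modes a confirmed qualifying score there becomes
#' an UNDEFINED event (gated by the undefined constraint). Either way the
#' reference is then reset to the residual score, so RAW/PIRA output is
#' identical between `"never"` and `"rebaselining_only"`.
#'
#' @param period An `msfollowup`.
#' @param def An `accrual_definition`.
#' @return A data.frame of events with columns `detection_day`,
#'   `event_type`, `reference_score`, `event_score`, `delta_edss`,
#'   `confirmation_days` (semicolon-joined), `merged_from`. Zero rows when
#'   no event is detected. When `def$event_merging` is `TRUE` the result
#'   has [merge_events()] applied.
#' @export
#' @examples
#' fp <- followup_period("p", days = c(0, 30, 120, 210, 300),
#'                       edss = c(3.0, 3.0, 4.5, 4.0, 4.0))
#' annotate_followup(fp, accrual_definition(confirmation_mode = "w12_last"))
annotate_followup <- function(period, def) {
  days <- period$assessments$day
  scores <- period$assessments$edss
  n <- length(days)
  if (n < 2) return(empty_events())
  rb <- rebaseline_days(period, def$raw_window)
  roving <- def$baseline_mode == "roving_next_confirmed"

  ref <- scores[1]
  ev <- list()
  record <- function(day, type, reference, conf) {
    ev[[length(ev) + 1L]] <<- data.frame(
      detection_day = day, event_type = type,
      reference_score = reference, event_score = conf$event_score,
      delta_edss = conf$event_score - reference,
      confirmation_days = paste(conf$confirmation_days, collapse = ";"),
      merged_from = 1L, stringsAsFactors = FALSE
    )
  }

  for (i in 2:n) {
    d <- days[i]
    s <- scores[i]
    if (d %in% rb) {
      # post-relapse re-baselining assessment: undefined-event candidate,
      # then residual-disability re-baselining
      if (def$undefined_mode != "never" &&
          s >= ref + minimal_required_increase(ref)) {
        conf <- confirm_event(period, i, ref, def)
        if (conf$confirmed &&
            undefined_gate(s, ref, def$undefined_constraint)) {
          record(d, "UNDEFINED", ref, conf)
        }
      }
      if (s > ref) {
        ref <- s
      } else if (roving && s < ref && i < n && scores[i + 1] <= s) {
        ref <- s
      }
    } else if (s >= ref + minimal_required_increase(ref)) {
      conf <- confirm_event(period, i, ref, def)
      if (conf$confirmed) {
        type <- classify_event(d, conf, period, def, rb)
        record(d, type, ref, conf)
        ref <- conf$event_score
      }
    } else if (roving && s < ref && i < n && scores[i + 1] <= s) {
      ref <- s
    }
  }

  out <- if (length(ev)) do.call(rbind, ev) else empty_events()
  if (def$event_merging) out <- merge_events(out, def, period)
  out
}

#' Merge sequential events of the same type
#'
#' With event merging on, consecutive events of the same type with no
#' intervening stabilization fuse into a single event whose EDSS change is
#' the last event score minus the first reference score. An assessment
#' between two events ends the merge (stabilization) unless it still
#' satisfies the later event's confirmation threshold, or repeats the
#' earlier event's score within `max_repetition_time` days of the previous
#' assessment. There is no maximal merge distance.
#'
#' @param events Event data.frame from [annotate_followup()] (unmerged),
#'   ordered by detection day.
#' @param def An `accrual_definition` with `event_merging = TRUE` (the
#'   function is the identity when merging is off).
#' @param period The `msfollowup` the events were detected in.
#' @return The merged event data.frame.
#' @export
merge_events <- function(events, def, period) {
  if (!def$event_merging || nrow(events) < 2) return(events)
  days <- period$assessments$day
  scores <- period$assessments$edss
  maxrep <- def$max_repetition_time

  can_merge <- function(e1, e2) {
    if (e1$event_type != e2$event_type) return(FALSE)
    thr <- e2$reference_score +
      minimal_required_increase(e2$reference_score)
    between <- which(days > e1$detection_day & days < e2$detection_day)
    prev_day <- e1$detection_day
    for (j in between) {
      if (scores[j] >= thr) {
        prev_day <- days[j]
        next
      }
      if (scores[j] == e1$event_score &&
          days[j] - prev_day <= maxrep) {
        prev_day <- days[j]
        next
      }
      return(FALSE) # stabilization
    }
    TRUE
  }

  out <- events[1, , drop = FALSE]
  for (k in 2:nrow(events)) {
    e2 <- events[k, , drop = FALSE]
    e1 <- out[nrow(out), , drop = FALSE]
    if (can_merge(e1, e2)) {
      e1$event_score <- e2$event_score
      e1$delta_edss <- e2$event_score - e1$reference_score
      e1$confirmation_days <- paste(
        c(e1$confirmation_days[e1$confirmation_days != ""],
          e2$confirmation_days[e2$confirmation_days != ""]),
        collapse = ";")
      e1$merged_from <- e1$merged_from + e2$merged_from
      out[nrow(out), ] <- e1
    } else {
      out <- rbind(out, e2)
    }
  }
  rownames(out) <- NULL
  out
}

#' Annotate a whole cohort
#'
#' Applies [annotate_followup()] to every period and binds the results
#' with patient and period identifiers.
#'
#' @param cohort An `msaccrual_cohort` (or plain list of `msfollowup`).
#' @param def An `accrual_definition`.
#' @return A data.frame: `patient_id`, `period_index` plus the columns of
#'   [annotate_followup()].
#' @export
annotate_cohort <- function(cohort, def) {
  res <- lapply(cohort, function(p) {
    e <- annotate_followup(p, def)
    if (nrow(e)) {
      cbind(data.frame(patient_id = p$patient_id,
                       period_index = p$period_index,
                       stringsAsFactors = FALSE), e)
    } else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(cbind(data.frame(patient_id = character(),
                            period_index = integer(),
                            stringsAsFactors = FALSE), empty_events()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
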