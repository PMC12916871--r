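# Brute-force reference annotator, written independently of the engine:
# every quantity (window membership, re-baselining assessments,
# confirmation sets, minimal increase) is recomputed from scratch with
# plain loops at each assessment; no precomputation and no package
# helpers. Used only to cross-check annotate_followup().

oracle_annotate <- function(period, def) {
  days <- period$assessments$day
  sc <- period$assessments$edss
  rl <- period$relapses
  pre <- def$raw_window[1]
  post <- def$raw_window[2]
  n <- length(days)

  inc_for <- function(ref) {
    if (ref == 0) 1.5 else if (ref < 5.5) 1.0 else 0.5
  }
  in_window <- function(d) {
    hit <- FALSE
    for (r in rl) if (d >= r - pre && d <= r + post) hit <- TRUE
    hit
  }
  # is day d the first assessment after some relapse's post-window that is
  # outside every relapse window?
  is_rebaseline <- function(d) {
    for (r in rl) {
      first <- NA
      for (j in 1:n) {
        if (days[j] > r + post && !in_window(days[j])) {
          first <- days[j]
          break
        }
      }
      if (!is.na(first) && first == d) return(TRUE)
    }
    FALSE
  }
  confirm <- function(i, ref) {
    thr <- ref + inc_for(ref)
    fail <- list(ok = FALSE, score = NA_real_, conf_days = integer(),
                 relapse_in_conf = FALSE)
    idx <- integer()
    for (j in 1:n) {
      if (days[j] <= days[i]) next
      if (def$confirmation_score_handling == "skip_relapse_proximal" &&
          in_window(days[j])) next
      idx <- c(idx, j)
    }
    mode <- def$confirmation_mode
    W <- 0
    if (mode %in% c("w12_all", "w12_last", "sustained_min12")) W <- 84
    if (mode %in% c("w24_all", "w24_last", "sustained_min24")) W <- 168
    set <- integer()
    if (mode == "none") {
      # confirmed by definition
    } else if (mode %in% c("w12_all", "w24_all")) {
      first <- NA
      for (j in idx) if (days[j] >= days[i] + W) { first <- j; break }
      if (is.na(first)) return(fail)
      for (j in idx) if (days[j] <= days[first]) set <- c(set, j)
      for (j in set) if (sc[j] < thr) return(fail)
    } else if (mode %in% c("w12_last", "w24_last")) {
      first <- NA
      for (j in idx) if (days[j] >= days[i] + W) { first <- j; break }
      if (is.na(first)) return(fail)
      set <- first
      if (sc[first] < thr) return(fail)
    } else { # sustained family
      if (length(idx) == 0) return(fail)
      set <- idx
      for (j in set) if (sc[j] < thr) return(fail)
      if (W > 0 && days[idx[length(idx)]] < days[i] + W) return(fail)
    }
    ric <- FALSE
    for (j in set) if (in_window(days[j])) ric <- TRUE
    list(ok = TRUE, score = min(c(sc[i], sc[set])),
         conf_days = days[set], relapse_in_conf = ric)
  }

  events <- data.frame(detection_day = integer(), event_type = character(),
                       reference_score = numeric(), event_score = numeric(),
                       delta_edss = numeric(), confirmation_days = character(),
                       merged_from = integer(), stringsAsFactors = FALSE)
  if (n < 2) return(events)
  ref <- sc[1]
  for (i in 2:n) {
    d <- days[i]
    s <- sc[i]
    if (is_rebaseline(d)) {
      if (def$undefined_mode != "never" && s >= ref + inc_for(ref)) {
        cf <- confirm(i, ref)
        gate <- switch(def$undefined_constraint,
                       greater_only = s > ref,
                       equal_or_greater = s >= ref,
                       unconstrained = TRUE)
        if (cf$ok && gate) {
          events <- rbind(events, data.frame(
            detection_day = d, event_type = "UNDEFINED",
            reference_score = ref, event_score = cf$score,
            delta_edss = cf$score - ref,
            confirmation_days = paste(cf$conf_days, collapse = ";"),
            merged_from = 1L, stringsAsFactors = FALSE))
        }
      }
      if (s > ref) {
        ref <- s
      } else if (def$baseline_mode == "roving_next_confirmed" &&
                 s < ref && i < n && sc[i + 1] <= s) {
        ref <- s
      }
    } else if (s >= ref + inc_for(ref)) {
      cf <- confirm(i, ref)
      if (cf$ok) {
        if (in_window(d)) {
          type <- "RAW"
        } else if (cf$relapse_in_conf &&
                   !def$allow_relapse_in_confirmation &&
                   def$confirmation_score_handling == "use_all") {
          type <- "PIRA_RELAPSE_DURING_CONFIRMATION"
        } else {
          type <- "PIRA"
        }
        events <- rbind(events, data.frame(
          detection_day = d, event_type = type,
          reference_score = ref, event_score = cf$score,
          delta_edss = cf$score - ref,
          confirmation_days = paste(cf$conf_days, collapse = ";"),
          merged_from = 1L, stringsAsFactors = FALSE))
        ref <- cf$score
      }
    } else if (def$baseline_mode == "roving_next_confirmed" &&
               s < ref && i < n && sc[i + 1] <= s) {
      ref <- s
    }
  }

  if (def$event_merging && nrow(events) >= 2) {
    merged <- events[1, , drop = FALSE]
    for (k in 2:nrow(events)) {
      e2 <- events[k, , drop = FALSE]
      e1 <- merged[nrow(merged), , drop = FALSE]
      fuse <- e1$event_type == e2$event_type
      if (fuse) {
        thr2 <- e2$reference_score + inc_for(e2$reference_score)
        prev <- e1$detection_day
        for (j in 1:n) {
          if (days[j] <= e1$detection_day || days[j] >= e2$detection_day) next
          if (sc[j] >= thr2) {
            prev <- days[j]
          } else if (sc[j] == e1$event_score &&
                     days[j] - prev <= def$max_repetition_time) {
            prev <- days[j]
          } else {
            fuse <- FALSE
            break
          }
        }
      }
      if (fuse) {
        e1$event_score <- e2$event_score
        e1$delta_edss <- e2$event_score - e1$reference_score
        e1$confirmation_days <- paste(
          c(e1$confirmation_days[e1$confirmation_days != ""],
            e2$confirmation_days[e2$confirmation_days != ""]),
          collapse = ";")
        e1$merged_from <- e1$merged_from + e2$merged_from
        merged[nrow(merged), ] <- e1
      } else {
        merged <- rbind(merged, e2)
      }
    }
    events <- merged
  }
  rownames(events) <- NULL
  events
}
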