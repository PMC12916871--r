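EVENT_TYPES <- c("RAW", "PIRA", "PIRA_RELAPSE_DURING_CONFIRMATION",
                 "UNDEFINED")

period_key <- function(patient_id, period_index) {
  paste(patient_id, period_index, sep = "\r")
}

#' Summarize annotations at cohort level
#'
#' Computes the cohort metrics used to compare definitions: the overall
#' event rate (fraction of follow-up periods with at least one event of
#' any type), per-type event rates, each type's contribution to the total
#' event count and to the total EDSS change (sum of event delta over all
#' events of the type divided by the sum over all events), the fraction of
#' event-bearing periods with only PIRA / only RAW events, the
#' Kaplan-Meier median time to first event (years, censoring periods
#' without events at their last assessment), and the distribution of event
#' counts among event-bearing periods.
#'
#' @param annotations Event data.frame from [annotate_cohort()] (must
#'   carry `patient_id` and `period_index`).
#' @param periods The annotated `msaccrual_cohort` (denominator and
#'   censoring times).
#' @param include_undefined_in_tte Logical; whether undefined-worsening
#'   events start the time-to-first-event clock (default `TRUE`).
#' @return A list of class `accrual_cohort_summary`.
#' @export
summarize_cohort <- function(annotations, periods,
                             include_undefined_in_tte = TRUE) {
  n_periods <- length(periods)
  if (n_periods == 0) stop("cannot summarize an empty cohort")
  keys <- vapply(periods, function(p) period_key(p$patient_id, p$period_index),
                 character(1))
  if (anyDuplicated(keys)) stop("duplicate patient/period identifiers")
  ann_key <- if (nrow(annotations))
    period_key(annotations$patient_id, annotations$period_index)
  else character()
  if (length(ann_key) && !all(ann_key %in% keys)) {
    stop("annotations refer to periods absent from the cohort")
  }

  has_any <- keys %in% ann_key
  type_of <- function(k, type) {
    sum(annotations$event_type == type & ann_key == k) > 0
  }
  per_type_rate <- vapply(EVENT_TYPES, function(tp) {
    mean(vapply(keys, function(k) type_of(k, tp), logical(1)))
  }, numeric(1))

  n_events <- nrow(annotations)
  count_contrib <- vapply(EVENT_TYPES, function(tp) {
    if (n_events == 0) NA_real_
    else sum(annotations$event_type == tp) / n_events
  }, numeric(1))
  total_delta <- sum(annotations$delta_edss)
  delta_contrib <- vapply(EVENT_TYPES, function(tp) {
    if (n_events == 0 || total_delta == 0) NA_real_
    else sum(annotations$delta_edss[annotations$event_type == tp]) /
      total_delta
  }, numeric(1))

  bearing <- keys[has_any]
  only_type <- function(tp) {
    if (!length(bearing)) return(NA_real_)
    mean(vapply(bearing, function(k) {
      all(annotations$event_type[ann_key == k] == tp)
    }, logical(1)))
  }

  # time to first event, right-censored at the last assessment
  tte_ann <- annotations
  tte_key <- ann_key
  if (!include_undefined_in_tte && n_events) {
    keep <- tte_ann$event_type != "UNDEFINED"
    tte_ann <- tte_ann[keep, , drop = FALSE]
    tte_key <- tte_key[keep]
  }
  time_days <- vapply(seq_along(periods), function(i) {
    k <- keys[i]
    ev <- tte_ann$detection_day[tte_key == k]
    if (length(ev)) min(ev) else max(periods[[i]]$assessments$day)
  }, numeric(1))
  status <- as.integer(keys %in% tte_key)
  fit <- survival::survfit(
    survival::Surv(time_days / DAYS_PER_YEAR, status) ~ 1)
  km_median <- unname(summary(fit)$table["median"])

  counts <- if (length(bearing)) {
    table(vapply(bearing, function(k) sum(ann_key == k), integer(1)))
  } else table(integer())

  structure(list(
    n_periods = n_periods,
    n_events = n_events,
    total_delta_edss = total_delta,
    overall_event_rate = mean(has_any),
    per_type_event_rate = per_type_rate,
    per_type_count_contribution = count_contrib,
    per_type_delta_contribution = delta_contrib,
    pira_only_rate = only_type("PIRA"),
    raw_only_rate = only_type("RAW"),
    km_median_years = km_median,
    events_per_period_distribution = counts
  ), class = "accrual_cohort_summary")
}

#' @export
print.accrual_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d periods, %d events (total dEDSS %.1f)\n",
              x$n_periods, x$n_events, x$total_delta_edss))
  cat(sprintf("  overall event rate: %.1f%%\n", 100 * x$overall_event_rate))
  for (tp in EVENT_TYPES) {
    cat(sprintf("  %-34s rate %5.1f%% | count %5.1f%% | dEDSS %5.1f%%\n", tp,
                100 * x$per_type_event_rate[tp],
                100 * x$per_type_count_contribution[tp],
                100 * x$per_type_delta_contribution[tp]))
  }
  cat(sprintf("  PIRA-only %.1f%%, RAW-only %.1f%% of event-bearing periods\n",
              100 * x$pira_only_rate, 100 * x$raw_only_rate))
  cat(sprintf("  KM median time to first event: %s\n",
              if (is.na(x$km_median_years)) "not reached"
              else sprintf("%.2f years", x$km_median_years)))
  invisible(x)
}

summary_to_row <- function(s) {
  data.frame(
    n_periods = s$n_periods, n_events = s$n_events,
    total_delta_edss = s$total_delta_edss,
    overall_event_rate = s$overall_event_rate,
    rate_raw = s$per_type_event_rate[["RAW"]],
    rate_pira = s$per_type_event_rate[["PIRA"]],
    rate_pira_conf = s$per_type_event_rate[["PIRA_RELAPSE_DURING_CONFIRMATION"]],
    rate_undefined = s$per_type_event_rate[["UNDEFINED"]],
    count_contrib_raw = s$per_type_count_contribution[["RAW"]],
    count_contrib_pira = s$per_type_count_contribution[["PIRA"]],
    count_contrib_pira_conf =
      s$per_type_count_contribution[["PIRA_RELAPSE_DURING_CONFIRMATION"]],
    count_contrib_undefined = s$per_type_count_contribution[["UNDEFINED"]],
    delta_contrib_raw = s$per_type_delta_contribution[["RAW"]],
    delta_contrib_pira = s$per_type_delta_contribution[["PIRA"]],
    delta_contrib_pira_conf =
      s$per_type_delta_contribution[["PIRA_RELAPSE_DURING_CONFIRMATION"]],
    delta_contrib_undefined = s$per_type_delta_contribution[["UNDEFINED"]],
    pira_only_rate = s$pira_only_rate,
    raw_only_rate = s$raw_only_rate,
    km_median_years = s$km_median_years,
    stringsAsFactors = FALSE
  )
}

#' Apply every definition of a grid to a cohort
#'
#' Annotates the cohort under each definition and returns one metrics row
#' per definition, keyed by the definition's axis values.
#'
#' @param cohort An `msaccrual_cohort`.
#' @param grid A list of `accrual_definition` objects (e.g. from
#'   [definition_grid()]).
#' @param include_undefined_in_tte Passed to [summarize_cohort()].
#' @return A data.frame of class `accrual_grid_summary`: the columns of
#'   [grid_to_df()] followed by the cohort metrics.
#' @export
summarize_grid <- function(cohort, grid, include_undefined_in_tte = TRUE) {
  stopifnot(length(grid) > 0)
  key <- grid_to_df(grid)
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    rows[[i]] <- tryCatch(
      summary_to_row(summarize_cohort(annotate_cohort(cohort, grid[[i]]),
                                      cohort, include_undefined_in_tte)),
      error = function(e) {
        stop(sprintf("definition %d (%s) failed: %s", i,
                     paste(unlist(key[i, -1]), collapse = ","),
                     conditionMessage(e)))
      })
  }
  out <- cbind(key, do.call(rbind, rows))
  rownames(out) <- NULL
  class(out) <- c("accrual_grid_summary", "data.frame")
  out
}

#' Min / mean / max of each metric across a definition grid
#'
#' @param grid_summary Result of [summarize_grid()].
#' @return A data.frame with one row per metric and columns `min`, `mean`,
#'   `max` (NA metrics dropped from the averages).
#' @export
grid_metric_ranges <- function(grid_summary) {
  metric_cols <- setdiff(names(grid_summary),
                         c(names(grid_to_df(list(accrual_definition())))))
  rows <- lapply(metric_cols, function(m) {
    v <- grid_summary[[m]]
    data.frame(metric = m,
               min = suppressWarnings(min(v, na.rm = TRUE)),
               mean = mean(v, na.rm = TRUE),
               max = suppressWarnings(max(v, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot metric distributions across a grid
#'
#' Simple panel of boxplots for the per-type rates and contributions
#' across the definitions of a grid summary.
#'
#' @param x An `accrual_grid_summary`.
#' @param which Character vector of metric column names to draw.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.accrual_grid_summary <- function(x,
                                      which = c("overall_event_rate",
                                                "rate_pira", "rate_raw",
                                                "count_contrib_pira",
                                                "count_contrib_raw"),
                                      ...) {
  which <- intersect(which, names(x))
  graphics::boxplot(as.data.frame(x)[, which, drop = FALSE],
                    las = 2, ylab = "fraction", ...)
  invisible(x)
}

#' Paired permutation test between two parameter choices
#'
#' Pairs every definition with `axis = value_a` to the definition
#' identical in all other axes with `axis = value_b` and tests whether the
#' chosen metric differs between the two choices with a two-sided
#' sign-flip permutation test on the paired differences. With at most 12
#' pairs all 2^n sign assignments are enumerated exactly; otherwise
#' `n_permutations` random assignments are drawn reproducibly from `seed`.
#'
#' @param grid_summary Result of [summarize_grid()].
#' @param axis Name of a definition axis column (e.g. `"baseline_mode"`).
#' @param value_a,value_b The two levels to compare (value of `axis`).
#' @param metric Name of the metric column to compare.
#' @param n_permutations Number of random sign assignments (ignored when
#'   the exact enumeration is used).
#' @param seed Integer seed for the random assignments.
#' @return A list: `p_value`, `mean_difference` (a minus b), `n_pairs`,
#'   `method` (`"exact"` or `"sampled"`).
#' @export
paired_parameter_test <- function(grid_summary, axis, value_a, value_b,
                                  metric = "overall_event_rate",
                                  n_permutations = 10000L, seed = 1L) {
  stopifnot(axis %in% names(grid_summary), metric %in% names(grid_summary))
  key_cols <- setdiff(
    names(grid_to_df(list(accrual_definition()))),
    c("config_id", axis))
  mk_key <- function(df) do.call(paste, c(df[key_cols], sep = "\r"))
  a <- grid_summary[grid_summary[[axis]] == value_a, , drop = FALSE]
  b <- grid_summary[grid_summary[[axis]] == value_b, , drop = FALSE]
  ka <- mk_key(a)
  kb <- mk_key(b)
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    stop("axis levels do not uniquely identify definitions within pairs")
  }
  orphans <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(orphans)) {
    stop("unmatched definition pair(s): ",
         paste(utils::head(gsub("\r", ",", orphans), 5), collapse = " | "))
  }
  d <- a[[metric]][order(ka)] - b[[metric]][order(kb)]
  d <- d[!is.na(d)]
  n <- length(d)
  if (n == 0) stop("no complete pairs with non-missing metric values")
  obs <- mean(d)
  tol <- 1e-12
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats <- abs(signs %*% d) / n
    p <- mean(stats >= abs(obs) - tol)
    method <- "exact"
  } else {
    set.seed(seed)
    stats <- replicate(n_permutations,
                       abs(mean(sample(c(-1, 1), n, replace = TRUE) * d)))
    p <- (1 + sum(stats >= abs(obs) - tol)) / (1 + n_permutations)
    method <- "sampled"
  }
  list(p_value = p, mean_difference = obs, n_pairs = n, method = method)
}

#' Leave-one-out cohort subsets by group label
#'
#' For sensitivity analyses by a grouping variable (typically the baseline
#' disease-modifying treatment), returns, for each group present in at
#' least `min_group` periods, the cohort with that group removed.
#'
#' @param periods An `msaccrual_cohort`.
#' @param group_field Name of the period field holding the label
#'   (default `"dmt_label"`).
#' @param min_group Minimum group size for a group to be left out.
#' @return A named list of `msaccrual_cohort` objects (one per qualifying
#'   group); empty when no label is present or no group qualifies.
#' @export
leave_one_out_groups <- function(periods, group_field = "dmt_label",
                                 min_group = 100L) {
  labels <- vapply(periods, function(p) {
    v <- p[[group_field]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
  tab <- table(labels[!is.na(labels)])
  keep <- names(tab)[tab >= min_group]
  out <- lapply(keep, function(g) {
    as_cohort(unclass(periods)[is.na(labels) | labels != g])
  })
  names(out) <- keep
  out
}
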