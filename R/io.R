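#' Read a cohort from assessment / relapse CSV files
#'
#' Schemas: assessments CSV with columns `patient_id`, `period_index`,
#' `day`, `edss`; relapses CSV with columns `patient_id`, `period_index`,
#' `day`. Days are integers relative to the period start; files are UTF-8,
#' comma-separated, dot-decimal. Validation findings are surfaced as
#' warnings in permissive mode; in strict mode any error finding aborts.
#'
#' @param assessments_path Path to the assessments CSV.
#' @param relapses_path Optional path to the relapses CSV; if `NULL` or
#'   missing, the cohort has zero relapses (with a warning).
#' @param permissive Logical; `TRUE` downgrades tolerable findings (e.g.
#'   EDSS 0.5) to warnings.
#' @param dmt_path Optional CSV `patient_id`, `period_index`, `dmt_label`.
#' @return An `msaccrual_cohort`.
#' @export
read_cohort <- function(assessments_path, relapses_path = NULL,
                        permissive = TRUE, dmt_path = NULL) {
  a <- utils::read.csv(assessments_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "period_index", "day", "edss")
  if (!all(need %in% names(a))) {
    stop("assessments file must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(a$edss))))
  if (length(bad)) {
    stop("non-numeric EDSS value in assessments row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  a$edss <- as.numeric(a$edss)
  bad <- which(!is.finite(suppressWarnings(as.numeric(a$day))))
  if (length(bad)) {
    stop("non-numeric day in assessments row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  a$day <- as.integer(a$day)

  r <- NULL
  if (is.null(relapses_path) || !file.exists(relapses_path)) {
    warning("no relapse file: cohort read with zero relapses")
  } else {
    r <- utils::read.csv(relapses_path, stringsAsFactors = FALSE)
    if (!all(c("patient_id", "period_index", "day") %in% names(r))) {
      stop("relapses file must have columns: patient_id, period_index, day")
    }
    r$day <- as.integer(r$day)
  }
  dmt <- if (!is.null(dmt_path)) {
    utils::read.csv(dmt_path, stringsAsFactors = FALSE)
  } else NULL

  keys <- unique(a[c("patient_id", "period_index")])
  periods <- lapply(seq_len(nrow(keys)), function(i) {
    pid <- keys$patient_id[i]
    px <- keys$period_index[i]
    ai <- a[a$patient_id == pid & a$period_index == px, , drop = FALSE]
    rl <- if (is.null(r)) integer() else
      r$day[r$patient_id == pid & r$period_index == px]
    lab <- NA_character_
    if (!is.null(dmt)) {
      m <- dmt$dmt_label[dmt$patient_id == pid & dmt$period_index == px]
      if (length(m)) lab <- m[1]
    }
    followup_period(pid, ai$day, ai$edss, rl, period_index = px,
                    dmt_label = lab)
  })
  for (p in periods) {
    f <- validate_period(p, permissive = permissive)
    err <- f$message[f$severity == "error"]
    wrn <- f$message[f$severity == "warning"]
    where <- sprintf("patient %s period %d", p$patient_id, p$period_index)
    if (length(err) && !permissive) {
      stop(where, ": ", paste(err, collapse = "; "))
    }
    for (m in c(err, wrn)) warning(where, ": ", m)
  }
  as_cohort(periods)
}

#' Write a cohort to assessment / relapse CSV files
#'
#' Inverse of [read_cohort()]: write-then-read round trips are lossless
#' for the assessment and relapse schemas.
#'
#' @param cohort An `msaccrual_cohort`.
#' @param assessments_path,relapses_path Output CSV paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_cohort <- function(cohort, assessments_path, relapses_path) {
  a <- do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$patient_id, period_index = p$period_index,
               day = p$assessments$day, edss = p$assessments$edss,
               stringsAsFactors = FALSE)
  }))
  r <- do.call(rbind, lapply(cohort, function(p) {
    if (!length(p$relapses)) return(NULL)
    data.frame(patient_id = p$patient_id, period_index = p$period_index,
               day = p$relapses, stringsAsFactors = FALSE)
  }))
  utils::write.csv(a, assessments_path, row.names = FALSE, quote = FALSE)
  if (is.null(r)) {
    r <- data.frame(patient_id = character(), period_index = integer(),
                    day = integer())
  }
  utils::write.csv(r, relapses_path, row.names = FALSE, quote = FALSE)
  invisible(list(assessments = assessments_path, relapses = relapses_path))
}

#' Write annotation results to CSV
#'
#' @param annotations Data.frame from [annotate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced an output: package version, timestamp, seed(s),
#' the MD5 of the definition file and of every input file. Identical
#' manifests (ignoring the timestamp) imply identical outputs because the
#' annotation engine is deterministic.
#'
#' @param path Output JSON path.
#' @param config_path Optional definition file to digest.
#' @param input_paths Character vector of input files to digest.
#' @param seed Optional integer seed used by the run.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, config_path = NULL,
                               input_paths = character(), seed = NULL) {
  digest_of <- function(p) unname(tools::md5sum(p))
  manifest <- list(
    package = "msaccrual",
    version = as.character(utils::packageVersion("msaccrual")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config_md5 = if (!is.null(config_path)) digest_of(config_path),
    inputs = if (length(input_paths)) {
      stats::setNames(as.list(vapply(input_paths, digest_of, character(1))),
                      basename(input_paths))
    }
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null")
  invisible(manifest)
}
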