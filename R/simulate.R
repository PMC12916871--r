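#' Parameters for the synthetic-cohort generator
#'
#' The generator emulates the structure of registry follow-up data:
#' latent disability is a step function (relapse residuals plus
#' relapse-independent progression steps), visits sample it on an
#' irregular schedule with optional half-point measurement jitter, and
#' relapses are a homogeneous Poisson process recorded independently of
#' visit days. Defaults are chosen to resemble a treated relapsing-MS
#' registry cohort: around 13 visits over a median 4-year follow-up, a
#' relapse hazard putting roughly 38% of 4.3-year periods at one or more
#' relapses (rate 0.113/year), and progression steps rare enough that a
#' quarter of periods worsen.
#'
#' @param n_patients Number of patients (one period each).
#' @param followup_years Length-2 range; each patient's follow-up duration
#'   is drawn uniformly from it.
#' @param visit_interval_days Length-2 `c(mean, jitter)`: inter-visit
#'   intervals are uniform in `mean +/- jitter` days (floored at 14).
#' @param baseline_edss_levels,baseline_edss_probs Support and weights of
#'   the baseline EDSS distribution.
#' @param relapse_rate Relapses per year (Poisson intensity).
#' @param p_residual Probability a relapse leaves residual disability.
#' @param residual_step Residual step size (EDSS points, multiple of 0.5).
#' @param pira_rate Relapse-independent progression steps per year.
#' @param pira_step Progression step size (EDSS points, multiple of 0.5).
#' @param noise_p Probability a visit's score is jittered by +/-0.5.
#' @param transient_relapse_peak Logical; if `TRUE` every relapse adds a
#'   transient elevation that resolves before the post-relapse window
#'   closes, exercising RAW-window logic without permanent disability.
#' @param peak_height Transient elevation (EDSS points).
#' @param peak_days Duration of the transient elevation (days); keep below
#'   the post-relapse window of the definitions under study.
#' @param seed Optional integer seed (applied inside
#'   [generate_cohort()]).
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_patients = 200L,
                              followup_years = c(2, 6),
                              visit_interval_days = c(120, 40),
                              baseline_edss_levels = c(0, 1, 1.5, 2, 2.5,
                                                       3, 3.5, 4, 5, 6),
                              baseline_edss_probs = c(0.08, 0.20, 0.10,
                                                      0.25, 0.10, 0.12,
                                                      0.06, 0.05, 0.03,
                                                      0.01),
                              relapse_rate = 0.113,
                              p_residual = 0.4,
                              residual_step = 1.0,
                              pira_rate = 0.06,
                              pira_step = 1.0,
                              noise_p = 0.1,
                              transient_relapse_peak = TRUE,
                              peak_height = 1.5,
                              peak_days = 30L,
                              seed = NULL) {
  p <- list(n_patients = as.integer(n_patients),
            followup_years = as.numeric(followup_years),
            visit_interval_days = as.numeric(visit_interval_days),
            baseline_edss_levels = baseline_edss_levels,
            baseline_edss_probs = baseline_edss_probs /
              sum(baseline_edss_probs),
            relapse_rate = relapse_rate, p_residual = p_residual,
            residual_step = residual_step, pira_rate = pira_rate,
            pira_step = pira_step, noise_p = noise_p,
            transient_relapse_peak = isTRUE(transient_relapse_peak),
            peak_height = peak_height, peak_days = as.integer(peak_days),
            seed = seed)
  stopifnot(p$n_patients > 0,
            length(p$followup_years) == 2,
            p$followup_years[1] > 0,
            p$followup_years[1] <= p$followup_years[2],
            p$visit_interval_days[1] > 0,
            p$relapse_rate >= 0, p$pira_rate >= 0,
            p$p_residual >= 0, p$p_residual <= 1,
            p$noise_p >= 0, p$noise_p <= 1,
            (p$residual_step * 2) == round(p$residual_step * 2),
            (p$pira_step * 2) == round(p$pira_step * 2),
            all(is_valid_edss(p$baseline_edss_levels)),
            length(p$baseline_edss_levels) ==
              length(p$baseline_edss_probs))
  if (p$visit_interval_days[1] > 365 * p$followup_years[1]) {
    stop("visit interval longer than the shortest follow-up: no visits")
  }
  structure(p, class = "simulation_params")
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws one follow-up period per patient. Latent disability starts at a
#' baseline EDSS and increases stepwise: each relapse leaves a residual
#' step with probability `p_residual`, and relapse-independent progression
#' steps arrive as a Poisson process. Visits sample the latent value
#' (plus any transient relapse peak) with optional half-point jitter and
#' snapping to the valid EDSS grid. With `noise_p = 0` and
#' `transient_relapse_peak = FALSE`, the cumulated ground-truth steps
#' reconstruct every emitted score exactly.
#'
#' @param params A [simulation_params()] object.
#' @return A list with elements `cohort` (an `msaccrual_cohort`) and
#'   `truth`: per period, data.frames `relapses` (`day`, `residual_step`)
#'   and `pira_steps` (`day`, `step`).
#' @export
#' @examples
#' sim <- generate_cohort(simulation_params(n_patients = 5, seed = 1))
#' sim$cohort
generate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  periods <- vector("list", params$n_patients)
  truth <- vector("list", params$n_patients)
  for (i in seq_len(params$n_patients)) {
    fy <- stats::runif(1, params$followup_years[1], params$followup_years[2])
    T_days <- round(fy * DAYS_PER_YEAR)
    # visit schedule
    m <- params$visit_interval_days[1]
    j <- params$visit_interval_days[2]
    visits <- 0L
    while (visits[length(visits)] < T_days) {
      step <- max(14, round(stats::runif(1, m - j, m + j)))
      visits <- c(visits, visits[length(visits)] + step)
    }
    visits <- visits[visits <= T_days]
    if (length(visits) < 2) visits <- c(0L, T_days)

    baseline <- params$baseline_edss_levels[
      sample.int(length(params$baseline_edss_levels), 1,
                 prob = params$baseline_edss_probs)]

    n_rel <- stats::rpois(1, params$relapse_rate * fy)
    relapse_days <- sort(round(stats::runif(n_rel, 1, T_days)))
    residual <- stats::rbinom(length(relapse_days), 1, params$p_residual) *
      params$residual_step

    n_pira <- stats::rpois(1, params$pira_rate * fy)
    pira_days <- sort(round(stats::runif(n_pira, 1, T_days)))

    latent_at <- function(d) {
      baseline +
        sum(residual[relapse_days <= d]) +
        params$pira_step * sum(pira_days <= d)
    }
    peak_at <- function(d) {
      if (!params$transient_relapse_peak || !length(relapse_days)) return(0)
      if (any(d >= relapse_days & d <= relapse_days + params$peak_days)) {
        params$peak_height
      } else 0
    }
    scores <- vapply(visits, function(d) {
      x <- latent_at(d) + peak_at(d)
      if (params$noise_p > 0 && stats::runif(1) < params$noise_p) {
        x <- x + sample(c(-0.5, 0.5), 1)
      }
      snap_edss(x)
    }, numeric(1))

    periods[[i]] <- followup_period(
      patient_id = sprintf("sim%04d", i),
      days = visits, edss = scores, relapse_days = relapse_days,
      period_index = 1L
    )
    truth[[i]] <- list(
      relapses = data.frame(day = relapse_days, residual_step = residual),
      pira_steps = data.frame(
        day = pira_days,
        step = rep(params$pira_step, length(pira_days)))
    )
  }
  list(cohort = as_cohort(periods), truth = truth)
}
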