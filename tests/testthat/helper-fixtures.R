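# Shorthand period builder: mk_period(days, edss, relapses)
mk_period <- function(days, edss, relapses = integer(), id = "p1") {
  followup_period(id, days = days, edss = edss, relapse_days = relapses)
}

# Random small follow-up period with unrestricted EDSS jumps: deliberately
# rougher than real trajectories so that the engine's edge cases
# (re-baselining, window overlap, confirmation failure) are all exercised.
random_period <- function(n_range = c(4L, 9L), max_relapses = 3L,
                          horizon = 900L) {
  n <- sample(seq(n_range[1], n_range[2]), 1)
  days <- sort(sample(0:horizon, n))
  days <- days - days[1]
  edss <- sample(edss_levels(), n, replace = TRUE)
  nr <- sample(0:max_relapses, 1)
  relapses <- if (nr) sort(sample(seq(-60L, horizon + 60L), nr)) else integer()
  mk_period(days, edss, relapses)
}

# Random definition drawn uniformly from the legal space (the allow flag
# only where a last-confirmed mode permits it).
random_definition <- function() {
  mode <- sample(c("none", "w12_all", "w12_last", "w24_all", "w24_last",
                   "sustained", "sustained_min12", "sustained_min24"), 1)
  allow <- mode %in% c("w12_last", "w24_last") && runif(1) < 0.5
  accrual_definition(
    event_merging = runif(1) < 0.5,
    undefined_mode = sample(c("rebaselining_only", "never", "all", "end"), 1),
    undefined_constraint = sample(c("greater_only", "equal_or_greater",
                                    "unconstrained"), 1),
    baseline_mode = sample(c("fixed", "roving_next_confirmed"), 1),
    confirmation_mode = mode,
    raw_window = list(c(30L, 30L), c(30L, 90L), c(90L, 90L))[[sample(3, 1)]],
    allow_relapse_in_confirmation = allow,
    confirmation_score_handling = sample(c("use_all",
                                           "skip_relapse_proximal"), 1)
  )
}
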