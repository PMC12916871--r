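# msaccrual

Configurable annotation of EDSS disability accrual in relapsing
multiple sclerosis.

## What it does and who it is for

In relapsing MS, confirmed worsening on the Expanded Disability Status
Scale (EDSS, ordinal 0–10 in half-point steps) is attributed either to
incomplete relapse recovery (**RAW**, relapse-associated worsening) or
to relapse-independent progression (**PIRA**). Published studies differ
in nearly every definitional detail — minimal increase, fixed versus
roving baseline, confirmation requirement, relapse-proximity window,
re-baselining, handling of ambiguous events — and those choices move
event rates and RAW/PIRA attribution substantially. `msaccrual` is for
MS epidemiologists and registry analysts who need to (a) annotate
longitudinal EDSS trajectories under an explicit, fully specified
definition, and (b) quantify how results change across the whole
definitional space.

The core algorithm scans each follow-up period left to right against a
maintained reference score. An assessment is a worsening candidate when

    score >= reference + Δmin(reference),   Δmin = 1.5 / 1.0 / 0.5
                                            for reference 0 / <5.5 / >=5.5

Candidates are confirmed per the configured rule (none; all or only the
last score up to the first assessment ≥ 84/168 days away; sustained to
end of follow-up), with the confirmed **event score** equal to the
minimum over candidate and confirmation scores. Confirmed events are
classified as RAW (inside the relapse window, e.g. 30 days before to 90
days after a relapse), PIRA (outside, clean confirmation), **PIRA with
relapse during confirmation**, or **undefined worsening** (at a
post-relapse re-baselining assessment). After each event the event score
becomes the new reference; post-relapse residual disability re-baselines
without confirmation; a roving baseline additionally tracks confirmed
improvement. Crossing all tested axes yields 1440 definition variants,
with 360 remaining under the harmonized and 144 under the standardized
PIRA proposals.

## Worked example

Annotate a single follow-up period under a 12-week last-confirmed
definition:

```r
library(msaccrual)
fp <- followup_period("patient-07", days = c(0, 30, 120, 210, 300, 420),
                      edss = c(3.0, 3.0, 4.5, 4.0, 4.0, 4.0),
                      relapse_days = 380)
annotate_followup(fp, accrual_definition(confirmation_mode = "w12_last"))
#>   detection_day event_type reference_score event_score delta_edss
#> 1           120       PIRA               3           4          1
#>   confirmation_days merged_from
#> 1               210           1
```

The rise from 3.0 to 4.5 at day 120 is confirmed by the 4.0 at day 210
(the first assessment ≥ 84 days later); the event score is the
confirmed minimum 4.0, so the event contributes ΔEDSS = 1.0 measured
from reference 3.0. The relapse at day 380 is too late to make the event
relapse-associated.

Cohort level, on a simulated registry-like cohort:

```r
sim <- generate_cohort(simulation_params(n_patients = 150, seed = 42))
def <- accrual_definition(confirmation_mode = "w12_last",
                          baseline_mode = "roving_next_confirmed")
ann <- annotate_cohort(sim$cohort, def)
summarize_cohort(ann, sim$cohort)
#> Cohort summary: 150 periods, 37 events (total dEDSS 38.5)
#>   overall event rate: 20.7%
#>   RAW                                rate   4.7% | count  18.9% | dEDSS  18.2%
#>   PIRA                               rate  11.3% | count  59.5% | dEDSS  58.4%
#>   PIRA_RELAPSE_DURING_CONFIRMATION   rate   0.0% | count   0.0% | dEDSS   0.0%
#>   UNDEFINED                          rate   5.3% | count  21.6% | dEDSS  23.4%
#>   PIRA-only 51.6%, RAW-only 22.6% of event-bearing periods
#>   KM median time to first event: not reached
```

20.7% of periods worsen under this definition, and PIRA carries most of
the accrued EDSS change; the median time to first event is not reached
because fewer than half of the periods ever have an event. Sweep a
definition grid and reduce:

```r
gs <- summarize_grid(sim$cohort, definition_grid("standardized")[1:12])
grid_metric_ranges(gs)[c(4, 6, 9, 10), ]
#>                metric        min      mean       max
#> 4  overall_event_rate 0.20000000 0.2033333 0.2066667
#> 6           rate_pira 0.11333333 0.1155556 0.1200000
#> 9   count_contrib_raw 0.08333333 0.1505255 0.1891892
#> 10 count_contrib_pira 0.59459459 0.6119870 0.6388889
```

Even within the standardized preset the RAW share of events spans
8–19% on this cohort, driven by the remaining free axes. Use
`paired_parameter_test()` to test one axis while holding all others
fixed, and `leave_one_out_groups()` for treatment-group sensitivity
analyses.

A command-line front end wrapping the same functions is installed at
`system.file("cli", "msaccrual.R", package = "msaccrual")` with
subcommands `annotate`, `grid`, `metrics`, `simulate` and `validate`.

## Documentation

The methods vignette
(`vignettes/annotating-disability-accrual.Rmd`) describes the scan
semantics, every definitional axis with defaults and units, the
synthetic-cohort generator and its limits, and the design decisions
taken where published definitions are underspecified.
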