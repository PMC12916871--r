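---
title: "Annotating EDSS disability accrual: model, definitional axes, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating EDSS disability accrual}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msaccrual)
```

## The problem

In relapsing multiple sclerosis, disability measured on the Expanded
Disability Status Scale (EDSS, ordinal 0–10 in half-point steps, no 0.5
level) accumulates through two mechanisms: incomplete recovery from
relapses (relapse-associated worsening, RAW) and slow worsening without
relapse activity (progression independent of relapse activity, PIRA).
Whether a given confirmed EDSS increase counts as an event at all — and
whether it is RAW or PIRA — depends on a surprisingly long list of
definitional choices: the minimal increase required, fixed versus roving
reference, the confirmation requirement, the width of the
relapse-proximity window, how the reference is reset after events and
relapses, and what to do with events that fit neither category. This
package implements the full definitional space as configurable axes so
that event rates and RAW/PIRA attributions can be compared across
definitions on the same cohort.

## The annotation procedure

Each follow-up period is scanned left to right while a *reference* score
is maintained:

1. **Reference initialisation.** The reference is the first assessment's
   score.
2. **Candidate test.** An assessment with score
   `s >= reference + minimal_required_increase(reference)` is a worsening
   candidate. The required increase is 1.5 points from reference 0, 1.0
   below 5.5, and 0.5 at 5.5 or above.
3. **Confirmation.** Depending on the definition: none; all or only the
   last score up to the first assessment at ≥ 84/168 days; or sustained
   to the end of follow-up (optionally with ≥ 84/168 days of post-event
   follow-up). All checks use the condition
   `score >= reference + minimal increase`; the confirmed *event score*
   is the minimum over the candidate and every score that entered the
   check, so an increase from 3.0 to 4.5 confirmed by 4.0 yields an
   event score of 4.0 and a delta of 1.0.
4. **Classification.** A confirmed candidate inside the relapse window
   (inclusive on both edges, windows of several relapses unioned) is RAW.
   A candidate at a post-relapse re-baselining assessment — the first
   visit after a relapse's post-window that is outside every window — is
   an undefined-worsening candidate. A clean candidate whose confirmation
   score lies inside a relapse window is *PIRA with relapse during
   confirmation*, unless the definition allows such relapses (then plain
   PIRA) or skips relapse-proximal scores from the confirmation set
   before checking (the confirmation implementation of the standardized
   proposal). Everything else is PIRA.
5. **Re-baselining.** After a RAW/PIRA event the confirmed event score
   becomes the new reference. At a post-relapse re-baselining assessment,
   residual disability above the reference becomes the new reference
   *without* confirmation. Under a roving baseline, a score strictly
   below the reference becomes the new reference once the immediately
   following assessment does not exceed it ("next-confirmed").
6. **Merging (optional).** Consecutive events of the same type with no
   intervening stabilization fuse into one event whose delta is the last
   event score minus the first reference score.

```{r}
fp <- followup_period("example", days = c(0, 30, 120, 210, 300),
                      edss = c(3.0, 3.0, 4.5, 4.0, 4.0))
annotate_followup(fp, accrual_definition(confirmation_mode = "w12_last"))
```

## The definitional grid

Crossing event merging (2), undefined-event mode (4), undefined
constraint (3), baseline mode (2), confirmation mode with the
relapse-in-confirmation flag (10 legal combinations), and relapse window
(3) yields 1440 definitions. The harmonized sub-grid (360) fixes merging
off and the roving next-confirmed baseline; the standardized sub-grid
(144) fixes the confirmation dimension. Because the proposals pin these
values down only in supplementary sources, the presets here are
*reconstructed*: the harmonized preset keeps merging off with a roving
baseline, and the standardized preset uses 12-week last-confirmed
confirmation without relapses in the confirmation interval; both are
overridable through the `fix` argument of `definition_grid()`.

```{r}
length(definition_grid("full"))
length(definition_grid("harmonized"))
length(definition_grid("standardized"))
```

## Units and time conversions

Time is integer days relative to the period start; 12 weeks = 84 days,
24 weeks = 168 days, one year = 365 days, 24 months = 730 days. These
conversions are fixed so that runs are reproducible across data sources
that store calendar dates. Eligibility defaults mirror common registry
inclusion rules: span ≥ 730 days, ≥ 3 EDSS scores, and "at least one
assessment per year" read as a *rolling* rule (no inter-assessment gap
above 365 days), which is stricter and deterministic compared with a
calendar-year reading. Maximal eligible windows are grown greedily from
the left; ties break toward the earlier start.

## Numerical and degenerate-input choices

* EDSS values are multiples of 0.5 and therefore exact in double
  precision; all comparisons are exact, no tolerance is applied.
* Duplicate assessment days keep the last record and warn — registries
  occasionally double-enter visits, and determinism requires a rule.
* The strict validator rejects EDSS 0.5 (not a standard scale level);
  permissive mode accepts it with a warning because registry data
  contain entry errors.
* A candidate at the final visit with a confirmation-requiring
  definition is never an event (there is nothing to confirm); with
  `confirmation_mode = "none"` final-visit candidates count, which keeps
  the unconfirmed mode meaningful.
* When no assessment exists inside a relapse's window, residual
  disability is read directly at the re-baselining assessment (the first
  post-window visit).
* A relapse on the same day as an assessment places that assessment
  inside the window (the conservative, inclusive reading of "within x
  days").
* Relapses up to 90 days before the period start or after its end (the
  widest window in the grid) are retained as context so that early and
  late assessments classify identically however the period was cut.

## Design decisions in genuinely open territory

**Undefined-event constraint.** The three constraint labels are
implemented as a gate comparing the re-baselining assessment's score to
the previous reference (`greater_only`: strictly greater;
`equal_or_greater`; `unconstrained`: magnitude rule alone), *on top of*
the magnitude rule that every candidate must pass. Under the
reference-dependent magnitude rule the first two gates are then
automatically satisfied, making this axis inert in the default engine;
it is kept as a separately enumerated axis and isolated behind one
predicate (`undefined_gate()`) because the comparison semantics are the
least standardised aspect of the definitional space and may need
revision against other implementations.

**"All" and "end" undefined modes.** In this classification every
confirmed candidate away from a re-baselining assessment receives a
RAW/PIRA/PIRA-with-relapse label, so no event "fails both" criteria
elsewhere; consequently `all` and `end` coincide behaviourally with
`rebaselining_only`, and only `never` differs (identical RAW/PIRA lists
with zero undefined events — a property the engine test-suite asserts on
thousands of random periods).

**Reference after an undefined event.** At a re-baselining assessment
the reference is reset to the assessment's residual score rather than to
the confirmed minimum. This is what makes the `never` and
`rebaselining_only` modes agree on all downstream RAW/PIRA events: the
residual rule is applied identically whether or not the undefined event
was emitted.

**Roving reference.** The default roving rule is "next-confirmed": an
improvement becomes the reference only when the immediately following
assessment does not exceed it. An unconfirmed improvement (next score
higher) leaves the reference unchanged.

**Time-to-first-event.** The clock starts at the detection day of the
first event of any type by default; undefined events can be excluded
with `include_undefined_in_tte = FALSE`, since definitions disagree on
whether they represent true worsening. Kaplan–Meier estimation censors
event-free periods at their last assessment; with no censoring the KM
median provably equals the naive median, which the tests assert.
Permutation comparisons between parameter choices are two-sided
sign-flip tests on paired per-definition differences, enumerated exactly
up to 12 pairs and sampled reproducibly from a seed beyond that.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` draws latent disability as a *step function*:
baseline EDSS from a registry-like distribution (median 2.0), relapses
as a Poisson process (default 0.113/year, putting roughly 38% of
4.3-year periods at ≥ 1 relapse), residual steps with probability 0.4,
relapse-independent progression steps at 0.06/year, irregular visits
every 120 ± 40 days (about 13 per 4-year period), optional ± 0.5
measurement jitter, and an optional transient relapse peak that resolves
within 30 days so that relapse-window logic is exercised without
permanent disability. A step model (rather than drift) was chosen so
that ground-truth events are unambiguous: with zero noise every emitted
score is exactly the cumulated truth, and under dense noise-free
observation every true progression step maps to a detected PIRA event —
properties the test-suite checks.

The generator targets structural realism, not cohort replication: it
does not model EDSS measurement error structure (inter-rater
variability is not ± 0.5 uniform), treatment switches, relapse-severity
heterogeneity, floor/ceiling dynamics near EDSS 0 and 10, or informative
visit timing (patients presenting *because* they worsen). Passing tests
therefore demonstrate the correctness of the annotation machinery on
trajectories with known truth, not that any particular real-world event
rate will be reproduced.

## Problem sizes used by the test-suite

The bundled checks run the engine against an independently written
brute-force annotator on 10,000 random small periods across 100 random
definitions, verify the structural properties (relapse-free ⇒ all PIRA;
`never` ≡ `rebaselining_only` on RAW/PIRA; no relapse-during-confirmation
labels without a confirmation set; monotonicity of first-candidate
confirmation across confirmation strictness) on 1,000 random periods
each, and validate simulator recovery on 50 noise-free densely observed
patients. These sizes give comfortable coverage of the edge cases
(window overlap, deferred re-baselining, boundary days) while keeping a
full run in the low minutes on one core.

## Known limitations

* Only EDSS is supported; definitions built on the timed 25-foot walk,
  9-hole peg test or composite endpoints are out of scope.
* MRI-aware classification (progression independent of relapse *and MRI*
  activity) is not implemented.
* The harmonized/standardized presets are reconstructions (see above);
  users replicating a specific published definition should set every
  axis explicitly rather than rely on a preset.
* Relapse records carry only an onset day; severity and recovery are not
  modelled in classification beyond the proximity window.
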