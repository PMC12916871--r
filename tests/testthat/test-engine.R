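test_that("minimal required increase follows the reference-dependent rule", {
  expect_identical(minimal_required_increase(0), 1.5)
  expect_identical(minimal_required_increase(3.0), 1.0)
  expect_identical(minimal_required_increase(6.0), 0.5)
  expect_identical(minimal_required_increase(5.0), 1.0)
  expect_identical(minimal_required_increase(5.5), 0.5)
  expect_error(minimal_required_increase(3.25), "invalid")
})

test_that("RAW window membership is an inclusive union over relapses", {
  expect_true(in_raw_window(75, 100, c(30, 90)))
  expect_false(in_raw_window(69, 100, c(30, 90)))
  expect_true(in_raw_window(70, 100, c(30, 90)))  # boundary inclusive
  expect_true(in_raw_window(190, 100, c(30, 90))) # boundary inclusive
  expect_true(in_raw_window(100, 100, c(30, 90))) # same-day assessment
  # union of [70,130] and [370,430] leaves 150 outside
  expect_false(in_raw_window(150, c(100, 400), c(30, 30)))
  expect_identical(in_raw_window(c(80, 150, 400), c(100, 400), c(30, 30)),
                   c(TRUE, FALSE, TRUE))
  expect_false(any(in_raw_window(c(0, 50), integer(), c(30, 90))))
})

test_that("post-relapse re-baselining picks the first out-of-window visit", {
  expect_identical(
    post_relapse_rebaseline_day(100, c(95, 150, 200), 100, c(30, 90)), 200L)
  expect_identical(
    post_relapse_rebaseline_day(100, c(95, 150), 100, c(30, 90)),
    NA_integer_)
  # overlapping windows defer the re-baselining assessment: with relapses
  # at 100 and 260 (windows [70,190] and [230,350]), day 240 is inside the
  # second window, so the first eligible visit after day 190 is day 200;
  # had 200 not existed, 380 would be it
  expect_identical(
    post_relapse_rebaseline_day(100, c(200, 240, 380), c(100, 260),
                                c(30, 90)), 200L)
  expect_identical(
    post_relapse_rebaseline_day(100, c(240, 300, 380), c(100, 260),
                                c(30, 90)), 380L)
})

test_that("confirmation computes the confirmed minimum event score", {
  # an increase from 3.0 to 4.5 confirmed by 4.0 has event score 4.0
  fp <- mk_period(c(0, 60, 150), c(3.0, 4.5, 4.0))
  cf <- confirm_event(fp, 2, 3.0,
                      accrual_definition(confirmation_mode = "w12_last"))
  expect_true(cf$confirmed)
  expect_identical(cf$event_score, 4.0)

  # no confirmation required: event score is the candidate score
  cf0 <- confirm_event(mk_period(c(0, 60), c(3.0, 4.0)), 2, 3.0,
                       accrual_definition(confirmation_mode = "none"))
  expect_true(cf0$confirmed)
  expect_identical(cf0$event_score, 4.0)

  # all-confirmed: every score up to the first at >= 84 days must reach
  # reference + 1.0; a 3.5 in the interval fails the check
  fp2 <- mk_period(c(0, 60, 100, 160), c(3.0, 4.5, 4.5, 3.5))
  cf2 <- confirm_event(fp2, 2, 3.0,
                       accrual_definition(confirmation_mode = "w12_all"))
  expect_false(cf2$confirmed)
  # last-confirmed ignores intermediate scores but here the score at the
  # distance itself fails
  cf2l <- confirm_event(fp2, 2, 3.0,
                        accrual_definition(confirmation_mode = "w12_last"))
  expect_false(cf2l$confirmed)

  # candidate at the last visit is never confirmed when confirmation is on
  fp3 <- mk_period(c(0, 200), c(3.0, 4.5))
  expect_false(confirm_event(fp3, 2, 3.0, accrual_definition())$confirmed)

  # sustained requires every later score to qualify until end of follow-up
  fp4 <- mk_period(c(0, 60, 400, 800), c(3.0, 4.0, 4.0, 4.5))
  expect_true(confirm_event(
    fp4, 2, 3.0, accrual_definition(confirmation_mode = "sustained"))$confirmed)
  expect_true(confirm_event(
    fp4, 2, 3.0,
    accrual_definition(confirmation_mode = "sustained_min24"))$confirmed)
  fp5 <- mk_period(c(0, 60, 100), c(3.0, 4.0, 4.0))
  expect_true(confirm_event(
    fp5, 2, 3.0, accrual_definition(confirmation_mode = "sustained"))$confirmed)
  expect_false(confirm_event(
    fp5, 2, 3.0,
    accrual_definition(confirmation_mode = "sustained_min12"))$confirmed)
})

test_that("relapse-proximal confirmation is flagged or skipped", {
  # candidate at day 180 outside windows; the only confirmation score sits
  # inside the next relapse's window
  fp <- mk_period(c(0, 180, 290), c(2.0, 3.0, 3.0), relapses = 300)
  def <- accrual_definition(confirmation_mode = "w12_last",
                            raw_window = c(30, 90))
  cf <- confirm_event(fp, 2, 2.0, def)
  expect_true(cf$confirmed)
  expect_true(cf$relapse_in_confirmation)
  expect_identical(
    classify_event(180, cf, fp, def, integer()),
    "PIRA_RELAPSE_DURING_CONFIRMATION")

  # allowing relapses in the confirmation interval keeps the PIRA label
  def_allow <- accrual_definition(confirmation_mode = "w12_last",
                                  allow_relapse_in_confirmation = TRUE)
  expect_identical(classify_event(180, cf, fp, def_allow, integer()), "PIRA")

  # the standardized confirmation implementation drops relapse-proximal
  # scores from the confirmation set entirely: no eligible score remains
  def_skip <- accrual_definition(
    confirmation_mode = "w12_last",
    confirmation_score_handling = "skip_relapse_proximal")
  expect_false(confirm_event(fp, 2, 2.0, def_skip)$confirmed)

  # with a later clean score the skip variant confirms on it
  fp2 <- mk_period(c(0, 180, 290, 420), c(2.0, 3.0, 3.0, 3.0),
                   relapses = 300)
  cf2 <- confirm_event(fp2, 2, 2.0, def_skip)
  expect_true(cf2$confirmed)
  expect_identical(cf2$confirmation_days, 420L)
  expect_false(cf2$relapse_in_confirmation)
})

test_that("event classification covers RAW, PIRA and re-baselining days", {
  fp <- mk_period(c(0, 160, 260, 350), c(2.0, 3.5, 3.5, 3.5),
                  relapses = 150)
  def <- accrual_definition(confirmation_mode = "none")
  cf <- list(confirmed = TRUE, event_score = 3.5,
             confirmation_days = integer(), relapse_in_confirmation = FALSE)
  rb <- 260L
  expect_identical(classify_event(160, cf, fp, def, rb), "RAW")
  expect_identical(classify_event(260, cf, fp, def, rb), "UNDEFINED")
  expect_identical(classify_event(350, cf, fp, def, rb), "PIRA")
})

test_that("the scan detects, classifies and re-baselines as specified", {
  # constant trajectory: no candidates
  flat <- mk_period(seq(0, 900, by = 100), rep(2, 10))
  expect_identical(nrow(annotate_followup(flat, accrual_definition())), 0L)

  # worked example: 3.0 3.0 4.5 4.0 4.0 with 12-week last-confirmed
  fp <- mk_period(c(0, 30, 120, 210, 300), c(3.0, 3.0, 4.5, 4.0, 4.0))
  ev <- annotate_followup(fp, accrual_definition(confirmation_mode = "w12_last"))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$event_type, "PIRA")
  expect_identical(ev$reference_score, 3.0)
  expect_identical(ev$event_score, 4.0)
  expect_identical(ev$delta_edss, 1.0)
  expect_identical(ev$detection_day, 120L)

  # relapse at 150 (window [120,240]): the 3.5 at day 160 is RAW; the
  # re-baselining assessment at day 260 equals the current reference and
  # is not an event
  fp2 <- mk_period(c(0, 160, 260, 350), c(2.0, 3.5, 3.5, 3.5),
                   relapses = 150)
  ev2 <- annotate_followup(fp2, accrual_definition(
    confirmation_mode = "none", undefined_mode = "rebaselining_only"))
  expect_identical(ev2$event_type, "RAW")
  expect_identical(nrow(ev2), 1L)

  # residual disability at the re-baselining assessment that itself
  # satisfies the magnitude rule: UNDEFINED under rebaselining_only,
  # absent under never, with identical RAW/PIRA output
  fp3 <- mk_period(c(0, 100, 260, 350, 500), c(2.0, 2.0, 3.5, 3.5, 3.5),
                   relapses = 150)
  ev_rb <- annotate_followup(fp3, accrual_definition(
    confirmation_mode = "none", undefined_mode = "rebaselining_only"))
  ev_nv <- annotate_followup(fp3, accrual_definition(
    confirmation_mode = "none", undefined_mode = "never"))
  expect_identical(ev_rb$event_type, "UNDEFINED")
  expect_identical(ev_rb$detection_day, 260L)
  expect_identical(nrow(ev_nv), 0L)
})

test_that("reference updates follow event, residual and roving rules", {
  # confirmed event score becomes the new baseline: a second identical
  # increase is measured against 4.0, not 3.0
  fp <- mk_period(c(0, 60, 150, 240, 330, 420),
                  c(3.0, 4.5, 4.0, 5.0, 5.0, 5.0))
  ev <- annotate_followup(fp, accrual_definition(confirmation_mode = "w12_last"))
  expect_identical(ev$reference_score, c(3.0, 4.0))
  expect_identical(ev$event_score, c(4.0, 5.0))

  # post-relapse residual disability re-baselines without confirmation:
  # 2.0 -> relapse -> 2.5 residual (below the magnitude rule, no event),
  # later 3.5 is PIRA with reference 2.5
  fp2 <- mk_period(c(0, 100, 260, 400, 500), c(2.0, 2.0, 2.5, 3.5, 3.5),
                   relapses = 150)
  ev2 <- annotate_followup(fp2, accrual_definition(
    confirmation_mode = "w12_last"))
  expect_identical(ev2$event_type, "PIRA")
  expect_identical(ev2$reference_score, 2.5)

  # roving next-confirmed: 3.0 3.0 2.0 2.0 3.0 3.0 -> reference drops to
  # 2.0 after the second 2.0, so the return to 3.0 is a new event
  fp3 <- mk_period(c(0, 100, 200, 300, 400, 500),
                   c(3.0, 3.0, 2.0, 2.0, 3.0, 3.0))
  ev_fix <- annotate_followup(fp3, accrual_definition(
    baseline_mode = "fixed", confirmation_mode = "w12_last"))
  ev_rov <- annotate_followup(fp3, accrual_definition(
    baseline_mode = "roving_next_confirmed", confirmation_mode = "w12_last"))
  expect_identical(nrow(ev_fix), 0L)
  expect_identical(nrow(ev_rov), 1L)
  expect_identical(ev_rov$reference_score, 2.0)
  expect_identical(ev_rov$event_score, 3.0)

  # an unconfirmed improvement (next score higher) does not move the
  # roving reference
  fp4 <- mk_period(c(0, 100, 200, 300, 400),
                   c(3.0, 2.0, 3.0, 3.0, 3.0))
  ev4 <- annotate_followup(fp4, accrual_definition(
    baseline_mode = "roving_next_confirmed", confirmation_mode = "w12_last"))
  expect_identical(nrow(ev4), 0L)
})

test_that("sequential same-type events merge without stabilization", {
  # two adjacent PIRA steps 2->3 then 3->4 merge into one event of delta 2
  # (the repeated 3.0 at day 160 sits within the 90-day repetition window)
  fp <- mk_period(c(0, 80, 160, 240, 320, 400),
                  c(2.0, 3.0, 3.0, 4.0, 4.0, 4.0))
  def_on <- accrual_definition(confirmation_mode = "w12_last",
                               event_merging = TRUE)
  def_off <- accrual_definition(confirmation_mode = "w12_last")
  ev_off <- annotate_followup(fp, def_off)
  expect_identical(nrow(ev_off), 2L)
  ev_on <- annotate_followup(fp, def_on)
  expect_identical(nrow(ev_on), 1L)
  expect_identical(ev_on$delta_edss, 2.0)
  expect_identical(ev_on$merged_from, 2L)
  expect_identical(merge_events(ev_off, def_off, fp), ev_off) # identity off

  # different types never merge: RAW (in window) followed by PIRA
  fp2 <- mk_period(c(0, 60, 300, 500, 700), c(2.0, 3.0, 3.0, 4.0, 4.0),
                   relapses = 50)
  ev2 <- annotate_followup(fp2, accrual_definition(
    confirmation_mode = "w12_last", event_merging = TRUE,
    undefined_mode = "never"))
  expect_identical(nrow(ev2), 2L)
  expect_setequal(ev2$event_type, c("RAW", "PIRA"))

  # a dip below the second event's threshold between events blocks merging
  fp3 <- mk_period(c(0, 100, 200, 300, 400, 500, 600),
                   c(2.0, 3.0, 3.0, 2.0, 4.0, 4.0, 4.0))
  ev3 <- annotate_followup(fp3, accrual_definition(
    confirmation_mode = "w12_last", event_merging = TRUE))
  expect_identical(nrow(ev3), 2L)
  expect_true(all(ev3$merged_from == 1L))
})
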