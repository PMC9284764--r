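test_that("assessment schedules reproduce the study arithmetic", {
  sched <- build_assessment_schedule(3, 30, seed = 1)
  expect_equal(nrow(sched$events), 90)
  expect_equal(sched$trial_duration_s, 10)
  expect_equal(sched$phases$name, c("cue", "mi", "rest"))
  expect_equal(sched$phases$start_s, c(0, 2, 7))
  expect_equal(sched$phases$end_s, c(2, 7, 10))
  # contiguous non-overlapping phases starting at 0
  expect_equal(sched$phases$start_s[-1], sched$phases$end_s[-3])
  # back-to-back trials
  expect_equal(diff(sched$events$onset_s), rep(10, 89))
  # three assessment days cover 270 trials
  days <- lapply(1:3, function(d)
    build_assessment_schedule(3, 30, seed = d, day_index = d))
  expect_equal(sum(vapply(days, function(s) nrow(s$events), 0L)), 270)
})

test_that("every set is class balanced for any seed", {
  for (seed in c(2, 11, 99)) {
    sched <- build_assessment_schedule(2, 4, seed = seed)
    counts <- table(sched$events$set_index, sched$events$label)
    expect_true(all(counts == 2))
    big <- build_assessment_schedule(3, 30, seed = seed)
    bc <- table(big$events$set_index, big$events$label)
    expect_true(all(bc == 15))
  }
})

test_that("training schedules give 120 trials/day and 1,680 over 14 days", {
  days <- build_training_schedule(1, 3, 40, seed = 5)
  expect_length(days, 1)
  expect_equal(nrow(days[[1]]$events), 120)
  expect_equal(days[[1]]$trial_duration_s, 7)
  expect_equal(days[[1]]$phases$name, c("cue", "mi", "feedback"))
  expect_equal(days[[1]]$phases$start_s, c(0, 1, 5))
  expect_equal(days[[1]]$phases$end_s, c(1, 5, 7))
  all_days <- build_training_schedule(14, 3, 40, seed = 5)
  expect_equal(sum(vapply(all_days, function(s) nrow(s$events), 0L)), 1680)
  expect_equal(vapply(all_days, function(s) s$day_index, 0L), 1:14)
})

test_that("empty and invalid schedule requests behave as documented", {
  empty <- build_assessment_schedule(1, 0, seed = 7)
  expect_equal(nrow(empty$events), 0)
  expect_equal(empty$trial_duration_s, 10)
  expect_length(build_training_schedule(0, 3, 40, seed = 1), 0)
  expect_error(build_assessment_schedule(1, 31, seed = 1), "even")
  expect_error(build_assessment_schedule(-1, 30, seed = 1), "non-negative")
  expect_error(build_training_schedule(2, 1, -4, seed = 1), "non-negative")
})

test_that("seeds control only the label order, never the timing", {
  a <- build_assessment_schedule(3, 30, seed = 42)
  b <- build_assessment_schedule(3, 30, seed = 42)
  expect_identical(a$events, b$events)
  c_ <- build_assessment_schedule(3, 30, seed = 43)
  expect_equal(a$events$onset_s, c_$events$onset_s)
  expect_false(identical(a$events$label, c_$events$label))
  expect_equal(sort(a$events$label), sort(c_$events$label))
})

test_that("events tables round-trip losslessly", {
  sched <- build_assessment_schedule(3, 30, seed = 3)
  tab <- schedule_to_events_table(sched)
  expect_equal(nrow(tab), 90)
  expect_equal(names(tab), c("onset", "duration", "trial_type", "set_index"))
  expect_equal(nrow(schedule_to_events_table(
    build_assessment_schedule(0, 30, seed = 1))), 0)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(sched, path)
  back <- read_events_tsv(path)
  expect_equal(back$events$onset_s, sched$events$onset_s)
  expect_equal(back$events$label, sched$events$label)
  expect_equal(back$trial_duration_s, sched$trial_duration_s)
  expect_equal(back$session_kind, "assessment")

  tr <- build_training_schedule(1, 2, 10, seed = 4)[[1]]
  write_events_tsv(tr, path)
  expect_equal(read_events_tsv(path)$session_kind, "training")
})
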