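# Trial paradigm: timed left/right motor-imagery schedules.
#
# Two session kinds are modeled. Assessment trials last 10 s
# (cue 0-2 s, motor imagery 2-7 s, rest 7-10 s); training trials last 7 s
# (cue 0-1 s, motor imagery 1-5 s, feedback 5-7 s). Trials are back-to-back
# with no extra inter-trial gap.

assessment_phases <- function() {
  data.frame(name = c("cue", "mi", "rest"),
             start_s = c(0, 2, 7), end_s = c(2, 7, 10),
             stringsAsFactors = FALSE)
}

training_phases <- function() {
  data.frame(name = c("cue", "mi", "feedback"),
             start_s = c(0, 1, 5), end_s = c(1, 5, 7),
             stringsAsFactors = FALSE)
}

new_trial_schedule <- function(events, phases, session_kind, trial_duration_s,
                               day_index = 1L, seed = NULL) {
  stopifnot(is.data.frame(events))
  structure(list(events = events, phases = phases,
                 session_kind = session_kind,
                 trial_duration_s = trial_duration_s,
                 day_index = as.integer(day_index), seed = seed),
            class = "trial_schedule")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule: %s, %d trials, %g s each, day %d>\n",
              x$session_kind, nrow(x$events), x$trial_duration_s, x$day_index))
  invisible(x)
}

# Balanced, seed-shuffled label sequence for one set of trials.
balanced_labels <- function(n_trials) {
  sample(rep(c("left", "right"), each = n_trials / 2L))
}

build_schedule_events <- function(n_sets, trials_per_set, trial_duration_s) {
  if (n_sets < 0 || trials_per_set < 0)
    stop("trial counts must be non-negative")
  if (trials_per_set %% 2L != 0L)
    stop("trials_per_set must be even so left/right counts balance")
  n <- n_sets * trials_per_set
  labels <- character(0)
  set_index <- integer(0)
  for (s in seq_len(n_sets)) {
    labels <- c(labels, balanced_labels(trials_per_set))
    set_index <- c(set_index, rep(s, trials_per_set))
  }
  data.frame(trial_index = seq_len(n) - 1L,
             onset_s = (seq_len(n) - 1L) * trial_duration_s,
             label = labels,
             set_index = if (n > 0) set_index else integer(0),
             stringsAsFactors = FALSE)
}

#' Build an assessment-session trial schedule
#'
#' One assessment session consists of `n_sets` sets of `trials_per_set`
#' left/right motor-imagery trials of 10 s each (cue 0-2 s, MI 2-7 s,
#' rest 7-10 s), back to back. Each set is class-balanced
#' (`trials_per_set/2` per label) with a seed-shuffled order, so downstream
#' stratified folds and CSP fitting always see both classes equally.
#'
#' @param n_sets number of sets in the session (study setting: 3).
#' @param trials_per_set even number of trials per set (study setting: 30).
#' @param seed integer seed controlling only the label order.
#' @param day_index day number carried as metadata.
#' @return a `trial_schedule` whose `events` data frame has one row per trial
#'   (`trial_index`, `onset_s`, `label`, `set_index`).
#' @examples
#' sched <- build_assessment_schedule(3, 30, seed = 1)
#' nrow(sched$events)  # 90
#' @export
build_assessment_schedule <- function(n_sets, trials_per_set, seed = NULL,
                                      day_index = 1L) {
  events <- with_seed(seed,
                      build_schedule_events(n_sets, trials_per_set, 10))
  new_trial_schedule(events, assessment_phases(), "assessment", 10,
                     day_index = day_index, seed = seed)
}

#' Build a multi-day training schedule
#'
#' Training trials last 7 s (cue 0-1 s, MI 1-5 s, feedback 5-7 s). Each day
#' holds `sessions_per_day` sessions of `trials_per_session` balanced trials;
#' with the study settings (3 sessions of 40) a day holds 120 trials and a
#' 14-day course 1,680.
#'
#' @param n_days number of training days.
#' @param sessions_per_day sessions (sets) per day.
#' @param trials_per_session even number of trials per session.
#' @param seed integer seed; each day uses an independent substream.
#' @return list of `trial_schedule`, one per day.
#' @export
build_training_schedule <- function(n_days, sessions_per_day,
                                    trials_per_session, seed = NULL) {
  if (n_days < 0) stop("n_days must be non-negative")
  with_seed(seed, {
    lapply(seq_len(n_days), function(d) {
      events <- build_schedule_events(sessions_per_day, trials_per_session, 7)
      new_trial_schedule(events, training_phases(), "training", 7,
                         day_index = d, seed = seed)
    })
  })
}

#' Flatten a schedule to an events table
#'
#' Produces the tab-separable events representation (BIDS-events dialect):
#' one row per trial with `onset`, `duration` and `trial_type` columns, plus
#' the set index.
#'
#' @param schedule a `trial_schedule`.
#' @return data frame with columns `onset`, `duration`, `trial_type`,
#'   `set_index`.
#' @export
schedule_to_events_table <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  ev <- schedule$events
  data.frame(onset = ev$onset_s,
             duration = rep(schedule$trial_duration_s, nrow(ev)),
             trial_type = ev$label,
             set_index = ev$set_index,
             stringsAsFactors = FALSE)
}

# Duration in seconds covered by a schedule (end of the last trial).
schedule_duration_s <- function(schedule) {
  if (nrow(schedule$events) == 0) return(0)
  max(schedule$events$onset_s) + schedule$trial_duration_s
}

# (start, end) seconds of a named phase window, relative to trial onset.
phase_window <- function(schedule, phase = "mi") {
  ph <- schedule$phases
  row <- ph[ph$name == phase, ]
  if (nrow(row) != 1) stop(sprintf("schedule has no phase named '%s'", phase))
  c(row$start_s, row$end_s)
}
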