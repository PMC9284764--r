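# Tabular and config I/O: events tables (TSV), recognition-rate tables
# (CSV) and the TOML run configuration.

#' Write a schedule as a tab-separated events table
#'
#' Columns `onset`, `duration`, `trial_type`, `set_index` (BIDS-events
#' dialect plus the set column).
#'
#' @param schedule a `trial_schedule`.
#' @param path output path.
#' @export
write_events_tsv <- function(schedule, path) {
  tab <- schedule_to_events_table(schedule)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events table back into a schedule
#'
#' Validates strictly increasing onsets and known trial types. The session
#' kind is inferred from the trial duration (10 s = assessment, 7 s =
#' training).
#'
#' @param path events TSV path.
#' @return a `trial_schedule`.
#' @export
read_events_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(tab))) stop("events table missing columns")
  if (nrow(tab) > 0) {
    if (any(diff(tab$onset) <= 0)) stop("event onsets must be increasing")
    if (!all(tab$trial_type %in% c("left", "right")))
      stop("unknown trial_type in events table")
  }
  dur <- if (nrow(tab) > 0) tab$duration[1] else 10
  kind <- if (isTRUE(all.equal(dur, 7))) "training" else "assessment"
  phases <- if (kind == "training") training_phases() else assessment_phases()
  events <- data.frame(
    trial_index = seq_len(nrow(tab)) - 1L,
    onset_s = tab$onset,
    label = as.character(tab$trial_type),
    set_index = if ("set_index" %in% names(tab)) tab$set_index
                else rep(1L, nrow(tab)),
    stringsAsFactors = FALSE)
  new_trial_schedule(events, phases, kind, dur)
}

#' Write a recognition-rate table to CSV
#'
#' Mirrors the online-training summary layout: one row per training day, one
#' column per subject, followed by an average row and a standard-deviation
#' row (the deviation of the rate expressed as a fraction, matching how such
#' tables are conventionally printed).
#'
#' @param table a `rate_table` from [online_recognition_rate()], or a plain
#'   day-by-subject numeric matrix of rates in percent.
#' @param path output CSV path.
#' @export
write_rate_table <- function(table, path) {
  rates <- if (inherits(table, "rate_table")) table$rates else as.matrix(table)
  if (is.null(colnames(rates)))
    colnames(rates) <- paste0("S", seq_len(ncol(rates)))
  body <- rbind(rates,
                average = colMeans(rates),
                sd = apply(rates / 100, 2, sd))
  rn <- c(sprintf("Day_%02d", seq_len(nrow(rates))), "Average", "SD")
  df <- data.frame(row = rn, body, check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a rate-table CSV
#'
#' @param path CSV written by [write_rate_table()].
#' @return list with `rates` (day x subject matrix), `average`, `sd`.
#' @export
read_rate_table <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) < 3) stop("rate table must have at least one day row")
  m <- as.matrix(df[, -1, drop = FALSE])
  nd <- nrow(m) - 2L
  list(rates = m[seq_len(nd), , drop = FALSE],
       average = m[nd + 1L, ], sd = m[nd + 2L, ])
}

# ---- run configuration (TOML) ----------------------------------------

#' Default run configuration
#'
#' Parameter groups for every pipeline stage, with the study's settings as
#' defaults. Serialize with [write_run_config()] and load with
#' [read_run_config()]; unknown groups or keys are rejected on read so a
#' config file cannot silently misspell a parameter.
#'
#' @return nested named list of parameter groups.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    paradigm = list(n_sets = 3L, trials_per_set = 30L, n_days = 14L,
                    sessions_per_day = 3L, trials_per_session = 40L),
    generator = list(mu_amp = 2, beta_amp = 1, erd_depth = 1,
                     pink_noise_sd = 1, spatial_spread = 0.4,
                     scene = "vr", scene_gains = list(static = 0.2,
                                                     dynamic = 0.5, vr = 0.8)),
    preprocessing = list(baseline_window_s = 1.0, line_f0 = 50,
                         lms_step = 0.002, band_low = 8, band_high = 32,
                         ica_corr_threshold = 0.7,
                         ica_kurtosis_threshold = 5.0,
                         ica_lowfreq_fraction = 0.6),
    feature = list(psd_segment_s = 1.0, psd_overlap = 0.5, csp_pairs = 3L),
    classifier = list(swarm_size = 30L, iterations = 100L, inertia = 0.72,
                      c1 = 1.49, c2 = 1.49,
                      log10_c_bounds = c(-2, 3), log10_gamma_bounds = c(-4, 1),
                      inner_folds = 3L),
    evaluation = list(outer_folds = 3L, beam_threshold = 0.6,
                      beam_grid_size = 64L)
  )
}

toml_scalar <- function(x) {
  if (is.character(x)) sprintf('"%s"', x)
  else if (is.logical(x)) tolower(as.character(x))
  else format(x, digits = 15)
}

toml_emit <- function(x, prefix = NULL) {
  lines <- character(0)
  scalars <- Filter(function(n) !is.list(x[[n]]), names(x))
  tables <- Filter(function(n) is.list(x[[n]]), names(x))
  if (!is.null(prefix)) lines <- c(lines, sprintf("[%s]", prefix))
  for (n in scalars) {
    v <- x[[n]]
    val <- if (length(v) == 1) toml_scalar(v)
           else sprintf("[%s]", paste(vapply(v, toml_scalar, ""),
                                      collapse = ", "))
    lines <- c(lines, sprintf("%s = %s", n, val))
  }
  for (n in tables) {
    sub <- if (is.null(prefix)) n else paste(prefix, n, sep = ".")
    lines <- c(lines, "", toml_emit(x[[n]], sub))
  }
  lines
}

#' Write a run configuration as TOML
#' @param config nested list as from [default_run_config()].
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  writeLines(toml_emit(config), path)
  invisible(path)
}

check_config_keys <- function(cfg, ref, where = "config") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown) > 0)
    stop(sprintf("unknown %s key(s): %s", where,
                 paste(unknown, collapse = ", ")))
  for (n in names(cfg))
    if (is.list(ref[[n]]) && is.list(cfg[[n]]) && n != "scene_gains")
      check_config_keys(cfg[[n]], ref[[n]], paste0(where, ".", n))
  invisible(TRUE)
}

#' Read and validate a TOML run configuration
#'
#' Keys absent from the file fall back to [default_run_config()]; keys not
#' in the default schema raise an error.
#'
#' @param path TOML file path.
#' @return nested named list of parameter groups.
#' @export
read_run_config <- function(path) {
  cfg <- RcppTOML::parseTOML(path)
  ref <- default_run_config()
  check_config_keys(cfg, ref)
  modify_defaults <- function(def, new) {
    for (n in names(new)) {
      def[[n]] <- if (is.list(def[[n]]) && is.list(new[[n]]))
        modify_defaults(def[[n]], new[[n]]) else new[[n]]
    }
    def
  }
  modify_defaults(ref, cfg)
}
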