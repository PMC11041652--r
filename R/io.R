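# On-disk formats. Every record type is a main text file plus a JSON
# sidecar ("<stem>.json") holding scalar metadata; numbers are written with
# 9 significant digits.

sidecar_path <- function(path) paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".json")
events_path <- function(path) paste0(sub("\\.[A-Za-z0-9]+$", "", path), "_events.csv")

write_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  assert_that(file.exists(sp), "missing sidecar file %s", sp)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a record to disk
#'
#' Writes any of the package's record types (trial schedule, spike train,
#' trace set, behavior session, photometry series) as plain-text files that
#' [load_session()] reads back losslessly (9 significant digits). Each
#' record becomes a main file plus a `<stem>.json` sidecar; spike trains
#' and photometry series also get a `<stem>_events.csv` companion.
#'
#' @param record a `trial_schedule`, `spike_train`, `trace_set`,
#'   `behavior_session` or `photometry_series`.
#' @param path path of the main file (`.csv`, or `.txt` for spike trains).
#' @return Invisibly, `path`.
#' @export
write_session <- function(record, path) {
  UseMethod("write_session")
}

#' @export
write_session.trial_schedule <- function(record, path) {
  tr <- record$trials
  tr$onset_s <- fmt_num(tr$onset_s)
  utils::write.csv(tr, path, row.names = FALSE, quote = FALSE)
  write_sidecar(list(kind = "schedule", phase = record$phase,
                     cs_duration_s = record$cs_duration_s,
                     us_delay_s = record$us_delay_s,
                     us_duration_s = record$us_duration_s,
                     iti_bounds_s = record$iti_bounds_s), path)
  invisible(path)
}

#' @export
write_session.spike_train <- function(record, path) {
  writeLines(fmt_num(record$spike_times_s), path)
  utils::write.csv(data.frame(onset_s = fmt_num(record$fs_event_times_s)),
                   events_path(path), row.names = FALSE, quote = FALSE)
  write_sidecar(list(kind = "spikes", neuron_id = record$neuron_id,
                     duration_s = record$duration_s,
                     fs_duration_s = record$fs_duration_s), path)
  invisible(path)
}

write_trial_matrix <- function(mat, path) {
  n_tr <- nrow(mat); n_s <- ncol(mat)
  long <- data.frame(trial = rep(seq_len(n_tr), each = n_s),
                     sample = rep(seq_len(n_s), n_tr),
                     value = fmt_num(as.vector(t(mat))))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
}

read_trial_matrix <- function(path) {
  long <- utils::read.csv(path)
  for (col in c("trial", "sample", "value"))
    assert_that(col %in% names(long), "%s: missing column '%s'", path, col)
  n_tr <- max(long$trial); n_s <- max(long$sample)
  assert_that(nrow(long) == n_tr * n_s, "%s: ragged trial matrix", path)
  ord <- order(long$trial, long$sample)
  matrix(long$value[ord], nrow = n_tr, ncol = n_s, byrow = TRUE)
}

#' @export
write_session.trace_set <- function(record, path) {
  write_trial_matrix(record$raw_f, path)
  meta <- list(kind = "traces", neuron_id = record$neuron_id,
               session_id = record$session_id, phase = record$phase,
               sample_rate_hz = record$window$sample_rate_hz,
               pre_s = record$window$pre_s, total_s = record$window$total_s,
               cue_per_trial = record$cue_per_trial)
  if (!is.null(record$dff_pct)) {
    dff_file <- paste0(sub("\\.[A-Za-z0-9]+$", "", path), "_dff.csv")
    write_trial_matrix(record$dff_pct, dff_file)
    meta$dff_file <- basename(dff_file)
  }
  write_sidecar(meta, path)
  invisible(path)
}

#' @export
write_session.behavior_session <- function(record, path) {
  write_trial_matrix(record$eye_area, path)
  write_sidecar(list(kind = "behavior", mouse_id = record$mouse_id,
                     phase = record$phase,
                     sample_rate_hz = record$window$sample_rate_hz,
                     pre_s = record$window$pre_s,
                     total_s = record$window$total_s,
                     cue_per_trial = record$cue_per_trial), path)
  invisible(path)
}

#' @export
write_session.photometry_series <- function(record, path) {
  n <- length(record$counts)
  utils::write.csv(data.frame(
    bin_start_s = fmt_num((seq_len(n) - 1) * record$bin_width_s),
    count = record$counts), path, row.names = FALSE, quote = FALSE)
  ev <- record$events
  ev$onset_s <- fmt_num(ev$onset_s)
  utils::write.csv(ev, events_path(path), row.names = FALSE, quote = FALSE)
  write_sidecar(list(kind = "photometry", animal_id = record$animal_id,
                     sensor = record$sensor,
                     bin_width_s = record$bin_width_s), path)
  invisible(path)
}

#' Load a record from disk
#'
#' Counterpart of [write_session()]. Validates the file against the
#' documented dialect and returns a fully validated record; a malformed
#' file (missing column, unsorted times, unknown cue label) raises an error
#' naming the file and the violated invariant.
#'
#' @param path path of the main file written by [write_session()].
#' @param kind one of `"schedule"`, `"spikes"`, `"traces"`, `"behavior"`,
#'   `"photometry"`.
#' @return The corresponding record object.
#' @export
load_session <- function(path, kind = c("schedule", "spikes", "traces",
                                        "behavior", "photometry")) {
  kind <- match.arg(kind)
  assert_that(file.exists(path), "file not found: %s", path)
  meta <- read_sidecar(path)
  assert_that(identical(meta$kind, kind),
              "%s: sidecar says kind '%s', expected '%s'", path, meta$kind, kind)
  switch(kind,
    schedule = {
      tr <- utils::read.csv(path)
      trial_schedule(tr, phase = meta$phase,
                     cs_duration_s = meta$cs_duration_s,
                     us_delay_s = meta$us_delay_s,
                     us_duration_s = meta$us_duration_s,
                     iti_bounds_s = unlist(meta$iti_bounds_s))
    },
    spikes = {
      st <- as.numeric(readLines(path))
      assert_that(!anyNA(st), "%s: non-numeric spike time", path)
      assert_that(!is.unsorted(st), "%s: spike times not sorted", path)
      ev <- utils::read.csv(events_path(path))
      assert_that("onset_s" %in% names(ev),
                  "%s: events file missing column 'onset_s'", events_path(path))
      spike_train_recording(meta$neuron_id, st, meta$duration_s,
                            ev$onset_s, meta$fs_duration_s)
    },
    traces = {
      raw <- read_trial_matrix(path)
      w <- trace_window(meta$sample_rate_hz, meta$pre_s, meta$total_s)
      dff <- NULL
      if (!is.null(meta$dff_file))
        dff <- read_trial_matrix(file.path(dirname(path), meta$dff_file))
      neuron_trace_set(meta$neuron_id, meta$session_id, meta$phase, w,
                       unlist(meta$cue_per_trial), raw, dff)
    },
    behavior = {
      area <- read_trial_matrix(path)
      w <- trace_window(meta$sample_rate_hz, meta$pre_s, meta$total_s)
      behavior_session(meta$mouse_id, meta$phase, unlist(meta$cue_per_trial),
                       area, w)
    },
    photometry = {
      d <- utils::read.csv(path)
      assert_that(all(c("bin_start_s", "count") %in% names(d)),
                  "%s: needs columns bin_start_s,count", path)
      ev <- utils::read.csv(events_path(path))
      photometry_series(meta$animal_id, meta$sensor, d$count, ev,
                        meta$bin_width_s)
    })
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns an [analysis_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  analysis_config(alpha = y$alpha %||% 0.05,
                  cr_window = unlist(y$cr_window) %||% c(0, 1.5),
                  imaging_baseline_window_s = y$imaging_baseline_window_s %||% 1.5,
                  dff_f0_window_s = y$dff_f0_window_s %||% 3,
                  behavior_f0_window_s = y$behavior_f0_window_s %||% 5,
                  rng_seed = y$rng_seed %||% 1L)
}

#' @rdname read_config
#' @param cfg an [analysis_config()].
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
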