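#' Single-channel physiological signal
#'
#' A uniformly sampled signal from one sensor channel. ECG, EOG and EEG are
#' in microvolts, EDA in microsiemens, and the respiration accelerometer in
#' m/s^2. Missing samples are explicit `NaN`, never dropped.
#'
#' @param name channel identifier, one of `ecg`, `resp_accel`, `eda`,
#'   `eog_h`, `eeg_t5`, `eeg_p3`, `eeg_p4`, `eeg_t6`.
#' @param sample_rate sampling rate, Hz (> 0).
#' @param values numeric samples.
#' @param start_time session-clock time of the first sample, seconds
#'   (0 = operation start).
#' @return A `channel_signal` object.
#' @export
channel_signal <- function(name, sample_rate, values, start_time = 0) {
  if (!is.character(name) || length(name) != 1L)
    stop("channel name must be a single string", call. = FALSE)
  if (!(name %in% .REQUIRED_CHANNELS))
    stop("unknown channel name '", name, "'", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive number", call. = FALSE)
  if (length(values) < 1L)
    stop("values must hold at least one sample", call. = FALSE)
  structure(list(name = name, sample_rate = as.numeric(sample_rate),
                 start_time = as.numeric(start_time),
                 values = as.numeric(values)),
            class = "channel_signal")
}

# Sample times of a channel on the session clock.
channel_times <- function(ch) {
  ch$start_time + (seq_along(ch$values) - 1) / ch$sample_rate
}

#' Timed subjective report
#'
#' One verbal report of the operator's state: sickness (VIMS) level on a
#' five-point scale, with optional drowsiness and fatigue ratings (carried
#' through I/O but unused by the classifier).
#'
#' @param time_s session-clock time of the report, seconds.
#' @param vims_level integer 1-5.
#' @param drowsiness,fatigue optional integers 1-5.
#' @return A `report_event` object.
#' @export
report_event <- function(time_s, vims_level, drowsiness = NA_integer_,
                         fatigue = NA_integer_) {
  vims_level <- as.integer(vims_level)
  if (is.na(vims_level) || vims_level < 1L || vims_level > 5L)
    stop("vims_level must be an integer in 1..5", call. = FALSE)
  structure(list(time_s = as.numeric(time_s), vims_level = vims_level,
                 drowsiness = as.integer(drowsiness),
                 fatigue = as.integer(fatigue)),
            class = "report_event")
}

#' One participant/session recording
#'
#' All eight required channels plus the ordered report events of a single
#' operating session under one display condition.
#'
#' @param participant_id string identifier.
#' @param display_condition `"MD"` (multi-display) or `"HMD"` (head-mounted).
#' @param channels named list of [channel_signal()] objects; all of `ecg`,
#'   `resp_accel`, `eda`, `eog_h`, `eeg_t5`, `eeg_p3`, `eeg_p4`, `eeg_t6`
#'   must be present.
#' @param reports list of [report_event()] objects, strictly increasing in
#'   time.
#' @param duration_s session length in seconds (at least 150, so that a
#'   120-s baseline plus labelled data fit).
#' @return A validated `vims_recording` object.
#' @export
recording <- function(participant_id, display_condition, channels, reports,
                      duration_s) {
  rec <- structure(list(participant_id = as.character(participant_id),
                        display_condition = display_condition,
                        channels = channels, reports = reports,
                        duration_s = as.numeric(duration_s)),
                   class = "vims_recording")
  validate_recording(rec)
  rec
}

#' Validate a recording
#'
#' Checks channel completeness, report ordering and range, minimum duration
#' and the termination rule (a level-5 report must be the last one, at the
#' session end).
#'
#' @param rec a `vims_recording`.
#' @return `rec`, invisibly; otherwise an error.
#' @export
validate_recording <- function(rec) {
  if (!identical(sort(names(rec$channels) [names(rec$channels) %in%
                                           .REQUIRED_CHANNELS]),
                 sort(.REQUIRED_CHANNELS))) {
    missing <- setdiff(.REQUIRED_CHANNELS, names(rec$channels))
    stop("channel missing: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!rec$display_condition %in% c("MD", "HMD"))
    stop("display_condition must be 'MD' or 'HMD'", call. = FALSE)
  if (rec$duration_s < 150)
    stop("recording too short: duration_s must be >= 150 s", call. = FALSE)
  times <- vapply(rec$reports, function(r) r$time_s, numeric(1))
  levels <- vapply(rec$reports, function(r) r$vims_level, integer(1))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("events unordered", call. = FALSE)
  if (length(times) > 0L && any(times > rec$duration_s))
    stop("event out of range", call. = FALSE)
  if (any(levels == 5L)) {
    k <- which(levels == 5L)
    if (length(k) > 1L || k != length(levels))
      stop("a level-5 report must be the single last report", call. = FALSE)
    if (abs(times[k] - rec$duration_s) > 1e-9)
      stop("session must terminate at its level-5 report", call. = FALSE)
  }
  for (nm in .REQUIRED_CHANNELS) {
    ch <- rec$channels[[nm]]
    if (!inherits(ch, "channel_signal"))
      stop("channel '", nm, "' is not a channel_signal", call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.vims_recording <- function(x, ...) {
  cat(sprintf("<vims_recording> participant %s, %s, %.0f s, %d reports\n",
              x$participant_id, x$display_condition, x$duration_s,
              length(x$reports)))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-10s %7.1f Hz, %d samples\n", nm, ch$sample_rate,
                length(ch$values)))
  }
  invisible(x)
}
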