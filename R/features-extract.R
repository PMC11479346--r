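#' Extract the 23-feature series from a recording
#'
#' Runs every per-channel detector once over the whole session, then slides
#' a 30-s window in 1-s steps (half-open `[t-30, t)`, feature timestamp `t`)
#' and assembles one row per integer second from `t = 30` to
#' `duration - 1`, holding exactly the 23 canonical feature columns (see
#' [vims_feature_names()]). Windows with too little data yield `NaN`
#' entries, which the preprocessing stage repairs.
#'
#' @param rec a validated `vims_recording`.
#' @param cfg a [pipeline_config()].
#' @return A `data.table` with columns `participant_id`, `display`, `t_s`
#'   and the 23 features, one row per second.
#' @export
extract_features <- function(rec, cfg = pipeline_config()) {
  validate_recording(rec)
  if (rec$duration_s < 150)
    stop("recording shorter than 150 s: cannot form baseline plus data",
         call. = FALSE)
  W <- cfg$window_s
  ts <- seq(W, floor(rec$duration_s) - 1, by = cfg$step_s)

  # one-off per-session preprocessing
  peaks <- tryCatch(detect_r_peaks(rec$channels$ecg, cfg),
                    error = function(e) numeric(0))
  resp_ev <- .resp_events(rec$channels$resp_accel, cfg)
  eda <- eda_decompose(rec$channels$eda, cfg)
  saccades <- detect_saccades(rec$channels$eog_h, cfg)
  avg_eeg <- .eeg_average(rec$channels[.EEG_CHANNELS], cfg)
  sub_starts <- seq(0, floor(rec$duration_s) - cfg$eeg_subwindow_s,
                    by = 1)
  subtab <- .band_subwindow_table(avg_eeg, cfg, sub_starts)
  epochs <- .efrp_epochs(avg_eeg, saccades$offset_s)

  n_sub <- W / cfg$eeg_subwindow_s
  rows <- matrix(NaN, nrow = length(ts), ncol = length(.FEATURE_NAMES),
                 dimnames = list(NULL, .FEATURE_NAMES))
  for (i in seq_along(ts)) {
    t <- ts[i]
    win <- c(t - W, t)
    hr <- hr_features(peaks, win, cfg)
    rs <- .resp_agg(resp_ev, win)
    ed <- eda_features(eda$scl, eda$scr, win)
    sc <- saccade_features(saccades, win)
    starts <- win[1] + cfg$eeg_subwindow_s * (seq_len(n_sub) - 1)
    bd <- .band_agg(subtab[match(starts, sub_starts), , drop = FALSE])
    lam <- .efrp_agg(epochs,
                     saccades$offset_s >= win[1] & saccades$offset_s < win[2],
                     cfg$lambda_window_ms)
    rows[i, ] <- c(hr, rs, ed, sc, bd, lam)[.FEATURE_NAMES]
  }
  out <- data.table::data.table(participant_id = rec$participant_id,
                                display = rec$display_condition,
                                t_s = as.integer(ts))
  out <- cbind(out, data.table::as.data.table(rows))
  out
}
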