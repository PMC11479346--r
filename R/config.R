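#' Pipeline configuration
#'
#' Bundles every tunable of the feature-extraction and preprocessing stages.
#' Defaults follow the published analysis settings: a 30-s sliding window
#' stepped by 1 s, a 120-s standardization baseline, heart-rate resampling at
#' 50 Hz with LF 0.04-0.15 Hz and HF 0.15-0.40 Hz bands, ECG band-pass
#' 0.05-30 Hz, respiration band-pass 0.5-2 Hz, tonic EDA low-pass 0.04 Hz and
#' EDA noise high-pass 0.5 Hz, EEG band-pass 0.5-30 Hz with alpha 8-13 Hz and
#' theta 4-8 Hz evaluated on 2-s subwindows, lambda-response search window
#' 50-200 ms, and 1/99 percentile outlier clipping.
#'
#' @param window_s sliding-window length in seconds.
#' @param step_s window step in seconds.
#' @param baseline_span_s span of the standardization baseline, seconds.
#' @param hr_resample_hz uniform resampling rate for instantaneous HR, Hz.
#' @param lf_band,hf_band HRV spectral bands, Hz.
#' @param ecg_bandpass,resp_bandpass,eeg_bandpass band edges, Hz.
#' @param scl_lowpass_hz tonic EDA low-pass cutoff, Hz.
#' @param eda_noise_highpass_hz EDA noise high-pass cutoff, Hz.
#' @param alpha_band,theta_band EEG bands, Hz.
#' @param eeg_subwindow_s EEG spectral subwindow, seconds.
#' @param lambda_window_ms lambda-response search window after fixation, ms.
#' @param outlier_percentiles lower/upper clip percentiles on pooled ratios.
#' @param trend_segments number of normalized-time segments.
#' @param saccade_speed_floor_uvs absolute floor on the saccade velocity
#'   threshold, microvolt/s (the adaptive threshold is 6 x MAD of the
#'   trailing-window velocity, never below this floor).
#' @param rr_gate_s physiological gate on RR intervals, seconds.
#' @param random_seed default seed for seeded operations.
#' @return A list with class `vims_config`.
#' @export
pipeline_config <- function(window_s = 30, step_s = 1, baseline_span_s = 120,
                            hr_resample_hz = 50,
                            lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40),
                            ecg_bandpass = c(0.05, 30),
                            resp_bandpass = c(0.5, 2),
                            scl_lowpass_hz = 0.04,
                            eda_noise_highpass_hz = 0.5,
                            eeg_bandpass = c(0.5, 30),
                            alpha_band = c(8, 13), theta_band = c(4, 8),
                            eeg_subwindow_s = 2,
                            lambda_window_ms = c(50, 200),
                            outlier_percentiles = c(1, 99),
                            trend_segments = 1000,
                            saccade_speed_floor_uvs = 500,
                            rr_gate_s = c(0.3, 2.0),
                            random_seed = 1L) {
  cfg <- list(window_s = window_s, step_s = step_s,
              baseline_span_s = baseline_span_s,
              hr_resample_hz = hr_resample_hz,
              lf_band = lf_band, hf_band = hf_band,
              ecg_bandpass = ecg_bandpass, resp_bandpass = resp_bandpass,
              scl_lowpass_hz = scl_lowpass_hz,
              eda_noise_highpass_hz = eda_noise_highpass_hz,
              eeg_bandpass = eeg_bandpass,
              alpha_band = alpha_band, theta_band = theta_band,
              eeg_subwindow_s = eeg_subwindow_s,
              lambda_window_ms = lambda_window_ms,
              outlier_percentiles = outlier_percentiles,
              trend_segments = trend_segments,
              saccade_speed_floor_uvs = saccade_speed_floor_uvs,
              rr_gate_s = rr_gate_s,
              random_seed = as.integer(random_seed))
  for (nm in c("lf_band", "hf_band", "ecg_bandpass", "resp_bandpass",
               "eeg_bandpass", "alpha_band", "theta_band",
               "lambda_window_ms", "outlier_percentiles", "rr_gate_s")) {
    b <- cfg[[nm]]
    if (length(b) != 2L || !(b[1] < b[2]))
      stop("config band '", nm, "' must have lower < upper", call. = FALSE)
  }
  if (cfg$window_s <= 0 || cfg$step_s <= 0 || cfg$baseline_span_s <= 0)
    stop("window, step and baseline span must be positive", call. = FALSE)
  class(cfg) <- "vims_config"
  cfg
}
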