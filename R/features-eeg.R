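# EEG band-power ratios / peak frequencies on 2-s subwindows, and the
# lambda response of the eye-fixation-related potential (EFRP).

# Band-pass each channel (0.5-30 Hz) and average the four channels.
.eeg_average <- function(eeg_channels, cfg = pipeline_config()) {
  stopifnot(length(eeg_channels) == 4L)
  fs <- eeg_channels[[1]]$sample_rate
  filt <- lapply(eeg_channels, function(ch) {
    stopifnot(ch$sample_rate == fs)
    zerophase_bandpass(ch$values, fs, cfg$eeg_bandpass)
  })
  n <- min(lengths(filt))
  avg <- Reduce(`+`, lapply(filt, function(v) v[seq_len(n)])) / 4
  ch <- eeg_channels[[1]]
  ch$values <- avg
  ch
}

# Periodogram band summary of one subwindow: theta/alpha power ratios
# (denominator = total power in the analysed 0.5-30 Hz band) and peak
# frequencies (argmax bin inside each band).
.subwindow_bands <- function(x, fs, cfg) {
  n <- length(x)
  sp <- abs(fft(x - mean(x)))^2
  nf <- floor(n / 2)
  f <- seq_len(nf) * fs / n
  p <- sp[2:(nf + 1)]
  tot_sel <- f >= cfg$eeg_bandpass[1] & f < cfg$eeg_bandpass[2]
  th_sel <- f >= cfg$theta_band[1] & f < cfg$theta_band[2]
  al_sel <- f >= cfg$alpha_band[1] & f < cfg$alpha_band[2]
  tot <- sum(p[tot_sel])
  c(theta_ratio = if (tot > 0) sum(p[th_sel]) / tot else NaN,
    alpha_ratio = if (tot > 0) sum(p[al_sel]) / tot else NaN,
    peak_theta = f[th_sel][which.max(p[th_sel])],
    peak_alpha = f[al_sel][which.max(p[al_sel])])
}

# Subwindow table for a set of start times (seconds).
.band_subwindow_table <- function(avg, cfg, starts) {
  fs <- avg$sample_rate
  len <- round(cfg$eeg_subwindow_s * fs)
  out <- matrix(NaN, nrow = length(starts), ncol = 4,
                dimnames = list(NULL, c("theta_ratio", "alpha_ratio",
                                        "peak_theta", "peak_alpha")))
  for (k in seq_along(starts)) {
    i0 <- round((starts[k] - avg$start_time) * fs) + 1L
    i1 <- i0 + len - 1L
    if (i0 < 1L || i1 > length(avg$values)) next
    x <- avg$values[i0:i1]
    if (anyNA(x)) next
    out[k, ] <- .subwindow_bands(x, fs, cfg)
  }
  out
}

.band_agg <- function(subtab) {
  valid <- !is.na(subtab[, "theta_ratio"])
  if (sum(valid) < 8L)
    return(c(ThetaRatio_mean = NaN, AlphaRatio_mean = NaN,
             ThetaRatio_sd = NaN, AlphaRatio_sd = NaN,
             PeakThetaFreq_mean = NaN, PeakAlphaFreq_mean = NaN,
             PeakThetaFreq_sd = NaN, PeakAlphaFreq_sd = NaN))
  s <- subtab[valid, , drop = FALSE]
  c(ThetaRatio_mean = mean(s[, "theta_ratio"]),
    AlphaRatio_mean = mean(s[, "alpha_ratio"]),
    ThetaRatio_sd = sd(s[, "theta_ratio"]),
    AlphaRatio_sd = sd(s[, "alpha_ratio"]),
    PeakThetaFreq_mean = mean(s[, "peak_theta"]),
    PeakAlphaFreq_mean = mean(s[, "peak_alpha"]),
    PeakThetaFreq_sd = sd(s[, "peak_theta"]),
    PeakAlphaFreq_sd = sd(s[, "peak_alpha"]))
}

#' Windowed EEG band features
#'
#' The four EEG channels are band-pass filtered (0.5-30 Hz) and averaged;
#' the window is split into non-overlapping 2-s subwindows; each subwindow's
#' periodogram yields theta (4-8 Hz) and alpha (8-13 Hz) power ratios
#' (relative to total 0.5-30 Hz power) and peak frequencies. Features are
#' the mean and standard deviation across subwindows; fewer than 8 valid
#' subwindows yields `NaN`.
#'
#' @param eeg_channels list of the four EEG [channel_signal()]s.
#' @param window numeric `c(from, to)`, half-open.
#' @param cfg a [pipeline_config()].
#' @return Named numeric vector of the eight band features.
#' @export
eeg_band_features <- function(eeg_channels, window, cfg = pipeline_config()) {
  avg <- .eeg_average(eeg_channels, cfg)
  starts <- seq(window[1], window[2] - cfg$eeg_subwindow_s,
                by = cfg$eeg_subwindow_s)
  .band_agg(.band_subwindow_table(avg, cfg, starts))
}

# Epoch matrix around fixation onsets: rows = fixations, columns = samples
# on the -100..+300 ms grid, baseline-corrected by the -100..0 ms mean.
.efrp_epochs <- function(avg, fixation_times, pre_s = 0.1, post_s = 0.3) {
  fs <- avg$sample_rate
  off <- seq(-round(pre_s * fs), round(post_s * fs))
  tgrid_ms <- off / fs * 1000
  base_sel <- tgrid_ms < 0
  n <- length(avg$values)
  keep <- logical(length(fixation_times))
  mat <- matrix(NA_real_, nrow = length(fixation_times), ncol = length(off))
  for (k in seq_along(fixation_times)) {
    i0 <- round((fixation_times[k] - avg$start_time) * fs) + 1L
    idx <- i0 + off
    if (idx[1] < 1L || idx[length(idx)] > n) next
    ep <- avg$values[idx]
    if (anyNA(ep)) next
    mat[k, ] <- ep - mean(ep[base_sel])
    keep[k] <- TRUE
  }
  list(mat = mat, keep = keep, tgrid_ms = tgrid_ms)
}

.efrp_agg <- function(epochs, sel, lambda_window_ms) {
  rows <- which(sel & epochs$keep)
  if (length(rows) < 3L)
    return(c(LambdaAmplitude = NaN, LambdaLatency = NaN))
  avg_ep <- colMeans(epochs$mat[rows, , drop = FALSE])
  wsel <- epochs$tgrid_ms >= lambda_window_ms[1] &
    epochs$tgrid_ms <= lambda_window_ms[2]
  y <- avg_ep[wsel]
  tt <- epochs$tgrid_ms[wsel]
  k <- which.max(y)
  lat <- tt[k]
  # parabolic sub-sample refinement of the peak time (standard ERP latency
  # practice; the amplitude stays the sampled maximum as defined)
  if (k > 1L && k < length(y)) {
    denom <- y[k - 1L] - 2 * y[k] + y[k + 1L]
    if (denom < 0) {
      delta <- 0.5 * (y[k - 1L] - y[k + 1L]) / denom
      lat <- lat + delta * (tt[2] - tt[1])
    }
  }
  c(LambdaAmplitude = y[k], LambdaLatency = lat)
}

#' Windowed lambda-response features
#'
#' Epochs the channel-averaged EEG from -100 to +300 ms around each fixation
#' onset in the window (fixation onset := saccade offset), baseline-corrects
#' by the -100..0 ms mean, averages across epochs, and reads the lambda
#' response off the average: `LambdaAmplitude` is the maximum between 50 and
#' 200 ms (microvolts), `LambdaLatency` the time of that maximum (ms). Fewer
#' than three fixations yields `NaN`.
#'
#' @param avg_eeg channel-averaged EEG (e.g. from the internal averaging
#'   used by [eeg_band_features()]), a [channel_signal()].
#' @param saccades data frame from [detect_saccades()].
#' @param window numeric `c(from, to)`, half-open.
#' @param cfg a [pipeline_config()].
#' @return Named numeric vector `LambdaAmplitude, LambdaLatency`.
#' @export
efrp_features <- function(avg_eeg, saccades, window, cfg = pipeline_config()) {
  fix <- saccades$offset_s
  epochs <- .efrp_epochs(avg_eeg, fix)
  sel <- fix >= window[1] & fix < window[2]
  .efrp_agg(epochs, sel, cfg$lambda_window_ms)
}
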