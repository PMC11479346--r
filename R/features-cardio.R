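# ECG -> R peaks -> instantaneous HR -> windowed HR statistics and
# LF/HF spectral powers; respiration accelerometer -> breath period stats.

# Index range of samples with session time in [from, to).
.window_idx <- function(ch, from, to) {
  i0 <- ceiling((from - ch$start_time) * ch$sample_rate - 1e-9) + 1
  i1 <- ceiling((to - ch$start_time) * ch$sample_rate - 1e-9)
  i0 <- max(1L, as.integer(i0))
  i1 <- min(length(ch$values), as.integer(i1))
  if (i1 < i0) integer(0) else i0:i1
}

# Centered moving average, width w samples (odd).
.movavg <- function(x, w) {
  if (w <= 1) return(x)
  k <- rep(1 / w, w)
  y <- stats::filter(x, k, sides = 2)
  y <- as.numeric(y)
  # fill edge NAs with nearest valid value
  nas <- which(is.na(y))
  if (length(nas)) {
    valid <- which(!is.na(y))
    y[nas] <- y[valid[pmax(1, findInterval(nas, valid))]]
    y[nas[nas < valid[1]]] <- y[valid[1]]
  }
  y
}

#' Detect R peaks in an ECG channel
#'
#' Band-pass filters the ECG (0.05-30 Hz by default), then applies an
#' R-wave enhancement chain: time derivative, squaring, 150-ms
#' moving-window integration, and an adaptive threshold at 50% of the
#' running median of the last eight accepted enhanced peaks. Peak times are
#' refined to the local maximum of the filtered ECG.
#'
#' @param ecg a [channel_signal()] named `ecg`.
#' @param cfg a [pipeline_config()].
#' @return Strictly increasing numeric vector of R-peak times (seconds,
#'   session clock).
#' @export
detect_r_peaks <- function(ecg, cfg = pipeline_config()) {
  fs <- ecg$sample_rate
  xf <- zerophase_bandpass(ecg$values, fs, cfg$ecg_bandpass)
  d <- c(0, diff(xf)) * fs
  sq <- d^2
  integ <- .movavg(sq, max(3L, 2L * (round(0.075 * fs)) + 1L))
  # candidate peaks: local maxima separated by >= 300 ms
  half <- max(1L, round(0.15 * fs))
  n <- length(integ)
  is_max <- integ > c(-Inf, integ[-n]) & integ >= c(integ[-1], -Inf)
  cand <- which(is_max & integ > 1e-9 * max(integ, na.rm = TRUE) &
                  !is.na(integ))
  if (length(cand) == 0 || max(integ, na.rm = TRUE) <= 0)
    stop("no rhythm", call. = FALSE)
  # enforce separation: keep the larger of peaks closer than 300 ms
  keep <- logical(length(cand))
  last <- 0L
  for (i in seq_along(cand)) {
    if (last == 0L || cand[i] - cand[last] >= 2 * half) {
      keep[i] <- TRUE; last <- i
    } else if (integ[cand[i]] > integ[cand[last]]) {
      keep[last] <- FALSE; keep[i] <- TRUE; last <- i
    }
  }
  cand <- cand[keep]
  # adaptive acceptance
  h <- integ[cand]
  init <- median(h[seq_len(min(16L, length(h)))])
  hist8 <- rep(init, 8L)
  acc <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (h[i] >= 0.5 * median(hist8)) {
      acc[i] <- TRUE
      hist8 <- c(hist8[-1], h[i])
    }
  }
  cand <- cand[acc]
  if (length(cand) < 2L) stop("no rhythm", call. = FALSE)
  # refine to the ECG maximum within +-80 ms
  w <- max(1L, round(0.08 * fs))
  ref <- vapply(cand, function(i) {
    lo <- max(1L, i - w); hi <- min(length(xf), i + w)
    as.integer(lo + which.max(xf[lo:hi]) - 1L)
  }, integer(1))
  ref <- sort(unique(ref))
  # drop refinements that collapsed onto the same beat
  ref <- ref[c(TRUE, diff(ref) >= 2 * half)]
  ecg$start_time + (ref - 1) / fs
}

# Gated instantaneous HR points: 60/RR placed at the ending beat of each
# interval; RR outside the physiological gate is flagged (dropped).
.instantaneous_hr <- function(r_peaks, gate = c(0.3, 2.0)) {
  if (length(r_peaks) < 2L)
    return(data.frame(time_s = numeric(0), hr = numeric(0)))
  rr <- diff(r_peaks)
  ok <- rr >= gate[1] & rr <= gate[2]
  data.frame(time_s = r_peaks[-1][ok], hr = 60 / rr[ok])
}

# One-sided Hann periodogram power in [lo, hi) of a uniformly sampled
# series; returns integrated band power.
.band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  tt <- seq_len(n)
  fitted <- stats::lsfit(tt, x)$residuals      # linear detrend
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  xw <- fitted * w
  sp <- abs(fft(xw))^2 / (fs * sum(w^2))
  nf <- floor(n / 2)
  f <- (seq_len(nf)) * fs / n                  # exclude DC
  psd <- 2 * sp[2:(nf + 1)]
  df <- fs / n
  sum(psd[f >= lo & f < hi]) * df
}

#' Windowed heart-rate features
#'
#' Computes the five ECG-derived features for one window: instantaneous HR
#' (60/RR at beat times, RR gated to 0.3-2 s) is cubic-spline interpolated
#' and resampled at 50 Hz across the window; `HR_mean` and `HR_sd` are taken
#' over the resampled samples, `LF` and `HF` are integrated Hann-periodogram
#' powers over 0.04-0.15 Hz and 0.15-0.40 Hz, and `LF_HF` is their ratio.
#' Fewer than four R peaks overlapping the window yields `NaN` features.
#'
#' @param r_peaks R-peak times from [detect_r_peaks()].
#' @param window numeric `c(from, to)`, half-open `[from, to)`.
#' @param cfg a [pipeline_config()].
#' @return Named numeric vector `HR_mean, HR_sd, LF, HF, LF_HF`.
#' @export
hr_features <- function(r_peaks, window, cfg = pipeline_config()) {
  out <- c(HR_mean = NaN, HR_sd = NaN, LF = NaN, HF = NaN, LF_HF = NaN)
  in_win <- r_peaks >= window[1] & r_peaks < window[2]
  if (sum(in_win) < 4L) return(out)
  ctx <- r_peaks[r_peaks >= window[1] - 10 & r_peaks < window[2] + 10]
  hr <- .instantaneous_hr(ctx, cfg$rr_gate_s)
  if (nrow(hr) < 4L) return(out)
  fs <- cfg$hr_resample_hz
  xout <- seq(window[1], window[2] - 1 / fs, by = 1 / fs)
  hr_u <- spline(hr$time_s, hr$hr, xout = xout, method = "fmm")$y
  lf <- .band_power(hr_u, fs, cfg$lf_band[1], cfg$lf_band[2])
  hf <- .band_power(hr_u, fs, cfg$hf_band[1], cfg$hf_band[2])
  c(HR_mean = mean(hr_u), HR_sd = sd(hr_u), LF = lf, HF = hf,
    LF_HF = if (hf > 0) lf / hf else NaN)
}

# Breath events: positive-going zero crossings of the differenced band-passed
# accelerometer signal.
.resp_events <- function(resp, cfg = pipeline_config()) {
  fs <- resp$sample_rate
  raw_rng <- range(resp$values, na.rm = TRUE)
  if (!all(is.finite(raw_rng)) || diff(raw_rng) < 1e-9)
    return(numeric(0))   # constant signal: nothing survives the band-pass
  xf <- zerophase_bandpass(resp$values, fs, cfg$resp_bandpass)
  rng <- range(xf, na.rm = TRUE)
  if (diff(rng) < 1e-6 * diff(raw_rng))
    return(numeric(0))   # degenerate: only filter startup residue remains
  d <- c(0, diff(xf))
  up <- which(d[-1] > 0 & d[-length(d)] <= 0) + 1L
  resp$start_time + (up - 1) / fs
}

# Mean/sd of inter-event periods whose onset lies in the window.
.resp_agg <- function(events, window) {
  if (length(events) < 2L)
    return(c(RespPeriod_mean = NaN, RespPeriod_sd = NaN))
  periods <- diff(events)
  onset <- events[-length(events)]
  sel <- onset >= window[1] & onset < window[2]
  if (sum(sel) < 1L) return(c(RespPeriod_mean = NaN, RespPeriod_sd = NaN))
  c(RespPeriod_mean = mean(periods[sel]),
    RespPeriod_sd = if (sum(sel) > 1L) sd(periods[sel]) else 0)
}

#' Windowed respiratory-period features
#'
#' Band-pass filters the respiration accelerometer (0.5-2 Hz as published,
#' configurable), applies a difference filter, marks breath events at
#' positive-going zero crossings of the differenced signal, and returns the
#' mean and standard deviation of inter-event periods whose onset lies in
#' the window. Fewer than two events yields `NaN`.
#'
#' @param resp a `resp_accel` [channel_signal()].
#' @param window numeric `c(from, to)`, half-open.
#' @param cfg a [pipeline_config()].
#' @return Named numeric vector `RespPeriod_mean, RespPeriod_sd`.
#' @export
resp_features <- function(resp, window, cfg = pipeline_config()) {
  .resp_agg(.resp_events(resp, cfg), window)
}
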