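# Saccade detection from the horizontal EOG and windowed saccade features.

# Detection velocity: central difference over +-10 ms. The 20-ms support
# suppresses sample noise (robust thresholding) at the cost of a few percent
# amplitude bias on fast saccades.
.eog_velocity <- function(x, fs) {
  w <- max(1L, round(0.01 * fs))
  n <- length(x)
  v <- numeric(n)
  i <- (w + 1L):(n - w)
  v[i] <- (x[i + w] - x[i - w]) * fs / (2 * w)
  v[seq_len(w)] <- v[w + 1L]
  v[(n - w + 1L):n] <- v[n - w]
  v
}

# Readout velocity: 5-point stencil derivative (4th-order accurate), used
# only inside detected spans so its higher noise does not affect detection.
.eog_velocity_fine <- function(x, fs) {
  n <- length(x)
  v <- numeric(n)
  i <- 3L:(n - 2L)
  v[i] <- (8 * (x[i + 1L] - x[i - 1L]) - (x[i + 2L] - x[i - 2L])) *
    fs / 12
  v[c(1L, 2L)] <- v[3L]
  v[c(n - 1L, n)] <- v[n - 2L]
  v
}

# Per-second adaptive threshold: 6 x MAD of the velocity over the trailing
# 30 s (expanding during the first 30 s), floored at `floor_uvs`.
.saccade_threshold <- function(v, fs, floor_uvs, span_s = 30) {
  n_sec <- ceiling(length(v) / fs)
  thr <- numeric(n_sec)
  for (s in seq_len(n_sec)) {
    lo <- max(1L, round((s - span_s) * fs) + 1L)
    hi <- min(length(v), round(s * fs))
    m <- stats::mad(v[lo:hi], na.rm = TRUE)
    thr[s] <- max(6 * m, floor_uvs, na.rm = TRUE)
  }
  thr
}

#' Detect saccades in the horizontal EOG
#'
#' Velocity is a smoothed time-derivative of the EOG; a saccade is a
#' contiguous span where `|velocity|` exceeds an adaptive threshold (6 x
#' median absolute deviation of the trailing 30 s of velocity, floored at
#' `cfg$saccade_speed_floor_uvs`), lasting 10-150 ms. Events closer than
#' 50 ms are merged. The peak speed is the maximum `|velocity|` in the span
#' (microvolt/s), the field proxy for saccade speed.
#'
#' @param eog an `eog_h` [channel_signal()] in microvolts.
#' @param cfg a [pipeline_config()].
#' @return Data frame with `onset_s`, `offset_s`, `peak_speed`; zero rows if
#'   no saccades.
#' @export
detect_saccades <- function(eog, cfg = pipeline_config()) {
  fs <- eog$sample_rate
  v <- .eog_velocity(eog$values, fs)
  thr_sec <- .saccade_threshold(v, fs, cfg$saccade_speed_floor_uvs)
  sec_of <- pmin(length(thr_sec), floor((seq_along(v) - 1) / fs) + 1L)
  above <- abs(v) > thr_sec[sec_of]
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  off <- ends[r$values]
  if (length(on) == 0L)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_speed = numeric(0)))
  # merge spans separated by < 50 ms
  gap <- (on[-1] - off[-length(off)]) / fs
  merged_on <- on[c(TRUE, gap >= 0.05)]
  grp <- cumsum(c(TRUE, gap >= 0.05))
  merged_off <- tapply(off, grp, max)
  on <- merged_on
  off <- as.integer(merged_off)
  dur <- (off - on + 1L) / fs
  keep <- dur >= 0.010 & dur <= 0.150
  on <- on[keep]; off <- off[keep]
  if (length(on) == 0L)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_speed = numeric(0)))
  vf <- .eog_velocity_fine(eog$values, fs)
  peak <- vapply(seq_along(on), function(k) max(abs(vf[on[k]:off[k]])),
                 numeric(1))
  data.frame(onset_s = eog$start_time + (on - 1) / fs,
             offset_s = eog$start_time + (off - 1) / fs,
             peak_speed = peak)
}

#' Windowed saccade features
#'
#' `SaccadeFreq` is the count of saccade onsets in the window divided by the
#' window length (events/s); `SaccadeSpeed_mean`/`_sd` summarise the peak
#' speeds of those events. With zero events the frequency is 0 and the speed
#' features are `NaN`.
#'
#' @param events data frame from [detect_saccades()].
#' @param window numeric `c(from, to)`, half-open.
#' @return Named numeric vector `SaccadeFreq, SaccadeSpeed_mean,
#'   SaccadeSpeed_sd`.
#' @export
saccade_features <- function(events, window) {
  sel <- events$onset_s >= window[1] & events$onset_s < window[2]
  n <- sum(sel)
  if (n == 0L)
    return(c(SaccadeFreq = 0, SaccadeSpeed_mean = NaN, SaccadeSpeed_sd = NaN))
  sp <- events$peak_speed[sel]
  c(SaccadeFreq = n / (window[2] - window[1]),
    SaccadeSpeed_mean = mean(sp),
    SaccadeSpeed_sd = if (n > 1L) sd(sp) else 0)
}
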