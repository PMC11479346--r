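# Electrodermal tonic/phasic decomposition and windowed statistics.

#' Decompose skin conductance into tonic and phasic components
#'
#' The tonic skin conductance level (SCL) is the 0.04-Hz low-pass of the
#' signal; the noise component is the 0.5-Hz high-pass; the phasic skin
#' conductance response (SCR) is the de-noised signal minus the SCL:
#' `SCR = (x - noise) - SCL`. All series share the input's length and rate;
#' `NaN` spans propagate unchanged.
#'
#' @param eda an `eda` [channel_signal()] in microsiemens, at least 120 s
#'   long.
#' @param cfg a [pipeline_config()].
#' @return List with `scl` and `scr` [channel_signal()]-like objects (name
#'   `eda`, same rate and start time).
#' @export
eda_decompose <- function(eda, cfg = pipeline_config()) {
  fs <- eda$sample_rate
  if (length(eda$values) / fs < 120)
    stop("EDA record must be at least 120 s long", call. = FALSE)
  scl <- zerophase_lowpass(eda$values, fs, cfg$scl_lowpass_hz)
  noise <- zerophase_highpass(eda$values, fs, cfg$eda_noise_highpass_hz)
  scr <- (eda$values - noise) - scl
  mk <- function(v) {
    ch <- eda
    ch$values <- v
    ch
  }
  list(scl = mk(scl), scr = mk(scr))
}

#' Windowed electrodermal features
#'
#' `SCL_mean` and `SCL_sd` over the window's tonic samples, and the `SCR`
#' feature: the trapezoidal integral of the absolute phasic component over
#' the window (microsiemens-seconds).
#'
#' @param scl,scr components from [eda_decompose()].
#' @param window numeric `c(from, to)`, half-open.
#' @return Named numeric vector `SCL_mean, SCL_sd, SCR`.
#' @export
eda_features <- function(scl, scr, window) {
  idx <- .window_idx(scl, window[1], window[2])
  if (length(idx) < 2L)
    stop("window outside the decomposed series", call. = FALSE)
  v <- scl$values[idx]
  a <- abs(scr$values[idx])
  dt <- 1 / scr$sample_rate
  integral <- sum((a[-1] + a[-length(a)]) / 2) * dt
  c(SCL_mean = mean(v), SCL_sd = sd(v), SCR = integral)
}
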