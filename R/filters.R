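# Zero-phase Butterworth filtering. Design is classical: analog prototype
# poles, frequency pre-warping, bilinear transform. Band-pass filters are a
# cascade of a high-pass and a low-pass section, each applied
# forward-backward, so event timing is unbiased (matters for saccade and
# lambda-response latencies).

.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p) * rt
  p
}

#' Butterworth filter coefficients
#'
#' Designs a digital low- or high-pass Butterworth filter via the bilinear
#' transform and returns transfer-function coefficients.
#'
#' @param order filter order.
#' @param cutoff_hz cutoff frequency, Hz.
#' @param fs sampling rate, Hz.
#' @param type `"low"` or `"high"`.
#' @return List with numerator `b` and denominator `a`.
#' @export
butter_coefs <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  Wn <- cutoff_hz / (fs / 2)
  if (Wn <= 0 || Wn >= 1)
    stop("cutoff must lie strictly inside (0, Nyquist)", call. = FALSE)
  fs2 <- 2                       # normalized design rate
  warped <- 2 * fs2 * tan(pi * Wn / 2)
  k <- seq_len(order)
  p0 <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit prototype
  if (type == "low") {
    p <- warped * p0
    z <- complex(0)
    gain <- warped^order
  } else {
    p <- warped / p0
    z <- rep(0 + 0i, order)
    gain <- 1
  }
  # bilinear transform at fs2
  fs4 <- 2 * fs2
  pd <- (fs4 + p) / (fs4 - p)
  zd <- if (length(z)) (fs4 + z) / (fs4 - z) else complex(0)
  gain_d <- gain * Re(prod(fs4 - z) / prod(fs4 - p))
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))
  b <- Re(.poly_from_roots(zd)) * gain_d
  a <- Re(.poly_from_roots(pd))
  list(b = b, a = a)
}

.filtfilt_core <- function(b, a, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 2L)
  if (padlen < 1L) padlen <- 0L
  if (padlen > 0L) {
    pre <- 2 * x[1] - x[seq(padlen + 1L, 2L)]
    post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
    xe <- c(pre, x, post)
  } else xe <- x
  y <- .iir_filter(b, a, xe)
  y <- rev(.iir_filter(b, a, rev(y)))
  if (padlen > 0L) y[seq(padlen + 1L, padlen + n)] else y
}

#' Zero-phase filtering
#'
#' Applies the filter forward and backward (`filtfilt`) with odd-reflection
#' edge padding. `NaN` runs in the input are preserved: each contiguous
#' non-`NaN` run is filtered independently and `NaN` samples stay `NaN`.
#'
#' @param b,a transfer-function coefficients from [butter_coefs()].
#' @param x numeric signal.
#' @param padlen reflection pad length in samples; defaults to
#'   `3 * (max(length(a), length(b)) - 1)` and is capped by run length.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(b, a, x, padlen = NULL) {
  if (is.null(padlen)) padlen <- 3L * (max(length(a), length(b)) - 1L)
  ok <- !is.na(x)
  if (all(ok)) return(.filtfilt_core(b, a, x, padlen))
  out <- rep(NaN, length(x))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    seg <- starts[i]:ends[i]
    if (length(seg) >= 4L)
      out[seg] <- .filtfilt_core(b, a, x[seg], padlen)
    else out[seg] <- x[seg]
  }
  out
}

# Zero-phase Butterworth convenience wrappers. `pad_s` expresses padding in
# seconds; slow cutoffs (e.g. the 0.04 Hz tonic EDA low-pass) need long pads.
zerophase_lowpass <- function(x, fs, cutoff_hz, order = 4, pad_s = NULL) {
  co <- butter_coefs(order, cutoff_hz, fs, "low")
  if (is.null(pad_s)) pad_s <- 3 / cutoff_hz
  filtfilt(co$b, co$a, x, padlen = as.integer(min(pad_s * fs,
                                                  length(x) - 2)))
}

zerophase_highpass <- function(x, fs, cutoff_hz, order = 4, pad_s = NULL) {
  co <- butter_coefs(order, cutoff_hz, fs, "high")
  if (is.null(pad_s)) pad_s <- 3 / cutoff_hz
  filtfilt(co$b, co$a, x, padlen = as.integer(min(pad_s * fs,
                                                  length(x) - 2)))
}

zerophase_bandpass <- function(x, fs, band, order = 4) {
  y <- zerophase_highpass(x, fs, band[1], order)
  zerophase_lowpass(y, fs, band[2], order)
}
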