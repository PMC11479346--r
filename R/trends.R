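# Normalized-time trend analysis: sessions of unequal length are mapped to
# a common [0,1] axis in 1000 segments, averaged with a 95% confidence
# band, and correlated with the sickness-level trend.

#' Resample a series onto normalized time
#'
#' Linearly interpolates a series onto `n_segments` equally spaced points of
#' normalized time, 0 = session start, 1 = session end.
#'
#' @param series numeric vector (length >= 2).
#' @param n_segments number of output points (default 1000).
#' @return Numeric vector of length `n_segments`.
#' @export
normalize_time_resample <- function(series, n_segments = 1000) {
  n <- length(series)
  if (n < 2L) stop("series must have at least 2 points", call. = FALSE)
  approx(x = seq(0, 1, length.out = n), y = series,
         xout = seq(0, 1, length.out = n_segments))$y
}

#' Normalized-time trend analysis
#'
#' Resamples each session's standardized features, sickness level, and
#' prediction-correctness series (correct = 1, wrong = 0) into `n_segments`
#' normalized-time segments, averages across sessions with a 95% confidence
#' band (mean +- 1.96 standard errors), and reports each feature's Pearson
#' correlation `R` (and `R^2`) between its segment-mean trend and the
#' segment-mean sickness-level trend.
#'
#' @param sessions list of per-session lists with elements `features`
#'   (standardized feature table), `labels` (label series), and optionally
#'   `correct` (0/1 vector aligned with the rows).
#' @param n_segments normalized-time grid size (default 1000).
#' @return A `vims_trend` list: `grid` (normalized time), `feature_mean`,
#'   `feature_lo`, `feature_hi` (matrices segments x features),
#'   `vims_mean`, `vims_lo`, `vims_hi`, optional `accuracy_mean` (+ bounds),
#'   and `correlations` (`data.table` with `feature`, `R`, `R2`).
#' @export
trend_analysis <- function(sessions, n_segments = 1000) {
  if (length(sessions) < 2L)
    stop("need at least 2 sessions", call. = FALSE)
  grid <- seq(0, 1, length.out = n_segments)
  nf <- length(.FEATURE_NAMES)
  arr <- array(NA_real_, dim = c(n_segments, nf, length(sessions)))
  vims <- matrix(NA_real_, n_segments, length(sessions))
  acc <- matrix(NA_real_, n_segments, length(sessions))
  has_acc <- all(vapply(sessions, function(s) !is.null(s$correct),
                        logical(1)))
  for (k in seq_along(sessions)) {
    s <- sessions[[k]]
    for (j in seq_len(nf))
      arr[, j, k] <- normalize_time_resample(s$features[[.FEATURE_NAMES[j]]],
                                             n_segments)
    vims[, k] <- normalize_time_resample(as.numeric(s$labels$vims_level),
                                         n_segments)
    if (has_acc)
      acc[, k] <- normalize_time_resample(as.numeric(s$correct), n_segments)
  }
  band <- function(m) {
    mu <- rowMeans(m)
    sem <- apply(m, 1, sd) / sqrt(ncol(m))
    list(mean = mu, lo = mu - 1.96 * sem, hi = mu + 1.96 * sem)
  }
  fm <- matrix(NA_real_, n_segments, nf,
               dimnames = list(NULL, .FEATURE_NAMES))
  flo <- fm; fhi <- fm
  for (j in seq_len(nf)) {
    b <- band(arr[, j, , drop = TRUE])
    fm[, j] <- b$mean; flo[, j] <- b$lo; fhi[, j] <- b$hi
  }
  vb <- band(vims)
  cors <- data.table::data.table(feature = .FEATURE_NAMES, R = NA_real_,
                                 R2 = NA_real_)
  if (var(vb$mean) > 0) {
    for (j in seq_len(nf)) {
      r <- if (var(fm[, j]) > 0)
        stats::cor(fm[, j], vb$mean) else NaN
      data.table::set(cors, i = j, j = "R", value = r)
      data.table::set(cors, i = j, j = "R2", value = r^2)
    }
  } else {
    warning("constant sickness trend: correlations undefined",
            call. = FALSE)
  }
  out <- list(grid = grid, feature_mean = fm, feature_lo = flo,
              feature_hi = fhi, vims_mean = vb$mean, vims_lo = vb$lo,
              vims_hi = vb$hi, correlations = cors)
  if (has_acc) {
    ab <- band(acc)
    out$accuracy_mean <- ab$mean
    out$accuracy_lo <- ab$lo
    out$accuracy_hi <- ab$hi
  }
  structure(out, class = "vims_trend")
}
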