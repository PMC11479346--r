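# Per-second sickness labels, baseline-ratio standardization, pooled
# percentile clipping and previous-value outlier repair.

#' Build the per-second sickness label series
#'
#' The level at time `t` is the most recent reported level at or before `t`
#' (level 1 before the first report). A level-5 report terminates the
#' session at its own timestamp, so the series never contains a 5 and its
#' maximum is 4. The binary class is 1 for levels 3-4, 0 for 1-2.
#'
#' @param reports list of [report_event()]s (ordered).
#' @param timestamps integer feature timestamps (from [extract_features()]).
#' @return A `data.table` with `t_s`, `vims_level`, `binary_class`.
#' @export
build_label_series <- function(reports, timestamps) {
  times <- vapply(reports, function(r) r$time_s, numeric(1))
  levels <- vapply(reports, function(r) r$vims_level, integer(1))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("events unordered", call. = FALSE)
  if (any(levels == 5L)) {
    k5 <- which(levels == 5L)[1]
    timestamps <- timestamps[timestamps < times[k5]]
    times <- times[seq_len(k5 - 1L)]
    levels <- levels[seq_len(k5 - 1L)]
  }
  idx <- findInterval(timestamps, times)
  lv <- ifelse(idx == 0L, 1L, levels[pmax(idx, 1L)])
  data.table::data.table(t_s = as.integer(timestamps),
                         vims_level = as.integer(lv),
                         binary_class = as.integer(lv >= 3L))
}

#' Standardize features to per-session baseline ratios
#'
#' Each feature is divided by its session reference: the mean of the 90
#' feature rows with timestamps in `[30, 120)` (the first 120 s of the
#' session under the half-open window convention), `NaN` rows excluded from
#' the mean. A reference smaller than `1e-9` in magnitude makes that
#' feature's ratios `NaN` (logged); fewer than half the baseline rows valid
#' triggers an `unreliable baseline` warning.
#'
#' @param fs feature table from [extract_features()].
#' @param cfg a [pipeline_config()].
#' @return List: `ratios` (table shaped like `fs`), `reference` (named
#'   numeric), `log` (character notes).
#' @export
standardize_features <- function(fs, cfg = pipeline_config()) {
  W <- cfg$window_s
  base_rows <- fs$t_s >= W & fs$t_s < cfg$baseline_span_s
  n_base <- sum(base_rows)
  if (n_base < 1L)
    stop("session too short for a baseline: need timestamps in [",
         W, ", ", cfg$baseline_span_s, ")", call. = FALSE)
  ratios <- data.table::copy(fs)
  reference <- setNames(numeric(length(.FEATURE_NAMES)), .FEATURE_NAMES)
  log <- character(0)
  for (f in .FEATURE_NAMES) {
    v <- fs[[f]]
    bv <- v[base_rows]
    n_ok <- sum(!is.na(bv))
    if (n_ok < ceiling(n_base / 2)) {
      warning("unreliable baseline for feature '", f, "' (", n_ok, " of ",
              n_base, " rows valid)", call. = FALSE)
      log <- c(log, sprintf("unreliable baseline: %s (%d/%d)", f, n_ok,
                            n_base))
    }
    ref <- mean(bv, na.rm = TRUE)
    reference[f] <- ref
    if (!is.finite(ref) || abs(ref) < 1e-9) {
      ratios[[f]] <- rep(NaN, length(v))
      log <- c(log, sprintf("degenerate reference: %s", f))
    } else {
      ratios[[f]] <- v / ref
    }
  }
  list(ratios = ratios, reference = reference, log = log)
}

#' Fit pooled clip thresholds
#'
#' Pools the ratio-standardized values of all sessions per feature and
#' returns the empirical 1st and 99th percentiles (linear-interpolation
#' definition) as lower/upper clip thresholds.
#'
#' @param ratio_tables list of ratio tables (from [standardize_features()]).
#' @param percentiles length-2 numeric, default `c(1, 99)`.
#' @return A `data.table` with `feature`, `lower`, `upper`.
#' @export
fit_clip_thresholds <- function(ratio_tables, percentiles = c(1, 99)) {
  out <- data.table::data.table(feature = .FEATURE_NAMES,
                                lower = NA_real_, upper = NA_real_)
  for (f in .FEATURE_NAMES) {
    pooled <- unlist(lapply(ratio_tables, function(tb) tb[[f]]),
                     use.names = FALSE)
    pooled <- pooled[!is.na(pooled)]
    if (length(pooled) == 0L)
      stop("feature '", f, "' is all-NaN in the pooled data", call. = FALSE)
    q <- quantile(pooled, percentiles / 100, names = FALSE, type = 7)
    data.table::set(out, i = which(out$feature == f), j = "lower",
                    value = q[1])
    data.table::set(out, i = which(out$feature == f), j = "upper",
                    value = q[2])
  }
  out
}

#' Repair out-of-range and missing values
#'
#' Walks each feature in time order and replaces any value outside its
#' `[lower, upper]` clip thresholds, or any `NaN`, with the previous
#' already-repaired value; a bad leading value takes the first subsequent
#' in-range value. Every replacement is logged.
#'
#' @param ratios a ratio table (one session).
#' @param thresholds from [fit_clip_thresholds()].
#' @return List: `features` (repaired table), `repair_log` (`data.table`
#'   with `t_s`, `feature`, `reason`).
#' @export
repair_outliers <- function(ratios, thresholds) {
  out <- data.table::copy(ratios)
  logs <- list()
  for (f in .FEATURE_NAMES) {
    v <- out[[f]]
    th <- thresholds[thresholds$feature == f, ]
    bad <- is.na(v) | v < th$lower | v > th$upper
    if (all(bad))
      stop("feature '", f, "' is entirely out of range", call. = FALSE)
    if (any(bad)) {
      reason <- ifelse(is.na(v[bad]), "missing",
                       ifelse(v[bad] < th$lower, "below lower threshold",
                              "above upper threshold"))
      logs[[f]] <- data.table::data.table(t_s = out$t_s[bad], feature = f,
                                          reason = reason)
      # leading bad values take the first in-range value
      first_ok <- which(!bad)[1]
      if (first_ok > 1L) v[seq_len(first_ok - 1L)] <- v[first_ok]
      # previous-value carry-forward
      idx <- cumsum(!bad)
      idx[seq_len(first_ok)] <- pmax(idx[seq_len(first_ok)], 1L)
      v <- v[!bad][pmax(idx, 1L)]
      out[[f]] <- v
    }
  }
  list(features = out,
       repair_log = if (length(logs)) data.table::rbindlist(logs) else
         data.table::data.table(t_s = integer(0), feature = character(0),
                                reason = character(0)))
}

#' Assemble the modelling dataset
#'
#' Stacks standardized, repaired feature tables with their label series into
#' one row-per-second table carrying participant and display identifiers,
#' and tabulates per-session class counts.
#'
#' @param sessions list of `list(features =, labels =)` pairs with aligned
#'   timestamps (features already standardized and repaired).
#' @return List: `data` (stacked `data.table`), `class_counts` (per
#'   participant/display/class row counts).
#' @export
assemble_dataset <- function(sessions) {
  tabs <- lapply(sessions, function(s) {
    ft <- s$features
    lb <- s$labels
    m <- ft[ft$t_s %in% lb$t_s, ]
    lb2 <- lb[lb$t_s %in% ft$t_s, ]
    if (nrow(m) == 0L ||
        !identical(as.integer(m$t_s), as.integer(lb2$t_s)))
      stop("misaligned feature/label timestamps", call. = FALSE)
    m$vims_level <- lb2$vims_level
    m$binary_class <- lb2$binary_class
    m
  })
  data <- data.table::rbindlist(tabs)
  counts <- data[, list(n = .N),
                 by = c("participant_id", "display", "binary_class")]
  list(data = data, class_counts = counts)
}
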