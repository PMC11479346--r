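# Seeded synthetic-session generator. Emits all eight channels with a
# ground-truth sickness trajectory and sickness-coupled dynamics whose signs
# follow the published trends: HR up, respiratory period up, SCL/SCR up,
# saccade frequency down, saccade speed up, theta up, alpha down, lambda
# amplitude and latency up.

.LEVEL_THRESHOLDS <- c(0.2, 0.4, 0.6, 0.8)

#' Scenario configuration for the synthetic generator
#'
#' Describes one simulated operating session. `severity = "severe"` drives
#' the latent sickness trajectory to the report ceiling (level 5), which
#' terminates the session at that report; `"mild"` stays at level <= 2.
#' Effect sizes are fractional changes from baseline reached at full latent
#' severity; their signs are fixed to the published trend directions.
#'
#' @param duration_s planned session length, seconds (default 600; real
#'   operating sessions run ~25 min, shortened here for desk-scale
#'   runtimes).
#' @param report_interval_s task-cycle length between subjective reports.
#' @param severity `"severe"` or `"mild"`.
#' @param onset_frac,rise_frac latent-severity onset time and rise length as
#'   fractions of `duration_s` (gradual vs rapid onsets).
#' @param effects named list of fractional effect sizes at full severity:
#'   `hr`, `resp_period`, `scl`, `scr_rate`, `saccade_rate`,
#'   `saccade_speed`, `alpha`, `theta`, `lambda_amp`, `lambda_lat`.
#' @param noise named list of per-channel noise amplitudes (`ecg`,
#'   `ecg_wander`, `resp`, `eda`, `eog`, `eeg`, `eeg_pink`); scaled by
#'   `noise_scale`.
#' @param baselines named list of baseline physiology: `hr0` (bpm),
#'   `resp_period0` (s), `scl0` (uS), `scr_rate0` (events/s), `scr_area0`
#'   (uS s), `saccade_rate0` (events/s), `saccade_speed0` (uV/s),
#'   `alpha_amp0`, `theta_amp0` (uV), `lambda_amp0` (uV), `lambda_lat0` (ms).
#' @param hrv_lf_amp,hrv_hf_amp amplitudes (bpm) of sinusoidal HR modulation
#'   at 0.1 Hz and 0.3 Hz.
#' @param noise_scale multiplier on all noise amplitudes (0 = noise-free).
#' @param effect_scale multiplier on all effect sizes.
#' @param sample_rates named list: `ecg`, `eog`, `eeg` (250 Hz), `resp_accel`
#'   (50 Hz), `eda` (32 Hz) by default.
#' @param seed integer; fully determines the session.
#' @return A list with class `vims_scenario`.
#' @export
scenario_config <- function(duration_s = 600, report_interval_s = 60,
                            severity = c("severe", "mild"),
                            onset_frac = 0.2, rise_frac = 0.65,
                            effects = list(), noise = list(),
                            baselines = list(),
                            hrv_lf_amp = 2.5, hrv_hf_amp = 1.5,
                            noise_scale = 1, effect_scale = 1,
                            sample_rates = list(), seed = 1L) {
  severity <- match.arg(severity)
  eff <- utils::modifyList(list(
    hr = 0.10, resp_period = 0.25, scl = 0.30, scr_rate = 1.5,
    saccade_rate = -0.40, saccade_speed = 0.30, alpha = -0.35, theta = 0.50,
    alpha_freq = -1.0, theta_freq = -0.5,
    lambda_amp = 0.40, lambda_lat = 0.25), effects)
  nz <- utils::modifyList(list(
    ecg = 15, ecg_wander = 40, resp = 0.05, eda = 0.008, eog = 4,
    eeg = 2, eeg_pink = 4, alpha_freq_jitter = 0.4,
    theta_freq_jitter = 0.4), noise)
  bl <- utils::modifyList(list(
    hr0 = 65, resp_period0 = 1.0, scl0 = 5, scr_rate0 = 1 / 30,
    scr_area0 = 0.5, saccade_rate0 = 2.0, saccade_speed0 = 3000,
    alpha_amp0 = 6, theta_amp0 = 3, lambda_amp0 = 10, lambda_lat0 = 100),
    baselines)
  sr <- utils::modifyList(list(ecg = 250, eog = 250, eeg = 250,
                               resp_accel = 50, eda = 32), sample_rates)
  dir_ok <- c(hr = 1, resp_period = 1, scl = 1, scr_rate = 1,
              saccade_rate = -1, saccade_speed = 1, alpha = -1, theta = 1,
              alpha_freq = -1, theta_freq = -1,
              lambda_amp = 1, lambda_lat = 1)
  for (nm in names(dir_ok)) {
    if (eff[[nm]] * dir_ok[[nm]] < 0)
      stop("effect '", nm, "' has the wrong sign (fixed trend direction)",
           call. = FALSE)
  }
  if (duration_s < 150 + report_interval_s)
    stop("duration too short for one baseline plus one report", call. = FALSE)
  structure(list(duration_s = duration_s,
                 report_interval_s = report_interval_s, severity = severity,
                 onset_frac = onset_frac, rise_frac = rise_frac,
                 effects = lapply(eff, function(e) e * effect_scale),
                 noise = lapply(nz, function(v) v * noise_scale),
                 baselines = bl, hrv_lf_amp = hrv_lf_amp,
                 hrv_hf_amp = hrv_hf_amp, sample_rates = sr,
                 seed = as.integer(seed)),
            class = "vims_scenario")
}

# Latent severity in [0,1] as a function of time (piecewise linear).
.latent_severity <- function(cfg) {
  s_max <- if (cfg$severity == "severe") 1.0 else 0.3
  t_on <- cfg$onset_frac * cfg$duration_s
  rise <- cfg$rise_frac * cfg$duration_s
  function(t) pmin(1, pmax(0, (t - t_on) / rise)) * s_max
}

.level_of <- function(s) 1L + findInterval(s, .LEVEL_THRESHOLDS)

# Bi-exponential SCR pulse (rise 0.75 s, decay 2.5 s), unit area.
.scr_pulse <- function(t, tau_r = 0.75, tau_d = 2.5) {
  ifelse(t < 0, 0, (exp(-t / tau_d) - exp(-t / tau_r)) / (tau_d - tau_r))
}

# Analytic area of a unit-area SCR pulse, restricted to [a, b] after onset.
.scr_pulse_area <- function(a, b, tau_r = 0.75, tau_d = 2.5) {
  a <- max(a, 0)
  if (b <= a) return(0)
  intexp <- function(tau, x) tau * (1 - exp(-x / tau))
  ((intexp(tau_d, b) - intexp(tau_d, a)) -
     (intexp(tau_r, b) - intexp(tau_r, a))) / (tau_d - tau_r)
}

# 1/f ("pink") noise via spectral shaping, unit sd.
.pink_noise <- function(n) {
  white <- stats::rnorm(n)
  sp <- fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  sp <- sp / sqrt(f)
  x <- Re(fft(sp, inverse = TRUE)) / n
  x / sd(x)
}

# Inhomogeneous point events by thinning, with a minimum gap.
.draw_events <- function(rate_fun, rate_max, duration, min_gap) {
  t <- 0
  out <- numeric(0)
  last <- -Inf
  while (TRUE) {
    t <- t + stats::rexp(1, rate_max)
    if (t >= duration) break
    if (stats::runif(1) <= rate_fun(t) / rate_max && t - last >= min_gap) {
      out <- c(out, t)
      last <- t
    }
  }
  out
}

#' Simulate one synthetic session
#'
#' Generates a complete eight-channel [recording()] plus its ground truth
#' from a [scenario_config()]. The ECG is an R-peak impulse train (beat rate
#' tracking the latent severity, with sinusoidal LF/HF rate modulation)
#' convolved with a biphasic Gaussian-derivative QRS template, plus baseline
#' wander and white noise. Respiration is an oscillation whose period grows
#' with severity. EDA is a rising tonic level plus bi-exponential phasic
#' pulses of known area at a severity-coupled rate, plus high-frequency
#' noise. The horizontal EOG is a sequence of sigmoidal gaze steps whose
#' rate falls and peak slope rises with severity. Each EEG channel combines
#' 1/f noise, an alpha oscillator losing power and a theta oscillator
#' gaining power with severity, and a lambda-response template after every
#' fixation onset. Reports are emitted at each task-cycle boundary; a severe
#' scenario reaches level 5 and the session truncates at that report.
#'
#' @param cfg a [scenario_config()].
#' @param participant_id,display_condition metadata for the recording.
#' @return List with elements `recording` (a `vims_recording`) and `truth`
#'   (a `vims_ground_truth` list: 1-Hz trend grids, SCR event table, saccade
#'   event table, level trajectory).
#' @export
simulate_session <- function(cfg, participant_id = "P01",
                             display_condition = "MD") {
  stopifnot(inherits(cfg, "vims_scenario"))
  withr::local_seed(cfg$seed)
  sev <- .latent_severity(cfg)
  eff <- cfg$effects
  bl <- cfg$baselines
  nz <- cfg$noise

  # --- reports and truncation ---
  rep_times <- seq(cfg$report_interval_s, cfg$duration_s,
                   by = cfg$report_interval_s)
  rep_levels <- .level_of(sev(rep_times))
  duration <- cfg$duration_s
  if (cfg$severity == "severe") {
    k5 <- which(rep_levels == 5L)
    if (length(k5) == 0L)
      stop("severe scenario never reaches level 5; lengthen the session",
           call. = FALSE)
    keep <- seq_len(k5[1])
    rep_times <- rep_times[keep]
    rep_levels <- rep_levels[keep]
    duration <- rep_times[k5[1]]
  }
  if (duration < 150)
    stop("duration too short for one baseline plus one report", call. = FALSE)
  g <- sev  # severity coupling function on [0, duration]

  # --- ECG ---
  fs_ecg <- cfg$sample_rates$ecg
  hr_of <- function(t) bl$hr0 * (1 + eff$hr * g(t)) +
    cfg$hrv_lf_amp * sin(2 * pi * 0.10 * t) +
    cfg$hrv_hf_amp * sin(2 * pi * 0.30 * t)
  beats <- numeric(0)
  t <- stats::runif(1, 0, 0.5)
  while (t < duration + 2) {
    beats <- c(beats, t)
    t <- t + 60 / hr_of(t)
  }
  n_ecg <- round(duration * fs_ecg)
  ecg <- numeric(n_ecg)
  sig_q <- 0.02
  tt <- seq(-0.05, 0.05, by = 1 / fs_ecg)
  qrs <- -(tt / sig_q) * exp(0.5) * exp(-tt^2 / (2 * sig_q^2)) * 800
  half <- (length(qrs) - 1) / 2
  for (b in beats) {
    i0 <- round(b * fs_ecg) + 1
    lo <- i0 - half; hi <- i0 + half
    if (lo >= 1 && hi <= n_ecg) ecg[lo:hi] <- ecg[lo:hi] + qrs
  }
  tgrid_ecg <- (seq_len(n_ecg) - 1) / fs_ecg
  ecg <- ecg + nz$ecg_wander * sin(2 * pi * 0.25 * tgrid_ecg +
                                     stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(n_ecg, 0, max(nz$ecg, 1e-12))

  # --- respiration accelerometer ---
  fs_resp <- cfg$sample_rates$resp_accel
  n_resp <- round(duration * fs_resp)
  tgrid_resp <- (seq_len(n_resp) - 1) / fs_resp
  period_of <- function(t) bl$resp_period0 * (1 + eff$resp_period * g(t))
  phase <- cumsum(1 / period_of(tgrid_resp)) / fs_resp
  resp <- 0.5 * sin(2 * pi * phase) +
    stats::rnorm(n_resp, 0, max(nz$resp, 1e-12))

  # --- EDA ---
  fs_eda <- cfg$sample_rates$eda
  n_eda <- round(duration * fs_eda)
  tgrid_eda <- (seq_len(n_eda) - 1) / fs_eda
  scl_trend <- bl$scl0 * (1 + eff$scl * g(tgrid_eda))
  scr_rate_of <- function(t) bl$scr_rate0 * (1 + eff$scr_rate * g(t))
  scr_times <- .draw_events(scr_rate_of,
                            bl$scr_rate0 * (1 + max(0, eff$scr_rate)) + 1e-9,
                            duration, min_gap = 1.0)
  scr_areas <- bl$scr_area0 * exp(stats::rnorm(length(scr_times), 0, 0.3))
  eda <- scl_trend
  if (length(scr_times)) {
    for (k in seq_along(scr_times)) {
      i0 <- floor(scr_times[k] * fs_eda) + 1
      i1 <- min(n_eda, i0 + round(25 * fs_eda))
      if (i0 > n_eda) next
      tloc <- tgrid_eda[i0:i1] - scr_times[k]
      eda[i0:i1] <- eda[i0:i1] + scr_areas[k] * .scr_pulse(tloc)
    }
  }
  if (nz$eda > 0) {
    hf <- zerophase_highpass(stats::rnorm(n_eda), fs_eda, 1.0, order = 4)
    eda <- eda + nz$eda * hf / sd(hf)
  }

  # --- EOG: sigmoidal gaze steps ---
  fs_eog <- cfg$sample_rates$eog
  n_eog <- round(duration * fs_eog)
  tgrid_eog <- (seq_len(n_eog) - 1) / fs_eog
  sac_rate_of <- function(t) bl$saccade_rate0 * (1 + eff$saccade_rate * g(t))
  sac_times <- .draw_events(sac_rate_of, bl$saccade_rate0 + 1e-9, duration,
                            min_gap = 0.25)
  sac_times <- sac_times[sac_times > 0.5 & sac_times < duration - 0.5]
  n_sac <- length(sac_times)
  sac_speed <- bl$saccade_speed0 * (1 + eff$saccade_speed * g(sac_times)) *
    exp(stats::rnorm(n_sac, 0, 0.05))
  sac_amp <- stats::runif(n_sac, 60, 150)
  pos <- 0
  eog <- numeric(n_eog)
  gaze <- numeric(n_sac + 1)
  sign_s <- numeric(n_sac)
  for (k in seq_len(n_sac)) {
    s <- sample(c(-1, 1), 1)
    if (abs(pos + s * sac_amp[k]) > 300) s <- -s
    sign_s[k] <- s
    pos <- pos + s * sac_amp[k]
    gaze[k + 1] <- pos
  }
  # logistic transitions: x = A / (1 + exp(-k (t - t0))), peak slope A k / 4;
  # between transitions the gaze sits at its step level
  eog <- if (n_sac > 0) gaze[findInterval(tgrid_eog, sac_times) + 1] else
    rep(gaze[1], n_eog)
  for (k in seq_len(n_sac)) {
    kk <- 4 * sac_speed[k] / sac_amp[k]
    span <- 8 / kk
    i0 <- max(1, floor((sac_times[k] - span) * fs_eog))
    i1 <- min(n_eog, ceiling((sac_times[k] + span) * fs_eog))
    tloc <- tgrid_eog[i0:i1] - sac_times[k]
    eog[i0:i1] <- eog[i0:i1] +
      sign_s[k] * sac_amp[k] * (stats::plogis(kk * tloc) - (tloc > 0))
  }
  eog <- eog + stats::rnorm(n_eog, 0, max(nz$eog, 1e-12))
  # saccade onset/offset: where the transition velocity crosses the detector
  # floor (velocity of a logistic step is v_peak * sech^2(k t / 2)); the
  # offset doubles as the fixation onset
  cross_dt <- (sac_amp / (2 * sac_speed)) *
    acosh(sqrt(pmax(sac_speed / 500, 1.0001)))
  sac_onset <- sac_times - cross_dt
  fix_onset <- sac_times + cross_dt

  # --- EEG (4 channels) ---
  fs_eeg <- cfg$sample_rates$eeg
  n_eeg <- round(duration * fs_eeg)
  tgrid_eeg <- (seq_len(n_eeg) - 1) / fs_eeg
  alpha_amp <- bl$alpha_amp0 * (1 + eff$alpha * g(tgrid_eeg))
  theta_amp <- bl$theta_amp0 * (1 + eff$theta * g(tgrid_eeg))
  # oscillator frequencies shift with severity and wander slowly (real peak
  # frequencies are not constant); jitter scales with the noise setting
  slow_jitter <- function(amp) {
    if (amp <= 0) return(numeric(n_eeg))
    j <- zerophase_lowpass(stats::rnorm(n_eeg), fs_eeg, 0.2, order = 2)
    amp * j / sd(j)
  }
  f_alpha <- 10 + eff$alpha_freq * g(tgrid_eeg) +
    slow_jitter(nz$alpha_freq_jitter)
  f_theta <- 6 + eff$theta_freq * g(tgrid_eeg) +
    slow_jitter(nz$theta_freq_jitter)
  ph_a <- stats::runif(1, 0, 2 * pi)
  ph_t <- stats::runif(1, 0, 2 * pi)
  common <- alpha_amp * sin(2 * pi * cumsum(f_alpha) / fs_eeg + ph_a) +
    theta_amp * sin(2 * pi * cumsum(f_theta) / fs_eeg + ph_t)
  lam_amp_of <- function(t) bl$lambda_amp0 * (1 + eff$lambda_amp * g(t))
  lam_lat_of <- function(t) (bl$lambda_lat0 / 1000) *
    (1 + eff$lambda_lat * g(t))
  lam <- numeric(n_eeg)
  sig_l <- 0.025
  for (k in seq_along(fix_onset)) {
    peak_t <- fix_onset[k] + lam_lat_of(fix_onset[k])
    i0 <- max(1, floor((peak_t - 4 * sig_l) * fs_eeg))
    i1 <- min(n_eeg, ceiling((peak_t + 4 * sig_l) * fs_eeg))
    if (i0 >= i1) next
    tloc <- tgrid_eeg[i0:i1] - peak_t
    lam[i0:i1] <- lam[i0:i1] +
      lam_amp_of(fix_onset[k]) * exp(-tloc^2 / (2 * sig_l^2))
  }
  eeg <- list()
  for (ch in .EEG_CHANNELS) {
    gain <- stats::runif(1, 0.9, 1.1)
    chn <- gain * (common + lam)
    if (nz$eeg_pink > 0) chn <- chn + nz$eeg_pink * .pink_noise(n_eeg)
    chn <- chn + stats::rnorm(n_eeg, 0, max(nz$eeg, 1e-12))
    eeg[[ch]] <- chn
  }

  # --- assemble ---
  channels <- c(list(
    ecg = channel_signal("ecg", fs_ecg, ecg),
    resp_accel = channel_signal("resp_accel", fs_resp, resp),
    eda = channel_signal("eda", fs_eda, eda),
    eog_h = channel_signal("eog_h", fs_eog, eog)),
    lapply(setNames(.EEG_CHANNELS, .EEG_CHANNELS), function(ch)
      channel_signal(ch, fs_eeg, eeg[[ch]])))
  reports <- lapply(seq_along(rep_times), function(i)
    report_event(rep_times[i], rep_levels[i]))
  rec <- recording(participant_id, display_condition, channels, reports,
                   duration)

  tg <- 0:(ceiling(duration) - 1)
  truth <- structure(list(
    time_s = tg,
    severity = g(tg),
    level = .level_of(g(tg)),
    hr_trend = bl$hr0 * (1 + eff$hr * g(tg)),
    resp_period_trend = period_of(tg),
    scl_trend = bl$scl0 * (1 + eff$scl * g(tg)),
    alpha_amp_trend = bl$alpha_amp0 * (1 + eff$alpha * g(tg)),
    theta_amp_trend = bl$theta_amp0 * (1 + eff$theta * g(tg)),
    alpha_freq_trend = 10 + eff$alpha_freq * g(tg),
    theta_freq_trend = 6 + eff$theta_freq * g(tg),
    lambda_amp_trend = lam_amp_of(tg),
    lambda_lat_trend = 1000 * lam_lat_of(tg),
    saccade_rate_trend = sac_rate_of(tg),
    scr_events = data.frame(time_s = scr_times, area = scr_areas),
    saccades = data.frame(onset_s = sac_onset, center_s = sac_times,
                          fixation_onset_s = fix_onset,
                          peak_speed = sac_speed),
    beats = beats[beats < duration],
    duration_s = duration,
    config = cfg), class = "vims_ground_truth")
  list(recording = rec, truth = truth)
}

#' Injected SCR pulse area within a window
#'
#' Analytic area contributed by the generator's bi-exponential skin
#' conductance pulses inside a time window; the independent oracle for the
#' extracted SCR window-integral feature.
#'
#' @param scr_events data frame with `time_s` and `area` columns (from the
#'   ground truth).
#' @param from,to window bounds, seconds.
#' @return Area in microsiemens-seconds.
#' @export
scr_injected_area <- function(scr_events, from, to) {
  if (nrow(scr_events) == 0) return(0)
  sum(vapply(seq_len(nrow(scr_events)), function(k)
    scr_events$area[k] * .scr_pulse_area(from - scr_events$time_s[k],
                                         to - scr_events$time_s[k]),
    numeric(1)))
}

#' Simulate a cohort of participants
#'
#' Generates two sessions (multi-display and head-mounted display) per
#' participant. By default 7 of 9 participants develop severe sickness in at
#' least one session (the first three of them under both displays, the rest
#' under the head-mounted display only) and the last two stay mild
#' throughout, mirroring the reference cohort structure. Participants
#' carry random baseline offsets shared by their two sessions, so grouped
#' cross-validation is meaningful. Per-session seeds derive deterministically
#' from the master seed.
#'
#' @param n_participants number of participants (>= 2).
#' @param template a [scenario_config()] used for every session (severity and
#'   seed fields are overridden per session).
#' @param seed master seed.
#' @param severe_fraction fraction of participants with at least one severe
#'   session (default 7/9).
#' @param both_fraction fraction of severe participants severe under both
#'   displays (default 3/7).
#' @return List of session objects, each `list(recording, truth)`, ordered
#'   participant-major (MD then HMD).
#' @export
simulate_cohort <- function(n_participants, template = scenario_config(),
                            seed = 1L, severe_fraction = 7 / 9,
                            both_fraction = 3 / 7) {
  if (n_participants < 2) stop("need at least 2 participants", call. = FALSE)
  withr::local_seed(as.integer(seed))
  n_severe <- round(severe_fraction * n_participants)
  n_both <- round(both_fraction * n_severe)
  severe_ids <- seq_len(n_severe)
  both_ids <- if (n_both > 0) severe_ids[seq(2, length.out = n_both)] else
    integer(0)
  both_ids <- both_ids[!is.na(both_ids) & both_ids <= n_severe]
  session_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                     n_participants * 2),
                          nrow = n_participants)
  part_factor <- matrix(exp(stats::rnorm(n_participants * 4, 0, 0.06)),
                        nrow = n_participants)
  onset <- stats::runif(n_participants, 0.1, 0.3)
  rise <- stats::runif(n_participants, 0.45, 0.7)
  out <- list()
  for (i in seq_len(n_participants)) {
    pid <- sprintf("P%02d", i)
    bl <- template$baselines
    bl$hr0 <- bl$hr0 * part_factor[i, 1]
    bl$scl0 <- bl$scl0 * part_factor[i, 2]
    bl$saccade_rate0 <- bl$saccade_rate0 * part_factor[i, 3]
    bl$alpha_amp0 <- bl$alpha_amp0 * part_factor[i, 4]
    for (d in c("MD", "HMD")) {
      severe <- (i %in% severe_ids) &&
        (d == "HMD" || i %in% both_ids)
      cfg <- template
      cfg$severity <- if (severe) "severe" else "mild"
      cfg$baselines <- bl
      cfg$onset_frac <- onset[i]
      cfg$rise_frac <- rise[i]
      cfg$seed <- session_seeds[i, if (d == "MD") 1L else 2L]
      class(cfg) <- "vims_scenario"
      out[[paste(pid, d, sep = "_")]] <-
        simulate_session(cfg, participant_id = pid, display_condition = d)
    }
  }
  out
}
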