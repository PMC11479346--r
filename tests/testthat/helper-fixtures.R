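# Shared fixtures and independent oracles. Everything is generated in code;
# expensive sessions are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Noise-free scenario: no channel noise, no HRV modulation; effects and
# severity configurable.
nf_scenario <- function(seed, duration_s = 300, severity = "mild",
                        effect_scale = 0, ...) {
  scenario_config(duration_s = duration_s, severity = severity,
                  noise_scale = 0, effect_scale = effect_scale,
                  hrv_lf_amp = 0, hrv_hf_amp = 0, seed = seed, ...)
}

nf_session <- function(seed = 3, duration_s = 300, ...) {
  key <- paste0("nf_", seed, "_", duration_s, "_",
                paste(deparse(substitute(list(...))), collapse = ""))
  cached(key, simulate_session(nf_scenario(seed, duration_s, ...)))
}

# Construct an R-peak train whose RR intervals follow rr_of(t).
make_beats <- function(rr_of, t_end, t0 = 0.1) {
  beats <- t0
  while (tail(beats, 1) < t_end) {
    t <- tail(beats, 1)
    beats <- c(beats, t + rr_of(t))
  }
  beats
}

# Brute-force metric oracles ------------------------------------------------

# ROC-AUC by explicit threshold enumeration + trapezoidal integration.
bf_roc_auc <- function(y, p) {
  th <- sort(unique(p), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(p[y == 1] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(p[y == 0] >= t), numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Average precision by explicit threshold enumeration (step integral).
bf_pr_auc <- function(y, p) {
  th <- sort(unique(p), decreasing = TRUE)
  rec <- vapply(th, function(t) sum(y == 1 & p >= t) / sum(y == 1),
                numeric(1))
  prec <- vapply(th, function(t) sum(y == 1 & p >= t) / sum(p >= t),
                 numeric(1))
  sum(diff(c(0, rec)) * prec)
}

bf_kappa <- function(y, pred) {
  po <- mean(y == pred)
  pe <- mean(y == 1) * mean(pred == 1) + mean(y == 0) * mean(pred == 0)
  (po - pe) / (1 - pe)
}

# Build a y/prob pair realising exact confusion counts at threshold 0.5.
confusion_case <- function(tp, fn, fp, tn) {
  y <- c(rep(1, tp + fn), rep(0, fp + tn))
  p <- c(rep(0.9, tp), rep(0.1, fn), rep(0.9, fp), rep(0.1, tn))
  list(y = y, p = p)
}

# Small quick dataset for model tests: separable two-class table with
# participant ids, signal in two named features.
toy_dataset <- function(n_per = 150, n_participants = 4, seed = 1,
                        signal_features = c("SaccadeFreq", "SCR"),
                        noise_sd = 0.25) {
  withr::local_seed(seed)
  rows <- list()
  for (i in seq_len(n_participants)) {
    y <- rep(c(0L, 1L), each = n_per / 2)
    X <- matrix(stats::rnorm(n_per * 23, 1, noise_sd), n_per, 23,
                dimnames = list(NULL, vims_feature_names()))
    for (f in signal_features)
      X[, f] <- X[, f] + ifelse(y == 1L, 1.5, 0)
    dt <- data.table::as.data.table(X)
    dt$binary_class <- y
    dt$vims_level <- ifelse(y == 1L, 3L, 1L)
    dt$participant_id <- sprintf("P%02d", i)
    dt$display <- "MD"
    dt$t_s <- seq_len(n_per) + 29L
    rows[[i]] <- dt
  }
  data.table::rbindlist(rows)
}
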