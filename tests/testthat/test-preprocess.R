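mk_reports <- function(...) {
  spec <- list(...)
  lapply(spec, function(p) report_event(p[1], p[2]))
}

test_that("label series follows most-recent-report semantics", {
  lb <- build_label_series(mk_reports(c(100, 2), c(200, 3)), 30:299)
  expect_true(all(lb$vims_level[lb$t_s < 100] == 1L))
  expect_true(all(lb$vims_level[lb$t_s >= 100 & lb$t_s < 200] == 2L))
  expect_true(all(lb$vims_level[lb$t_s >= 200] == 3L))
  expect_true(all(lb$binary_class == as.integer(lb$t_s >= 200)))

  none <- build_label_series(list(), 30:99)
  expect_true(all(none$vims_level == 1L))
  expect_true(all(none$binary_class == 0L))
})

test_that("a level-5 report caps the series at level 4", {
  lb <- build_label_series(
    mk_reports(c(120, 2), c(300, 3), c(420, 4), c(540, 5)), 30:539)
  expect_identical(max(lb$t_s), 539L)
  expect_identical(max(lb$vims_level), 4L)
  expect_true(all(lb$binary_class == as.integer(lb$vims_level >= 3L)))
})

test_that("standardization divides by the 90-row baseline mean", {
  ft <- cached("ft_nf1", extract_features(nf_session(seed = 1)$recording))
  std <- standardize_features(ft)
  expect_identical(sum(ft$t_s >= 30 & ft$t_s < 120), 90L)
  # constant features give ratios of exactly 1
  const_cols <- vims_feature_names()[vapply(vims_feature_names(), function(f)
    isTRUE(sd(ft[[f]]) < 1e-12), logical(1))]
  for (f in setdiff(vims_feature_names(), const_cols)) {
    ref <- mean(ft[[f]][ft$t_s < 120], na.rm = TRUE)
    if (abs(ref) > 1e-9)
      expect_equal(std$ratios[[f]], ft[[f]] / ref, tolerance = 1e-12)
  }
  # hand rule: reference 2, value 3 -> ratio 1.5
  toy <- data.table::copy(ft)
  toy$HR_mean <- rep(2, nrow(toy))
  toy$HR_mean[200] <- 3
  std2 <- standardize_features(toy)
  expect_equal(std2$ratios$HR_mean[200], 1.5)
})

test_that("standardization is scale-invariant and NaN-aware", {
  ft <- cached("ft_nf1", extract_features(nf_session(seed = 1)$recording))
  scaled <- data.table::copy(ft)
  scaled$SCL_mean <- scaled$SCL_mean * 7.3
  expect_equal(standardize_features(scaled)$ratios$SCL_mean,
               standardize_features(ft)$ratios$SCL_mean, tolerance = 1e-12)
  holey <- data.table::copy(ft)
  holey$HF[10:20] <- NaN
  std <- standardize_features(holey)
  ref <- mean(holey$HF[holey$t_s < 120], na.rm = TRUE)
  expect_equal(std$reference[["HF"]], ref)
  expect_warning(
    standardize_features(within(data.table::copy(ft),
                                LF[t_s < 100] <- NaN)),
    "unreliable baseline")
})

test_that("clip thresholds are linear-interpolation percentiles of pooled data", {
  mk_tab <- function(v) {
    tb <- data.table::as.data.table(
      matrix(1, length(v), 23, dimnames = list(NULL, vims_feature_names())))
    tb$HR_mean <- v
    tb$t_s <- seq_along(v)
    tb
  }
  # brute-force percentile oracle (type-7 linear interpolation)
  bf_pct <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[pmin(lo + 1, length(x))] - x[lo])
  }
  th <- fit_clip_thresholds(list(mk_tab(1:100)))
  expect_equal(th$lower[th$feature == "HR_mean"], bf_pct(1:100, 0.01))
  expect_equal(th$upper[th$feature == "HR_mean"], bf_pct(1:100, 0.99))
  expect_equal(th$lower[th$feature == "HR_mean"], 1.99)
  expect_equal(th$upper[th$feature == "HR_mean"], 99.01)

  th1 <- fit_clip_thresholds(list(mk_tab(rep(1, 50))))
  expect_equal(th1$lower[th1$feature == "HR_mean"], 1)
  expect_equal(th1$upper[th1$feature == "HR_mean"], 1)

  # 2% spike mass at 1000: the 99th percentile lands inside the spike mass
  spikes <- c(rep(1, 980), rep(1000, 20))
  th2 <- fit_clip_thresholds(list(mk_tab(spikes)))
  expect_equal(th2$upper[th2$feature == "HR_mean"], 1000)

  bad <- mk_tab(rep(NaN, 10))
  expect_error(fit_clip_thresholds(list(bad)), "all-NaN")
})

test_that("outlier repair carries the previous value forward", {
  mk_tab <- function(v) {
    tb <- data.table::as.data.table(
      matrix(1, length(v), 23, dimnames = list(NULL, vims_feature_names())))
    tb$HR_mean <- v
    tb$t_s <- seq_along(v) + 29L
    tb
  }
  thr <- data.table::data.table(feature = vims_feature_names(),
                                lower = 0.5, upper = 2)
  r <- repair_outliers(mk_tab(c(1.0, 1.1, 50.0, 1.2)), thr)
  expect_equal(r$features$HR_mean, c(1.0, 1.1, 1.1, 1.2))
  expect_identical(nrow(r$repair_log), 1L)
  expect_identical(r$repair_log$feature, "HR_mean")

  clean <- mk_tab(c(1.0, 1.1, 1.2, 1.3))
  r2 <- repair_outliers(clean, thr)
  expect_equal(r2$features, clean)
  expect_identical(nrow(r2$repair_log), 0L)

  r3 <- repair_outliers(mk_tab(c(NaN, 1.0, 1.0)), thr)
  expect_equal(r3$features$HR_mean, c(1.0, 1.0, 1.0))

  expect_error(repair_outliers(mk_tab(c(100, 200, 300)), thr),
               "entirely out of range")
})

test_that("repair is idempotent on random ratio tables", {
  withr::with_seed(8, {
    for (rep_i in 1:5) {
      v <- exp(stats::rnorm(200, 0, 1))
      tb <- data.table::as.data.table(
        matrix(exp(stats::rnorm(200 * 23, 0, 0.3)), 200, 23,
               dimnames = list(NULL, vims_feature_names())))
      tb$HR_mean <- v
      tb$t_s <- seq_len(200) + 29L
      thr <- fit_clip_thresholds(list(tb))
      once <- repair_outliers(tb, thr)
      twice <- repair_outliers(once$features, thr)
      expect_equal(twice$features, once$features)
      expect_identical(nrow(twice$repair_log), 0L)
      # post-repair values never violate the thresholds
      for (f in c("HR_mean", "SCR")) {
        th <- thr[thr$feature == f, ]
        expect_true(all(once$features[[f]] >= th$lower &
                          once$features[[f]] <= th$upper))
      }
    }
  })
})

test_that("assemble_dataset stacks sessions and conserves class counts", {
  mk_sess <- function(n, pid, cls) {
    ft <- data.table::as.data.table(
      matrix(1, n, 23, dimnames = list(NULL, vims_feature_names())))
    ft <- cbind(data.table::data.table(participant_id = pid, display = "MD",
                                       t_s = seq_len(n) + 29L), ft)
    lb <- data.table::data.table(t_s = seq_len(n) + 29L,
                                 vims_level = ifelse(cls == 1L, 3L, 1L),
                                 binary_class = cls)
    list(features = ft, labels = lb)
  }
  ds <- assemble_dataset(list(mk_sess(570, "P01", 0L), mk_sess(270, "P02", 1L)))
  expect_identical(nrow(ds$data), 840L)
  expect_identical(sum(ds$class_counts$n), 840L)
  expect_identical(ds$data$binary_class,
                   c(rep(0L, 570), rep(1L, 270)))

  bad <- mk_sess(100, "P03", 0L)
  bad$labels$t_s <- bad$labels$t_s + 1000L
  expect_error(assemble_dataset(list(bad)), class = "error")
})
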