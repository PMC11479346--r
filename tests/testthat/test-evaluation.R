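test_that("binary_metrics matches brute-force oracles on random inputs", {
  withr::with_seed(12, {
    for (i in 1:100) {
      n <- sample(20:80, 1)
      y <- stats::rbinom(n, 1, stats::runif(1, 0.2, 0.8))
      if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
      p <- round(stats::runif(n), sample(1:3, 1))  # force ties
      m <- binary_metrics(y, p)
      expect_equal(m[["roc_auc"]], bf_roc_auc(y, p), tolerance = 1e-12)
      expect_equal(m[["pr_auc"]], bf_pr_auc(y, p), tolerance = 1e-12)
      expect_equal(m[["accuracy"]], mean((p >= 0.5) == (y == 1)))
      expect_equal(m[["kappa"]], bf_kappa(y, as.integer(p >= 0.5)),
                   tolerance = 1e-12)
    }
  })
})

test_that("hand-checked confusion example: TP=45 FN=5 FP=10 TN=40", {
  cc <- confusion_case(45, 5, 10, 40)
  m <- binary_metrics(cc$y, cc$p)
  expect_equal(m[["accuracy"]], 0.85)
  expect_equal(m[["kappa"]], 0.70)

  perfect <- binary_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
})

test_that("uninformative probabilities give chance-level ROC-AUC", {
  withr::with_seed(5, {
    y <- stats::rbinom(1e4, 1, 0.3)
    p <- stats::runif(1e4)
  })
  expect_lt(abs(binary_metrics(y, p)[["roc_auc"]] - 0.5), 0.02)
})

test_that("ROC-AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(6, {
    y <- stats::rbinom(500, 1, 0.4)
    p <- stats::runif(500)
  })
  a0 <- binary_metrics(y, p)[["roc_auc"]]
  expect_equal(binary_metrics(y, stats::qlogis(p * 0.98 + 0.01))[["roc_auc"]],
               a0, tolerance = 1e-12)
  expect_equal(binary_metrics(y, p^3)[["roc_auc"]], a0, tolerance = 1e-12)
})

test_that("recall/precision diagnostics handle the published worked shape", {
  # 9 true positives, 91 false negatives, 9 false positives
  y <- c(rep(1, 100), rep(0, 50))
  p <- c(rep(0.9, 9), rep(0.1, 91), rep(0.9, 9), rep(0.1, 41))
  rp <- recall_precision_at(y, p)
  expect_equal(rp[["recall"]], 0.09)
  expect_equal(rp[["precision"]], 0.5)

  all_pos <- recall_precision_at(c(1, 1, 0), c(0.9, 0.9, 0.9))
  expect_equal(all_pos[["recall"]], 1)
  none <- recall_precision_at(c(1, 0), c(0.1, 0.1))
  expect_equal(none[["recall"]], 0)
  expect_true(is.nan(none[["precision"]]))
})

test_that("normalized-time resampling is linear interpolation onto [0,1]", {
  expect_equal(normalize_time_resample(rep(3.5, 7), 1000), rep(3.5, 1000))
  ramp <- seq(0, 1, length.out = 200)
  rs <- normalize_time_resample(ramp, 1000)
  expect_lt(max(abs(rs - seq(0, 1, length.out = 1000))), 1 / 200)
  x <- stats::runif(1000)
  expect_equal(normalize_time_resample(x, 1000), x, tolerance = 1e-12)
  expect_error(normalize_time_resample(1, 1000), "at least 2")
})

mk_trend_session <- function(feat_series, levels, correct = NULL) {
  n <- length(levels)
  ft <- data.table::as.data.table(
    matrix(feat_series, n, 23, dimnames = list(NULL, vims_feature_names())))
  list(features = ft,
       labels = data.table::data.table(t_s = seq_len(n) + 29L,
                                       vims_level = levels),
       correct = correct)
}

test_that("trend correlations recover exact positive/negative coupling", {
  lv <- rep(1:4, each = 50)
  s1 <- mk_trend_session(as.numeric(lv), lv)
  s2 <- mk_trend_session(as.numeric(lv) * 2, lv)
  tr <- trend_analysis(list(s1, s2), n_segments = 200)
  expect_true(all(abs(tr$correlations$R - 1) < 1e-9))
  expect_equal(tr$correlations$R2, tr$correlations$R^2, tolerance = 1e-12)
  expect_true(all(tr$feature_lo <= tr$feature_mean + 1e-12))
  expect_true(all(tr$feature_hi >= tr$feature_mean - 1e-12))

  neg <- trend_analysis(list(mk_trend_session(-as.numeric(lv) + 10, lv),
                             mk_trend_session(-as.numeric(lv) + 9, lv)),
                        n_segments = 200)
  expect_true(all(abs(neg$correlations$R + 1) < 1e-9))

  expect_warning(
    flat <- trend_analysis(list(mk_trend_session(as.numeric(lv), rep(2L, 200)),
                                mk_trend_session(as.numeric(lv), rep(2L, 200))),
                           n_segments = 100),
    "constant")
  expect_true(all(is.na(flat$correlations$R)))
})

test_that("the 95% band covers a known mean at nominal rate", {
  n_rep <- 500
  n_sessions <- 30
  n_seg <- 50
  len <- 60
  truth <- 2
  covered <- 0L
  total <- 0L
  template <- data.table::as.data.table(
    matrix(truth, len, 23, dimnames = list(NULL, vims_feature_names())))
  lv <- rep(1:4, each = 15)
  withr::with_seed(99, {
    for (r in seq_len(n_rep)) {
      sessions <- lapply(seq_len(n_sessions), function(i) {
        ft <- data.table::copy(template)
        ft$HR_mean <- truth + stats::rnorm(len)
        list(features = ft,
             labels = data.table::data.table(t_s = seq_len(len) + 29L,
                                             vims_level = lv))
      })
      tr <- trend_analysis(sessions, n_segments = n_seg)
      covered <- covered + sum(tr$feature_lo[, "HR_mean"] <= truth &
                                 truth <= tr$feature_hi[, "HR_mean"])
      total <- total + n_seg
    }
  })
  expect_gte(covered / total, 0.93)
  expect_lte(covered / total, 0.97)
})

test_that("evaluate_folds appends an arithmetic mean row", {
  folds <- list(
    A = list(participant = "A",
             predictions = data.table::data.table(
               y_true = c(1, 1, 0, 0), y_prob = c(0.9, 0.8, 0.2, 0.1))),
    B = list(participant = "B",
             predictions = data.table::data.table(
               y_true = c(1, 0, 1, 0), y_prob = c(0.9, 0.8, 0.2, 0.1))))
  ev <- evaluate_folds(folds)
  expect_identical(ev$participant, c("A", "B", "Mean"))
  expect_equal(ev$accuracy[3], mean(ev$accuracy[1:2]))
  expect_equal(ev$roc_auc[3], mean(ev$roc_auc[1:2]))
})
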