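# Gradient-boosted VIMS classifier: class-weighted binary boosting with
# stepwise hyperparameter search (stratified 5-fold CV, mean ROC-AUC
# objective) and leave-one-participant-out evaluation.

.HYPER_NAMES <- c("lambda_l1", "lambda_l2", "num_leaves", "feature_fraction",
                  "bagging_fraction", "bagging_freq", "min_child_samples")

#' Default booster hyperparameters
#'
#' The seven tunables plus fixed training controls (learning rate 0.1,
#' histogram bin cap 63).
#'
#' @return Named list.
#' @export
default_hyperparameters <- function() {
  list(lambda_l1 = 0, lambda_l2 = 0, num_leaves = 31, feature_fraction = 1,
       bagging_fraction = 1, bagging_freq = 0, min_child_samples = 20)
}

.feature_matrix <- function(tab) {
  as.matrix(tab[, .FEATURE_NAMES, with = FALSE])
}

# Per-sample weights: class weight = n_total / (2 * n_class).
.class_weights <- function(y) {
  n <- length(y)
  n1 <- sum(y == 1L)
  n0 <- n - n1
  if (n0 == 0L || n1 == 0L)
    stop("training data holds a single class", call. = FALSE)
  ifelse(y == 1L, n / (2 * n1), n / (2 * n0))
}

.booster_params <- function(hyper, seed, n_rounds, early_stopping_rounds,
                            es_min_delta = 0) {
  c(hyper,
    list(learning_rate = 0.1, max_bin = 63, n_rounds = n_rounds,
         early_stopping_rounds = early_stopping_rounds,
         es_min_delta = es_min_delta, seed = seed))
}

.fit_booster <- function(X, y, w, hyper, seed, n_rounds = 1000,
                         early_stopping_rounds = 30, es_min_delta = 0,
                         Xv = NULL, yv = NULL) {
  if (is.null(Xv)) {
    Xv <- matrix(numeric(0), nrow = 0, ncol = ncol(X))
    yv <- numeric(0)
  }
  .gbdt_train(X, as.numeric(y), w,
              .booster_params(hyper, seed, n_rounds, early_stopping_rounds,
                              es_min_delta),
              Xv, as.numeric(yv))
}

# Stratified k-fold assignment on the binary label.
.stratified_folds <- function(y, k, seed) {
  withr::local_seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Mean best validation AUC across stratified folds for one hyper setting.
# Tuning fits are capped at 150 rounds with a 1e-4 minimum-improvement early
# stop: AUC differences below that are noise for model selection, and the
# shorter cap keeps the stepwise search fast (the final fit uses the full
# 1000-round cap).
.cv_auc <- function(X, y, hyper, k, seed, n_rounds = 150) {
  fold <- .stratified_folds(y, k, seed)
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    w <- .class_weights(y[tr])
    fit <- .fit_booster(X[tr, , drop = FALSE], y[tr], w, hyper,
                        seed = seed + f, n_rounds = n_rounds,
                        early_stopping_rounds = 20, es_min_delta = 1e-4,
                        Xv = X[!tr, , drop = FALSE], yv = y[!tr])
    aucs[f] <- fit$best_valid_auc
  }
  mean(aucs)
}

#' Stepwise hyperparameter search
#'
#' Tunes the seven booster hyperparameters (`lambda_l1`, `lambda_l2`,
#' `num_leaves`, `feature_fraction`, `bagging_fraction`, `bagging_freq`,
#' `min_child_samples`) by a staged search in the style of automated
#' boosting tuners: feature fraction, then tree size, then bagging, then L1/
#' L2 leaf regularisation (log-uniform draws), then minimum leaf size. Each
#' trial is scored by mean ROC-AUC over stratified 5-fold cross-validation
#' with class weights; the trial budget is divided across stages.
#'
#' @param train_table dataset rows (features + `binary_class`).
#' @param seed integer seed; the search is fully reproducible.
#' @param n_trials total trial budget (default 20).
#' @param n_folds stratified folds (default 5).
#' @return List: `hyperparameters` (the seven tuned values), `trials`
#'   (`data.table` log with one row per trial), `best_auc`.
#' @export
tune_hyperparameters <- function(train_table, seed = 1L, n_trials = 20L,
                                 n_folds = 5L) {
  y <- train_table$binary_class
  if (length(unique(y)) < 2L)
    stop("training data holds a single class", call. = FALSE)
  X <- .feature_matrix(train_table)
  withr::local_seed(as.integer(seed))
  best <- default_hyperparameters()
  trials <- list()
  trial_no <- 0L

  eval_setting <- function(hyper, stage) {
    trial_no <<- trial_no + 1L
    auc <- .cv_auc(X, y, hyper, n_folds, seed = seed + 1000L * trial_no)
    trials[[trial_no]] <<- data.table::as.data.table(
      c(list(trial = trial_no, stage = stage, auc = auc), hyper))
    auc
  }
  run_stage <- function(stage, candidates) {
    scores <- vapply(candidates, function(h) eval_setting(h, stage),
                     numeric(1))
    candidates[[which.max(scores)]]
  }
  # budget split across the five stages, never below one trial per stage
  quota <- pmax(1L, floor(n_trials * c(4, 4, 3, 5, 4) / 20))

  cand <- lapply(seq(0.4, 1.0, length.out = quota[1]), function(v)
    utils::modifyList(best, list(feature_fraction = round(v, 2))))
  best <- run_stage("feature_fraction", cand)

  leaves <- c(7L, 15L, 31L, 63L, 127L)[seq_len(quota[2])]
  cand <- lapply(leaves, function(v)
    utils::modifyList(best, list(num_leaves = v)))
  best <- run_stage("num_leaves", cand)

  cand <- lapply(seq_len(quota[3]), function(i)
    utils::modifyList(best, list(
      bagging_fraction = round(stats::runif(1, 0.4, 1), 3),
      bagging_freq = sample(1:7, 1))))
  cand <- c(cand, list(utils::modifyList(best, list(bagging_fraction = 1,
                                                    bagging_freq = 0))))
  best <- run_stage("bagging", cand)

  cand <- lapply(seq_len(quota[4]), function(i)
    utils::modifyList(best, list(
      lambda_l1 = signif(10^stats::runif(1, -8, 1), 3),
      lambda_l2 = signif(10^stats::runif(1, -8, 1), 3))))
  cand <- c(cand, list(best))
  best <- run_stage("regularisation", cand)

  mcs <- c(5L, 10L, 25L, 50L, 100L)[seq_len(quota[5])]
  cand <- lapply(mcs, function(v)
    utils::modifyList(best, list(min_child_samples = v)))
  best <- run_stage("min_child_samples", cand)

  trials <- data.table::rbindlist(trials, fill = TRUE)
  list(hyperparameters = best[.HYPER_NAMES],
       trials = trials, best_auc = max(trials$auc))
}

#' Train the gradient-boosted classifier
#'
#' Fits the boosted ensemble with class weights on an internal stratified
#' 90/10 split (the 10% is the early-stopping validation set; boosting is
#' capped at 1000 rounds). The fitted model exposes predicted probabilities
#' and split-gain feature importance.
#'
#' @param train_table dataset rows (features + `binary_class`).
#' @param hyperparameters the seven tuned values (e.g. from
#'   [tune_hyperparameters()], or [default_hyperparameters()]).
#' @param seed integer seed.
#' @return A `vims_model` object.
#' @export
train_model <- function(train_table, hyperparameters = default_hyperparameters(),
                        seed = 1L) {
  y <- train_table$binary_class
  if (length(unique(y)) < 2L)
    stop("training data holds a single class", call. = FALSE)
  X <- .feature_matrix(train_table)
  fold <- .stratified_folds(y, 10L, seed)
  va <- fold == 1L
  w <- .class_weights(y[!va])
  fit <- .fit_booster(X[!va, , drop = FALSE], y[!va], w,
                      hyperparameters[.HYPER_NAMES], seed = seed,
                      n_rounds = 1000, early_stopping_rounds = 30,
                      Xv = X[va, , drop = FALSE], yv = y[va])
  imp <- fit$importance_gain
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp),
                                                   length(imp))
  structure(list(booster = fit,
                 hyperparameters = hyperparameters[.HYPER_NAMES],
                 class_weights = c(`0` = unique(w[y[!va] == 0L]),
                                   `1` = unique(w[y[!va] == 1L])),
                 importance = setNames(imp, .FEATURE_NAMES),
                 train_participants = unique(train_table$participant_id),
                 seed = as.integer(seed)),
            class = "vims_model")
}

#' @export
predict.vims_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else .feature_matrix(newdata)
  raw <- .gbdt_predict_raw(object$booster, X)
  1 / (1 + exp(-raw))
}

#' Feature-importance table
#'
#' Split-gain importance of the 23 features, normalized to sum to one, in
#' the canonical feature order.
#'
#' @param model a `vims_model`.
#' @return A `data.table` with `feature` and `importance`.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "vims_model"))
  data.table::data.table(feature = .FEATURE_NAMES,
                         importance = as.numeric(model$importance))
}

#' @export
print.vims_model <- function(x, ...) {
  cat("<vims_model> boosted trees:", x$booster$best_iter, "\n")
  cat("  hyperparameters:",
      paste(names(x$hyperparameters), unlist(x$hyperparameters),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Leave-one-participant-out cross-validation
#'
#' One fold per participant who ever reached the severe class (binary label
#' 1) in any session. In each fold, every session of the held-out
#' participant forms the test set; all remaining participants (including
#' never-severe ones, unless `include_mild_participants = FALSE`) form the
#' training set, on which hyperparameters are tuned (when `tune = TRUE`)
#' and the final model is fitted. Nothing from the held-out participant
#' touches tuning or training.
#'
#' @param dataset assembled dataset (`data` element of
#'   [assemble_dataset()]).
#' @param seed master seed; per-fold seeds derive from it.
#' @param n_trials tuning budget per fold (see [tune_hyperparameters()]).
#' @param tune if `FALSE`, skip tuning and use `hyperparameters`.
#' @param hyperparameters used when `tune = FALSE`.
#' @param include_mild_participants keep never-severe participants in every
#'   training fold (default `TRUE`).
#' @return List of folds; each holds `participant`, `model`, `predictions`
#'   (`data.table`: ids, `t_s`, `y_true`, `y_prob`).
#' @export
loocv <- function(dataset, seed = 1L, n_trials = 20L, tune = TRUE,
                  hyperparameters = default_hyperparameters(),
                  include_mild_participants = TRUE) {
  parts <- unique(dataset$participant_id)
  if (length(parts) < 3L) stop("need at least 3 participants", call. = FALSE)
  severe <- sort(unique(dataset$participant_id[dataset$binary_class == 1L]))
  if (length(severe) == 0L) stop("no severe participants", call. = FALSE)
  if (length(severe) < 2L)
    stop("need at least 2 severe participants", call. = FALSE)
  folds <- list()
  for (i in seq_along(severe)) {
    p <- severe[i]
    test <- dataset[dataset$participant_id == p, ]
    train <- dataset[dataset$participant_id != p, ]
    if (!include_mild_participants)
      train <- train[train$participant_id %in% severe, ]
    fold_seed <- as.integer(seed) + 7919L * i
    hyper <- if (tune)
      tune_hyperparameters(train, seed = fold_seed,
                           n_trials = n_trials)$hyperparameters
    else hyperparameters
    model <- train_model(train, hyper, seed = fold_seed)
    prob <- predict(model, test)
    folds[[p]] <- list(participant = p, model = model,
                       predictions = data.table::data.table(
                         participant_id = test$participant_id,
                         display = test$display, t_s = test$t_s,
                         y_true = test$binary_class, y_prob = prob))
  }
  folds
}

#' Write a fitted model to a directory
#'
#' Stores the ensemble as plain text: `hyperparameters.csv`,
#' `importance.csv`, `trees.csv` (one row per node) and `meta.csv`.
#'
#' @param model a `vims_model`.
#' @param path directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "vims_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  hp <- data.table::data.table(parameter = names(model$hyperparameters),
                               value = unlist(model$hyperparameters))
  data.table::fwrite(hp, file.path(path, "hyperparameters.csv"))
  data.table::fwrite(feature_importance(model),
                     file.path(path, "importance.csv"))
  trees <- model$booster$trees
  rows <- lapply(seq_along(trees), function(t) {
    tr <- trees[[t]]
    # thresholds/values as %.17g text so bin-edge comparisons survive
    data.table::data.table(tree = t - 1L, node = seq_along(tr$feat) - 1L,
                           feat = tr$feat, thr = sprintf("%.17g", tr$thr),
                           left = tr$left, right = tr$right,
                           val = sprintf("%.17g", tr$val))
  })
  data.table::fwrite(data.table::rbindlist(rows),
                     file.path(path, "trees.csv"))
  meta <- data.table::data.table(
    name = c("base_score", "best_iter", "seed", "n_features",
             "train_participants"),
    value = c(sprintf("%.17g", model$booster$base_score),
              as.character(model$booster$best_iter),
              as.character(model$seed),
              as.character(length(.FEATURE_NAMES)),
              paste(model$train_participants, collapse = ";")))
  data.table::fwrite(meta, file.path(path, "meta.csv"))
  invisible(path)
}

#' Read a fitted model from a directory
#'
#' @param path directory written by [write_model()].
#' @return A `vims_model`.
#' @export
read_model <- function(path) {
  hp <- data.table::fread(file.path(path, "hyperparameters.csv"))
  hyper <- as.list(setNames(hp$value, hp$parameter))
  for (nm in c("num_leaves", "bagging_freq", "min_child_samples"))
    hyper[[nm]] <- as.integer(hyper[[nm]])
  nodes <- data.table::fread(file.path(path, "trees.csv"))
  meta <- data.table::fread(file.path(path, "meta.csv"))
  mv <- setNames(meta$value, meta$name)
  trees <- lapply(split(nodes, nodes$tree), function(tb) {
    tb <- tb[order(tb$node), ]
    list(feat = as.integer(tb$feat), thr = as.numeric(tb$thr),
         left = as.integer(tb$left), right = as.integer(tb$right),
         val = as.numeric(tb$val))
  })
  imp <- data.table::fread(file.path(path, "importance.csv"))
  booster <- list(trees = unname(trees),
                  base_score = as.numeric(mv[["base_score"]]),
                  best_iter = as.integer(mv[["best_iter"]]))
  structure(list(booster = booster, hyperparameters = hyper[.HYPER_NAMES],
                 importance = setNames(imp$importance, imp$feature),
                 train_participants = strsplit(mv[["train_participants"]],
                                               ";")[[1]],
                 seed = as.integer(mv[["seed"]])),
            class = "vims_model")
}
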