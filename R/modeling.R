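# Balanced random-forest modeling on folded circular fingerprints, with the
# associated splitting protocol and performance metrics.

.default_grid <- function() {
  list(nodesize = c(1, 2, 5, 10), ntree = c(25, 50, 100, 200, 400))
}

#' Stratified train/test splits over independent trials
#'
#' For each trial, draws a random test set of approximately
#' `test_fraction` of each class (within one compound of the stratified
#' ideal), the remainder forming the training set. Reproducible under
#' `seed`.
#'
#' @param labels class label per compound.
#' @param n_trials number of independent trials (default 10).
#' @param test_fraction test-set fraction (default 0.3).
#' @param seed integer seed for the split stream.
#' @return list of `n_trials` lists with integer index vectors `train`,
#'   `test`.
#' @export
stratified_trials <- function(labels, n_trials = 10, test_fraction = 0.3,
                              seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("every class needs at least 2 members for stratification",
         call. = FALSE)
  }
  set.seed(seed)
  lapply(seq_len(n_trials), function(t) {
    test <- integer(0)
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      k <- round(test_fraction * length(idx))
      k <- max(1L, min(length(idx) - 1L, k))
      test <- c(test, sample(idx, k))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}

# Fit one balanced random forest: per-tree bootstrap draws are balanced by
# sampling min(class size) compounds from every class (stratified sampsize).
.fit_one_brf <- function(x, y, ntree, nodesize, seed) {
  set.seed(seed)
  n_draw <- min(table(y))
  randomForest::randomForest(
    x = x, y = y, ntree = ntree, nodesize = nodesize,
    strata = y, sampsize = rep(n_draw, nlevels(y)))
}

# Grid selection on an inner stratified validation split (macro F1), then a
# refit on the full training data with the winning hyperparameters.
.fit_brf <- function(x, y, grid = .default_grid(), seed = 1,
                     validation_fraction = 0.3) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training data has a single class", call. = FALSE)
  combos <- expand.grid(nodesize = grid$nodesize, ntree = grid$ntree)
  if (nrow(combos) == 0) stop("empty hyperparameter grid", call. = FALSE)
  inner <- stratified_trials(as.character(y), n_trials = 1,
                             test_fraction = validation_fraction,
                             seed = seed)[[1]]
  best <- NULL
  best_f1 <- -Inf
  for (i in seq_len(nrow(combos))) {
    fit <- .fit_one_brf(x[inner$train, , drop = FALSE], droplevels(y[inner$train]),
                        ntree = combos$ntree[i], nodesize = combos$nodesize[i],
                        seed = seed + i)
    pred <- stats::predict(fit, x[inner$test, , drop = FALSE])
    conf <- confusion_matrix(as.character(y[inner$test]), as.character(pred),
                             classes = levels(y))
    f1 <- suppressMessages(macro_metrics(conf))["F1"]
    if (f1 > best_f1) {
      best_f1 <- f1
      best <- combos[i, ]
    }
  }
  fit <- .fit_one_brf(x, y, ntree = best$ntree, nodesize = best$nodesize,
                      seed = seed)
  list(forest = fit, ntree = best$ntree, nodesize = best$nodesize,
       validation_f1 = unname(best_f1),
       sampsize = rep(min(table(y)), nlevels(y)), classes = levels(y))
}

#' Train a balanced random-forest classifier on SMILES
#'
#' Featurizes compounds as folded circular fingerprints (diameter 4),
#' selects tree count and leaf size on an inner stratified validation split
#' by macro F1, and fits a class-balanced random forest: each tree's
#' bootstrap draws the same number of compounds (the minority class size)
#' from every class. Class probabilities are tree-vote fractions.
#'
#' @param smiles training compound SMILES.
#' @param labels class label per compound.
#' @param n_bits fingerprint length (default 2048).
#' @param grid list with numeric vectors `nodesize` (minimum samples per
#'   leaf; default 1, 2, 5, 10) and `ntree` (default 25, 50, 100, 200, 400).
#' @param seed integer seed.
#' @param validation_fraction inner validation fraction (default 0.3).
#' @return a `molce_classifier`: list with `predict_proba(smiles)` (matrix
#'   of per-class probabilities), `classes`, `n_bits`, and the chosen
#'   hyperparameters (`ntree`, `nodesize`, `sampsize`).
#' @export
train_brf <- function(smiles, labels, n_bits = 2048, grid = .default_grid(),
                      seed = 1, validation_fraction = 0.3) {
  x <- ecfp4(smiles, n_bits)
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  fit <- .fit_brf(x, labels, grid = grid, seed = seed,
                  validation_fraction = validation_fraction)
  structure(list(
    predict_proba = function(smiles) {
      xx <- ecfp4(smiles, n_bits)
      colnames(xx) <- paste0("b", seq_len(ncol(xx)))
      pr <- stats::predict(fit$forest, xx, type = "prob")
      pr[, order(colnames(pr)), drop = FALSE]
    },
    classes = sort(fit$classes), n_bits = n_bits,
    ntree = fit$ntree, nodesize = fit$nodesize, sampsize = fit$sampsize,
    validation_f1 = fit$validation_f1),
    class = "molce_classifier")
}

#' Confusion matrix with a fixed class set
#'
#' @param truth,pred character vectors of true and predicted labels.
#' @param classes class levels (default: union of observed labels).
#' @return square integer matrix, rows = true classes, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  as.matrix(table(factor(truth, levels = classes),
                  factor(pred, levels = classes)))
}

#' Balanced accuracy
#'
#' Binary: the mean of true positive and true negative rates. Multiclass:
#' the macro mean of per-class recall (which reduces to the binary formula
#' for two classes).
#'
#' @param confusion square confusion matrix (rows = truth).
#' @return value in `[0, 1]`.
#' @export
balanced_accuracy <- function(confusion) {
  if (length(confusion) == 0 || sum(confusion) == 0) {
    stop("empty confusion matrix", call. = FALSE)
  }
  rs <- rowSums(confusion)
  rec <- diag(confusion)[rs > 0] / rs[rs > 0]
  mean(rec)
}

#' Macro-averaged precision, recall and F1
#'
#' Computes one-vs-rest precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' `F1 = 2*TP/(2*TP+FP+FN)` separately for each class and returns the
#' arithmetic means with equal class weights. A class that is never
#' predicted contributes precision 0 (reported via a message).
#'
#' @param confusion square confusion matrix (rows = truth).
#' @return named numeric vector with elements `precision`, `recall`, `F1`.
#' @export
macro_metrics <- function(confusion) {
  cls <- seq_len(nrow(confusion))
  prec <- rec <- f1 <- numeric(length(cls))
  for (k in cls) {
    tp <- confusion[k, k]
    fp <- sum(confusion[-k, k])
    fn <- sum(confusion[k, -k])
    if (tp + fp == 0) {
      message("class ", rownames(confusion)[k] %||% k,
              " never predicted; precision set to 0")
      prec[k] <- 0
    } else prec[k] <- tp / (tp + fp)
    rec[k] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[k] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  c(precision = mean(prec), recall = mean(rec), F1 = mean(f1))
}

#' Matthews correlation coefficient
#'
#' Binary confusion matrices use the textbook formula
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; larger matrices
#' use the standard multi-category generalization. A zero denominator
#' yields 0 with a warning.
#'
#' @param confusion square confusion matrix (rows = truth).
#' @return value in `[-1, 1]`.
#' @export
mcc <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) == 2) {
    tp <- m[1, 1]; fn <- m[1, 2]; fp <- m[2, 1]; tn <- m[2, 2]
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) {
      warning("MCC denominator is zero; returning 0", call. = FALSE)
      return(0)
    }
    return((tp * tn - fp * fn) / den)
  }
  s <- sum(m)
  c0 <- sum(diag(m))
  t <- rowSums(m)
  p <- colSums(m)
  den <- sqrt(s^2 - sum(p^2)) * sqrt(s^2 - sum(t^2))
  if (den == 0) {
    warning("MCC denominator is zero; returning 0", call. = FALSE)
    return(0)
  }
  (c0 * s - sum(p * t)) / den
}

#' Run the full classification experiment
#'
#' Featurizes a labeled compound table once, then runs independent
#' stratified trials: per trial a balanced random forest is grid-selected
#' and fitted on the training split and evaluated on the test split with
#' balanced accuracy, macro precision/recall/F1 and MCC.
#'
#' @param data data.frame with columns `id`, `smiles`, `label`.
#' @param n_trials number of trials (default 10).
#' @param test_fraction test fraction (default 0.3).
#' @param n_bits fingerprint length (default 2048).
#' @param grid hyperparameter grid (see [train_brf()]).
#' @param seed master seed; each trial derives its own stream from it.
#' @return list with `trials` (per trial: `trial_index`, `split`,
#'   `confusion`, `metrics`, `ntree`, `nodesize`), `metrics` (long
#'   data.frame trial x metric), and `normalized_confusion` (mean row-
#'   normalized confusion matrix over trials).
#' @export
run_experiment <- function(data, n_trials = 10, test_fraction = 0.3,
                           n_bits = 2048, grid = .default_grid(), seed = 1) {
  stopifnot(all(c("id", "smiles", "label") %in% names(data)))
  x <- ecfp4(data$smiles, n_bits)
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  y <- as.character(data$label)
  classes <- sort(unique(y))
  splits <- stratified_trials(y, n_trials = n_trials,
                              test_fraction = test_fraction, seed = seed)
  trials <- vector("list", n_trials)
  norm_acc <- matrix(0, length(classes), length(classes),
                     dimnames = list(classes, classes))
  for (t in seq_len(n_trials)) {
    sp <- splits[[t]]
    fit <- .fit_brf(x[sp$train, , drop = FALSE], y[sp$train], grid = grid,
                    seed = seed + 1000L * t)
    pred <- as.character(stats::predict(fit$forest, x[sp$test, , drop = FALSE]))
    conf <- confusion_matrix(y[sp$test], pred, classes = classes)
    mm <- suppressMessages(macro_metrics(conf))
    metrics <- c(BA = balanced_accuracy(conf),
                 precision_macro = unname(mm["precision"]),
                 recall_macro = unname(mm["recall"]),
                 F1_macro = unname(mm["F1"]),
                 MCC = suppressWarnings(mcc(conf)))
    trials[[t]] <- list(trial_index = t, split = sp, confusion = conf,
                        metrics = metrics, ntree = fit$ntree,
                        nodesize = fit$nodesize)
    norm_acc <- norm_acc + conf / pmax(rowSums(conf), 1)
  }
  metrics_df <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(trial = tr$trial_index, metric = names(tr$metrics),
               value = unname(tr$metrics), stringsAsFactors = FALSE)
  }))
  list(trials = trials, metrics = metrics_df,
       normalized_confusion = norm_acc / n_trials)
}
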