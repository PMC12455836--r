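test_that("fingerprints are deterministic and structure-sensitive", {
  f <- ecfp4(c("Cc1ccccc1", "Cc1ccccc1", "C1CCCCC1", "c1ccccc1"))
  expect_identical(f[1, ], f[2, ])
  expect_false(all(f[3, ] == f[4, ]))
  expect_true(all(f %in% c(0, 1)))
  expect_equal(ncol(f), 2048)
  expect_equal(ncol(ecfp4("CCO", n_bits = 512)), 512)
  expect_error(ecfp4("not-a-molecule"), "parse")
  expect_error(ecfp4(character(0)), "no molecules")
})

test_that("stratified trials hit class proportions within one compound", {
  labels <- rep(c("a", "b", "c"), times = c(70, 20, 10))
  sp <- stratified_trials(labels, n_trials = 5, test_fraction = 0.3, seed = 7)
  for (s in sp) {
    expect_equal(length(s$test), 30)
    tab <- table(labels[s$test])
    expect_equal(as.vector(tab[c("a", "b", "c")]), c(21, 6, 3))
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), seq_along(labels))
  }
  # reproducible under seed, different across trials
  sp2 <- stratified_trials(labels, n_trials = 5, test_fraction = 0.3, seed = 7)
  expect_identical(sp, sp2)
  expect_false(identical(sp[[1]]$test, sp[[2]]$test))
  expect_error(stratified_trials(c("a", "a", "b"), seed = 1), "2 members")
  expect_error(stratified_trials(labels, test_fraction = 0, seed = 1),
               "test_fraction")
})

test_that("balanced accuracy follows the TPR/TNR mean and macro recall", {
  conf <- matrix(c(40, 10, 20, 30), 2, 2, byrow = TRUE)
  expect_equal(balanced_accuracy(conf), (0.8 + 0.6) / 2)
  expect_equal(balanced_accuracy(diag(c(5, 9, 2))), 1)
  expect_error(balanced_accuracy(matrix(0, 2, 2)), "empty")
})

test_that("macro metrics and MCC match the printed formulas", {
  # binary TP=40 FN=10 FP=20 TN=30 (class 1 = positive)
  conf <- matrix(c(40, 10, 20, 30), 2, 2, byrow = TRUE,
                 dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m <- macro_metrics(conf)
  prec1 <- 40 / 60; rec1 <- 40 / 50; f11 <- 80 / 110
  prec2 <- 30 / 40; rec2 <- 30 / 50; f12 <- 60 / 90
  expect_equal(unname(m["precision"]), (prec1 + prec2) / 2)
  expect_equal(unname(m["recall"]), (rec1 + rec2) / 2)
  expect_equal(unname(m["F1"]), (f11 + f12) / 2)
  expect_equal(mcc(conf), 1000 / sqrt(60 * 50 * 50 * 40), tolerance = 1e-12)
  expect_equal(mcc(diag(c(50, 50))), 1)
  expect_equal(mcc(matrix(25, 2, 2)), 0)
  perfect <- diag(c(10, 20, 30))
  expect_equal(unname(macro_metrics(perfect)), c(1, 1, 1))
  # all predictions into one of two balanced classes
  one_sided <- matrix(c(50, 0, 50, 0), 2, 2, byrow = TRUE)
  expect_message(m1 <- macro_metrics(one_sided), "never predicted")
  expect_equal(unname(m1["recall"]), 0.5)
})

test_that("metrics agree with label-vector oracles on random confusions", {
  # independent oracle: rebuild truth/prediction label vectors and compute
  # every metric from first principles (binary MCC as the phi coefficient)
  set.seed(11)
  for (rep in seq_len(1000)) {
    k <- sample(2:3, 1)
    n <- sample(12:40, 1)
    truth <- sample(letters[1:k], n, replace = TRUE)
    while (length(unique(truth)) < k) {
      truth <- sample(letters[1:k], n, replace = TRUE)
    }
    pred <- sample(letters[1:k], n, replace = TRUE)
    conf <- confusion_matrix(truth, pred, classes = letters[1:k])
    expect_equal(sum(conf), n)
    # balanced accuracy = macro recall from vectors
    rec <- vapply(unique(truth), function(cl) {
      mean(pred[truth == cl] == cl)
    }, numeric(1))
    expect_equal(balanced_accuracy(conf), mean(rec), tolerance = 1e-12)
    m <- suppressMessages(macro_metrics(conf))
    prf <- vapply(letters[1:k], function(cl) {
      tp <- sum(truth == cl & pred == cl)
      c(p = if (sum(pred == cl) == 0) 0 else tp / sum(pred == cl),
        r = if (sum(truth == cl) == 0) 0 else tp / sum(truth == cl),
        f = if (2 * tp + sum(pred == cl & truth != cl) +
                  sum(truth == cl & pred != cl) == 0) 0 else
          2 * tp / (2 * tp + sum(pred == cl & truth != cl) +
                      sum(truth == cl & pred != cl)))
    }, numeric(3))
    expect_equal(unname(m["precision"]), mean(prf["p", ]), tolerance = 1e-12)
    expect_equal(unname(m["recall"]), mean(prf["r", ]), tolerance = 1e-12)
    expect_equal(unname(m["F1"]), mean(prf["f", ]), tolerance = 1e-12)
    got <- suppressWarnings(mcc(conf))
    expect_true(got >= -1 - 1e-12 && got <= 1 + 1e-12)
    if (k == 2) {
      t01 <- as.numeric(truth == "a"); p01 <- as.numeric(pred == "a")
      if (sd(t01) > 0 && sd(p01) > 0) {
        expect_equal(got, cor(t01, p01), tolerance = 1e-12)
      }
    } else {
      # one-hot covariance form of the multi-category coefficient
      X <- outer(truth, letters[1:k], "==") * 1
      Y <- outer(pred, letters[1:k], "==") * 1
      num <- sum(diag(cov(X, Y)))
      den <- sqrt(sum(diag(cov(X, X)))) * sqrt(sum(diag(cov(Y, Y))))
      if (den > 0) expect_equal(got, num / den, tolerance = 1e-9)
    }
  }
})

test_that("balanced forests separate planted structure and stay balanced", {
  lib <- small_library()
  # binary task: motif class vs rest, trained on a subset for speed
  y <- ifelse(lib$label == "selective", "selective", "rest")
  fit <- train_brf(lib$smiles, y, n_bits = 512,
                   grid = list(nodesize = c(1, 5), ntree = c(50)), seed = 3)
  expect_s3_class(fit, "molce_classifier")
  expect_identical(fit$classes, c("rest", "selective"))
  # balanced sampling contract: per-tree draws equal across classes
  expect_equal(length(unique(fit$sampsize)), 1)
  expect_equal(unname(fit$sampsize[1]), min(table(y)))
  pr <- fit$predict_proba(lib$smiles[1:5])
  expect_equal(dim(pr), c(5, 2))
  expect_equal(unname(rowSums(pr)), rep(1, 5), tolerance = 1e-12)
  # linearly separable toy case reaches perfect training accuracy
  toy_y <- ifelse(grepl("F", lib$smiles[1:60]), "f", "nof")
  fit2 <- train_brf(lib$smiles[1:60], toy_y, n_bits = 512,
                    grid = list(nodesize = 1, ntree = 50), seed = 5)
  pred <- fit2$classes[max.col(fit2$predict_proba(lib$smiles[1:60]))]
  expect_gte(mean(pred == toy_y), 0.95)
  expect_error(train_brf(lib$smiles[1:10], rep("one", 10), seed = 1),
               "single class")
  expect_error(
    train_brf(lib$smiles[1:20], rep(c("a", "b"), 10),
              grid = list(nodesize = numeric(0), ntree = numeric(0)),
              seed = 1),
    "grid")
})

test_that("experiments are seed-reproducible with conserved confusions", {
  lib <- small_library()[1:80, ]
  cfg <- list(grid = list(nodesize = 5, ntree = 25), n_bits = 256)
  r1 <- run_experiment(lib, n_trials = 2, grid = cfg$grid,
                       n_bits = cfg$n_bits, seed = 9)
  r2 <- run_experiment(lib, n_trials = 2, grid = cfg$grid,
                       n_bits = cfg$n_bits, seed = 9)
  expect_equal(r1$metrics, r2$metrics)
  for (tr in r1$trials) {
    expect_equal(sum(tr$confusion), length(tr$split$test))
    expect_true(all(tr$metrics[c("BA", "precision_macro", "recall_macro",
                                 "F1_macro")] >= 0))
    expect_true(all(tr$metrics[c("BA", "precision_macro", "recall_macro",
                                 "F1_macro")] <= 1))
    expect_true(tr$metrics["MCC"] >= -1 && tr$metrics["MCC"] <= 1)
  }
  expect_true(all(abs(rowSums(r1$normalized_confusion) - 1) < 1e-9))
})
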