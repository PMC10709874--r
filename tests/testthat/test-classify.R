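test_that("task label maps follow the Gleason groupings", {
  gs <- c("3+3", "3+4", "4+3", "4+5")
  expect_equal(as.character(task_labels("sig_vs_nonsig", gs)),
               c("nonsig", "sig", "sig", "sig"))
  g2 <- task_labels("g34_vs_g43plus", gs)
  expect_true(is.na(g2[1]))
  expect_equal(as.character(g2[-1]), c("G3+4", "G>=4+3", "G>=4+3"))
  expect_equal(as.character(task_labels("three_class", gs)),
               c("G3+3", "G3+4", "G>=4+3", "G>=4+3"))
  expect_error(task_labels("sig_vs_nonsig", "5+5"), "unknown")
})

test_that("stratified folds partition the data evenly", {
  y <- rep(c("nonsig", "sig"), c(13, 37))
  folds <- make_folds(y, 5, seed = 9)
  expect_equal(sort(unlist(folds)), 1:50)
  expect_equal(lengths(folds), rep(10L, 5))
  # per-class counts within 1 of n_c / n_folds
  for (f in folds) {
    expect_true(abs(sum(y[f] == "nonsig") - 13 / 5) < 1)
    expect_true(abs(sum(y[f] == "sig") - 37 / 5) < 1)
  }
  # random label vectors: stratification within +-1 sample
  set.seed(43)
  for (trial in 1:10) {
    y2 <- sample(c("a", "b", "c"), 40, replace = TRUE,
                 prob = c(0.5, 0.3, 0.2))
    folds2 <- suppressWarnings(make_folds(y2, 5, seed = trial))
    expect_equal(sort(unlist(folds2)), seq_along(y2))
    for (cl in unique(y2)) {
      per_fold <- sapply(folds2, function(f) sum(y2[f] == cl))
      expect_lte(max(per_fold) - min(per_fold), 1)
    }
  }
  expect_error(make_folds(c("a", "b"), 5), "at least")
})

test_that("KNN with k = 1 returns a training point's own label", {
  x <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c("p", "q", "r"), 5)
  spec <- classifier_spec("knn", k = 1)
  pred <- train_predict(spec, x, y, x)
  expect_equal(pred, y)
})

test_that("Gaussian naive Bayes matches the closed-form likelihood rule", {
  set.seed(44)
  tr_x <- matrix(c(rnorm(30, 0, 1), rnorm(20, 2.5, 0.6)), ncol = 1,
                 dimnames = list(NULL, "x"))
  tr_y <- rep(c("a", "b"), c(30, 20))
  te_x <- matrix(seq(-2, 5, length.out = 40), ncol = 1,
                 dimnames = list(NULL, "x"))
  pred <- train_predict(classifier_spec("gaussian_nb"), tr_x, tr_y, te_x)
  # oracle: empirical-prior Gaussian likelihood-ratio rule (z-scoring is
  # affine and cancels from the decision)
  m <- tapply(tr_x[, 1], tr_y, mean); s <- tapply(tr_x[, 1], tr_y, sd)
  pri <- table(tr_y) / length(tr_y)
  oracle <- ifelse(
    pri["a"] * dnorm(te_x[, 1], m["a"], s["a"]) >=
      pri["b"] * dnorm(te_x[, 1], m["b"], s["b"]), "a", "b")
  expect_equal(pred, unname(oracle))
})

test_that("all classifiers separate well-separated blobs perfectly", {
  set.seed(45)
  n <- 30
  x <- rbind(matrix(rnorm(2 * n, 0, 0.2), ncol = 2),
             matrix(rnorm(2 * n, 8, 0.2), ncol = 2))
  colnames(x) <- c("a", "b")
  y <- rep(c("lo", "hi"), each = n)
  te <- rbind(matrix(rnorm(20, 0, 0.2), ncol = 2),
              matrix(rnorm(20, 8, 0.2), ncol = 2))
  colnames(te) <- c("a", "b")
  truth <- rep(c("lo", "hi"), each = 10)
  for (kind in c("svm_rbf", "knn", "gaussian_nb")) {
    pred <- train_predict(classifier_spec(kind), x, y, te, seed = 1)
    expect_equal(pred, truth, info = kind)
  }
})

test_that("test rows cannot influence the trained model", {
  set.seed(46)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c("p", "q"), 15)
  te <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  for (kind in c("svm_rbf", "knn", "gaussian_nb")) {
    p1 <- train_predict(classifier_spec(kind), x, y, te, seed = 2)
    # appending arbitrary extra test rows must not change predictions
    p2 <- train_predict(classifier_spec(kind), x, y,
                        rbind(te, te * 100 + 3), seed = 2)
    expect_equal(p2[1:10], p1, info = kind)
  }
})

test_that("cross-validation is deterministic and self-consistent", {
  set.seed(47)
  tab <- data.frame(label = rep(c("3+3", "3+4"), c(13, 37)),
                    f1 = rnorm(50), f2 = rnorm(50),
                    check.names = FALSE)
  tab$f1 <- tab$f1 + 2 * (tab$label == "3+4")
  ev1 <- cross_validate(tab, "sig_vs_nonsig", classifier_spec("gaussian_nb"),
                        seed = 5)
  ev2 <- cross_validate(tab, "sig_vs_nonsig", classifier_spec("gaussian_nb"),
                        seed = 5)
  expect_identical(ev1, ev2)
  # mean accuracy is the arithmetic fold mean; confusion counts add up
  expect_equal(ev1$mean_accuracy, mean(ev1$per_fold_accuracy))
  expect_equal(sum(ev1$confusion), 50)
  expect_equal(unname(rowSums(ev1$confusion)), c(13, 37))
  # equal fold sizes: overall accuracy equals trace / total
  expect_equal(ev1$mean_accuracy,
               sum(diag(ev1$confusion)) / sum(ev1$confusion))
})

test_that("zero-variance training features are dropped with a warning", {
  x <- cbind(flat = rep(1, 20), ok = rnorm(20))
  y <- rep(c("p", "q"), 10)
  te <- cbind(flat = rep(1, 4), ok = rnorm(4))
  expect_warning(
    pred <- train_predict(classifier_spec("knn"), x, y, te),
    "zero-variance")
  expect_length(pred, 4)
})
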