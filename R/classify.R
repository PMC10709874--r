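# Cross-validated classification.
#
# Three classifiers are evaluated under stratified 5-fold cross-validation
# (80/20 train/test rotations): an RBF-kernel SVM with an inner 3-fold grid
# search over cost and gamma, a k = 5 Euclidean KNN with a nearest-neighbour
# tie rule, and a Gaussian naive Bayes classifier with empirical priors and
# a minimum-expected-cost decision. SMOTE balancing and z-scoring are fitted
# on training folds only, so test rows never leak into training.

#' Map Gleason-score labels to task classes
#'
#' Tasks: `sig_vs_nonsig` contrasts non-significant (Gleason 3+3) against
#' clinically significant (3+4 and above); `g34_vs_g43plus` contrasts
#' Gleason 3+4 against 4+3 and above (3+3 lesions are excluded, returned as
#' NA); `three_class` groups 3+3 / 3+4 / >=4+3.
#'
#' @param task task name.
#' @param gs character vector of Gleason tags ("3+3", "3+4", "4+3", "4+5",
#'   or aggregate tags ">=3+4", ">=4+3").
#' @return factor of task classes (NA for excluded lesions).
#' @export
task_labels <- function(task = c("sig_vs_nonsig", "g34_vs_g43plus",
                                 "three_class"), gs) {
  task <- match.arg(task)
  gs <- as.character(gs)
  known <- c("3+3", "3+4", "4+3", "4+4", "4+5", ">=3+4", ">=4+3")
  if (!all(gs %in% known))
    stop("unknown Gleason tag(s): ",
         paste(unique(setdiff(gs, known)), collapse = ", "))
  high <- c("4+3", "4+4", "4+5", ">=4+3")
  switch(task,
    sig_vs_nonsig = factor(ifelse(gs == "3+3", "nonsig", "sig"),
                           levels = c("nonsig", "sig")),
    g34_vs_g43plus = factor(
      ifelse(gs == "3+4", "G3+4", ifelse(gs %in% high, "G>=4+3", NA)),
      levels = c("G3+4", "G>=4+3")),
    three_class = factor(
      ifelse(gs == "3+3", "G3+3", ifelse(gs == "3+4", "G3+4", "G>=4+3")),
      levels = c("G3+3", "G3+4", "G>=4+3")))
}

#' Stratified cross-validation folds
#'
#' Partitions indices into `n_folds` disjoint, exhaustive test folds. Each
#' class is split as evenly as possible across folds (per-fold class counts
#' within 1 of n_class / n_folds); leftover samples are placed in the folds
#' with the fewest members so total fold sizes are as equal as possible.
#'
#' @param y class labels.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return list of integer vectors of test indices, one per fold.
#' @export
make_folds <- function(y, n_folds = 5L, seed = 1L) {
  y <- as.character(y)
  n <- length(y)
  if (n < n_folds) stop("need at least n_folds samples")
  cnt <- sort(table(y), decreasing = TRUE)
  if (any(cnt < n_folds))
    warning("class(es) smaller than n_folds; stratification degrades: ",
            paste(names(cnt)[cnt < n_folds], collapse = ", "))
  assign <- integer(n)
  load <- numeric(n_folds)
  with_seed(seed, {
    for (cl in names(cnt)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      base <- length(idx) %/% n_folds
      rem <- length(idx) %% n_folds
      counts <- rep(base, n_folds)
      if (rem > 0) {
        extra <- order(load, seq_len(n_folds))[seq_len(rem)]
        counts[extra] <- counts[extra] + 1
      }
      assign[idx] <- rep.int(seq_len(n_folds), counts)
      load <- load + counts
    }
  })
  lapply(seq_len(n_folds), function(f) which(assign == f))
}

#' Classifier specification
#'
#' @param kind `"svm_rbf"`, `"knn"` or `"gaussian_nb"`.
#' @param cost_grid SVM cost values searched by the inner grid search
#'   (default 2^-5 .. 2^15 in factor-4 steps).
#' @param gamma_grid SVM RBF gamma values (default 2^-15 .. 2^3 in factor-4
#'   steps).
#' @param inner_folds folds of the inner grid-search CV (default 3).
#' @param k KNN neighbour count (default 5).
#' @param cost_matrix naive-Bayes misclassification cost matrix
#'   (true class x decision); default uniform 0/1 losses.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm_rbf", "knn", "gaussian_nb"),
                            cost_grid = 2^seq(-5, 15, by = 2),
                            gamma_grid = 2^seq(-15, 3, by = 2),
                            inner_folds = 3L, k = 5L, cost_matrix = NULL) {
  kind <- match.arg(kind)
  if (length(cost_grid) == 0 || length(gamma_grid) == 0)
    stop("SVM grids must be non-empty")
  if (k < 1) stop("k must be >= 1")
  structure(list(kind = kind, cost_grid = cost_grid,
                 gamma_grid = gamma_grid, inner_folds = as.integer(inner_folds),
                 k = as.integer(k), cost_matrix = cost_matrix),
            class = "classifier_spec")
}

# z-score test columns with training-fold statistics; drop zero-variance
# training features from both tables
zscore_train_test <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep))
    warning("dropping zero-variance training feature(s): ",
            paste(colnames(train_x)[!keep], collapse = ", "))
  if (!any(keep)) stop("all training features have zero variance")
  scale_one <- function(m) sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep],
                                       "-"), 2, sdv[keep], "/")
  list(train = scale_one(train_x), test = scale_one(test_x))
}

# KNN with the "nearest" tie rule: majority vote among the k nearest
# training rows; vote ties are resolved by the label of the nearest
# neighbour belonging to a tied class. Distance ties break by lowest
# training-row index.
knn_nearest <- function(train_x, train_y, test_x, k = 5L) {
  k <- min(k, nrow(train_x))
  out <- character(nrow(test_x))
  for (q in seq_len(nrow(test_x))) {
    d <- sqrt(colSums((t(train_x) - test_x[q, ])^2))
    ord <- order(d, seq_along(d))[seq_len(k)]
    votes <- table(train_y[ord])
    tied <- names(votes)[votes == max(votes)]
    out[q] <- if (length(tied) == 1) tied
    else train_y[ord[match(TRUE, train_y[ord] %in% tied)]]
  }
  out
}

# Gaussian naive Bayes via e1071, with a minimum-expected-cost decision on
# the posterior; per-class SDs are floored to avoid degenerate densities
nb_train_predict <- function(train_x, train_y, test_x, cost_matrix = NULL) {
  yf <- factor(train_y)
  fit <- e1071::naiveBayes(x = as.data.frame(train_x), y = yf)
  floor_sd <- 1e-6 * max(apply(train_x, 2, stats::sd), 1e-6)
  fit$tables <- lapply(fit$tables, function(tb) {
    tb[, 2] <- pmax(tb[, 2], floor_sd)
    tb
  })
  post <- stats::predict(fit, as.data.frame(test_x), type = "raw")
  classes <- colnames(post)
  if (is.null(cost_matrix))
    cost_matrix <- 1 - diag(length(classes))
  expected <- post %*% cost_matrix
  classes[apply(expected, 1, which.min)]
}

# inner grid-search RBF SVM: pick (cost, gamma) by 3-fold CV accuracy on
# the training fold, refit on all training rows (one-vs-one for >2 classes)
svm_train_predict <- function(train_x, train_y, test_x, spec, seed = 1L) {
  yf <- factor(train_y)
  inner <- tryCatch(
    suppressWarnings(make_folds(train_y, spec$inner_folds, seed)),
    error = function(e) NULL)
  best <- c(cost = spec$cost_grid[1], gamma = spec$gamma_grid[1])
  best_acc <- -1
  if (!is.null(inner)) {
    for (cost in spec$cost_grid) {
      for (gamma in spec$gamma_grid) {
        correct <- 0; total <- 0
        for (te in inner) {
          tr <- setdiff(seq_len(nrow(train_x)), te)
          if (length(unique(train_y[tr])) < 2 || length(te) == 0) next
          fit <- e1071::svm(train_x[tr, , drop = FALSE],
                            factor(train_y[tr], levels = levels(yf)),
                            type = "C-classification", kernel = "radial",
                            cost = cost, gamma = gamma, scale = FALSE)
          pr <- stats::predict(fit, train_x[te, , drop = FALSE])
          correct <- correct + sum(as.character(pr) == train_y[te])
          total <- total + length(te)
        }
        acc <- if (total > 0) correct / total else -1
        if (acc > best_acc) {
          best_acc <- acc
          best <- c(cost = cost, gamma = gamma)
        }
      }
    }
  }
  fit <- e1071::svm(train_x, yf, type = "C-classification",
                    kernel = "radial", cost = best[["cost"]],
                    gamma = best[["gamma"]], scale = FALSE)
  as.character(stats::predict(fit, test_x))
}

#' Train a classifier on one fold and predict test labels
#'
#' Features are z-scored with training statistics (zero-variance training
#' features dropped from both tables), then the classifier given by `spec`
#' is trained and applied to the test rows.
#'
#' @param spec a [classifier_spec()].
#' @param train_x,train_y training features and labels.
#' @param test_x test features (same columns as `train_x`).
#' @param seed seed for the SVM inner grid-search folds.
#' @return character vector of predicted labels.
#' @export
train_predict <- function(spec, train_x, train_y, test_x, seed = 1L) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (!identical(colnames(train_x), colnames(test_x)))
    stop("train and test feature columns differ")
  z <- zscore_train_test(train_x, test_x)
  switch(spec$kind,
    svm_rbf = svm_train_predict(z$train, as.character(train_y), z$test,
                                spec, seed),
    knn = knn_nearest(z$train, as.character(train_y), z$test, spec$k),
    gaussian_nb = nb_train_predict(z$train, as.character(train_y), z$test,
                                   spec$cost_matrix))
}

#' Cross-validated evaluation of one (task, classifier) cell
#'
#' Stratified `n_folds`-fold cross-validation: per fold, optional SMOTE on
#' the training rows only, z-scoring from training rows only, training,
#' prediction and scoring; the reported accuracy is the arithmetic mean
#' over folds. Folds whose training rows miss a class are skipped with a
#' warning.
#'
#' @param table feature data.frame with a `label` column of Gleason tags
#'   and feature columns.
#' @param task task name (see [task_labels()]).
#' @param spec a [classifier_spec()].
#' @param seed master seed (folds, SMOTE and the SVM search derive from
#'   it).
#' @param use_smote balance training folds with SMOTE (default TRUE).
#' @param n_folds folds (default 5).
#' @param features optional character vector restricting the feature
#'   columns used.
#' @return object of class `eval_result` with `per_fold_accuracy`,
#'   `mean_accuracy`, `confusion` (true x predicted counts over all test
#'   folds), `task`, `classifier`, `n`, `seed`, `dilation_level`.
#' @export
cross_validate <- function(table, task, spec, seed = 1L, use_smote = TRUE,
                           n_folds = 5L, features = NULL) {
  lab <- task_labels(task, table$label)
  keep <- !is.na(lab)
  feat_cols <- if (is.null(features))
    setdiff(colnames(table), c("label", "lesion_id", "dilation_level"))
  else features
  x <- as.matrix(table[keep, feat_cols, drop = FALSE])
  y <- as.character(lab[keep])
  folds <- make_folds(y, n_folds, seed)
  classes <- levels(lab)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  acc <- rep(NA_real_, n_folds)
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(nrow(x)), te)
    if (length(unique(y[tr])) < length(unique(y)) || length(te) == 0) {
      warning("fold ", f, " skipped: training set lacks a class")
      next
    }
    tr_x <- x[tr, , drop = FALSE]; tr_y <- y[tr]
    if (use_smote && length(unique(as.integer(base::table(tr_y)))) > 1) {
      bal <- smote(tr_x, tr_y, seed = derive_seed(seed, 100 + f))
      tr_x <- bal$x; tr_y <- bal$y
    }
    pred <- train_predict(spec, tr_x, tr_y, x[te, , drop = FALSE],
                          seed = derive_seed(seed, 200 + f))
    acc[f] <- mean(pred == y[te])
    for (i in seq_along(te))
      confusion[y[te[i]], pred[i]] <- confusion[y[te[i]], pred[i]] + 1L
  }
  structure(list(per_fold_accuracy = acc,
                 mean_accuracy = mean(acc, na.rm = TRUE),
                 confusion = confusion, task = task,
                 classifier = spec$kind, n = nrow(x), seed = seed,
                 dilation_level = NA_integer_),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result %s / %s: mean accuracy %.4f over %d folds (n = %d)>\n",
              x$task, x$classifier, x$mean_accuracy,
              sum(!is.na(x$per_fold_accuracy)), x$n))
  invisible(x)
}
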