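# Feature selection and univariate statistics.
#
# ReliefF estimates per-feature relevance from k nearest hits and misses of
# every sample (full deterministic pass, no subsampling); features with
# positive weight are retained. A one-way ANOVA screen and two-tailed
# t-test summaries mirror the univariate statistics a radiomics study
# reports alongside the selection.

#' ReliefF feature relevance weights
#'
#' Multi-class ReliefF: features are range-normalized to [0, 1]; every
#' sample is visited once; per visit the k nearest same-class hits and the
#' k nearest misses from each other class (Manhattan distance on the
#' normalized features, ties broken by lowest sample index) update the
#' weights, miss contributions scaled by the class prior relative to the
#' complement of the visited sample's class. Weights therefore lie in
#' [-1, 1] and a feature constant across all samples has weight exactly 0.
#'
#' @param x numeric matrix or data.frame of features (rows = samples).
#' @param y class labels.
#' @param k neighbours per class (default 10); reduced per class, with a
#'   warning, when a class has fewer than k + 1 members.
#' @return named numeric vector of weights with attributes `k` and
#'   `n_sample_iterations`.
#' @export
relieff <- function(x, y, k = 10L) {
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  if (n != length(y)) stop("x and y sizes differ")
  classes <- unique(y)
  if (length(classes) < 2) stop("need at least 2 classes")
  cnt <- table(y)
  if (any(cnt < 2)) stop("every class needs at least 2 samples")
  if (any(cnt < k + 1))
    warning("k reduced for classes smaller than k + 1: ",
            paste(names(cnt)[cnt < k + 1], collapse = ", "))

  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  den <- hi - lo
  xn <- sweep(x, 2, lo, "-")
  xn <- sweep(xn, 2, ifelse(den > 0, den, 1), "/")
  xn[, den == 0] <- 0  # constant features contribute no diff

  D <- as.matrix(stats::dist(xn, method = "manhattan"))
  prior <- as.numeric(cnt[classes]) / n
  names(prior) <- classes
  by_class <- split(seq_len(n), y)

  w <- numeric(ncol(x))
  for (i in seq_len(n)) {
    ci <- y[i]
    for (cl in classes) {
      cand <- setdiff(by_class[[cl]], i)
      kk <- min(k, length(cand))
      if (kk < 1) next
      nb <- cand[order(D[i, cand], cand)][seq_len(kk)]
      diffs <- abs(xn[nb, , drop = FALSE] -
                     matrix(xn[i, ], kk, ncol(x), byrow = TRUE))
      contrib <- colMeans(diffs) / n
      if (cl == ci) w <- w - contrib
      else w <- w + prior[[cl]] / (1 - prior[[ci]]) * contrib
    }
  }
  names(w) <- colnames(x)
  attr(w, "k") <- as.integer(k)
  attr(w, "n_sample_iterations") <- n
  w
}

#' Keep features with positive relevance weight
#'
#' @param w named numeric weight vector (e.g. from [relieff()]).
#' @return object of class `selection_result`: `kept` (feature names in
#'   descending weight order), `weights` (their weights), `rule`.
#' @export
select_positive <- function(w) {
  if (length(w) == 0) stop("empty weight vector")
  if (is.null(names(w)) || any(!nzchar(names(w))))
    stop("weights must be named by feature")
  pos <- w[w > 0]
  if (length(pos) == 0)
    stop("no feature has positive weight; review the selection threshold")
  ord <- order(-pos, names(pos))
  structure(list(kept = names(pos)[ord], weights = pos[ord],
                 rule = "weight > 0, descending weight"),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %d features kept (%s)>\n",
              length(x$kept), x$rule))
  print(round(x$weights, 4))
  invisible(x)
}

#' One-way ANOVA screen across three (or more) groups
#'
#' Per feature, a one-way ANOVA of the feature against the group labels;
#' features with p < alpha are flagged. When every group has zero
#' within-group variance the p-value is defined as 0 for separated group
#' means and 1 otherwise.
#'
#' @param x feature matrix or data.frame.
#' @param y group labels (>= 2 groups, each n >= 2).
#' @param alpha significance level (default 0.05).
#' @return data.frame with `feature`, `F`, `p`, `significant`.
#' @export
anova_screen <- function(x, y, alpha = 0.05) {
  x <- as.matrix(x)
  g <- factor(y)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs n >= 2")
  res <- lapply(colnames(x), function(f) {
    v <- x[, f]
    within_var <- tapply(v, g, stats::var)
    if (all(within_var == 0)) {
      means <- tapply(v, g, mean)
      p <- if (max(means) - min(means) > 0) 0 else 1
      return(data.frame(feature = f, F = NA_real_, p = p))
    }
    fit <- stats::aov(v ~ g)
    s <- summary(fit)[[1]]
    data.frame(feature = f, F = s[["F value"]][1], p = s[["Pr(>F)"]][1])
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Two-tailed t-test summary for a binary contrast
#'
#' Per feature: group means, group SDs and the two-sided two-sample t-test
#' p-value (Welch by default). Degenerate features (both groups constant)
#' get a missing p-value.
#'
#' @param x feature matrix or data.frame.
#' @param y binary group labels (each group n >= 2).
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return data.frame with `feature`, `mean_1`, `mean_2`, `sd_1`, `sd_2`,
#'   `p`; attribute `classes` records which label is group 1.
#' @export
ttest_summary <- function(x, y, var_equal = FALSE) {
  x <- as.matrix(x)
  g <- factor(y)
  if (nlevels(g) != 2) stop("need exactly 2 groups")
  if (any(table(g) < 2)) stop("both groups need n >= 2")
  l1 <- levels(g)[1]; l2 <- levels(g)[2]
  res <- lapply(colnames(x), function(f) {
    v1 <- x[g == l1, f]; v2 <- x[g == l2, f]
    p <- tryCatch(
      stats::t.test(v1, v2, var.equal = var_equal)$p.value,
      error = function(e) NA_real_)
    data.frame(feature = f, mean_1 = mean(v1), mean_2 = mean(v2),
               sd_1 = stats::sd(v1), sd_2 = stats::sd(v2), p = p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "classes") <- c(l1, l2)
  out
}
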