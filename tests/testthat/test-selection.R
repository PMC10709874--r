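test_that("ReliefF matches an explicitly unrolled Relief pass", {
  # tiny n = 6 / k = 1 case, checked against the independent oracle
  x <- matrix(c(0.1, 0.2, 0.15, 0.9, 0.85, 0.95,
                0.5, 0.4, 0.6, 0.45, 0.55, 0.5), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  y <- c("a", "a", "a", "b", "b", "b")
  w <- relieff(x, y, k = 1)
  expect_equal(as.numeric(w), as.numeric(oracle_relieff(x, y, 1)),
               tolerance = 1e-12)
  # and on a larger random problem with k = 3
  set.seed(31)
  x2 <- matrix(rnorm(25 * 4), 25, 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  y2 <- rep(c("a", "b"), c(12, 13))
  expect_equal(as.numeric(suppressWarnings(relieff(x2, y2, 3))),
               as.numeric(oracle_relieff(x2, y2, 3)), tolerance = 1e-12)
})

test_that("constant features get weight exactly zero", {
  set.seed(32)
  x <- cbind(flat = rep(1, 20), noise = rnorm(20))
  y <- rep(c("a", "b"), 10)
  w <- suppressWarnings(relieff(x, y, k = 3))
  expect_identical(unname(w["flat"]), 0)
})

test_that("a label-copy feature dominates and permutation nulls weights", {
  set.seed(33)
  top <- replicate(30, {
    y <- rep(c("a", "b"), each = 20)
    x <- cbind(copy = as.numeric(y == "b"),
               matrix(rnorm(40 * 4), 40, 4,
                      dimnames = list(NULL, paste0("n", 1:4))))
    w <- relieff(x, y, k = 10)
    w[["copy"]] > 0 && which.max(w) == 1
  })
  expect_true(all(top))
  # label permutation: weights concentrate near zero
  y <- rep(c("a", "b"), each = 25)
  x <- cbind(sig = as.numeric(y == "b") + rnorm(50, 0, 0.3),
             n1 = rnorm(50))
  wmat <- replicate(60, relieff(x, sample(y), k = 10))
  expect_lt(max(abs(rowMeans(wmat))), 0.05)
})

test_that("ReliefF weight rises with class separation", {
  seps <- c(0.5, 1.5, 3)
  set.seed(34)
  w_by_sep <- sapply(seps, function(d) {
    mean(replicate(20, {
      y <- rep(c("a", "b"), each = 15)
      x <- cbind(sig = rnorm(30) + d * (y == "b"),
                 n1 = rnorm(30), n2 = rnorm(30))
      relieff(x, y, k = 5)[["sig"]]
    }))
  })
  expect_true(all(diff(w_by_sep) > 0))
})

test_that("positive-weight selection keeps exactly the positive features", {
  w <- c(a = 0.3, b = -0.1, c = 0.05, d = 0)
  s <- select_positive(w)
  expect_equal(s$kept, c("a", "c"))
  expect_true(all(s$weights > 0))
  expect_error(select_positive(c(a = -1, b = -0.2)), "positive")
})

test_that("ANOVA screen agrees with the textbook F ratio", {
  # 3 groups x 4 observations toy table, F computed by hand formulas
  v <- c(1, 2, 3, 4, 2, 4, 6, 8, 10, 11, 12, 13)
  g <- rep(c("g1", "g2", "g3"), each = 4)
  gm <- tapply(v, g, mean); n <- 4
  ssb <- n * sum((gm - mean(v))^2)
  ssw <- sum((v - gm[g])^2)
  f_hand <- (ssb / 2) / (ssw / 9)
  res <- anova_screen(matrix(v, ncol = 1, dimnames = list(NULL, "x")), g)
  expect_equal(res$F, f_hand, tolerance = 1e-12)
  expect_equal(res$p, pf(f_hand, 2, 9, lower.tail = FALSE),
               tolerance = 1e-12)
  # gross separation
  set.seed(35)
  x <- matrix(rnorm(30, rep(c(0, 0, 5), each = 10), 0.1), ncol = 1,
              dimnames = list(NULL, "x"))
  expect_lt(anova_screen(x, rep(c("a", "b", "c"), each = 10))$p, 1e-6)
  # degenerate: zero within-group variance
  z <- matrix(rep(c(1, 1, 2), each = 4), ncol = 1,
              dimnames = list(NULL, "x"))
  expect_equal(anova_screen(z, rep(c("a", "b", "c"), each = 4))$p, 0)
  z2 <- matrix(1, 12, 1, dimnames = list(NULL, "x"))
  expect_equal(anova_screen(z2, rep(c("a", "b", "c"), each = 4))$p, 1)
})

test_that("t-test summary reproduces the Welch formula and null case", {
  x1 <- c(1.1, 2.3, 0.8, 1.9, 1.4); x2 <- c(2.0, 3.1, 2.8, 2.2, 2.9)
  tstat <- (mean(x1) - mean(x2)) /
    sqrt(var(x1) / 5 + var(x2) / 5)
  df <- (var(x1) / 5 + var(x2) / 5)^2 /
    ((var(x1) / 5)^2 / 4 + (var(x2) / 5)^2 / 4)
  p_hand <- 2 * pt(-abs(tstat), df)
  tab <- matrix(c(x1, x2), ncol = 1, dimnames = list(NULL, "x"))
  res <- ttest_summary(tab, rep(c("a", "b"), each = 5))
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_equal(res$mean_1, mean(x1))
  expect_equal(res$sd_2, sd(x2))
  # identical groups: no difference
  same <- matrix(rep(c(1, 2, 3, 4), 2), ncol = 1,
                 dimnames = list(NULL, "x"))
  res0 <- ttest_summary(same, rep(c("a", "b"), each = 4))
  expect_equal(res0$mean_1, res0$mean_2)
  expect_equal(res0$p, 1)
  # gross separation
  set.seed(36)
  big <- matrix(c(rnorm(20, 0, 0.1), rnorm(20, 1, 0.1)), ncol = 1,
                dimnames = list(NULL, "x"))
  expect_lt(ttest_summary(big, rep(c("a", "b"), each = 20))$p, 1e-10)
  # degenerate: both groups constant -> missing p
  con <- matrix(rep(1, 8), ncol = 1, dimnames = list(NULL, "x"))
  expect_true(is.na(ttest_summary(con, rep(c("a", "b"), each = 4))$p))
})
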