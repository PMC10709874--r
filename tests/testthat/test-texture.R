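test_that("quantization maps the range ends and degenerate ROIs correctly", {
  expect_equal(quantize(c(0, 1), levels = 2), c(1L, 2L))
  expect_equal(quantize(rep(3.7, 5), levels = 32), rep(1L, 5))
  expect_equal(quantize(c(0, 0.49, 0.51, 1), levels = 2), c(1L, 1L, 2L, 2L))
  # direct floor-formula oracle
  set.seed(21)
  v <- runif(1000)
  lo <- min(v); hi <- max(v); L <- 32L
  oracle <- pmin(pmax(floor((v - lo) / (hi - lo) * L) + 1, 1), L)
  expect_equal(quantize(v, L), as.integer(oracle))
})

test_that("GLCM of simple patterns matches hand enumeration", {
  # constant 2x2 ROI, horizontal offset: all mass at one diagonal cell
  g <- glcm(matrix(1L, 2, 2), matrix(TRUE, 2, 2), c(0L, 1L), levels = 1)
  expect_equal(sum(g$counts), 1)
  expect_equal(g$counts[1, 1], 1)
  # 4x4 two-level checkerboard, horizontal: mass 0.5 / 0.5 off-diagonal
  img <- outer(1:4, 1:4, function(i, j) ((i + j) %% 2) + 1L)
  g <- glcm(img, matrix(TRUE, 4, 4), c(0L, 1L), levels = 2)
  expect_equal(g$counts, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  f <- glcm_features(g)
  expect_equal(unname(f["energy"]), 0.5)
  expect_equal(unname(f["entropy"]), log(2))
  expect_equal(unname(f["contrast"]), 1)
  expect_equal(unname(f["correlation"]), -1)
  expect_equal(unname(f["homogeneity"]), 0.5)
  expect_equal(unname(f["IDM"]), 0.5)
})

test_that("GLCM and features equal brute-force oracles on random images", {
  set.seed(22)
  for (trial in 1:30) {
    img <- matrix(sample.int(4, 64, replace = TRUE), 8, 8)
    mask <- random_mask(8, 8, 0.6)
    for (off in glcm_offsets()) {
      g <- glcm(img, mask, off, levels = 4)
      o <- oracle_glcm(img, mask, off, 4)
      expect_equal(g$counts, o, tolerance = 1e-14)
      if (g$n_pairs > 0)
        expect_equal(glcm_features(g), oracle_glcm_features(o),
                     tolerance = 1e-12)
    }
  }
})

test_that("degenerate GLCMs follow the stated conventions", {
  # single-cell diagonal GLCM (constant image)
  f <- glcm_features(matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(unname(f), c(1, 0, 0, 0, 1, 1),
               tolerance = 1e-14)  # energy..IDM with correlation = 0
  # offsets with no admissible pair give an unnormalized zero matrix
  m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE
  g <- glcm(matrix(1L, 3, 3), m, c(0L, 1L), 1)
  expect_equal(g$n_pairs, 0)
  expect_false(g$normalized)
  expect_error(glcm_features(g), "normalized")
})

test_that("feature bounds hold on random normalized GLCMs", {
  set.seed(23)
  for (trial in 1:50) {
    p <- matrix(rexp(36), 6, 6)
    p <- (p + t(p)) / (2 * sum(p))
    f <- glcm_features(p)
    expect_gt(f[["energy"]], 0); expect_lte(f[["energy"]], 1)
    expect_gte(f[["entropy"]], 0)
    expect_lte(f[["entropy"]], log(36))
    expect_gte(f[["correlation"]], -1); expect_lte(f[["correlation"]], 1)
    expect_gt(f[["homogeneity"]], 0); expect_lte(f[["homogeneity"]], 1)
    expect_gt(f[["IDM"]], 0); expect_lte(f[["IDM"]], 1)
  }
})

test_that("rotating the image permutes directions but not their average", {
  set.seed(24)
  img <- matrix(sample.int(5, 144, replace = TRUE), 12, 12)
  mask <- random_mask(12, 12, 0.7)
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  img_r <- rot90(img); mask_r <- rot90(mask)
  per_dir <- function(im, mk) lapply(glcm_offsets(), function(off) {
    g <- glcm(im, mk, off, 5)
    if (g$n_pairs > 0) glcm_features(g) else NULL
  })
  a <- per_dir(img, mask); b <- per_dir(img_r, mask_r)
  # 90-degree rotation swaps 0 <-> 90 and 45 <-> 135
  expect_equal(a[["0"]], b[["90"]], tolerance = 1e-12)
  expect_equal(a[["90"]], b[["0"]], tolerance = 1e-12)
  expect_equal(a[["45"]], b[["135"]], tolerance = 1e-12)
  expect_equal(a[["135"]], b[["45"]], tolerance = 1e-12)
  avg <- function(l) colMeans(do.call(rbind, Filter(Negate(is.null), l)))
  expect_equal(avg(a), avg(b), tolerance = 1e-12)
})

test_that("extract_features returns the canonical 21-vector", {
  mask <- matrix(FALSE, 10, 10); mask[3:7, 3:7] <- TRUE
  const_maps <- list(ADC = matrix(1.3, 10, 10), DCE = matrix(0.4, 10, 10),
                     T2 = matrix(95, 10, 10))
  f <- extract_features(const_maps, mask)
  expect_named(f, canonical_features())
  expect_equal(unname(f[c("ADC", "ALPHE", "T2")]), c(1.3, 0.4, 95))
  # constant maps: maximal homogeneity, zero entropy
  expect_equal(unname(f[c("ADC-energy", "T2-energy", "DCE-energy")]),
               rep(1, 3))
  expect_equal(unname(f[c("ADC-entropy", "DCE-entropy", "T2-entropy")]),
               rep(0, 3))
  expect_error(extract_features(const_maps, matrix(FALSE, 10, 10)),
               "no valid pixels")
})

test_that("directional spread is small for isotropic random-field ROIs", {
  set.seed(25)
  cv_all <- replicate(20, {
    img <- matrix(rnorm(400), 20, 20)
    mask <- matrix(FALSE, 20, 20); mask[3:18, 3:18] <- TRUE
    lev <- matrix(NA_integer_, 20, 20)
    lev[mask] <- quantize(img[mask], 8)
    per_dir <- sapply(glcm_offsets(), function(off)
      glcm_features(glcm(lev, mask, off, 8))[["entropy"]])
    sd(per_dir) / mean(per_dir)
  })
  expect_lt(mean(cv_all), 0.2)
})
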