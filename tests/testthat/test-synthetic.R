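test_that("feature tables honour profile counts, labels and degeneracy", {
  profs <- default_profiles("sig_vs_nonsig")
  tab <- gen_feature_table(profs, seed = 1)
  expect_equal(nrow(tab), 50)
  expect_equal(sum(tab$label == "3+3"), 13)
  expect_equal(sum(tab$label == ">=3+4"), 37)
  expect_true(all(attr(reference_class_stats("sig_vs_nonsig"),
                       "classes") %in% tab$label))
  # determinism
  expect_identical(gen_feature_table(profs, seed = 1), tab)
  # SD = 0 collapses each class onto its mean vector
  degen <- lapply(profs, function(p)
    class_profile(p$label, 3, p$feature_means, p$feature_sds * 0))
  dt <- gen_feature_table(degen, seed = 2)
  for (p in degen)
    for (f in names(p$feature_means))
      expect_true(all(dt[dt$label == p$label, f] == p$feature_means[[f]]))
  # a missing feature is a configuration error naming the feature
  p_bad <- class_profile("3+3", 5, c(ADC = 1.3), c(ADC = 0.1))
  expect_error(gen_feature_table(list(profs[[1]], p_bad)), "ALPHE")
})

test_that("per-class sample moments converge to the configured values", {
  profs <- default_profiles("sig_vs_nonsig", n_lesions = c(1000, 1000))
  feats <- names(profs[[1]]$feature_means)
  hit <- unlist(lapply(1:20, function(s) {
    tab <- gen_feature_table(profs, seed = s)
    unlist(lapply(profs, function(p) {
      rows <- tab$label == p$label
      sapply(feats, function(f)
        abs(mean(tab[rows, f]) - p$feature_means[[f]]) <=
          3 * p$feature_sds[[f]] / sqrt(1000))
    }))
  }))
  expect_gte(mean(hit), 0.99)
})

test_that("phantom cases respect containment, positivity and determinism", {
  cfg <- phantom_config(seed = 5)
  case <- gen_phantom_case("3+4", cfg, seed = 77, signals = FALSE)
  tr <- case$truth
  expect_true(all(tr$drawn_roi$grid <= tr$true_lesion))  # ROI inside lesion
  expect_gt(sum(tr$drawn_roi$grid), 0)
  for (g in list(tr$adc, tr$t2, tr$A, tr$alpha, tr$beta)) {
    expect_true(all(g > 0))
    expect_equal(dim(g), cfg$image_shape)
  }
  expect_identical(gen_phantom_case("3+4", cfg, seed = 77, signals = FALSE),
                   case)
  expect_error(gen_phantom_case("9+9", cfg), "unknown")
})

test_that("noiseless phantom series invert to the truth maps", {
  cfg <- phantom_config(noise_sd = c(dwi = 0, t2 = 0, dce = 0),
                        image_shape = c(48L, 48L), seed = 6)
  case <- gen_phantom_case("4+3", cfg, seed = 8, signals = TRUE)
  adc <- fit_map(case$series$dwi, "adc", case$series$axes$bvalues)
  expect_lt(max(abs(adc$grid - case$truth$adc) / case$truth$adc), 1e-6)
  t2 <- fit_map(case$series$t2, "t2", case$series$axes$echo_times)
  expect_lt(max(abs(t2$grid - case$truth$t2) / case$truth$t2), 1e-6)
  # EMM: spot-check a sample of lesion pixels
  px <- which(case$truth$true_lesion)[c(1, 20, 50, 80, 110)]
  for (p in px) {
    rc <- arrayInd(p, cfg$image_shape)
    curve <- compute_pse(case$series$dce[rc[1], rc[2], ],
                         case$series$axes$dce_times,
                         case$series$baseline_frames)
    f <- fit_emm(curve)
    expect_lt(abs(f$A - case$truth$A[p]) / case$truth$A[p], 1e-3)
    expect_lt(abs(f$alpha - case$truth$alpha[p]) / case$truth$alpha[p],
              1e-3)
    expect_lt(abs(f$beta - case$truth$beta[p]) / case$truth$beta[p], 1e-3)
  }
})

test_that("high-heterogeneity classes show higher ROI GLCM entropy", {
  ent <- sapply(1:50, function(s) {
    cfg <- phantom_config(seed = s)
    sapply(c("3+3", "4+5"), function(lab) {
      case <- gen_phantom_case(lab, cfg, seed = derive_seed(s, 999),
                               signals = FALSE)
      mask <- case$truth$true_lesion
      lev <- matrix(NA_integer_, nrow(mask), ncol(mask))
      lev[mask] <- quantize(case$truth$adc[mask], 32)
      # oracle: entropy computed from the brute-force GLCM
      mean(sapply(glcm_offsets(), function(off) {
        p <- oracle_glcm(lev, mask, off, 32)
        -sum(ifelse(p > 0, p * log(p), 0))
      }))
    })
  })
  expect_gt(mean(ent["4+5", ]), mean(ent["3+3", ]))
})

test_that("cohorts reproduce the configured class histogram", {
  coh <- gen_cohort(phantom_config(image_shape = c(48L, 48L), seed = 3))
  expect_length(coh, 50)
  expect_equal(table(sapply(coh, `[[`, "label")),
               table(rep(names(reference_cohort_counts()),
                         reference_cohort_counts())))
  # reduced counts, two classes only
  cfg <- phantom_config(counts = c("3+3" = 2, "3+4" = 2),
                        image_shape = c(48L, 48L), seed = 4)
  coh2 <- gen_cohort(cfg)
  expect_length(coh2, 4)
  expect_setequal(sapply(coh2, `[[`, "label"), c("3+3", "3+4"))
  # same master seed -> identical cohort; distinct per-case seeds
  expect_identical(gen_cohort(cfg), coh2)
  expect_equal(anyDuplicated(sapply(coh2, `[[`, "seed")), 0)
  expect_error(gen_cohort(phantom_config(counts = c("3+3" = 0))), "zero")
})

test_that("cohort feature tables carry metadata and canonical columns", {
  cfg <- phantom_config(counts = c("3+3" = 3, "3+4" = 3),
                        image_shape = c(48L, 48L), seed = 10)
  coh <- gen_cohort(cfg)
  tab <- cohort_feature_table(coh, dilation = 1)
  expect_equal(nrow(tab), 6)
  expect_true(all(canonical_features() %in% colnames(tab)))
  expect_true(all(tab$dilation_level == 1))
  expect_true(all(is.finite(as.matrix(tab[, canonical_features()]))))
})
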