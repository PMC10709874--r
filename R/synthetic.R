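# Synthetic cohorts: class-conditional feature tables and image phantoms.
#
# Two generators stand in for the unavailable patient cohort. The
# feature-table sampler draws each feature independently from per-class
# normal distributions parameterised by the bundled reference statistics.
# The phantom generator builds 2-D truth maps (ADC, T2, EMM A/alpha/beta)
# containing a star-convex lesion whose interior carries class-dependent
# spatial texture; the "drawn" ROI is the true lesion eroded by a margin,
# mimicking the conservative outlines radiologists place on mp-MRI, and the
# rim between drawn ROI and true lesion carries the class texture scaled by
# a margin-heterogeneity factor. Raw signal series are generated exactly
# from the three signal models and corrupted with additive Gaussian noise.

#' Class profile for the feature-table generator
#'
#' @param label Gleason-group tag (e.g. "3+3", "3+4", ">=3+4", ">=4+3").
#' @param n_lesions number of lesions to draw for this class.
#' @param means named numeric vector of feature means (canonical names).
#' @param sds named numeric vector of feature SDs (same names, all >= 0).
#' @return object of class `class_profile`.
#' @export
class_profile <- function(label, n_lesions, means, sds) {
  if (is.null(names(means)) || is.null(names(sds)))
    stop("means and sds must be named by feature")
  if (!setequal(names(means), names(sds)))
    stop("means and sds must cover the same features")
  bad <- setdiff(names(means), canonical_features())
  if (length(bad) > 0)
    stop("unknown feature name(s): ", paste(bad, collapse = ", "))
  if (any(sds < 0)) stop("SDs must be >= 0")
  if (n_lesions < 0) stop("n_lesions must be >= 0")
  structure(list(label = label, n_lesions = as.integer(n_lesions),
                 feature_means = means, feature_sds = sds[names(means)]),
            class = "class_profile")
}

#' Default class profiles from the bundled reference statistics
#'
#' @param task binary task name (see [reference_class_stats()]).
#' @param swap swap the reading order of the reference value pairs.
#' @param n_lesions optional integer vector of length 2 overriding the
#'   reference per-class lesion counts.
#' @return list of two [class_profile()]s.
#' @export
default_profiles <- function(task = c("sig_vs_nonsig", "g34_vs_g43plus"),
                             swap = FALSE, n_lesions = NULL) {
  task <- match.arg(task)
  st <- reference_class_stats(task, swap)
  cls <- attr(st, "classes")
  n <- if (is.null(n_lesions)) attr(st, "n_lesions") else as.integer(n_lesions)
  list(
    class_profile(cls[1], n[1],
                  stats::setNames(st$mean_1, st$feature),
                  stats::setNames(st$sd_1, st$feature)),
    class_profile(cls[2], n[2],
                  stats::setNames(st$mean_2, st$feature),
                  stats::setNames(st$sd_2, st$feature))
  )
}

#' Sample a class-conditional feature table
#'
#' Rows are sampled independently per feature from each profile's normal
#' distributions (no covariance structure is imposed; none is available
#' from summary statistics). The output is deterministic given `seed`.
#'
#' @param profiles list of [class_profile()]s; all profiles must provide
#'   every feature used.
#' @param seed integer seed.
#' @param features optional feature subset; defaults to the features of the
#'   first profile.
#' @return data.frame with a `label` column and one column per feature.
#' @export
gen_feature_table <- function(profiles, seed = 1L, features = NULL) {
  if (length(profiles) == 0) stop("need at least one profile")
  if (is.null(features)) features <- names(profiles[[1]]$feature_means)
  for (p in profiles) {
    miss <- setdiff(features, names(p$feature_means))
    if (length(miss) > 0)
      stop("profile '", p$label, "' is missing feature(s): ",
           paste(miss, collapse = ", "))
  }
  with_seed(seed, {
    blocks <- lapply(profiles, function(p) {
      n <- p$n_lesions
      cols <- lapply(features, function(f)
        stats::rnorm(n, p$feature_means[[f]], p$feature_sds[[f]]))
      names(cols) <- features
      cbind(data.frame(label = rep(p$label, n), stringsAsFactors = FALSE),
            data.frame(cols, check.names = FALSE))
    })
    do.call(rbind, blocks)
  })
}

# per-class phantom tissue parameters; adjacent Gleason groups overlap via
# the per-lesion variability applied in gen_phantom_case
phantom_class_params <- function(label) {
  tab <- list(
    "3+3" = list(adc = 1.50, t2 = 115, alpha = 0.27, A = 85, beta = 0.004,
                 tex_amp = 0.07, tex_fine = 0.02),
    "3+4" = list(adc = 1.35, t2 = 105, alpha = 0.32, A = 100, beta = 0.004,
                 tex_amp = 0.12, tex_fine = 0.30),
    "4+3" = list(adc = 1.22, t2 = 95, alpha = 0.38, A = 112, beta = 0.005,
                 tex_amp = 0.17, tex_fine = 0.60),
    "4+5" = list(adc = 1.12, t2 = 88, alpha = 0.42, A = 122, beta = 0.005,
                 tex_amp = 0.22, tex_fine = 0.95))
  if (!label %in% names(tab)) stop("unknown Gleason class: ", label)
  tab[[label]]
}

#' Phantom generator configuration
#'
#' @param image_shape (rows, cols) of the phantom grids (default 120 x
#'   120, i.e. the DWI matrix of the emulated protocol).
#' @param counts named integer vector of lesions per Gleason class
#'   (default the reference cohort counts 13/29/7/1).
#' @param noise_sd named per-modality additive Gaussian signal noise, as a
#'   fraction of the modality's baseline signal (default 1%).
#' @param margin_heterogeneity scalar >= 0 scaling the class texture in the
#'   rim between drawn ROI and true lesion (default 2: the tumour
#'   periphery missed by conservative outlines is the more heterogeneous
#'   tissue).
#' @param erosion_px pixels eroded off the true lesion to form the drawn
#'   ROI (default 2).
#' @param lesion_radius range of mean lesion radii in pixels.
#' @param lesion_cv per-lesion coefficient of variation of the class tissue
#'   values (lesion-to-lesion biological spread; default 0.18).
#' @param baseline_frames DCE pre-enhancement frames (default 3).
#' @param n_dce_frames total DCE frames (default 63).
#' @param bvalues DWI b-values in s/mm^2.
#' @param echo_times T2-mapping echo times in ms.
#' @param dce_dt DCE frame spacing in s (default 8.3).
#' @param seed master seed; per-case seeds are derived from it with
#'   [derive_seed()].
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(image_shape = c(120L, 120L),
                           counts = reference_cohort_counts(),
                           noise_sd = c(dwi = 0.01, t2 = 0.01, dce = 0.01),
                           margin_heterogeneity = 2,
                           erosion_px = 2L,
                           lesion_radius = c(7, 11),
                           lesion_cv = 0.18,
                           baseline_frames = 3L,
                           n_dce_frames = 63L,
                           bvalues = c(0, 50, 100, 150, 990, 1500),
                           echo_times = seq(30, 270, by = 30),
                           dce_dt = 8.3,
                           seed = 1L) {
  if (any(image_shape < 32)) stop("image_shape must be at least 32 x 32")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  if (margin_heterogeneity < 0) stop("margin_heterogeneity must be >= 0")
  structure(list(image_shape = as.integer(image_shape), counts = counts,
                 noise_sd = noise_sd,
                 margin_heterogeneity = margin_heterogeneity,
                 erosion_px = as.integer(erosion_px),
                 lesion_radius = lesion_radius, lesion_cv = lesion_cv,
                 baseline_frames = as.integer(baseline_frames),
                 n_dce_frames = as.integer(n_dce_frames),
                 bvalues = bvalues, echo_times = echo_times,
                 dce_dt = dce_dt, seed = as.integer(seed)),
            class = "phantom_config")
}

# random star-convex blob mask: radius modulated by low-order harmonics
star_convex_mask <- function(shape, center, r0) {
  amp <- stats::runif(3, 0, 1) * c(0.12, 0.10, 0.08)
  phase <- stats::runif(3, 0, 2 * pi)
  r <- outer(seq_len(shape[1]), rep(1, shape[2])) - center[1]
  c_ <- outer(rep(1, shape[1]), seq_len(shape[2])) - center[2]
  d <- sqrt(r^2 + c_^2)
  th <- atan2(c_, r)
  rad <- r0 * (1 + amp[1] * cos(th - phase[1]) +
                 amp[2] * cos(2 * (th - phase[2])) +
                 amp[3] * cos(3 * (th - phase[3])))
  d <= rad
}

# standardized smooth random field (mean 0, sd 1)
smooth_field <- function(shape, sigma) {
  f <- gauss_blur(matrix(stats::rnorm(prod(shape)), shape[1], shape[2]),
                  sigma)
  (f - mean(f)) / stats::sd(f)
}

# Class texture field: smooth base blended with a fine-scale (pixel-level)
# component; `fine` in [0, 1] is the variance fraction of the fine scale,
# the granularity axis along which Gleason classes are ordered. The blend
# is passed through a Gaussian-copula probability-integral transform so
# every field has the same bounded uniform marginal (mean 0, sd 1): texture
# classes then differ in spatial correlation only, not in value
# distribution, and lesion values stay strictly positive at the amplitudes
# used.
texture_field <- function(shape, fine, sigma = 2.2) {
  base <- smooth_field(shape, sigma)
  white <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  z <- sqrt(1 - fine) * base + sqrt(fine) * white
  sqrt(12) * (stats::pnorm(z / stats::sd(z)) - 0.5)
}

#' Generate one phantom case
#'
#' Builds truth parameter grids with a class-textured lesion, derives the
#' drawn ROI by erosion, and (optionally) synthesises the raw DWI,
#' multi-echo T2 and DCE signal series exactly from the three signal models
#' plus additive Gaussian noise.
#'
#' @param label Gleason class ("3+3", "3+4", "4+3", "4+5").
#' @param config a [phantom_config()].
#' @param seed integer seed for this case.
#' @param signals also generate the raw signal series (default TRUE).
#' @return object of class `phantom_case`: `truth` (matrices `adc`, `t2`,
#'   `A`, `alpha`, `beta`; masks `true_lesion`, `drawn_roi`), `series`
#'   (arrays `dwi`, `t2`, `dce` and their axes; NULL when `signals =
#'   FALSE`), `label`, `seed`.
#' @export
gen_phantom_case <- function(label, config = phantom_config(), seed = 1L,
                             signals = TRUE) {
  cp <- phantom_class_params(label)
  bg <- list(adc = 1.85, t2 = 140, alpha = 0.15, A = 60, beta = 0.003,
             tex_amp = 0.05, tex_sigma = 2.0)
  shape <- config$image_shape
  with_seed(seed, {
    # geometry: lesion away from the border so dilation headroom exists,
    # with the margin capped so small test images remain feasible
    r0 <- stats::runif(1, config$lesion_radius[1], config$lesion_radius[2])
    margin <- pmin(ceiling(r0 * 1.4) + 12, floor((shape - 1) / 2))
    center <- c(stats::runif(1, margin[1], shape[1] - margin[1]),
                stats::runif(1, margin[2], shape[2] - margin[2]))
    lesion <- star_convex_mask(shape, center, r0)
    er <- config$erosion_px
    drawn <- erode_roi(lesion, er)
    while (sum(drawn$grid) < 4 && er > 0) {
      er <- er - 1  # degenerate erosion of a small blob: back off
      drawn <- erode_roi(lesion, er)
    }
    rim <- lesion & !drawn$grid

    # per-lesion tissue values: class value times a lognormal factor
    jitter <- exp(stats::rnorm(5, 0, config$lesion_cv))
    vals <- list(adc = cp$adc * jitter[1], t2 = cp$t2 * jitter[2],
                 alpha = cp$alpha * jitter[3], A = cp$A * jitter[4],
                 beta = cp$beta * jitter[5])

    tex_scale <- matrix(0, shape[1], shape[2])
    tex_scale[drawn$grid] <- 0.5 * cp$tex_amp  # core: damped amplitude
    tex_scale[rim] <- cp$tex_amp * config$margin_heterogeneity

    # Per-map texture: a shared lesion field (tumour architecture seen by
    # every modality) blended with a map-specific component. In the ROI
    # core the class texture is additionally blended with a neutral
    # mid-granularity field, so the conservatively drawn core is less
    # class-informative than the peritumoral rim it omits.
    shared <- texture_field(shape, cp$tex_fine)
    make_grid <- function(lesion_val, bg_val) {
      own <- texture_field(shape, cp$tex_fine)
      cls_field <- sqrt(0.5) * shared + sqrt(0.5) * own
      neutral <- texture_field(shape, 0.3)
      core_field <- sqrt(0.25) * cls_field + sqrt(0.75) * neutral
      field <- rim * cls_field + drawn$grid * core_field
      g <- bg_val * (1 + bg$tex_amp * smooth_field(shape, bg$tex_sigma))
      g[lesion] <- lesion_val * (1 + (field * tex_scale)[lesion])
      pmax(g, 0.05 * min(lesion_val, bg_val))
    }
    truth <- list(adc = make_grid(vals$adc, bg$adc),
                  t2 = make_grid(vals$t2, bg$t2),
                  A = make_grid(vals$A, bg$A),
                  alpha = make_grid(vals$alpha, bg$alpha),
                  beta = make_grid(vals$beta, bg$beta),
                  true_lesion = lesion,
                  drawn_roi = roi_mask(drawn$grid, lesion_id = label))

    series <- NULL
    if (signals) {
      nz <- function(a, frac, s0) {
        if (frac > 0) a + stats::rnorm(length(a), 0, frac * s0) else a
      }
      s0_dwi <- 1000; s0_t2 <- 500; s0_dce <- 200
      adc_mm2s <- um2ms_to_mm2s(truth$adc)
      dwi <- vapply(config$bvalues,
                    function(b) s0_dwi * exp(-b * adc_mm2s),
                    matrix(0, shape[1], shape[2]))
      t2s <- vapply(config$echo_times,
                    function(te) s0_t2 * exp(-te / truth$t2),
                    matrix(0, shape[1], shape[2]))
      times <- (seq_len(config$n_dce_frames) - 1) * config$dce_dt
      t_post <- times - times[config$baseline_frames]
      dce <- vapply(seq_along(times), function(f) {
        if (t_post[f] <= 0) matrix(s0_dce, shape[1], shape[2])
        else s0_dce * (1 + emm_model(t_post[f], truth$A, truth$alpha,
                                     truth$beta) / 100)
      }, matrix(0, shape[1], shape[2]))
      dwi <- nz(dwi, config$noise_sd[["dwi"]], s0_dwi)
      t2s <- nz(t2s, config$noise_sd[["t2"]], s0_t2)
      dce <- nz(dce, config$noise_sd[["dce"]], s0_dce)
      series <- list(dwi = dwi, t2 = t2s, dce = dce,
                     axes = list(bvalues = config$bvalues,
                                 echo_times = config$echo_times,
                                 dce_times = times),
                     baseline_frames = config$baseline_frames)
    }
    structure(list(truth = truth, series = series, label = label,
                   seed = as.integer(seed)),
              class = "phantom_case")
  })
}

#' Generate a phantom cohort
#'
#' Emits exactly the configured per-class lesion counts, each case with a
#' seed derived from the master seed by a fixed counter scheme, so the
#' whole cohort is a pure function of the configuration.
#'
#' @param config a [phantom_config()].
#' @param signals generate raw signal series per case (default FALSE; the
#'   truth maps alone suffice for texture analyses).
#' @return list of [gen_phantom_case()] results (class `phantom_cohort`).
#' @export
gen_cohort <- function(config = phantom_config(), signals = FALSE) {
  counts <- config$counts
  if (sum(counts) == 0) stop("cohort has zero lesions")
  labels <- rep(names(counts), counts)
  cases <- lapply(seq_along(labels), function(i)
    gen_phantom_case(labels[i], config, derive_seed(config$seed, i),
                     signals = signals))
  structure(cases, class = "phantom_cohort")
}

#' Truth parameter maps of a phantom case, shaped for feature extraction
#'
#' @param case a `phantom_case`.
#' @return named list of `parameter_map`s `ADC` (um^2/ms), `DCE` (the
#'   enhancement-rate alpha grid, 1/s) and `T2` (ms).
#' @export
truth_maps <- function(case) {
  list(ADC = parameter_map("ADC", case$truth$adc, "um^2/ms"),
       DCE = parameter_map("ALPHA", case$truth$alpha, "1/s"),
       T2 = parameter_map("T2", case$truth$t2, "ms"))
}

#' Fit parameter maps from a phantom case's raw series
#'
#' ADC and T2 are fitted everywhere with the vectorised log-linear solver;
#' the EMM is fitted only inside a dilated neighbourhood of the true lesion
#' (`fit_margin` extra turns) to keep per-pixel nonlinear fitting
#' tractable.
#'
#' @param case a `phantom_case` generated with `signals = TRUE`.
#' @param fit_margin dilation turns around the true lesion delimiting the
#'   EMM fitting region (default 6).
#' @return named list of `parameter_map`s `ADC`, `DCE` (fitted alpha), `T2`.
#' @export
fitted_maps <- function(case, fit_margin = 6L) {
  if (is.null(case$series))
    stop("case was generated without signal series")
  s <- case$series
  adc <- fit_map(s$dwi, "adc", s$axes$bvalues)
  t2 <- fit_map(s$t2, "t2", s$axes$echo_times)
  emm_region <- dilate_roi(case$truth$true_lesion, fit_margin,
                           symmetric = TRUE)$grid
  emm <- fit_map(s$dce, "emm", s$axes$dce_times,
                 baseline_frames = s$baseline_frames, mask = emm_region)
  list(ADC = adc, DCE = emm$ALPHA, T2 = t2)
}

#' Feature table of a phantom cohort at one dilation level
#'
#' Dilates each case's drawn ROI by `dilation` turns and extracts the
#' canonical 21-feature vector from the given maps.
#'
#' @param cohort a `phantom_cohort`.
#' @param dilation dilation turns applied to every drawn ROI (default 0).
#' @param maps_list optional list of per-case map lists (defaults to
#'   [truth_maps()] of each case).
#' @param levels gray levels for texture quantization.
#' @param symmetric symmetric dilation mode (see [dilate_roi()]).
#' @return data.frame with `lesion_id`, `dilation_level`, `label` and the
#'   21 feature columns.
#' @export
cohort_feature_table <- function(cohort, dilation = 0L, maps_list = NULL,
                                 levels = 32L, symmetric = FALSE) {
  if (is.null(maps_list)) maps_list <- lapply(cohort, truth_maps)
  rows <- lapply(seq_along(cohort), function(i) {
    case <- cohort[[i]]
    mask <- case$truth$drawn_roi
    mask$lesion_id <- sprintf("case%03d", i)
    if (dilation > 0) mask <- dilate_roi(mask, dilation, symmetric)
    f <- extract_features(maps_list[[i]], mask, levels)
    cbind(data.frame(lesion_id = mask$lesion_id,
                     dilation_level = as.integer(dilation),
                     label = case$label, stringsAsFactors = FALSE),
          as.data.frame(as.list(f), check.names = FALSE))
  })
  do.call(rbind, rows)
}
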