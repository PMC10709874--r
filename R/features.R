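# Canonical radiomic feature set and bundled reference cohort statistics.
#
# The pipeline works on a fixed 21-feature vector per lesion: the ROI means
# of the three quantitative maps (ADC, DCE enhancement rate, T2) plus six
# GLCM texture features per map, averaged over four directions.

#' Names of the six GLCM texture features
#' @return character vector of length 6.
#' @export
glcm_feature_names <- function() {
  c("IDM", "contrast", "correlation", "energy", "entropy", "homogeneity")
}

#' Canonical 21-feature vector names
#'
#' The three map means come first (the DCE enhancement-rate mean is named
#' `ALPHE`), followed by the six GLCM features of each map. All feature
#' tables produced or consumed by the package use these names.
#'
#' @return character vector of length 21.
#' @export
canonical_features <- function() {
  c("ADC", "ALPHE", "T2",
    paste0("ADC-", glcm_feature_names()),
    paste0("DCE-", glcm_feature_names()),
    paste0("T2-", glcm_feature_names()))
}

#' Reference ReliefF feature weights for the two binary Gleason tasks
#'
#' Per-feature relevance weights reported for a 26-patient surgical mp-MRI
#' cohort (50 lesions; Gleason 3+3 / 3+4 / 4+3 / 4+5 counts 13/29/7/1),
#' bundled so the positive-weight selection rule can be exercised and
#' checked against a known outcome.
#'
#' @return data.frame with columns `feature`, `sig_vs_nonsig`
#'   (clinically-significant vs non-significant weights) and
#'   `g34_vs_g43plus` (Gleason 3+4 vs >=4+3 weights).
#' @export
reference_feature_weights <- function() {
  data.frame(
    feature = c("ADC", "ALPHE", "T2",
                "ADC-IDM", "ADC-contrast", "ADC-correlation", "ADC-energy",
                "ADC-entropy", "ADC-homogeneity",
                "DCE-IDM", "DCE-contrast", "DCE-correlation", "DCE-energy",
                "DCE-entropy", "DCE-homogeneity",
                "T2-IDM", "T2-contrast", "T2-correlation", "T2-energy",
                "T2-entropy", "T2-homogeneity"),
    sig_vs_nonsig = c(0.0237, 0.0669, 0.0620,
                      -0.0014, 0.0441, -0.0053, -0.0162, -0.0254, 0.0195,
                      -0.0157, -0.0069, 0.0377, 0.0116, 0.0282, 0.0037,
                      0.0080, -0.0053, -0.0156, 0.0067, 0.0413, 0.0307),
    g34_vs_g43plus = c(-0.0449, -0.0090, 0.0231,
                       -0.0128, 0.0632, 0.1528, -0.0169, 0.0610, 0.0128,
                       -0.0770, -0.0474, 0.0519, 0.0150, -0.0450, 0.0623,
                       -0.0388, -0.0319, -0.0622, -0.0471, -0.0014, -0.0387),
    stringsAsFactors = FALSE
  )
}

#' Reference class-conditional feature statistics
#'
#' Per-class means and standard deviations of the selected features for the
#' two binary tasks of the same reference cohort as
#' [reference_feature_weights()]. Units: ADC in um^2/ms, T2 in ms, ALPHE in
#' %/s; GLCM features are dimensionless (the reference cohort's texture
#' magnitudes reflect its own co-occurrence normalisation, see the package
#' vignette). These statistics parameterise the class-conditional
#' feature-table generator.
#'
#' In each printed "a/b" pair the first value is read as the
#' clinically-significant class (respectively Gleason 3+4) and the second as
#' the non-significant class (respectively Gleason >=4+3); `swap = TRUE`
#' reverses that reading.
#'
#' @param task one of `"sig_vs_nonsig"`, `"g34_vs_g43plus"`.
#' @param swap swap the class order of the printed value pairs.
#' @return data.frame with columns `feature`, `mean_1`, `sd_1`, `mean_2`,
#'   `sd_2`, `p_value`, plus attributes `classes` (labels of class 1 and 2)
#'   and `n_lesions` (their lesion counts).
#' @export
reference_class_stats <- function(task = c("sig_vs_nonsig", "g34_vs_g43plus"),
                                  swap = FALSE) {
  task <- match.arg(task)
  if (task == "sig_vs_nonsig") {
    d <- data.frame(
      feature = c("ADC", "ALPHE", "T2", "ADC-contrast", "ADC-homogeneity",
                  "DCE-correlation", "DCE-energy", "DCE-entropy",
                  "DCE-homogeneity", "T2-IDM", "T2-energy", "T2-entropy",
                  "T2-homogeneity"),
      mean_1 = c(1.45, 7.43, 104.21, 44.13, 41.12, 0.33, 0.08, 0.29, 0.49,
                 316.57, 0.03, 0.51, 0.55),
      mean_2 = c(1.27, 7.91, 114.41, 32.29, 32.99, 0.44, 0.02, 0.41, 0.42,
                 190.29, 0.01, 0.55, 0.47),
      sd_1 = c(0.37, 0.71, 25.81, 26.01, 15.31, 0.24, 0.10, 0.15, 0.13,
               211.65, 0.03, 0.11, 0.08),
      sd_2 = c(0.16, 0.51, 24.11, 16.55, 13.77, 0.19, 0.03, 0.09, 0.08,
               143.17, 0.01, 0.07, 0.04),
      p_value = c(0.0103, 0.0025, 0.0067, 0.0262, 0.0227, 0.0120, 0.0035,
                  0.0002, 0.0122, 0.0047, 0.0142, 0.0449, 0.0005),
      stringsAsFactors = FALSE
    )
    classes <- c(">=3+4", "3+3")
    n_lesions <- c(37L, 13L)
  } else {
    d <- data.frame(
      feature = c("T2", "ADC-contrast", "ADC-correlation", "ADC-entropy",
                  "ADC-homogeneity", "DCE-correlation", "DCE-energy",
                  "DCE-homogeneity"),
      mean_1 = c(89.96, 26.77, 0.55, 0.32, 0.49, 0.14, 0.15, 0.59),
      mean_2 = c(109.36, 46.19, 0.41, 0.36, 0.46, 0.29, 0.08, 0.52),
      sd_1 = c(14.54, 13.27, 0.02, 0.04, 0.05, 0.19, 0.06, 0.08),
      sd_2 = c(26.19, 23.67, 0.14, 0.06, 0.06, 0.26, 0.09, 0.13),
      p_value = c(0.0012, 0.0020, 0.0001, 0.0041, 0.0399, 0.0127, 0.0037,
                  0.0167),
      stringsAsFactors = FALSE
    )
    classes <- c("3+4", ">=4+3")
    n_lesions <- c(29L, 8L)
  }
  if (swap) {
    d[c("mean_1", "mean_2")] <- d[c("mean_2", "mean_1")]
    d[c("sd_1", "sd_2")] <- d[c("sd_2", "sd_1")]
    classes <- rev(classes)
    n_lesions <- rev(n_lesions)
  }
  attr(d, "classes") <- classes
  attr(d, "n_lesions") <- n_lesions
  d
}

#' Reference cohort lesion counts per Gleason group
#' @return named integer vector (Gleason 3+3, 3+4, 4+3, 4+5).
#' @export
reference_cohort_counts <- function() {
  c("3+3" = 13L, "3+4" = 29L, "4+3" = 7L, "4+5" = 1L)
}
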