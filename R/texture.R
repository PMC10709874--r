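# Gray-level co-occurrence matrix texture features.
#
# Map values inside the ROI are quantized to a fixed number of gray levels
# over the per-ROI min-max range (32 by default). For each of the four unit
# offsets 0, 45, 90 and 135 degrees a symmetric, normalized GLCM is
# accumulated over pixel pairs lying entirely inside the mask, six Haralick
# features are computed per direction, and the arithmetic mean over
# directions is the ROI's texture value.

#' Quantize values to gray levels
#'
#' Uniform binning of [lo, hi] into `levels` bins; `lo` maps to level 1 and
#' `hi` to level `levels`. A degenerate range (lo == hi, e.g. a constant
#' ROI) maps everything to level 1. Values outside [lo, hi] are clipped into
#' the end bins.
#'
#' @param values numeric vector.
#' @param levels number of gray levels (>= 2, default 32).
#' @param lo,hi quantization range; defaults to the range of `values`.
#' @return integer vector of levels in 1..levels.
#' @export
quantize <- function(values, levels = 32L, lo = min(values),
                     hi = max(values)) {
  if (levels < 2) stop("levels must be >= 2")
  if (hi < lo) stop("hi must be >= lo")
  if (hi == lo) return(rep(1L, length(values)))
  lev <- floor((values - lo) / (hi - lo) * levels) + 1
  as.integer(pmin(pmax(lev, 1L), levels))
}

#' Unit offsets of the four GLCM directions
#'
#' Offsets (dr, dc) in row-major image coordinates: 0 degrees = (0, 1),
#' 45 = (-1, 1), 90 = (-1, 0), 135 = (-1, -1).
#'
#' @return named list of integer pairs.
#' @export
glcm_offsets <- function() {
  list("0" = c(0L, 1L), "45" = c(-1L, 1L), "90" = c(-1L, 0L),
       "135" = c(-1L, -1L))
}

#' Gray-level co-occurrence matrix for one offset
#'
#' Counts ordered level pairs (p, p + offset) with both pixels inside the
#' mask, accumulated symmetrically (each pair also counted reversed), then
#' normalized to probabilities. When the mask admits no pair for the offset
#' the zero matrix is returned with `n_pairs = 0`.
#'
#' @param level_img integer matrix of gray levels (values outside the mask
#'   are ignored).
#' @param mask logical matrix or `roi_mask`.
#' @param offset integer pair (dr, dc), one of [glcm_offsets()].
#' @param levels number of gray levels.
#' @return object of class `glcm`: `counts` (levels x levels probability
#'   matrix), `offset`, `n_pairs` (unordered pair count), `normalized`.
#' @export
glcm <- function(level_img, mask, offset, levels = max(level_img, na.rm = TRUE)) {
  mk <- as_mask_matrix(mask)
  if (!identical(dim(level_img), dim(mk)))
    stop("level image and mask shapes differ")
  dr <- offset[1]; dc <- offset[2]
  if (!all(c(dr, dc) %in% -1:1) || (dr == 0 && dc == 0))
    stop("offset must be a unit-distance direction")
  nr <- nrow(level_img); nc <- ncol(level_img)
  ra <- max(1, 1 - dr):min(nr, nr - dr)
  ca <- max(1, 1 - dc):min(nc, nc - dc)
  a <- level_img[ra, ca, drop = FALSE]
  b <- level_img[ra + dr, ca + dc, drop = FALSE]
  ok <- mk[ra, ca, drop = FALSE] & mk[ra + dr, ca + dc, drop = FALSE] &
    !is.na(a) & !is.na(b)
  counts <- matrix(0, levels, levels)
  n_pairs <- sum(ok)
  if (n_pairs > 0) {
    ij <- (a[ok] - 1) * levels + b[ok]          # column index j fastest
    tab <- tabulate(ij, nbins = levels * levels)
    m <- matrix(tab, levels, levels, byrow = TRUE) # [i, j] ordered pairs
    counts <- m + t(m)                             # symmetric accumulation
    counts <- counts / sum(counts)
  }
  structure(list(counts = counts, offset = c(dr, dc), n_pairs = n_pairs,
                 normalized = n_pairs > 0),
            class = "glcm")
}

#' Six Haralick features of a normalized GLCM
#'
#' With p(i, j) the normalized entries and mu/sigma the marginal means and
#' SDs of the level indices:
#' Energy = sum p^2; Entropy = -sum p log p (0 log 0 := 0, natural log);
#' Contrast = sum (i - j)^2 p; Correlation = sum (i - mu_i)(j - mu_j) p /
#' (sigma_i sigma_j), defined as 0 when sigma_i sigma_j = 0;
#' Homogeneity = sum p / (1 + |i - j|); IDM = sum p / (1 + (i - j)^2).
#'
#' @param g a `glcm` (must be normalized) or probability matrix.
#' @return named numeric vector of the six features.
#' @export
glcm_features <- function(g) {
  p <- if (inherits(g, "glcm")) {
    if (!g$normalized) stop("GLCM is not normalized (no pairs counted)")
    g$counts
  } else g
  if (abs(sum(p) - 1) > 1e-8) stop("GLCM must be normalized to sum 1")
  L <- nrow(p)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  pi_m <- rowSums(p); pj_m <- colSums(p)
  mu_i <- sum(seq_len(L) * pi_m); mu_j <- sum(seq_len(L) * pj_m)
  sd_i <- sqrt(sum((seq_len(L) - mu_i)^2 * pi_m))
  sd_j <- sqrt(sum((seq_len(L) - mu_j)^2 * pj_m))
  corr <- if (sd_i * sd_j > 0)
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j) else 0
  ent <- -sum(ifelse(p > 0, p * log(p), 0))
  c(energy = sum(p^2),
    entropy = ent,
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    homogeneity = sum(p / (1 + abs(i - j))),
    IDM = sum(p / (1 + (i - j)^2)))
}

# per-map texture block: ROI mean + direction-averaged GLCM features
map_texture <- function(map, mask, levels, lesion_id = "lesion",
                        map_name = "map") {
  mg <- as_map_grid(map)
  mk <- as_mask_matrix(mask)
  fg <- mk & mg$valid
  if (!any(fg))
    stop("no valid pixels for lesion '", lesion_id, "', map '", map_name,
         "'")
  vals <- mg$grid[fg]
  lev_img <- matrix(NA_integer_, nrow(mk), ncol(mk))
  lev_img[fg] <- quantize(vals, levels)
  per_dir <- list()
  for (off in glcm_offsets()) {
    g <- glcm(lev_img, fg, off, levels)
    if (g$n_pairs > 0) per_dir[[length(per_dir) + 1]] <- glcm_features(g)
  }
  if (length(per_dir) == 0)
    stop("no co-occurring pixel pairs for lesion '", lesion_id, "', map '",
         map_name, "'")
  tex <- colMeans(do.call(rbind, per_dir))
  list(mean = mean(vals), texture = tex)
}

#' Extract the canonical 21-feature vector of one lesion
#'
#' Per map: the ROI mean over valid pixels, plus the six GLCM features
#' computed for each of the four directions and arithmetically averaged
#' over directions (directions without any admissible pair are excluded
#' from the average). The DCE map mean is named `ALPHE`.
#'
#' @param maps named list with elements `ADC`, `DCE`, `T2` (each a
#'   `parameter_map` or matrix co-registered with `mask`).
#' @param mask `roi_mask` or logical matrix.
#' @param levels gray levels for quantization (default 32).
#' @return named numeric vector with the 21 [canonical_features()] entries.
#' @export
extract_features <- function(maps, mask, levels = 32L) {
  if (!all(c("ADC", "DCE", "T2") %in% names(maps)))
    stop("maps must contain ADC, DCE and T2")
  id <- if (inherits(mask, "roi_mask")) mask$lesion_id else "lesion"
  mean_name <- c(ADC = "ADC", DCE = "ALPHE", T2 = "T2")
  out <- stats::setNames(numeric(0), character(0))
  for (mn in c("ADC", "DCE", "T2")) {
    blk <- map_texture(maps[[mn]], mask, levels, id, mn)
    out[mean_name[[mn]]] <- blk$mean
    out[paste0(mn, "-", names(blk$texture))] <- blk$texture
  }
  out[canonical_features()]
}
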