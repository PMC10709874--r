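# Lesion ROI masks and the ROI-inflation operator.
#
# Inflation is iterated binary dilation with a 2 x 2 square structuring
# element. A 2 x 2 element has no central pixel: the default origin is its
# top-left cell, so each turn grows the mask by one pixel toward increasing
# row and column (offsets {0,+1} x {0,+1}). This mirrors the convention of
# common numeric platforms for even-sized elements; an optional symmetric
# mode alternates {0,+1} and {-1,0} offsets between turns to cancel the
# drift.

#' Construct a lesion ROI mask
#'
#' @param grid logical (or 0/1) matrix; TRUE marks lesion pixels.
#' @param lesion_id identifier string.
#' @param dilation_level number of inflation turns already applied.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(grid, lesion_id = "lesion", dilation_level = 0L) {
  if (!is.matrix(grid)) stop("grid must be a matrix")
  storage.mode(grid) <- "logical"
  if (dilation_level < 0) stop("dilation_level must be >= 0")
  structure(list(grid = grid, lesion_id = lesion_id,
                 dilation_level = as.integer(dilation_level)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask %s, %d x %d, area %d, dilation level %d>\n",
              x$lesion_id, nrow(x$grid), ncol(x$grid), sum(x$grid),
              x$dilation_level))
  invisible(x)
}

#' Area (foreground pixel count) of a mask
#' @param mask `roi_mask` or logical matrix.
#' @return integer pixel count.
#' @export
roi_area <- function(mask) sum(as_mask_matrix(mask))

# one dilation turn: union of the mask shifted by each SE offset
dilate_once <- function(grid, offsets) {
  out <- matrix(FALSE, nrow(grid), ncol(grid))
  for (off in offsets)
    out <- out | shift_matrix(grid, off[1], off[2], fill = FALSE)
  out
}

#' Inflate an ROI by iterated 2 x 2 dilation
#'
#' Applies binary dilation `turns` times with the 2 x 2 square structuring
#' element anchored at its top-left cell, clipping at the image boundary.
#' `turns = 0` is the identity. With `symmetric = TRUE` odd turns use
#' offsets {0,+1} x {0,+1} and even turns {-1,0} x {-1,0}, so two turns
#' expand one pixel in every direction without net drift.
#'
#' @param mask `roi_mask` (or logical matrix).
#' @param turns number of dilation turns, 0..10.
#' @param symmetric alternate offset orientation between turns.
#' @return a `roi_mask` with `dilation_level` incremented by `turns`.
#' @export
dilate_roi <- function(mask, turns = 1L, symmetric = FALSE) {
  if (turns < 0) stop("turns must be >= 0")
  if (turns > 10) stop("turns must be <= 10")
  m <- if (inherits(mask, "roi_mask")) mask else roi_mask(mask)
  grid <- m$grid
  fwd <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  bwd <- list(c(0L, 0L), c(0L, -1L), c(-1L, 0L), c(-1L, -1L))
  for (i in seq_len(turns)) {
    offs <- if (symmetric && i %% 2 == 0) bwd else fwd
    grid <- dilate_once(grid, offs)
  }
  roi_mask(grid, m$lesion_id, m$dilation_level + as.integer(turns))
}

#' Binary erosion by an n-pixel square margin
#'
#' Iterated erosion with the symmetric 3 x 3 square element; used by the
#' phantom generator to derive a conservative "drawn" ROI strictly inside
#' the true lesion.
#'
#' @param mask `roi_mask` or logical matrix.
#' @param pixels number of erosion passes.
#' @return eroded `roi_mask` (dilation level reset to 0).
#' @export
erode_roi <- function(mask, pixels = 1L) {
  m <- if (inherits(mask, "roi_mask")) mask else roi_mask(mask)
  grid <- m$grid
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  for (i in seq_len(pixels)) {
    out <- matrix(TRUE, nrow(grid), ncol(grid))
    for (j in seq_len(nrow(offs)))
      out <- out & shift_matrix(grid, offs$dr[j], offs$dc[j], fill = FALSE)
    grid <- out
  }
  roi_mask(grid, m$lesion_id, 0L)
}

#' Map values inside an ROI
#'
#' Returns the map values at pixels that are both in the mask foreground and
#' valid, in row-major order (row by row, left to right).
#'
#' @param map `parameter_map` or numeric matrix.
#' @param mask `roi_mask` or logical matrix of the same shape.
#' @return numeric vector of values.
#' @export
masked_values <- function(map, mask) {
  mg <- as_map_grid(map)
  mk <- as_mask_matrix(mask)
  if (!identical(dim(mg$grid), dim(mk)))
    stop("map and mask shapes differ")
  fg <- mk & mg$valid
  if (!any(fg)) {
    id <- if (inherits(mask, "roi_mask")) mask$lesion_id else "mask"
    stop("no valid pixels inside ROI '", id, "'")
  }
  t(mg$grid)[t(fg)]  # transpose => row-major traversal
}
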