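# internal helpers shared across modules

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' seeded package functions do not disturb the global random stream.
#'
#' @param seed integer seed, or NULL for no seeding.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a child seed from a master seed by a fixed counter scheme
#'
#' @param master integer master seed.
#' @param index integer counter (case number, fold number, ...).
#' @return integer seed in [0, 2^31 - 2]; same (master, index) always maps to
#'   the same child seed.
#' @export
derive_seed <- function(master, index) {
  m <- as.double(master) %% 2147483647
  as.integer((m * 1009 + 9973 * as.double(index)) %% 2147483647)
}

# shift a matrix by (dr, dc), filling vacated cells with `fill`
shift_matrix <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_dst <- seq_len(nr) + dr
  c_dst <- seq_len(nc) + dc
  ok_r <- r_dst >= 1L & r_dst <= nr
  ok_c <- c_dst >= 1L & c_dst <= nc
  if (any(ok_r) && any(ok_c))
    out[r_dst[ok_r], c_dst[ok_c]] <- m[seq_len(nr)[ok_r], seq_len(nc)[ok_c]]
  out
}

# separable Gaussian blur via row/column kernel matrices; kernels are
# renormalised at the image edge so the local mean is preserved
gauss_kernel_matrix <- function(n, sigma) {
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-d^2 / (2 * sigma^2))
  k / rowSums(k)
}

gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  kr <- gauss_kernel_matrix(nrow(m), sigma)
  kc <- gauss_kernel_matrix(ncol(m), sigma)
  kr %*% m %*% t(kc)
}

# coerce a mask-ish object (roi_mask or matrix) to a logical matrix
as_mask_matrix <- function(mask) {
  if (inherits(mask, "roi_mask")) mask <- mask$grid
  if (!is.matrix(mask)) stop("mask must be a matrix or roi_mask")
  storage.mode(mask) <- "logical"
  mask
}

# coerce a map-ish object (parameter_map or matrix) to list(grid, valid)
as_map_grid <- function(map) {
  if (inherits(map, "parameter_map"))
    list(grid = map$grid, valid = map$valid_mask)
  else if (is.matrix(map))
    list(grid = map, valid = is.finite(map))
  else stop("map must be a matrix or parameter_map")
}
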