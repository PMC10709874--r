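# Per-pixel quantitative parameter fitting.
#
# Three mono-modal signal models are supported:
#   diffusion   S(b)  = S0 * exp(-b * ADC)          (b in s/mm^2)
#   relaxometry S(TE) = S0 * exp(-TE / T2)          (TE in ms)
#   enhancement PSE(t) = A * (1 - exp(-alpha*t)) * exp(-beta*t)   (t in s)
#
# ADC and T2 are fitted by weighted log-linear least squares (weights S^2,
# which de-biases the log transform); the empirical enhancement model is a
# bounded nonlinear least-squares fit.

#' Construct a parameter map
#'
#' @param name map name, one of "ADC", "T2", "ALPHA", "A", "BETA".
#' @param grid 2-D numeric matrix of fitted values.
#' @param units unit string (um^2/ms, ms, 1/s, %).
#' @param valid_mask logical matrix marking pixels with a usable fit.
#' @param diagnostics numeric matrix of per-pixel residual RMS (optional).
#' @return object of class `parameter_map`.
#' @export
parameter_map <- function(name, grid, units, valid_mask = NULL,
                          diagnostics = NULL) {
  stopifnot(is.matrix(grid))
  if (is.null(valid_mask)) valid_mask <- is.finite(grid)
  stopifnot(identical(dim(grid), dim(valid_mask)))
  structure(list(name = name, grid = grid, units = units,
                 valid_mask = valid_mask, diagnostics = diagnostics),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map %s [%s], %d x %d, %d valid px>\n",
              x$name, x$units, nrow(x$grid), ncol(x$grid),
              sum(x$valid_mask)))
  invisible(x)
}

#' Convert ADC between um^2/ms and mm^2/s
#'
#' 1 um^2/ms = 1e-3 mm^2/s; the conversion is an exact power of ten.
#' @param x numeric values.
#' @return converted values.
#' @export
um2ms_to_mm2s <- function(x) x / 1000

#' @rdname um2ms_to_mm2s
#' @export
mm2s_to_um2ms <- function(x) x * 1000

# weighted log-linear fit of y = a + b*x with weights w, closed form
loglin_wls <- function(x, y, w) {
  W <- sum(w); Sx <- sum(w * x); Sy <- sum(w * y)
  Sxx <- sum(w * x^2); Sxy <- sum(w * x * y)
  den <- W * Sxx - Sx^2
  slope <- (W * Sxy - Sx * Sy) / den
  intercept <- (Sy - slope * Sx) / W
  c(intercept = intercept, slope = slope)
}

#' Fit the apparent diffusion coefficient from a multi-b DWI series
#'
#' Weighted least squares on ln S = ln S0 - b * ADC with weights S^2.
#' Internally the slope is in mm^2/s; the returned ADC is in um^2/ms
#' (x 1000). ADC is clipped to [0, 10] um^2/ms and flagged invalid when the
#' unclipped estimate falls outside that range. Pixels with any non-positive
#' signal are marked invalid rather than clamped, to avoid log-domain bias.
#'
#' @param values signal intensities (same length as `bvalues`).
#' @param bvalues diffusion weightings in s/mm^2, strictly increasing.
#' @return list with `adc` (um^2/ms), `s0`, `rmse` (signal-domain residual
#'   RMS), `valid`.
#' @export
fit_adc <- function(values, bvalues) {
  if (length(values) != length(bvalues))
    stop("values and bvalues must have equal length")
  if (length(unique(bvalues)) < 2 || any(!is.finite(values)) ||
      any(values <= 0))
    return(list(adc = NA_real_, s0 = NA_real_, rmse = NA_real_,
                valid = FALSE))
  f <- loglin_wls(bvalues, log(values), values^2)
  adc <- mm2s_to_um2ms(-f[["slope"]])
  valid <- adc >= 0 && adc <= 10
  fitted <- exp(f[["intercept"]] + f[["slope"]] * bvalues)
  list(adc = min(max(adc, 0), 10), s0 = exp(f[["intercept"]]),
       rmse = sqrt(mean((values - fitted)^2)), valid = valid)
}

#' Fit T2 relaxation time from a multi-echo series
#'
#' Weighted least squares on ln S = ln S0 - TE / T2 with weights S^2. T2 is
#' reported in ms, clipped to (0, 2000]; non-decaying pixels (slope >= 0 in
#' the log domain, apart from the exactly-constant case) yield an invalid
#' fit.
#'
#' @param values signal intensities.
#' @param te echo times in ms, strictly increasing.
#' @return list with `t2` (ms), `s0`, `rmse`, `valid`.
#' @export
fit_t2 <- function(values, te) {
  if (length(values) != length(te))
    stop("values and te must have equal length")
  if (length(unique(te)) < 2 || any(!is.finite(values)) || any(values <= 0))
    return(list(t2 = NA_real_, s0 = NA_real_, rmse = NA_real_,
                valid = FALSE))
  f <- loglin_wls(te, log(values), values^2)
  slope <- f[["slope"]]
  t2 <- if (slope < 0) -1 / slope else Inf
  valid <- is.finite(t2) && t2 > 0 && t2 <= 2000
  fitted <- exp(f[["intercept"]] + slope * te)
  list(t2 = if (is.finite(t2)) min(t2, 2000) else 2000,
       s0 = exp(f[["intercept"]]),
       rmse = sqrt(mean((values - fitted)^2)), valid = valid)
}

#' Percentage signal enhancement of a DCE time course
#'
#' PSE(t) = 100 * (S(t) - S_base) / S_base with S_base the mean of the first
#' `baseline_frames` values; the time axis is re-zeroed at the last baseline
#' frame.
#'
#' @param values signal intensities over time.
#' @param times acquisition times in seconds, strictly increasing.
#' @param baseline_frames number of pre-enhancement frames (default 3).
#' @return list of class `pse_curve` with `pse` (%), `time` (s, zero at the
#'   last baseline frame), `s_base`, `valid`.
#' @export
compute_pse <- function(values, times, baseline_frames = 3L) {
  if (length(values) != length(times))
    stop("values and times must have equal length")
  if (baseline_frames < 1 || baseline_frames >= length(values))
    stop("baseline_frames must be in [1, length(values) - 1]")
  s_base <- mean(values[seq_len(baseline_frames)])
  if (!is.finite(s_base) || s_base <= 0)
    return(structure(list(pse = NULL, time = NULL, s_base = s_base,
                          valid = FALSE), class = "pse_curve"))
  structure(list(pse = 100 * (values - s_base) / s_base,
                 time = times - times[baseline_frames],
                 s_base = s_base, valid = TRUE),
            class = "pse_curve")
}

# the empirical enhancement model
emm_model <- function(t, A, alpha, beta) A * (1 - exp(-alpha * t)) * exp(-beta * t)

#' Fit the empirical enhancement model to a PSE curve
#'
#' Bounded nonlinear least squares of
#' PSE(t) = A (1 - exp(-alpha t)) exp(-beta t) over the post-baseline points
#' (t >= 0), with A in [0, 1000] %, alpha in [0, 10] 1/s, beta in [0, 1]
#' 1/s. Initialised at A0 = max PSE, alpha0 = ln 2 / (time to half max),
#' beta0 = 0.001; on failure a fixed 3 x 3 x 3 multi-start grid is tried and
#' the best-RMSE fit returned.
#'
#' @param pse a `pse_curve` from [compute_pse()], or a numeric PSE vector.
#' @param time times in s (ignored when `pse` is a `pse_curve`).
#' @return list with `A` (%), `alpha` (1/s), `beta` (1/s), `rmse`, `valid`.
#' @export
fit_emm <- function(pse, time = NULL) {
  if (inherits(pse, "pse_curve")) {
    if (!pse$valid)
      return(list(A = NA_real_, alpha = NA_real_, beta = NA_real_,
                  rmse = NA_real_, valid = FALSE))
    time <- pse$time
    pse <- pse$pse
  }
  keep <- time >= 0
  tt <- time[keep]; y <- pse[keep]
  if (sum(tt > 0) < 6) stop("need at least 6 post-baseline points")
  if (max(abs(y)) < 1e-12)
    return(list(A = 0, alpha = 0, beta = 0, rmse = 0, valid = TRUE))

  ymax <- max(y)
  i_half <- which(y >= ymax / 2)[1]
  t_half <- max(tt[i_half], min(tt[tt > 0]))
  start_grid <- expand.grid(A = c(25, 100, 400), alpha = c(0.05, 0.3, 1.5),
                            beta = c(5e-4, 5e-3, 5e-2))
  starts <- c(list(c(A = max(ymax, 1e-6), alpha = log(2) / t_half,
                     beta = 0.001)),
              lapply(seq_len(nrow(start_grid)),
                     function(i) unlist(start_grid[i, ])))
  lower <- c(0, 0, 0); upper <- c(1000, 10, 1)
  best <- NULL
  for (i in seq_along(starts)) {
    st <- pmin(pmax(starts[[i]], lower), upper)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ emm_model(tt, A, alpha, beta),
                        start = as.list(st),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rmse <- sqrt(mean(stats::residuals(fit)^2))
      if (is.null(best) || rmse < best$rmse) {
        p <- stats::coef(fit)
        best <- list(A = p[["A"]], alpha = p[["alpha"]], beta = p[["beta"]],
                     rmse = rmse, valid = TRUE)
      }
      # first start converging with a near-perfect fit: stop early
      if (i == 1 && best$rmse < 1e-8 * max(1, abs(ymax))) break
    }
  }
  if (is.null(best))
    return(list(A = NA_real_, alpha = NA_real_, beta = NA_real_,
                rmse = NA_real_, valid = FALSE))
  best
}

#' Initial enhancement slope A * alpha
#'
#' The product of EMM amplitude (%) and uptake rate (1/s) is the initial
#' slope of the PSE curve in %/s; it is emitted alongside the rate because
#' clinical summaries of the enhancement rate are often reported on this
#' scale.
#'
#' @param A amplitude (%), scalar or matrix.
#' @param alpha uptake rate (1/s).
#' @return initial slope in %/s.
#' @export
emm_initial_slope <- function(A, alpha) A * alpha

# vectorised weighted log-linear fit of every pixel row in V against x;
# returns slope/intercept/valid/rmse vectors
loglin_fit_rows <- function(V, x) {
  ok <- rowSums(!is.finite(V) | V <= 0) == 0
  n <- nrow(V)
  slope <- intercept <- rmse <- rep(NA_real_, n)
  if (any(ok)) {
    Vo <- V[ok, , drop = FALSE]
    y <- log(Vo); w <- Vo^2
    W <- rowSums(w)
    Sx <- as.vector(w %*% x)
    Sy <- rowSums(w * y)
    Sxx <- as.vector(w %*% x^2)
    Sxy <- rowSums(sweep(w * y, 2, x, "*"))
    den <- W * Sxx - Sx^2
    b <- (W * Sxy - Sx * Sy) / den
    a <- (Sy - b * Sx) / W
    fitted <- exp(outer(a, rep(1, length(x))) + outer(b, x))
    slope[ok] <- b; intercept[ok] <- a
    rmse[ok] <- sqrt(rowMeans((Vo - fitted)^2))
  }
  list(slope = slope, intercept = intercept, valid = ok, rmse = rmse)
}

#' Fit a parameter map from a per-pixel signal stack
#'
#' Applies the pixel-level fit at every grid position. ADC and T2 use the
#' vectorised weighted log-linear solver; the EMM is fitted pixel by pixel
#' (optionally restricted to a mask to keep large slices tractable).
#'
#' @param stack 3-D array (rows x cols x frames) of signals.
#' @param model one of "adc", "t2", "emm".
#' @param axis acquisition axis: b-values (s/mm^2) for "adc", echo times
#'   (ms) for "t2", frame times (s) for "emm".
#' @param baseline_frames EMM only: pre-enhancement frames for the PSE
#'   reference (default 3).
#' @param mask EMM only: optional logical matrix; pixels outside it are left
#'   invalid without fitting.
#' @return a `parameter_map` (ADC or T2), or for "emm" a named list of
#'   `parameter_map`s `A`, `ALPHA`, `BETA`.
#' @export
fit_map <- function(stack, model = c("adc", "t2", "emm"), axis,
                    baseline_frames = 3L, mask = NULL) {
  model <- match.arg(model)
  if (!is.array(stack) || length(dim(stack)) != 3 || any(dim(stack) == 0))
    stop("stack must be a non-empty rows x cols x frames array")
  d <- dim(stack)
  if (d[3] != length(axis)) stop("axis length must match frame count")
  V <- matrix(stack, nrow = d[1] * d[2], ncol = d[3])

  grid_of <- function(v) matrix(v, d[1], d[2])
  if (model == "adc") {
    f <- loglin_fit_rows(V, axis)
    adc <- mm2s_to_um2ms(-f$slope)
    valid <- f$valid & !is.na(adc) & adc >= 0 & adc <= 10
    adc <- pmin(pmax(adc, 0), 10)
    parameter_map("ADC", grid_of(adc), "um^2/ms", grid_of(valid),
                  grid_of(f$rmse))
  } else if (model == "t2") {
    f <- loglin_fit_rows(V, axis)
    t2 <- ifelse(f$slope < 0, -1 / f$slope, Inf)
    valid <- f$valid & is.finite(t2) & t2 > 0 & t2 <= 2000
    t2 <- ifelse(is.finite(t2), pmin(t2, 2000), 2000)
    parameter_map("T2", grid_of(t2), "ms", grid_of(valid), grid_of(f$rmse))
  } else {
    npix <- d[1] * d[2]
    A <- alpha <- beta <- rmse <- rep(NA_real_, npix)
    valid <- rep(FALSE, npix)
    do_fit <- if (is.null(mask)) rep(TRUE, npix) else as.vector(mask)
    for (p in which(do_fit)) {
      v <- V[p, ]
      if (any(!is.finite(v)) || any(v <= 0)) next
      curve <- compute_pse(v, axis, baseline_frames)
      if (!curve$valid) next
      fit <- tryCatch(fit_emm(curve), error = function(e) NULL)
      if (is.null(fit) || !fit$valid) next
      A[p] <- fit$A; alpha[p] <- fit$alpha; beta[p] <- fit$beta
      rmse[p] <- fit$rmse; valid[p] <- TRUE
    }
    list(A = parameter_map("A", grid_of(A), "%", grid_of(valid),
                           grid_of(rmse)),
         ALPHA = parameter_map("ALPHA", grid_of(alpha), "1/s",
                               grid_of(valid), grid_of(rmse)),
         BETA = parameter_map("BETA", grid_of(beta), "1/s", grid_of(valid),
                              grid_of(rmse)))
  }
}
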