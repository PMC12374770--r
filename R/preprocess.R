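#' Raw TCSPC histogram
#'
#' Uncalibrated time-correlated single-photon counting histogram as produced
#' by the detection electronics: integer counts on uniform channels of width
#' \code{channel_width} (ps), with acquisition metadata.
#'
#' @param counts nonnegative integer counts per channel.
#' @param channel_width channel width, ps (> 0).
#' @param integration_time acquisition time, s (metadata).
#' @param wavelength wavelength, nm (metadata).
#' @param rho source-detector separation, cm (metadata).
#' @return Object of class \code{"raw_histogram"}.
#' @export
raw_histogram <- function(counts, channel_width, integration_time = NA_real_,
                          wavelength = NA_real_, rho = NA_real_) {
  stopifnot(is.numeric(counts), length(counts) >= 2L,
            is.numeric(channel_width), channel_width > 0)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be nonnegative integers", call. = FALSE)
  structure(list(counts = as.numeric(counts), channel_width = channel_width,
                 integration_time = integration_time, wavelength = wavelength,
                 rho = rho),
            class = "raw_histogram")
}

#' @export
print.raw_histogram <- function(x, ...) {
  cat(sprintf("<raw_histogram> %d channels of %g ps, %s total counts\n",
              length(x$counts), x$channel_width,
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

# channel-center times in ns
.rh_times <- function(raw) (seq_along(raw$counts) - 0.5) * raw$channel_width / 1e3

# constant dark/background level from pre-peak channels, floored at 0
.estimate_background <- function(counts, frac = 0.02) {
  peak <- max(counts)
  rise <- which(counts > frac * peak)[1]
  if (is.na(rise) || rise <= 3) return(0)
  max(0, mean(counts[seq_len(max(1, rise - 3))]))
}

#' Estimate instrument calibration against a reference medium
#'
#' Recovers the laser emission time \code{t0} and the amplitude factor
#' mapping the theoretical reflectance of a reference medium with known
#' optical properties onto the measured histogram: a grid search of the time
#' shift at channel resolution (refined by parabolic interpolation of the
#' residual norm) with the closed-form least-squares amplitude at each shift.
#' A constant dark level estimated from pre-peak channels is subtracted
#' first.
#'
#' @param raw a \code{\link{raw_histogram}} with a single dominant peak.
#' @param reference an \code{\link{optical_layer}} or
#'   \code{\link{two_layer_medium}} describing the calibration medium.
#' @param rho source-detector separation, cm (defaults to \code{raw$rho}).
#' @param n_ambient ambient refractive index.
#' @param t0_range search range for \code{t0}, ns.
#' @param ... passed to \code{\link{td_two_layer}} when the reference is
#'   layered.
#' @return Object of class \code{"instrument_calibration"} with fields
#'   \code{t0} (ns), \code{amplitude_factor} (measured counts per model
#'   density unit) and the achieved residual.
#' @export
estimate_calibration <- function(raw, reference, rho = raw$rho, n_ambient = 1,
                                 t0_range = c(0, 3), ...) {
  stopifnot(inherits(raw, "raw_histogram"))
  if (is.na(rho)) stop("'rho' is required", call. = FALSE)
  counts <- raw$counts - .estimate_background(raw$counts)
  counts <- pmax(counts, 0)
  if (max(counts) <= 0 || sum(counts > 0) < 5L ||
      max(counts) < 5 * stats::median(counts[counts > 0]))
    stop("calibration failure: flat or empty histogram", call. = FALSE)
  dt <- raw$channel_width / 1e3
  times <- .rh_times(raw)

  # model on an extended grid so shifted lookups stay in range
  n_ext <- length(counts) + ceiling(diff(t0_range) / dt) + 2L
  grid <- time_grid(t_end = n_ext * dt, n_bins = n_ext)
  model <- if (inherits(reference, "two_layer_medium")) {
    td_two_layer(reference, rho = rho, grid = grid, ...)$values
  } else if (inherits(reference, "optical_layer")) {
    td_semi_infinite(reference, rho = rho, grid = grid,
                     n_ambient = n_ambient)$values
  } else stop("'reference' must be an optical_layer or two_layer_medium",
              call. = FALSE)
  model_at <- function(tau) {
    # model evaluated at times - tau (linear interpolation, 0 outside)
    approx(grid$centers, model, xout = times - tau, yleft = 0, yright = 0)$y
  }
  sse_amp <- function(tau) {
    m <- model_at(tau)
    mm <- sum(m * m)
    if (mm == 0) return(list(sse = sum(counts^2), amp = 0))
    a <- sum(counts * m) / mm
    list(sse = sum((counts - a * m)^2), amp = a)
  }
  shifts <- seq(t0_range[1], t0_range[2], by = dt)
  sses <- vapply(shifts, function(s) sse_amp(s)$sse, numeric(1))
  i <- which.min(sses)
  t0 <- shifts[i]
  if (i > 1 && i < length(shifts)) {
    # parabolic refinement on the discrete residual profile
    y1 <- sses[i - 1]; y2 <- sses[i]; y3 <- sses[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den > 0) t0 <- shifts[i] + 0.5 * dt * (y1 - y3) / den
  }
  best <- sse_amp(t0)
  if (best$amp <= 0)
    stop("calibration failure: non-positive amplitude", call. = FALSE)
  structure(list(t0 = t0, amplitude_factor = best$amp, residual = best$sse,
                 rho = rho, wavelength = raw$wavelength),
            class = "instrument_calibration")
}

#' @export
print.instrument_calibration <- function(x, ...) {
  cat(sprintf("<instrument_calibration> t0 = %.4f ns, amplitude factor = %.6g\n",
              x$t0, x$amplitude_factor))
  invisible(x)
}

#' Apply an instrument calibration to a raw histogram
#'
#' Shifts the time axis by \code{-t0}, divides by the amplitude factor and
#' resamples onto the target grid with bin-sum-preserving rebinning (total
#' counts over the common support are conserved before amplitude division).
#' Background estimated from pre-peak channels is subtracted first. If the
#' target grid extends beyond the shifted data, the uncovered bins are zero
#' and a warning is emitted.
#'
#' @param raw a \code{\link{raw_histogram}}.
#' @param cal an \code{\link{estimate_calibration}} result.
#' @param grid target \code{\link{time_grid}}.
#' @param subtract_background subtract the pre-peak dark level (default
#'   \code{TRUE}).
#' @return A model-density-kind \code{\link{transient}} (values are counts
#'   divided by the amplitude factor; \code{scale} holds the factor mapping
#'   back to counts for Poisson weighting).
#' @export
apply_calibration <- function(raw, cal, grid, subtract_background = TRUE) {
  stopifnot(inherits(raw, "raw_histogram"),
            inherits(cal, "instrument_calibration"),
            inherits(grid, "time_grid"))
  counts <- raw$counts
  if (subtract_background) counts <- pmax(counts - .estimate_background(counts), 0)
  dt <- raw$channel_width / 1e3
  old_edges <- (0:length(counts)) * dt - cal$t0
  if (grid$edges[length(grid$edges)] > old_edges[length(old_edges)] + 1e-12 ||
      grid$edges[1] < old_edges[1] - 1e-12)
    warning("target grid extends beyond the shifted histogram; cropped",
            call. = FALSE)
  res <- rebin_sums(old_edges, counts, grid$edges)
  transient(grid, pmax(res, 0) / cal$amplitude_factor, kind = "model_density",
            rho = raw$rho %||% cal$rho, wavelength = raw$wavelength,
            scale = cal$amplitude_factor)
}

#' Crop and rebin a transient
#'
#' Restricts a transient to a time window and merges groups of
#' \code{factor} consecutive bins by summation (counts) so that the total
#' within the window is conserved. Trailing bins that do not fill a complete
#' group are dropped.
#'
#' @param x a \code{\link{transient}}.
#' @param window numeric length-2 window \code{c(t1, t2)} in ns, or
#'   \code{NULL} to keep the full range.
#' @param factor integer rebinning factor (>= 1).
#' @return A \code{\link{transient}} on the new grid.
#' @export
crop_and_rebin <- function(x, window = NULL, factor = 1L) {
  stopifnot(inherits(x, "transient"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("'factor' must be >= 1", call. = FALSE)
  keep <- rep(TRUE, x$grid$n_bins)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < window[2])
    keep <- x$grid$centers >= window[1] & x$grid$centers <= window[2]
    if (!any(keep)) stop("empty window", call. = FALSE)
  }
  idx <- which(keep)
  vals <- x$values[idx]
  t0 <- x$grid$edges[idx[1]]
  ngroup <- length(vals) %/% factor
  if (ngroup < 2L) stop("window too small for the requested rebinning",
                        call. = FALSE)
  vals <- vals[seq_len(ngroup * factor)]
  newv <- colSums(matrix(vals, nrow = factor))
  grid <- time_grid(t_end = t0 + ngroup * factor * x$grid$dt,
                    n_bins = ngroup, t_start = t0)
  transient(grid, newv, kind = x$kind, rho = x$rho,
            wavelength = x$wavelength, scale = x$scale)
}
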