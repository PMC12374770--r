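#' Time-gate specification
#'
#' Selects the part of the time-of-flight curve to integrate. The late gate
#' discards early-arriving photons, which mostly sampled the superficial
#' layer, and thereby raises the relative contribution of the deep layer.
#'
#' @param mode \code{"full"} (integrate everything) or \code{"late"}.
#' @param q for the late gate: start at the time where the cumulative
#'   baseline counts reach this fraction (in (0, 1)); ignored when
#'   \code{start_ns} is given.
#' @param start_ns absolute gate start, ns (overrides \code{q}).
#' @param end_ns gate end, ns (default: end of record).
#' @return Object of class \code{"gate_spec"}.
#' @export
gate_spec <- function(mode = c("full", "late"), q = 0.7, start_ns = NULL,
                      end_ns = Inf) {
  mode <- match.arg(mode)
  if (mode == "late" && is.null(start_ns))
    stopifnot(q > 0, q < 1)
  if (!is.null(start_ns) && start_ns >= end_ns)
    stop("gate start must be before its end", call. = FALSE)
  structure(list(mode = mode, q = q, start_ns = start_ns, end_ns = end_ns),
            class = "gate_spec")
}

# bin mask of a gate on a grid, given the baseline profile for q-defined gates
.gate_mask <- function(gate, grid, baseline) {
  if (gate$mode == "full") return(rep(TRUE, grid$n_bins))
  start <- gate$start_ns
  if (is.null(start)) {
    cum <- cumsum(baseline) / sum(baseline)
    start <- grid$centers[which(cum >= gate$q)[1]]
  }
  mask <- grid$centers >= start & grid$centers <= gate$end_ns
  if (!any(mask)) stop("gate selects no bins", call. = FALSE)
  mask
}

#' Pulsatile two-layer simulation configuration
#'
#' Study conditions for the time-gated pulsatile-retrieval simulation: the
#' absorption of each layer of the baseline medium is modulated sinusoidally
#' (\eqn{\mu_{a,i}(t) = \mu_{a,i} + \Delta\mu_{a,i} \sin(2\pi f_i t)}) at the
#' maternal and fetal heart rates, frames are synthesized by Beer-Lambert
#' re-weighting of a single baseline Monte Carlo run, and shot noise is
#' applied per frame.
#'
#' @param baseline a \code{\link{two_layer_medium}}; default is the maternal
#'   layer (0.11, 11.19, 9.6 mm) over the fetal layer (0.09333, 9.551).
#' @param delta_mua per-layer modulation amplitudes, 1/cm; default 2\% of
#'   each baseline absorption.
#' @param freqs modulation frequencies c(maternal, fetal), Hz; default
#'   c(1.3, 2.1).
#' @param frame_rate frames per second; must exceed twice the fastest
#'   modulation frequency.
#' @param duration record length, s.
#' @param counts_per_frame expected detected photons per frame at baseline.
#' @param rho source-detector separation, cm.
#' @param n_photons photons for the baseline Monte Carlo run.
#' @param seed integer seed (Monte Carlo and shot noise).
#' @param max_time,n_bins arrival-time binning of each frame.
#' @return Object of class \code{"pulsatile_config"}.
#' @export
pulsatile_config <- function(baseline = NULL, delta_mua = NULL,
                             freqs = c(1.3, 2.1), frame_rate = 20,
                             duration = 60, counts_per_frame = 1e5,
                             rho = 2, n_photons = 1e6, seed = 1L,
                             max_time = 5, n_bins = 100) {
  if (is.null(baseline))
    baseline <- two_layer_medium(
      optical_layer(0.11, 11.19, thickness = 0.96),
      optical_layer(0.09333, 9.551))
  stopifnot(inherits(baseline, "two_layer_medium"), length(freqs) == 2L,
            all(freqs > 0), duration > 0, counts_per_frame >= 0)
  if (frame_rate <= 2 * max(freqs))
    stop("frame_rate must exceed twice the fastest modulation frequency",
         call. = FALSE)
  if (is.null(delta_mua))
    delta_mua <- 0.02 * c(baseline$top$mua, baseline$bottom$mua)
  stopifnot(length(delta_mua) == 2L, all(delta_mua >= 0))
  structure(list(baseline = baseline, delta_mua = delta_mua, freqs = freqs,
                 frame_rate = frame_rate, duration = duration,
                 counts_per_frame = counts_per_frame, rho = rho,
                 n_photons = n_photons, seed = as.integer(seed),
                 max_time = max_time, n_bins = as.integer(n_bins)),
            class = "pulsatile_config")
}

#' Simulate a pulsatile stream of time-of-flight frames
#'
#' Runs one baseline layered Monte Carlo simulation, then produces one frame
#' per time step by re-weighting the baseline DTOF for the instantaneous
#' per-layer absorption offsets (Beer-Lambert, using per-bin mean per-layer
#' pathlengths) and drawing Poisson counts with the expected baseline total
#' \code{counts_per_frame}.
#'
#' @param cfg a \code{\link{pulsatile_config}}.
#' @param mc optional precomputed baseline \code{mc_result} for
#'   \code{cfg$baseline} (reused across seeds in studies); when \code{NULL}
#'   it is run here.
#' @return Object of class \code{"pulsatile_stream"}: \code{counts} (frames
#'   x bins matrix), \code{times} (frame timestamps, s), \code{grid},
#'   \code{baseline_dtof}, \code{cfg}.
#' @export
simulate_pulsatile_stream <- function(cfg, mc = NULL) {
  stopifnot(inherits(cfg, "pulsatile_config"))
  if (is.null(mc)) {
    layers <- list(as_mc_layer(cfg$baseline$top),
                   as_mc_layer(cfg$baseline$bottom))
    mc <- run_layered_mc(layers, mc_config(
      n_photons = cfg$n_photons, seed = cfg$seed, rho = cfg$rho,
      max_time = cfg$max_time, n_bins = cfg$n_bins),
      n_ambient = cfg$baseline$n_ambient)
  }
  if (mc$empty) stop("baseline Monte Carlo run detected no photons",
                     call. = FALSE)
  w <- mc$dtof
  pos <- w > 0
  Lbar <- matrix(0, 2, length(w))
  Lbar[, pos] <- sweep(mc$pathlen_sums[, pos, drop = FALSE], 2, w[pos], "/")
  base_total <- sum(w)

  nframes <- floor(cfg$duration * cfg$frame_rate)
  times <- (seq_len(nframes) - 1) / cfg$frame_rate
  counts <- matrix(0L, nframes, length(w))
  with_seed(cfg$seed + 1L, {
    for (k in seq_len(nframes)) {
      dm <- cfg$delta_mua * sin(2 * pi * cfg$freqs * times[k])
      fac <- exp(-(dm[1] * Lbar[1, ] + dm[2] * Lbar[2, ]))
      lam <- w * fac * (cfg$counts_per_frame / base_total)
      counts[k, ] <- rpois(length(lam), lam)
    }
  })
  structure(list(counts = counts, times = times, grid = mc$grid,
                 baseline_dtof = w, cfg = cfg),
            class = "pulsatile_stream")
}

#' @export
print.pulsatile_stream <- function(x, ...) {
  cat(sprintf("<pulsatile_stream> %d frames at %g Hz, %d time bins\n",
              nrow(x$counts), x$cfg$frame_rate, ncol(x$counts)))
  invisible(x)
}

#' Integrate a frame stream over a time gate
#'
#' @param stream a \code{\link{simulate_pulsatile_stream}} result.
#' @param gate a \code{\link{gate_spec}}.
#' @return Numeric per-frame intensity series (summed counts in the gate).
#' @export
gate_integrate <- function(stream, gate) {
  stopifnot(inherits(stream, "pulsatile_stream"), inherits(gate, "gate_spec"))
  mask <- .gate_mask(gate, stream$grid, stream$baseline_dtof)
  as.numeric(stream$counts[, mask, drop = FALSE] %*% rep(1, sum(mask)))
}

#' One-sided power spectrum of an intensity series
#'
#' Mean-removed, Hann-windowed periodogram. The power is normalized so that
#' the sum over the one-sided grid equals the energy of the windowed,
#' mean-removed series (Parseval).
#'
#' @param series numeric series of per-frame intensities (>= 64 frames).
#' @param frame_rate sampling rate, Hz.
#' @return Object of class \code{"spectrum_result"} with \code{freq} (Hz, up
#'   to the Nyquist frequency) and \code{power}.
#' @export
power_spectrum <- function(series, frame_rate) {
  n <- length(series)
  if (n < 64) stop("need at least 64 frames", call. = FALSE)
  x <- series - mean(series)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)) # Hann
  xw <- x * win
  X <- fft(xw)
  half <- floor(n / 2)
  p <- Mod(X[1:(half + 1)])^2 / n
  # fold the negative frequencies onto the one-sided grid
  if (n %% 2 == 0) {
    p[2:half] <- 2 * p[2:half]
  } else {
    p[2:(half + 1)] <- 2 * p[2:(half + 1)]
  }
  structure(list(freq = (0:half) * frame_rate / n, power = p,
                 frame_rate = frame_rate, n = n,
                 detrend = "mean-removed, Hann window"),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result> %d frequency bins up to %.3g Hz (df = %.4g Hz)\n",
              length(x$freq), max(x$freq), x$freq[2]))
  invisible(x)
}

#' @export
plot.spectrum_result <- function(x, ...) {
  plot(x$freq, x$power, type = "h", xlab = "frequency [Hz]",
       ylab = "power", ...)
  invisible(x)
}

#' Signal-to-background ratio of a spectral peak
#'
#' SBR = power in the grid bin nearest \code{target_freq} divided by the
#' median power outside exclusion bands around all listed modulation
#' frequencies (the DC bin is always excluded from the background).
#'
#' @param spec a \code{\link{power_spectrum}} result.
#' @param target_freq frequency of interest, Hz (within the grid).
#' @param exclude frequencies around which to exclude bands from the
#'   background (should include all modulation frequencies); defaults to
#'   \code{target_freq}.
#' @param band half width of each exclusion band, Hz.
#' @return Scalar SBR (unitless).
#' @export
signal_to_background <- function(spec, target_freq, exclude = target_freq,
                                 band = 0.25) {
  stopifnot(inherits(spec, "spectrum_result"))
  if (target_freq < 0 || target_freq > max(spec$freq))
    stop("target frequency outside the spectral grid", call. = FALSE)
  i <- which.min(abs(spec$freq - target_freq))
  bg <- rep(TRUE, length(spec$freq))
  bg[1] <- FALSE # DC
  for (f in exclude) bg[abs(spec$freq - f) <= band] <- FALSE
  if (!any(bg)) stop("exclusion bands cover the whole grid", call. = FALSE)
  spec$power[i] / median(spec$power[bg])
}
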