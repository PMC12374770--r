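#' Uniform time grid for time-of-flight transients
#'
#' @param t_end end of the grid, ns.
#' @param n_bins number of uniform bins (>= 2).
#' @param t_start start of the grid, ns (default 0).
#' @return Object of class \code{"time_grid"} with fields \code{t_start},
#'   \code{t_end}, \code{n_bins}, \code{dt} and the bin-center vector
#'   \code{centers}.
#' @examples
#' g <- time_grid(t_end = 5, n_bins = 200)
#' g$dt # 25 ps
#' @export
time_grid <- function(t_end, n_bins, t_start = 0) {
  stopifnot(is.numeric(t_start), is.numeric(t_end), length(t_start) == 1L,
            length(t_end) == 1L, is.numeric(n_bins), length(n_bins) == 1L)
  if (!(t_start >= 0 && t_start < t_end))
    stop("need 0 <= t_start < t_end", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("'n_bins' must be >= 2", call. = FALSE)
  dt <- (t_end - t_start) / n_bins
  structure(list(t_start = t_start, t_end = t_end, n_bins = n_bins, dt = dt,
                 centers = t_start + (seq_len(n_bins) - 0.5) * dt,
                 edges = t_start + (0:n_bins) * dt),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> [%g, %g] ns, %d bins of %.4g ps\n",
              x$t_start, x$t_end, x$n_bins, 1e3 * x$dt))
  invisible(x)
}

#' Time-binned diffuse reflectance at one distance and wavelength
#'
#' Container for a distribution of times of flight (DTOF): either a model
#' reflectance density (photons per cm^2 per ns, per launched photon) or
#' measured/simulated photon counts.
#'
#' @param grid a \code{\link{time_grid}}.
#' @param values nonnegative per-bin values, length \code{grid$n_bins}.
#'   For \code{kind = "counts"} the values must be integers.
#' @param kind \code{"model_density"} or \code{"counts"}.
#' @param rho source-detector separation, cm.
#' @param wavelength wavelength, nm (optional).
#' @param scale for calibrated transients: multiplicative factor mapping the
#'   stored values back to raw detected counts (used to form Poisson weights
#'   when fitting); \code{NA} when unknown.
#' @return Object of class \code{"transient"}.
#' @export
transient <- function(grid, values, kind = c("model_density", "counts"),
                      rho = NA_real_, wavelength = NA_real_, scale = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "time_grid"), is.numeric(values),
            length(values) == grid$n_bins)
  if (any(!is.finite(values)) || any(values < 0))
    stop("transient values must be finite and >= 0", call. = FALSE)
  if (kind == "counts" && any(abs(values - round(values)) > 1e-8))
    stop("counts-kind transient values must be integers", call. = FALSE)
  structure(list(grid = grid, values = as.numeric(values), kind = kind,
                 rho = rho, wavelength = wavelength, scale = scale),
            class = "transient")
}

#' @export
print.transient <- function(x, ...) {
  cat(sprintf("<transient> %s, %d bins on [%g, %g] ns, rho = %s cm%s\n",
              x$kind, x$grid$n_bins, x$grid$t_start, x$grid$t_end,
              format(x$rho),
              if (is.na(x$wavelength)) "" else sprintf(", %g nm", x$wavelength)))
  if (x$kind == "counts")
    cat(sprintf("  total counts: %s\n", format(sum(x$values), big.mark = ",")))
  invisible(x)
}

#' @export
as.data.frame.transient <- function(x, ...) {
  data.frame(time_ns = x$grid$centers, value = x$values)
}

#' @export
plot.transient <- function(x, log = "y", main = NULL, ...) {
  v <- x$values
  if (grepl("y", log)) v[v <= 0] <- NA
  plot(x$grid$centers, v, type = "l", log = log, xlab = "time [ns]",
       ylab = if (x$kind == "counts") "counts" else "reflectance [cm^-2 ns^-1]",
       main = main %||% sprintf("DTOF at rho = %s cm", format(x$rho)), ...)
  invisible(x)
}

#' Read / write a transient as delimited text with a metadata sidecar
#'
#' The transient is stored as a two-column CSV (\code{time_ns,value}; times
#' are bin centers) plus a YAML sidecar \code{<file>.meta.yaml} holding
#' \code{kind}, \code{rho_cm}, \code{wavelength_nm} and the grid definition.
#'
#' @param x a \code{\link{transient}}.
#' @param file CSV path.
#' @return \code{read_transient} returns a \code{\link{transient}}.
#' @export
write_transient <- function(x, file) {
  stopifnot(inherits(x, "transient"))
  write.csv(as.data.frame(x), file, row.names = FALSE)
  meta <- list(kind = x$kind, rho_cm = x$rho, wavelength_nm = x$wavelength,
               t_start_ns = x$grid$t_start, t_end_ns = x$grid$t_end,
               n_bins = x$grid$n_bins, scale = x$scale)
  yaml::write_yaml(meta, paste0(file, ".meta.yaml"))
  invisible(file)
}

#' @rdname write_transient
#' @export
read_transient <- function(file) {
  d <- read.csv(file)
  meta_file <- paste0(file, ".meta.yaml")
  if (file.exists(meta_file)) {
    m <- yaml::read_yaml(meta_file)
    grid <- time_grid(t_end = m$t_end_ns, n_bins = m$n_bins,
                      t_start = m$t_start_ns)
    transient(grid, d$value, kind = m$kind,
              rho = m$rho_cm %||% NA_real_,
              wavelength = m$wavelength_nm %||% NA_real_,
              scale = m$scale %||% NA_real_)
  } else {
    # infer a uniform grid from the time column
    dt <- stats::median(diff(d$time_ns))
    grid <- time_grid(t_end = d$time_ns[nrow(d)] + dt / 2, n_bins = nrow(d),
                      t_start = max(0, d$time_ns[1] - dt / 2))
    kind <- if (all(abs(d$value - round(d$value)) < 1e-8)) "counts" else "model_density"
    transient(grid, d$value, kind = kind)
  }
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

# Conservative rebinning of bin-integrated data onto a new uniform grid.
# Values are treated as per-bin sums; overlap fractions redistribute them so
# that totals are conserved over the common support.
rebin_sums <- function(old_edges, values, new_edges) {
  cum <- c(0, cumsum(values))
  # cumulative sum interpolated at arbitrary times (linear within bins)
  cum_at <- function(t) {
    t <- pmin(pmax(t, old_edges[1]), old_edges[length(old_edges)])
    approx(old_edges, cum, xout = t)$y
  }
  diff(cum_at(new_edges))
}
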