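#' Default fit window of a transient
#'
#' The window runs from the bin where the rising edge first reaches
#' \code{rise_frac} of the peak to the last bin above \code{tail_frac} of the
#' peak. Early bins are dominated by the instrument response and the
#' breakdown of the diffusion approximation, late bins by noise; both
#' fractions are configurable.
#'
#' @param values per-bin transient values.
#' @param rise_frac rising-edge threshold as a fraction of the peak.
#' @param tail_frac tail threshold as a fraction of the peak.
#' @return Integer vector of bin indices.
#' @export
fit_window <- function(values, rise_frac = 0.5, tail_frac = 0.01) {
  stopifnot(rise_frac > 0, rise_frac < 1, tail_frac > 0, tail_frac < rise_frac)
  peak <- max(values)
  if (peak <= 0) stop("transient has no signal", call. = FALSE)
  from <- which(values >= rise_frac * peak)[1]
  to <- max(which(values >= tail_frac * peak))
  from:to
}

# Poisson-variance weights on the data scale (arbitrary overall factor).
# Noise-free model densities get the same relative weighting so that the
# information-rich late tail is not drowned by the peak.
.poisson_weights <- function(tr) {
  if (tr$kind == "counts") {
    1 / pmax(tr$values, 1)
  } else if (!is.na(tr$scale)) {
    1 / pmax(tr$values * tr$scale, 1) # counts before amplitude division
  } else {
    1 / pmax(tr$values, 1e-3 * max(tr$values))
  }
}

# Fast re-evaluable two-layer TD model: precomputes the Hankel quadrature,
# the Bessel coefficients and the FFT grid; returns f(mua1, musp1, mua2,
# musp2) giving reflectance at the bin centers of `grid`.
.tl_td_model <- function(rho, grid, n, n_ambient, thickness, nquad = 256,
                         smax = 300, dt_max = 0.0125, T_min = 10) {
  A <- boundary_A(n / n_ambient)
  # power-of-two fraction of the bin width: internal samples hit bin centers
  dt <- grid$dt / 2^max(1, ceiling(log2(grid$dt / dt_max)))
  span <- max(2 * grid$t_end, T_min)
  nfft <- 2^ceiling(log2(span / dt))
  Tspan <- nfft * dt
  omega <- 2 * pi * (0:(nfft / 2)) / Tspan
  gl <- pracma::gaussLegendre(nquad, 0, smax)
  coef <- gl$w * gl$x * besselJ(gl$x * rho, 0) / (2 * pi)
  tt <- (0:(nfft - 1)) * dt
  v <- .c0 / n
  half <- nfft / 2
  function(mua1, musp1, mua2, musp2) {
    D1 <- 1 / (3 * musp1)
    D2 <- 1 / (3 * musp2)
    z0 <- min(1 / musp1, 0.9 * thickness)
    zb <- 2 * A * D1
    phi_w <- .tl_kernel_cpp(gl$x, coef, omega, mua1, D1, v, mua2, D2, v,
                            thickness, z0, zb)
    # extreme parameter excursions during optimization can overflow the
    # kernel; signal an infeasible model by returning zeros
    if (any(!is.finite(phi_w))) return(numeric(grid$n_bins))
    spec <- complex(length.out = nfft)
    spec[seq_len(half + 1)] <- phi_w
    spec[nfft:(half + 2)] <- Conj(phi_w[2:half])
    phi_t <- Re(fft(spec, inverse = TRUE)) / Tspan
    vals <- spline(tt, phi_t, xout = grid$centers, method = "natural")$y
    vals[grid$centers <= 0] <- 0
    pmax(vals, 0) / (2 * A)
  }
}

# closed-form semi-infinite model on a grid
.si_td_model <- function(rho, grid, n, n_ambient) {
  A <- boundary_A(n / n_ambient)
  v <- .c0 / n
  t <- grid$centers
  function(mua, musp) {
    D <- 1 / (3 * musp)
    .semi_infinite_phi(t, mua, D, v, 1 / musp, 2 * A * D, rho) / (2 * A)
  }
}

# Levenberg-Marquardt driver on log-transformed positive parameters with the
# amplitude profiled out in closed form. `model_of(p)` maps the natural-scale
# parameter vector to model values on the fit window.
.lm_profiled <- function(y, w, model_of, p0, loss = "wls", maxiter = 100,
                         ftol = 1e-10, ptol = 1e-10) {
  amp_env <- new.env(parent = emptyenv())
  amp_env$a <- NA_real_
  resid_wls <- function(theta) {
    m <- model_of(exp(theta))
    mm <- sum(w * m * m)
    if (!is.finite(mm) || mm <= 0) return(sqrt(w) * y + 1e6)
    a <- sum(w * y * m) / mm
    amp_env$a <- a
    sqrt(w) * (y - a * m)
  }
  resid_dev <- function(theta) {
    # last element of theta is log amplitude
    k <- length(theta)
    m <- exp(theta[k]) * model_of(exp(theta[-k]))
    amp_env$a <- exp(theta[k])
    m <- pmax(m, 1e-12)
    d <- 2 * (ifelse(y > 0, y * log(y / m), 0) - (y - m))
    sign(y - m) * sqrt(pmax(d, 0))
  }
  resid_log <- function(theta) {
    m <- model_of(exp(theta))
    m <- pmax(m, .Machine$double.xmin)
    yy <- pmax(y, .Machine$double.xmin)
    la <- sum(w * (log(yy) - log(m))) / sum(w)
    amp_env$a <- exp(la)
    sqrt(w) * (log(yy) - log(m) - la)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol,
                                     ptol = ptol)
  if (loss == "poisson_deviance") {
    # initialize the amplitude from a WLS profile at p0
    m0 <- model_of(p0)
    a0 <- sum(w * y * m0) / max(sum(w * m0 * m0), .Machine$double.xmin)
    fit <- minpack.lm::nls.lm(par = c(log(p0), log(max(a0, 1e-300))),
                              fn = resid_dev, control = ctrl)
    theta <- fit$par[-length(fit$par)]
  } else {
    fn <- if (loss == "least_squares_on_log") resid_log else resid_wls
    fit <- minpack.lm::nls.lm(par = log(p0), fn = fn, control = ctrl)
    theta <- fit$par
  }
  list(p = exp(theta), amplitude = amp_env$a, rss = fit$deviance,
       iterations = fit$niter, info = fit$info, message = fit$message,
       converged = fit$info %in% 1:4 && fit$niter < maxiter,
       theta = theta, fn = switch(loss,
                                  poisson_deviance = resid_dev,
                                  least_squares_on_log = resid_log,
                                  resid_wls),
       par_full = fit$par)
}

# finite-difference covariance proxy on the log-parameter scale
.cov_proxy <- function(fn, theta, rss, nobs) {
  p <- length(theta)
  r0 <- fn(theta)
  h <- 1e-5
  J <- matrix(0, length(r0), p)
  for (j in seq_len(p)) {
    tp <- theta
    tp[j] <- tp[j] + h
    J[, j] <- (fn(tp) - r0) / h
  }
  sigma2 <- rss / max(nobs - p, 1)
  out <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  out
}

.new_tl_fit <- function(model, coefficients, data, window, weights, fitted,
                        rss, iterations, converged, message, cov, start,
                        thickness = NA_real_, rho = NA_real_, n = NA_real_,
                        n_ambient = NA_real_, loss = "wls", model_fun = NULL,
                        call = sys.call(-1)) {
  structure(list(model = model, coefficients = coefficients, data = data,
                 window = window, weights = weights, fitted = fitted,
                 rss = rss, iterations = iterations, converged = converged,
                 message = message, cov = cov, start = start,
                 thickness = thickness, rho = rho, n = n,
                 n_ambient = n_ambient, loss = loss, model_fun = model_fun,
                 call = call),
            class = "tl_fit")
}

#' Fit layer optical properties to diffuse-reflectance data
#'
#' The package's central model-fitting interface: Levenberg-Marquardt
#' estimation of absorption and reduced scattering coefficients from a
#' time-of-flight transient (semi-infinite or two-layer medium) or from
#' multi-distance CW intensities (two-layer medium). Positivity is enforced
#' by optimizing log-transformed parameters; the source/detection amplitude
#' is profiled out in closed form under the default weighted-least-squares
#' loss. This generic dispatches on the data: transients go to the TD
#' fitters, numeric intensity vectors to the CW fitter.
#'
#' @param data a \code{\link{transient}} (TD fits) or a numeric vector of CW
#'   intensities (CW fit, requires \code{rhos}).
#' @param top_thickness known top-layer thickness, cm. When \code{NULL}
#'   (with transient data) a homogeneous semi-infinite model is fitted; the
#'   thickness itself is never a free parameter (it is measured
#'   independently, e.g. by ultrasound).
#' @param ... passed to \code{\link{fit_homogeneous_td}},
#'   \code{\link{fit_two_layer_td}} or \code{\link{fit_two_layer_cw}}.
#' @return An object of class \code{"tl_fit"}; see
#'   \code{\link{fit_two_layer_td}} for its contents and available methods.
#' @export
tl_fit <- function(data, top_thickness = NULL, ...) {
  if (inherits(data, "transient")) {
    if (is.null(top_thickness)) fit_homogeneous_td(data, ...)
    else fit_two_layer_td(data, top_thickness = top_thickness, ...)
  } else if (is.numeric(data)) {
    if (is.null(top_thickness))
      stop("CW fitting requires 'top_thickness'", call. = FALSE)
    fit_two_layer_cw(data, top_thickness = top_thickness, ...)
  } else {
    stop("'data' must be a transient or a numeric intensity vector",
         call. = FALSE)
  }
}

#' Fit a homogeneous semi-infinite model to a transient
#'
#' Estimates (\eqn{\mu_a}, \eqn{\mu_s'}, amplitude) of a semi-infinite
#' medium from a single-distance time-of-flight transient. Mostly used to
#' initialize the two-layer fit.
#'
#' @param x a \code{\link{transient}} with \code{rho} set.
#' @param n,n_ambient refractive indices of the medium and the ambient.
#' @param start named start values \code{c(mua = , musp = )}.
#' @param window integer bin indices to fit, or \code{NULL} for the default
#'   \code{\link{fit_window}} rule.
#' @param rise_frac,tail_frac window rule thresholds.
#' @param loss \code{"wls"} (weighted least squares with Poisson-variance
#'   weights; default), \code{"poisson_deviance"} or
#'   \code{"least_squares_on_log"}.
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @return A \code{"tl_fit"} object.
#' @export
fit_homogeneous_td <- function(x, n = 1.4, n_ambient = 1,
                               start = c(mua = 0.1, musp = 10),
                               window = NULL, rise_frac = 0.5,
                               tail_frac = 0.01, loss = "wls",
                               maxiter = 100) {
  stopifnot(inherits(x, "transient"), !is.na(x$rho))
  if (is.null(window)) window <- fit_window(x$values, rise_frac, tail_frac)
  y <- x$values[window]
  w <- .poisson_weights(x)[window]
  mfun <- .si_td_model(x$rho, x$grid, n, n_ambient)
  model_of <- function(p) mfun(p[1], p[2])[window]
  p0 <- c(start[["mua"]], start[["musp"]])
  res <- .lm_profiled(y, w, model_of, p0, loss = loss, maxiter = maxiter)
  coefs <- c(mua = res$p[1], musp = res$p[2], amplitude = res$amplitude)
  cov <- .cov_proxy(res$fn, res$par_full, res$rss, length(y))
  .new_tl_fit("homogeneous_td", coefs, x, window, w,
              res$amplitude * model_of(res$p), res$rss, res$iterations,
              res$converged, res$message, cov, start, rho = x$rho, n = n,
              n_ambient = n_ambient, loss = loss,
              model_fun = function(p) mfun(p[1], p[2]))
}

#' Fit a two-layer model to a time-of-flight transient
#'
#' Levenberg-Marquardt estimation of the absorption and reduced scattering
#' coefficients of both layers of a two-layer medium from a single-distance
#' time-of-flight transient, with the top-layer thickness fixed (known from
#' ultrasound or the phantom specification). Default free set
#' \{\eqn{\mu_{a1}, \mu_{s1}', \mu_{a2}, \mu_{s2}'}\} plus a profiled
#' amplitude; positivity via log-parameters; bounds are reported as part of
#' the start specification but the log transform keeps estimates positive
#' without hard constraints. The fit is deterministic given its
#' configuration.
#'
#' When no start is supplied, a homogeneous fit initializes both layers.
#' A warning is issued when the transient carries fewer than 100 counts
#' beyond twice the peak time (little deep-layer sensitivity).
#'
#' @inheritParams fit_homogeneous_td
#' @param top_thickness top-layer thickness, cm (> 0), never fitted.
#' @param free character subset of \code{c("mua1", "musp1", "mua2",
#'   "musp2")} to optimize; the rest stay at their start values.
#' @param start named start values for all four layer parameters; \code{NULL}
#'   for homogeneous initialization.
#' @param multistart number of deterministic starts (1 to 5): the supplied
#'   start plus fixed multiplicative jitters, keeping the lowest-residual
#'   solution. Useful for poorly informed starts; the weighted-least-squares
#'   surface has a shallow secondary valley in the deep-layer scattering
#'   coefficient.
#' @param nquad,smax,dt_max,T_min forward-model numerics (see
#'   \code{\link{td_two_layer}}).
#' @return Object of class \code{"tl_fit"} with elements
#'   \code{coefficients} (the four layer coefficients and the amplitude),
#'   \code{converged}, \code{iterations}, \code{rss}, \code{window},
#'   \code{cov} (finite-difference covariance proxy of the free
#'   log-parameters), and the data. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{vcov}, \code{fitted}, \code{residuals},
#'   \code{predict}, \code{simulate}, \code{plot}.
#' @examples
#' \donttest{
#' med <- two_layer_medium(optical_layer(0.11, 11.19, thickness = 0.96),
#'                         optical_layer(0.09333, 9.551))
#' g <- time_grid(5, 200)
#' tr <- sample_counts(td_two_layer(med, 2, g), 1e6, seed = 1)
#' fit <- fit_two_layer_td(tr, top_thickness = 0.96)
#' coef(fit)
#' }
#' @export
fit_two_layer_td <- function(x, top_thickness, n = 1.4, n_ambient = 1,
                             free = c("mua1", "musp1", "mua2", "musp2"),
                             start = NULL, window = NULL, rise_frac = 0.5,
                             tail_frac = 0.01, loss = "wls", maxiter = 100,
                             multistart = 1L, nquad = 256, smax = 300,
                             dt_max = 0.0125, T_min = 10) {
  stopifnot(inherits(x, "transient"), !is.na(x$rho), top_thickness > 0)
  free <- match.arg(free, c("mua1", "musp1", "mua2", "musp2"),
                    several.ok = TRUE)
  if (is.null(window)) window <- fit_window(x$values, rise_frac, tail_frac)
  y <- x$values[window]
  w <- .poisson_weights(x)[window]

  # deep-layer sensitivity diagnostic on the counts scale
  counts <- if (x$kind == "counts") x$values
            else if (!is.na(x$scale)) x$values * x$scale else NULL
  if (!is.null(counts)) {
    tp <- x$grid$centers[which.max(x$values)]
    late <- sum(counts[x$grid$centers > 2 * tp])
    if (late <= 100)
      warning(sprintf(paste0("only %.0f counts beyond twice the peak time; ",
                             "deep-layer sensitivity is low"), late),
              call. = FALSE)
  }

  if (is.null(start)) {
    hom <- fit_homogeneous_td(x, n = n, n_ambient = n_ambient,
                              window = window, loss = loss)
    start <- c(mua1 = unname(coef(hom)["mua"]),
               musp1 = unname(coef(hom)["musp"]),
               mua2 = unname(coef(hom)["mua"]),
               musp2 = unname(coef(hom)["musp"]))
  }
  pars <- c("mua1", "musp1", "mua2", "musp2")
  stopifnot(all(pars %in% names(start)))
  fixed <- start[setdiff(pars, free)]

  mfun <- .tl_td_model(x$rho, x$grid, n, n_ambient, top_thickness,
                       nquad = nquad, smax = smax, dt_max = dt_max,
                       T_min = T_min)
  model_of <- function(p) {
    full <- start
    full[free] <- p
    mfun(full[["mua1"]], full[["musp1"]], full[["mua2"]],
         full[["musp2"]])[window]
  }
  # deterministic multi-start: the supplied start plus fixed multiplicative
  # jitters, keeping the lowest-residual solution (the least-squares surface
  # has a shallow secondary valley in the deep-layer scattering)
  jitter <- rbind(1, 0.5, 2, c(0.5, 2, 0.5, 2), c(2, 0.5, 2, 0.5))
  colnames(jitter) <- pars
  res <- NULL
  for (k in seq_len(max(1L, min(multistart, nrow(jitter))))) {
    cand <- .lm_profiled(y, w, model_of,
                         unname(start[free] * jitter[k, free]),
                         loss = loss, maxiter = maxiter)
    if (is.null(res) || cand$rss < res$rss) res <- cand
  }
  est <- start
  est[free] <- res$p
  coefs <- c(est, amplitude = res$amplitude)
  cov <- .cov_proxy(res$fn, res$par_full, res$rss, length(y))
  if (!is.null(cov)) {
    nm <- free
    if (loss == "poisson_deviance") nm <- c(nm, "amplitude")
    dimnames(cov) <- list(nm, nm)
  }
  .new_tl_fit("two_layer_td", coefs, x, window, w,
              res$amplitude * model_of(res$p), res$rss, res$iterations,
              res$converged, res$message, cov, start,
              thickness = top_thickness, rho = x$rho, n = n,
              n_ambient = n_ambient, loss = loss,
              model_fun = function(p) mfun(p[["mua1"]], p[["musp1"]],
                                           p[["mua2"]], p[["musp2"]]))
}

#' Fit a two-layer model to multi-distance CW intensities
#'
#' Least squares on log-intensities against the steady-state two-layer
#' reflectance \code{\link{cw_two_layer}}, with the same layer parameter set
#' as the TD fit. The amplitude (source strength times detection efficiency)
#' is free by default (profiled in closed form on the log scale); it can be
#' fixed to a known calibration with \code{amplitude = "fixed"}.
#'
#' @param intensities nonnegative CW intensities (e.g. photon counts), one
#'   per distance.
#' @param rhos source-detector separations, cm.
#' @param top_thickness top-layer thickness, cm (fixed).
#' @param weights per-distance weights for the log-intensity residuals;
#'   default \code{intensities} (Poisson counts give
#'   \eqn{var(\log y) \approx 1/y}).
#' @param amplitude \code{"free"} or \code{"fixed"}.
#' @param amplitude_value known amplitude when \code{amplitude = "fixed"}:
#'   expected counts = amplitude_value x model intensity.
#' @inheritParams fit_two_layer_td
#' @return A \code{"tl_fit"} object.
#' @export
fit_two_layer_cw <- function(intensities, rhos, top_thickness, n = 1.4,
                             n_ambient = 1,
                             free = c("mua1", "musp1", "mua2", "musp2"),
                             start = NULL, weights = NULL,
                             amplitude = c("free", "fixed"),
                             amplitude_value = 1, maxiter = 100,
                             nquad = 512, smax = 300) {
  amplitude <- match.arg(amplitude)
  stopifnot(is.numeric(intensities), is.numeric(rhos),
            length(intensities) == length(rhos), all(rhos > 0),
            top_thickness > 0)
  free <- match.arg(free, c("mua1", "musp1", "mua2", "musp2"),
                    several.ok = TRUE)
  if (length(rhos) < 4L)
    stop("CW fitting needs at least 4 distances", call. = FALSE)
  if (length(rhos) < length(free))
    stop(sprintf("%d distances cannot constrain %d free parameters",
                 length(rhos), length(free)), call. = FALSE)
  if (any(intensities <= 0))
    stop("CW intensities must be positive for log-domain fitting",
         call. = FALSE)
  if (is.null(weights)) weights <- intensities
  if (is.null(start))
    start <- c(mua1 = 0.1, musp1 = 10, mua2 = 0.1, musp2 = 10)
  pars <- c("mua1", "musp1", "mua2", "musp2")
  stopifnot(all(pars %in% names(start)))

  # per-distance quadrature coefficients, precomputed once
  gl <- pracma::gaussLegendre(nquad, 0, smax)
  coefs_rho <- lapply(rhos, function(r) gl$w * gl$x * besselJ(gl$x * r, 0) / (2 * pi))
  A <- boundary_A(n / n_ambient)
  v <- .c0 / n
  cw_model <- function(mua1, musp1, mua2, musp2) {
    D1 <- 1 / (3 * musp1); D2 <- 1 / (3 * musp2)
    z0 <- min(1 / musp1, 0.9 * top_thickness)
    zb <- 2 * A * D1
    vapply(coefs_rho, function(cf)
      Re(.tl_kernel_cpp(gl$x, cf, 0, mua1, D1, v, mua2, D2, v,
                        top_thickness, z0, zb)) / (2 * A), numeric(1))
  }
  ly <- log(intensities)
  w <- weights
  amp_env <- new.env(parent = emptyenv())
  resid_fn <- function(theta) {
    p <- exp(theta)
    full <- start
    full[free] <- p
    m <- cw_model(full[["mua1"]], full[["musp1"]], full[["mua2"]],
                  full[["musp2"]])
    m <- pmax(m, .Machine$double.xmin)
    la <- if (amplitude == "free") sum(w * (ly - log(m))) / sum(w)
          else log(amplitude_value)
    amp_env$a <- exp(la)
    sqrt(w) * (ly - log(m) - la)
  }
  fit <- minpack.lm::nls.lm(par = log(unname(start[free])), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, ftol = 1e-12, ptol = 1e-12))
  est <- start
  est[free] <- exp(fit$par)
  coefs <- c(est, amplitude = amp_env$a)
  cov <- .cov_proxy(resid_fn, fit$par, fit$deviance, length(rhos))
  if (!is.null(cov)) dimnames(cov) <- list(free, free)
  obj <- .new_tl_fit("two_layer_cw", coefs, intensities, seq_along(rhos),
                     w, NULL, fit$deviance, fit$niter,
                     fit$info %in% 1:4 && fit$niter < maxiter, fit$message,
                     cov, start, thickness = top_thickness, n = n,
                     n_ambient = n_ambient, loss = "least_squares_on_log",
                     model_fun = function(p) cw_model(p[["mua1"]], p[["musp1"]],
                                                     p[["mua2"]], p[["musp2"]]))
  obj$rhos <- rhos
  obj$fitted <- amp_env$a * cw_model(est[["mua1"]], est[["musp1"]],
                                     est[["mua2"]], est[["musp2"]])
  obj
}

#' @export
print.tl_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<tl_fit: %s>%s\n", x$model,
              if (x$converged) "" else "  ** not converged **"))
  print(round(x$coefficients, digits = 6))
  cat(sprintf("  weighted RSS %.4g after %d iterations\n", x$rss,
              x$iterations))
  invisible(x)
}

#' @export
summary.tl_fit <- function(object, ...) {
  se <- if (!is.null(object$cov)) sqrt(pmax(diag(object$cov), 0)) else NULL
  out <- list(model = object$model, coefficients = object$coefficients,
              log_se = se, converged = object$converged,
              iterations = object$iterations, rss = object$rss,
              n = length(object$window), message = object$message,
              thickness = object$thickness)
  class(out) <- "summary.tl_fit"
  out
}

#' @export
print.summary.tl_fit <- function(x, ...) {
  cat(sprintf("Two-layer diffuse optics fit (%s)\n", x$model))
  cat(sprintf("  %d data points, weighted RSS %.4g, %d iterations, %s\n",
              x$n, x$rss, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat("  estimates:\n")
  print(x$coefficients)
  if (!is.null(x$log_se)) {
    cat("  approximate relative standard errors (from the log-scale\n")
    cat("  covariance proxy of the free parameters):\n")
    print(round(x$log_se, 5))
  }
  invisible(x)
}

#' @export
coef.tl_fit <- function(object, ...) object$coefficients

#' @export
vcov.tl_fit <- function(object, ...) object$cov

#' @export
fitted.tl_fit <- function(object, ...) object$fitted

#' @export
residuals.tl_fit <- function(object, type = c("response", "weighted"), ...) {
  type <- match.arg(type)
  y <- if (inherits(object$data, "transient")) object$data$values[object$window]
       else log(object$data)
  r <- y - if (object$model == "two_layer_cw") log(object$fitted) else object$fitted
  if (type == "weighted") r * sqrt(object$weights) else r
}

#' Predict the fitted forward model
#'
#' Evaluates the model at the fitted coefficients (including the amplitude),
#' on the original or a new grid.
#'
#' @param object a \code{"tl_fit"}.
#' @param grid optional \code{\link{time_grid}} (TD fits).
#' @param rhos optional distances (CW fits).
#' @param ... unused.
#' @return A \code{\link{transient}} (TD models) or numeric vector (CW).
#' @export
predict.tl_fit <- function(object, grid = NULL, rhos = NULL, ...) {
  cf <- object$coefficients
  if (object$model == "two_layer_cw") {
    if (is.null(rhos)) return(object$fitted)
    med <- two_layer_medium(
      optical_layer(cf[["mua1"]], cf[["musp1"]], n = object$n,
                    thickness = object$thickness),
      optical_layer(cf[["mua2"]], cf[["musp2"]], n = object$n))
    return(cf[["amplitude"]] * cw_two_layer(med, rhos))
  }
  if (object$model == "homogeneous_td") {
    g <- grid %||% object$data$grid
    tr <- td_semi_infinite(optical_layer(cf[["mua"]], cf[["musp"]],
                                         n = object$n),
                           rho = object$rho, grid = g,
                           n_ambient = object$n_ambient)
  } else {
    g <- grid %||% object$data$grid
    med <- two_layer_medium(
      optical_layer(cf[["mua1"]], cf[["musp1"]], n = object$n,
                    thickness = object$thickness),
      optical_layer(cf[["mua2"]], cf[["musp2"]], n = object$n),
      n_ambient = object$n_ambient)
    tr <- td_two_layer(med, rho = object$rho, grid = g)
  }
  transient(tr$grid, cf[["amplitude"]] * tr$values, kind = "model_density",
            rho = object$rho, wavelength = if (inherits(object$data, "transient"))
              object$data$wavelength else NA_real_)
}

#' Simulate Poisson count transients from a fitted model
#'
#' @param object a TD \code{"tl_fit"}.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param total_counts expected total counts per replicate; defaults to the
#'   observed total when the data are counts.
#' @param ... unused.
#' @return List of counts-kind \code{\link{transient}}s.
#' @export
simulate.tl_fit <- function(object, nsim = 1, seed = NULL,
                            total_counts = NULL, ...) {
  if (object$model == "two_layer_cw")
    stop("simulate() supports the time-domain models", call. = FALSE)
  if (is.null(total_counts)) {
    if (inherits(object$data, "transient") && object$data$kind == "counts")
      total_counts <- sum(object$data$values)
    else stop("'total_counts' is required for non-count data", call. = FALSE)
  }
  mu <- predict(object)
  with_seed(seed, lapply(seq_len(nsim), function(i)
    sample_counts(mu, total_counts)))
}

#' @export
plot.tl_fit <- function(x, ...) {
  if (x$model == "two_layer_cw") {
    plot(x$rhos, x$data, log = "y", xlab = "rho [cm]", ylab = "intensity",
         main = "CW two-layer fit", ...)
    lines(x$rhos, x$fitted, col = 2)
    legend("topright", c("data", "fit"), pch = c(1, NA), lty = c(NA, 1),
           col = c(1, 2), bty = "n")
    return(invisible(x))
  }
  tr <- x$data
  tc <- tr$grid$centers
  v <- tr$values
  v[v <= 0] <- NA
  plot(tc, v, log = "y", type = "l", xlab = "time [ns]", ylab = "value",
       main = sprintf("%s fit", x$model), ...)
  lines(tc[x$window], x$fitted, col = 2, lwd = 2)
  abline(v = range(tc[x$window]), lty = 3, col = "grey50")
  legend("topright", c("data", "fit", "window"), col = c(1, 2, "grey50"),
         lty = c(1, 1, 3), bty = "n")
  invisible(x)
}
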