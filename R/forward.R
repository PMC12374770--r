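#' Time-resolved reflectance of a semi-infinite homogeneous medium
#'
#' Closed-form time-domain diffuse reflectance at distance \code{rho} from a
#' pencil beam normally incident on a semi-infinite turbid medium, using the
#' extrapolated-boundary condition with an isotropic point source at depth
#' \eqn{z_0 = 1/\mu_s'} and a negative image source at
#' \eqn{-(z_0 + 2 z_b)}, \eqn{z_b = 2 A D}:
#' \deqn{\Phi(\rho, 0, t) = v (4 \pi D v t)^{-3/2}
#'   e^{-\mu_a v t} \left[ e^{-(\rho^2 + z_0^2)/(4 D v t)}
#'   - e^{-(\rho^2 + (z_0 + 2 z_b)^2)/(4 D v t)} \right],}
#' with \eqn{D = 1/(3 \mu_s')} (absorption-independent by default) and
#' \eqn{v = c / n}. Reflectance is taken as the surface fluence divided by
#' \eqn{2A}. Values are evaluated at bin centers; \eqn{R(0) = 0}.
#'
#' @param layer an \code{\link{optical_layer}}.
#' @param rho source-detector separation, cm (> 0).
#' @param grid a \code{\link{time_grid}}.
#' @param n_ambient ambient refractive index (default 1).
#' @param wavelength optional wavelength tag, nm.
#' @param D_absorption if \code{TRUE}, use \eqn{D = 1/(3(\mu_a + \mu_s'))}
#'   instead of the default absorption-independent diffusion coefficient.
#' @return A model-density \code{\link{transient}}.
#' @examples
#' g <- time_grid(t_end = 5, n_bins = 200)
#' tr <- td_semi_infinite(optical_layer(0.1, 10), rho = 2, grid = g)
#' @export
td_semi_infinite <- function(layer, rho, grid, n_ambient = 1,
                             wavelength = NA_real_, D_absorption = FALSE) {
  stopifnot(inherits(layer, "optical_layer"), inherits(grid, "time_grid"),
            is.numeric(rho), length(rho) == 1L, rho > 0)
  D <- if (D_absorption) 1 / (3 * (layer$mua + layer$musp)) else 1 / (3 * layer$musp)
  v <- .c0 / layer$n
  z0 <- 1 / layer$musp
  A <- boundary_A(layer$n / n_ambient)
  zb <- 2 * A * D
  t <- grid$centers
  vals <- .semi_infinite_phi(t, layer$mua, D, v, z0, zb, rho) / (2 * A)
  transient(grid, vals, kind = "model_density", rho = rho,
            wavelength = wavelength)
}

# surface fluence of the image-source pair; vectorized over t, 0 at t <= 0
.semi_infinite_phi <- function(t, mua, D, v, z0, zb, rho) {
  out <- numeric(length(t))
  ok <- t > 0
  tt <- t[ok]
  q <- 4 * D * v * tt
  out[ok] <- v * (pi * q)^(-1.5) *
    exp(-mua * v * tt) *
    (exp(-(rho^2 + z0^2) / q) - exp(-(rho^2 + (z0 + 2 * zb)^2) / q))
  pmax(out, 0)
}

# Shared setup for the layered kernel: diffusion constants, source depth,
# extrapolated boundary, and Gauss-Legendre quadrature in Hankel space.
.tl_setup <- function(medium, rho, nquad, smax, D_absorption) {
  top <- medium$top; bottom <- medium$bottom
  if (abs(top$n - bottom$n) > 1e-12)
    warning("layers have different refractive indices; the layered kernel ",
            "assumes index-matched internal interfaces", call. = FALSE)
  D1 <- if (D_absorption) 1 / (3 * (top$mua + top$musp)) else 1 / (3 * top$musp)
  D2 <- if (D_absorption) 1 / (3 * (bottom$mua + bottom$musp)) else 1 / (3 * bottom$musp)
  z0 <- 1 / top$musp
  l <- top$thickness
  if (z0 >= l) {
    # very thin or weakly scattering top layer: keep the source inside it
    z0 <- 0.9 * l
  }
  A <- boundary_A(top$n / medium$n_ambient)
  zb <- 2 * A * D1
  gl <- pracma::gaussLegendre(nquad, 0, smax)
  coef <- gl$w * gl$x * besselJ(gl$x * rho, 0) / (2 * pi)
  list(D1 = D1, D2 = D2, v1 = .c0 / top$n, v2 = .c0 / bottom$n,
       z0 = z0, l = l, A = A, zb = zb, s = gl$x, coef = coef)
}

#' Time-resolved reflectance of a two-layer medium
#'
#' Time-domain diffuse reflectance at the top surface of a two-layer medium
#' (finite top layer over a semi-infinite bottom layer) at distance
#' \code{rho}. The layered diffusion Green's function is evaluated in Hankel
#' (spatial frequency) and temporal-frequency space, inverse-Hankel
#' transformed by fixed-order Gauss-Legendre quadrature, and synthesized to
#' the time domain by inverse FFT on a padded frequency grid. Small negative
#' excursions from transform ringing are clipped to zero (with a warning when
#' the clipped mass exceeds \code{1e-3} of the total). Values are evaluated
#' at bin centers.
#'
#' @param medium a \code{\link{two_layer_medium}}.
#' @param rho source-detector separation, cm.
#' @param grid a \code{\link{time_grid}}; bin widths of at most 25 ps are
#'   recommended for fitting.
#' @param nquad Gauss-Legendre order of the inverse Hankel quadrature.
#' @param smax upper limit of the Hankel integral, 1/cm.
#' @param dt_max upper bound on the internal FFT time step, ns; the actual
#'   step is the largest power-of-two fraction of the bin width not above
#'   this (internal samples then coincide with bin centers).
#' @param T_min minimum span of the internal FFT window, ns (padding against
#'   aliasing of the decaying tail).
#' @param check if \code{TRUE}, verify quadrature convergence by order
#'   doubling (relative tolerance \code{tol}) and raise an error with
#'   diagnostics on failure.
#' @param tol relative tolerance of the convergence check.
#' @inheritParams td_semi_infinite
#' @return A model-density \code{\link{transient}}.
#' @examples
#' med <- two_layer_medium(optical_layer(0.11, 11.19, thickness = 0.96),
#'                         optical_layer(0.09333, 9.551))
#' tr <- td_two_layer(med, rho = 2, grid = time_grid(5, 200))
#' @export
td_two_layer <- function(medium, rho, grid, wavelength = NA_real_,
                         nquad = 256, smax = 300, dt_max = 0.0125,
                         T_min = 10, check = FALSE, tol = 1e-6,
                         D_absorption = FALSE) {
  stopifnot(inherits(medium, "two_layer_medium"), inherits(grid, "time_grid"),
            is.numeric(rho), length(rho) == 1L, rho > 0)
  su <- .tl_setup(medium, rho, nquad, smax, D_absorption)

  # internal FFT grid: a power-of-two fraction of the bin width not above
  # dt_max, so that bin centers coincide with internal samples (spline
  # evaluation at the sharp rising edge is exact there);
  # span >= max(2 t_end, T_min)
  dt <- grid$dt / 2^max(1, ceiling(log2(grid$dt / dt_max)))
  span <- max(2 * grid$t_end, T_min)
  nfft <- 2^ceiling(log2(span / dt))
  Tspan <- nfft * dt
  omega <- 2 * pi * (0:(nfft / 2)) / Tspan

  phi_w <- .tl_kernel_cpp(su$s, su$coef, omega,
                          medium$top$mua, su$D1, su$v1,
                          medium$bottom$mua, su$D2, su$v2,
                          su$l, su$z0, su$zb)
  if (check) {
    gl2 <- pracma::gaussLegendre(2 * nquad, 0, smax)
    coef2 <- gl2$w * gl2$x * besselJ(gl2$x * rho, 0) / (2 * pi)
    probe <- c(1L, length(omega) %/% 8L + 1L)
    phi2 <- .tl_kernel_cpp(gl2$x, coef2, omega[probe],
                           medium$top$mua, su$D1, su$v1,
                           medium$bottom$mua, su$D2, su$v2,
                           su$l, su$z0, su$zb)
    rel <- abs(phi_w[probe] - phi2) / pmax(abs(phi2), .Machine$double.xmin)
    if (any(rel > tol))
      stop(sprintf(paste0("Hankel quadrature did not converge: relative ",
                          "change %.3g at order doubling (nquad = %d, ",
                          "smax = %g, tol = %g)"),
                   max(rel), nquad, smax, tol), call. = FALSE)
  }

  spec <- complex(length.out = nfft)
  spec[seq_len(nfft / 2 + 1)] <- phi_w
  spec[nfft:(nfft / 2 + 2)] <- Conj(phi_w[2:(nfft / 2)])
  phi_t <- Re(fft(spec, inverse = TRUE)) / Tspan

  tt <- (0:(nfft - 1)) * dt
  vals <- spline(tt, phi_t, xout = grid$centers, method = "natural")$y
  vals[grid$centers <= 0] <- 0
  neg <- vals < 0
  if (any(neg)) {
    clipped <- -sum(vals[neg])
    total <- sum(pmax(vals, 0))
    if (total > 0 && clipped > 1e-3 * total)
      warning(sprintf("clipped negative transform ringing of %.3g of total mass",
                      clipped / total), call. = FALSE)
    vals[neg] <- 0
  }
  transient(grid, vals / (2 * su$A), kind = "model_density", rho = rho,
            wavelength = wavelength)
}

#' Steady-state (CW) reflectance of a two-layer medium
#'
#' Zero-frequency limit of the layered kernel: the time-integrated diffuse
#' reflectance per unit area at each source-detector separation. Intensities
#' are strictly decreasing in \code{rho}.
#'
#' @inheritParams td_two_layer
#' @param rhos vector of source-detector separations, cm (> 0).
#' @return Numeric vector of intensities (photons per cm^2 per launched
#'   photon), one per distance.
#' @examples
#' med <- two_layer_medium(optical_layer(0.11, 11.19, thickness = 0.96),
#'                         optical_layer(0.09333, 9.551))
#' cw_two_layer(med, rhos = 1:4)
#' @export
cw_two_layer <- function(medium, rhos, nquad = 512, smax = 300,
                         check = FALSE, tol = 1e-6, D_absorption = FALSE) {
  stopifnot(inherits(medium, "two_layer_medium"), is.numeric(rhos),
            all(rhos > 0))
  vapply(rhos, function(rho) {
    su <- .tl_setup(medium, rho, nquad, smax, D_absorption)
    val <- Re(.tl_kernel_cpp(su$s, su$coef, 0,
                             medium$top$mua, su$D1, su$v1,
                             medium$bottom$mua, su$D2, su$v2,
                             su$l, su$z0, su$zb))
    if (check) {
      gl2 <- pracma::gaussLegendre(2 * nquad, 0, smax)
      coef2 <- gl2$w * gl2$x * besselJ(gl2$x * rho, 0) / (2 * pi)
      val2 <- Re(.tl_kernel_cpp(gl2$x, coef2, 0,
                                medium$top$mua, su$D1, su$v1,
                                medium$bottom$mua, su$D2, su$v2,
                                su$l, su$z0, su$zb))
      if (abs(val - val2) > tol * abs(val2))
        stop(sprintf("Hankel quadrature did not converge at rho = %g (rel %.3g)",
                     rho, abs(val - val2) / abs(val2)), call. = FALSE)
    }
    val / (2 * su$A)
  }, numeric(1))
}
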