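#' Optical properties of a single tissue layer
#'
#' Bundles the diffuse optical properties of one homogeneous layer. The
#' diffusion approximation underlying the analytical forward models requires
#' scattering to dominate absorption; a warning is emitted when
#' \code{mua > musp}.
#'
#' @param mua absorption coefficient, 1/cm (>= 0).
#' @param musp reduced scattering coefficient \eqn{\mu_s' = \mu_s (1-g)},
#'   1/cm (> 0).
#' @param n refractive index (>= 1). Tissue is close to 1.4 in the NIR.
#' @param thickness layer thickness, cm (> 0; \code{Inf} for a semi-infinite
#'   layer).
#' @return An object of class \code{"optical_layer"}.
#' @examples
#' maternal <- optical_layer(mua = 0.11, musp = 11.19, thickness = 0.96)
#' fetal <- optical_layer(mua = 0.09333, musp = 9.551)
#' @export
optical_layer <- function(mua, musp, n = 1.4, thickness = Inf) {
  stopifnot(is.numeric(mua), length(mua) == 1L, is.finite(mua),
            is.numeric(musp), length(musp) == 1L, is.finite(musp),
            is.numeric(n), length(n) == 1L, is.finite(n),
            is.numeric(thickness), length(thickness) == 1L)
  if (mua < 0) stop("'mua' must be >= 0", call. = FALSE)
  if (musp <= 0) stop("'musp' must be > 0", call. = FALSE)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (thickness <= 0) stop("'thickness' must be > 0", call. = FALSE)
  if (mua > musp)
    warning("mua > musp: the diffusion approximation is not valid for this layer",
            call. = FALSE)
  structure(list(mua = mua, musp = musp, n = n, thickness = thickness),
            class = "optical_layer")
}

#' @export
print.optical_layer <- function(x, ...) {
  cat(sprintf("<optical_layer> mua = %g /cm, musp = %g /cm, n = %g, thickness = %s cm\n",
              x$mua, x$musp, x$n,
              if (is.finite(x$thickness)) format(x$thickness) else "Inf"))
  invisible(x)
}

#' Two-layer turbid medium
#'
#' A finite superficial layer (e.g. the maternal abdominal wall) on top of a
#' semi-infinite deep layer (e.g. fetal tissue). This is the fixed N = 2
#' geometry used by all layered forward models and fits in the package.
#'
#' @param top \code{\link{optical_layer}} with finite thickness.
#' @param bottom \code{\link{optical_layer}}; its thickness must be
#'   \code{Inf}.
#' @param n_ambient refractive index of the external medium (default 1, air).
#' @return An object of class \code{"two_layer_medium"}.
#' @examples
#' med <- two_layer_medium(
#'   top = optical_layer(0.11, 11.19, thickness = 0.96),
#'   bottom = optical_layer(0.09333, 9.551))
#' @export
two_layer_medium <- function(top, bottom, n_ambient = 1) {
  stopifnot(inherits(top, "optical_layer"), inherits(bottom, "optical_layer"),
            is.numeric(n_ambient), length(n_ambient) == 1L, n_ambient >= 1)
  if (!is.finite(top$thickness))
    stop("the top layer must have finite thickness", call. = FALSE)
  if (is.finite(bottom$thickness))
    stop("the bottom layer must be semi-infinite (thickness = Inf)", call. = FALSE)
  structure(list(top = top, bottom = bottom, n_ambient = n_ambient),
            class = "two_layer_medium")
}

#' @export
print.two_layer_medium <- function(x, ...) {
  cat("<two_layer_medium>\n  top:    ")
  print(x$top)
  cat("  bottom: ")
  print(x$bottom)
  cat(sprintf("  n_ambient = %g\n", x$n_ambient))
  invisible(x)
}

#' Internal-reflection boundary factor A
#'
#' Mismatch factor entering the extrapolated-boundary distance
#' \eqn{z_b = 2 A D}. Computed from the effective internal reflection
#' coefficient obtained by integrating the unpolarized Fresnel reflectance
#' over the internal hemisphere (fluence- and flux-weighted moments):
#' \deqn{R_\phi = \int_0^{\pi/2} 2\sin\theta\cos\theta\, R_F(\theta)\,d\theta,
#'       \quad
#'       R_j = \int_0^{\pi/2} 3\sin\theta\cos^2\theta\, R_F(\theta)\,d\theta,}
#' \deqn{R_{\rm eff} = \frac{R_\phi + R_j}{2 - R_\phi + R_j}, \qquad
#'       A = \frac{1 + R_{\rm eff}}{1 - R_{\rm eff}}.}
#' For matched indices (\code{n_rel = 1}) this gives exactly A = 1; for
#' tissue against air (\code{n_rel = 1.4}) A is about 2.95.
#'
#' @param n_rel ratio of internal to ambient refractive index.
#' @return Scalar boundary factor A (>= 1).
#' @export
boundary_A <- function(n_rel) {
  stopifnot(is.numeric(n_rel), length(n_rel) == 1L, is.finite(n_rel), n_rel > 0)
  if (n_rel == 1) return(1)
  rf <- function(theta) {
    cosi <- cos(theta)
    sint2 <- n_rel^2 * sin(theta)^2 # internal incidence into ambient
    r <- numeric(length(theta))
    tir <- sint2 >= 1
    r[tir] <- 1
    ok <- !tir
    if (any(ok)) {
      cost <- sqrt(1 - sint2[ok])
      n1 <- n_rel; n2 <- 1
      rs <- (n1 * cosi[ok] - n2 * cost) / (n1 * cosi[ok] + n2 * cost)
      rp <- (n1 * cost - n2 * cosi[ok]) / (n1 * cost + n2 * cosi[ok])
      r[ok] <- 0.5 * (rs^2 + rp^2)
    }
    r
  }
  rphi <- integrate(function(th) 2 * sin(th) * cos(th) * rf(th), 0, pi / 2,
                    rel.tol = 1e-10)$value
  rj <- integrate(function(th) 3 * sin(th) * cos(th)^2 * rf(th), 0, pi / 2,
                  rel.tol = 1e-10)$value
  reff <- (rphi + rj) / (2 - rphi + rj)
  (1 + reff) / (1 - reff)
}

#' Read / write a medium configuration file
#'
#' Structured-text (YAML) description of a layered medium and measurement
#' geometry with keys \code{layers[].{mua, musp, n, thickness_cm}},
#' \code{ambient_n} and optional \code{rho_cm}, \code{wavelength_nm}.
#'
#' @param file path to a YAML file.
#' @return \code{read_medium_config}: a list with elements \code{medium}
#'   (\code{\link{two_layer_medium}}), \code{rho} and \code{wavelength}
#'   (possibly \code{NULL}).
#' @export
read_medium_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$layers) || length(cfg$layers) != 2L)
    stop("config must define exactly two layers", call. = FALSE)
  lay <- lapply(cfg$layers, function(l) {
    optical_layer(mua = l$mua, musp = l$musp,
                  n = if (is.null(l$n)) 1.4 else l$n,
                  thickness = if (is.null(l$thickness_cm)) Inf else l$thickness_cm)
  })
  medium <- two_layer_medium(lay[[1]], lay[[2]],
                             n_ambient = if (is.null(cfg$ambient_n)) 1 else cfg$ambient_n)
  list(medium = medium, rho = cfg$rho_cm, wavelength = cfg$wavelength_nm)
}

#' @rdname read_medium_config
#' @param medium a \code{\link{two_layer_medium}}.
#' @param rho,wavelength optional source-detector separation (cm) and
#'   wavelength (nm) stored alongside the medium.
#' @export
write_medium_config <- function(medium, file, rho = NULL, wavelength = NULL) {
  stopifnot(inherits(medium, "two_layer_medium"))
  as_list <- function(l) {
    out <- list(mua = l$mua, musp = l$musp, n = l$n)
    if (is.finite(l$thickness)) out$thickness_cm <- l$thickness
    out
  }
  cfg <- list(layers = list(as_list(medium$top), as_list(medium$bottom)),
              ambient_n = medium$n_ambient)
  if (!is.null(rho)) cfg$rho_cm <- rho
  if (!is.null(wavelength)) cfg$wavelength_nm <- wavelength
  yaml::write_yaml(cfg, file)
  invisible(file)
}
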