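#' Monte Carlo layer description
#'
#' Full transport properties of one layer for the Monte Carlo engine. The
#' forward diffusion models use the reduced scattering coefficient
#' \eqn{\mu_s' = \mu_s (1 - g)}; \code{mc_layer} takes the scattering
#' coefficient \code{mus} and anisotropy \code{g} explicitly.
#'
#' @param mua absorption coefficient, 1/cm.
#' @param mus scattering coefficient, 1/cm (> 0).
#' @param g Henyey-Greenstein anisotropy factor, in (-1, 1). Default 0.9
#'   (typical soft tissue).
#' @param n refractive index.
#' @param thickness layer thickness, cm (\code{Inf} for semi-infinite).
#' @return Object of class \code{"mc_layer"}.
#' @seealso \code{\link{as_mc_layer}} to convert an
#'   \code{\link{optical_layer}} preserving \eqn{\mu_s'}.
#' @export
mc_layer <- function(mua, mus, g = 0.9, n = 1.4, thickness = Inf) {
  stopifnot(is.numeric(mua), mua >= 0, is.numeric(mus), mus > 0,
            is.numeric(g), g > -1, g < 1, is.numeric(n), n >= 1,
            is.numeric(thickness), thickness > 0)
  structure(list(mua = mua, mus = mus, g = g, n = n, thickness = thickness),
            class = "mc_layer")
}

#' Convert a diffusion-model layer to a Monte Carlo layer
#'
#' Chooses \eqn{\mu_s = \mu_s' / (1 - g)} so that the reduced scattering
#' coefficient matches the diffusion description.
#'
#' @param layer an \code{\link{optical_layer}}.
#' @param g anisotropy factor.
#' @return An \code{\link{mc_layer}}.
#' @export
as_mc_layer <- function(layer, g = 0.9) {
  stopifnot(inherits(layer, "optical_layer"))
  mc_layer(mua = layer$mua, mus = layer$musp / (1 - g), g = g, n = layer$n,
           thickness = layer$thickness)
}

#' Monte Carlo run configuration
#'
#' @param n_photons number of photons to launch (>= 1).
#' @param seed integer seed; identical seeds give bit-identical results
#'   (per-photon counter-based substreams).
#' @param rho detector annulus center, cm.
#' @param half_width annulus half width, cm: photons exiting the top surface
#'   with radius in \code{[rho - half_width, rho + half_width]} are detected.
#' @param max_time latest recorded arrival time, ns; photons exceeding it are
#'   terminated.
#' @param n_bins number of uniform arrival-time bins on \code{[0, max_time]}.
#' @param weight_threshold roulette trigger weight.
#' @param roulette_survival roulette survival probability, in (0, 1).
#' @param cos_accept_min minimum exit-direction cosine (in the ambient
#'   medium) for detection; 0 accepts all exit angles (default), larger
#'   values emulate a finite numerical aperture.
#' @return Object of class \code{"mc_config"}.
#' @export
mc_config <- function(n_photons, seed = 1L, rho = 2, half_width = 0.05,
                      max_time = 5, n_bins = 50, weight_threshold = 1e-4,
                      roulette_survival = 0.1, cos_accept_min = 0) {
  stopifnot(n_photons >= 1, half_width > 0, rho - half_width >= 0,
            max_time > 0, n_bins >= 2,
            roulette_survival > 0, roulette_survival < 1,
            cos_accept_min >= 0, cos_accept_min <= 1)
  structure(list(n_photons = n_photons, seed = as.integer(seed), rho = rho,
                 half_width = half_width, max_time = max_time,
                 n_bins = as.integer(n_bins),
                 weight_threshold = weight_threshold,
                 roulette_survival = roulette_survival,
                 cos_accept_min = cos_accept_min),
            class = "mc_config")
}

#' Run the layered time-resolved Monte Carlo simulation
#'
#' MCML-style photon transport through a stack of plane-parallel layers
#' (pencil beam, normal incidence at the origin): implicit-capture
#' absorption, Henyey-Greenstein scattering, Fresnel reflection/refraction at
#' the surface and internal index mismatches, Russian roulette termination.
#' Photons exiting the top surface inside the detector annulus are binned by
#' optical arrival time \eqn{t = \sum_i n_i L_i / c} and their per-layer
#' geometric pathlengths \eqn{L_i} accumulated per bin.
#'
#' @param layers list of \code{\link{mc_layer}}s, top first; the last layer
#'   may be semi-infinite.
#' @param config an \code{\link{mc_config}}.
#' @param n_ambient ambient refractive index.
#' @return Object of class \code{"mc_result"}: \code{grid}
#'   (\code{\link{time_grid}}), \code{dtof} (detected weight per bin),
#'   \code{dtof_se} (per-bin Monte Carlo standard error of the weight sum),
#'   \code{n_detected_bin}, \code{pathlen_sums} (layers x bins matrix of
#'   weight-multiplied pathlengths, cm), \code{totals} (weight budget),
#'   \code{n_launched}, \code{seed}, \code{config}, \code{empty} flag.
#' @examples
#' lay <- list(mc_layer(0.1, 100, g = 0.9, thickness = Inf))
#' res <- run_layered_mc(lay, mc_config(n_photons = 1e4, seed = 7))
#' @export
run_layered_mc <- function(layers, config, n_ambient = 1) {
  stopifnot(is.list(layers), length(layers) >= 1L,
            all(vapply(layers, inherits, logical(1), "mc_layer")),
            inherits(config, "mc_config"))
  nf <- vapply(layers, function(l) is.finite(l$thickness), logical(1))
  if (any(nf == FALSE & seq_along(layers) != length(layers)))
    stop("only the last layer may be semi-infinite", call. = FALSE)
  res <- .mc_run_cpp(
    mua = vapply(layers, `[[`, numeric(1), "mua"),
    mus = vapply(layers, `[[`, numeric(1), "mus"),
    g = vapply(layers, `[[`, numeric(1), "g"),
    n_layer = vapply(layers, `[[`, numeric(1), "n"),
    thickness = vapply(layers, `[[`, numeric(1), "thickness"),
    n_ambient = n_ambient, n_photons = config$n_photons,
    seed = config$seed, rmin = config$rho - config$half_width,
    rmax = config$rho + config$half_width, tmax = config$max_time,
    nbins = config$n_bins, weight_threshold = config$weight_threshold,
    roulette_survival = config$roulette_survival,
    cos_accept_min = config$cos_accept_min)
  grid <- time_grid(t_end = config$max_time, n_bins = config$n_bins)
  empty <- res$totals$n_detected == 0
  structure(list(grid = grid, dtof = res$dtof,
                 dtof_se = sqrt(pmax(res$dtof_w2, 0)),
                 n_detected_bin = res$n_detected_bin,
                 pathlen_sums = res$pathlen_sums, totals = res$totals,
                 n_launched = config$n_photons, seed = config$seed,
                 rho = config$rho, half_width = config$half_width,
                 config = config, layers = layers, empty = empty),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> %s photons launched, %s detected (weight %.4g)\n",
              format(x$n_launched, big.mark = ","),
              format(x$totals$n_detected, big.mark = ","),
              x$totals$detected))
  cat(sprintf("  annulus [%g, %g] cm, %d bins on [0, %g] ns, seed %d\n",
              x$rho - x$half_width, x$rho + x$half_width,
              x$grid$n_bins, x$grid$t_end, x$seed))
  if (x$empty) cat("  ** no photons detected **\n")
  invisible(x)
}

#' Convert a Monte Carlo result to a reflectance-density transient
#'
#' Normalizes the detected weight per bin by launched photons, annulus area
#' and bin width, so the values are directly comparable with the diffusion
#' forward models (photons per cm^2 per ns per launched photon).
#'
#' @param x an \code{\link{run_layered_mc}} result.
#' @param normalize if \code{FALSE}, keep raw detected weight per bin.
#' @return A model-density \code{\link{transient}}.
#' @export
as_transient <- function(x, normalize = TRUE) {
  stopifnot(inherits(x, "mc_result"))
  area <- pi * ((x$rho + x$half_width)^2 - (x$rho - x$half_width)^2)
  fac <- if (normalize) 1 / (x$n_launched * area * x$grid$dt) else 1
  transient(x$grid, x$dtof * fac, kind = "model_density", rho = x$rho)
}

#' Beer-Lambert perturbation re-weighting of a Monte Carlo DTOF
#'
#' Predicts the DTOF of the same medium with per-layer absorption changed by
#' \code{delta_mua} without re-running the transport: each arrival bin is
#' re-weighted by \eqn{\exp(-\sum_i \Delta\mu_{a,i} \bar L_i(t))} where
#' \eqn{\bar L_i(t)} is the mean detected pathlength in layer \eqn{i} for
#' that bin. Exact in the limit of narrow bins when only absorption changes;
#' warns when \code{|delta_mua|} exceeds 20\% of the base absorption.
#'
#' @param base an \code{mc_result} with pathlength sums.
#' @param delta_mua per-layer absorption change, 1/cm (length = number of
#'   layers).
#' @param normalize passed to \code{\link{as_transient}}.
#' @return A model-density \code{\link{transient}}.
#' @export
perturb_transient <- function(base, delta_mua, normalize = TRUE) {
  stopifnot(inherits(base, "mc_result"))
  if (is.null(base$pathlen_sums))
    stop("base result has no per-layer pathlength sums", call. = FALSE)
  nl <- nrow(base$pathlen_sums)
  if (length(delta_mua) != nl)
    stop(sprintf("'delta_mua' must have length %d (one per layer)", nl),
         call. = FALSE)
  base_mua <- vapply(base$layers, `[[`, numeric(1), "mua")
  big <- abs(delta_mua) > 0.2 * pmax(base_mua, .Machine$double.eps)
  if (any(big))
    warning("absorption perturbation exceeds 20% of the base mua in layer(s) ",
            paste(which(big), collapse = ", "),
            "; re-weighting accuracy degrades", call. = FALSE)
  w <- base$dtof
  Lbar <- base$pathlen_sums
  pos <- w > 0
  fac <- rep(1, length(w))
  if (any(pos)) {
    expo <- colSums(Lbar[, pos, drop = FALSE] * delta_mua) / w[pos]
    fac[pos] <- exp(-expo)
  }
  tr <- as_transient(base, normalize = normalize)
  transient(base$grid, tr$values * fac, kind = "model_density", rho = base$rho)
}

#' Poisson shot-noise sampling of a transient
#'
#' Draws independent Poisson counts per bin with means proportional to the
#' input values, scaled so the expected total equals \code{total_counts}.
#'
#' @param x a \code{\link{transient}} (any kind) with nonnegative values.
#' @param total_counts expected total number of detected photons (>= 0).
#' @param seed integer seed (uses R's RNG; restored on exit).
#' @return A counts-kind \code{\link{transient}} whose \code{scale} attribute
#'   stores the applied scaling factor.
#' @export
sample_counts <- function(x, total_counts, seed = NULL) {
  stopifnot(inherits(x, "transient"), is.numeric(total_counts),
            length(total_counts) == 1L, total_counts >= 0)
  if (any(x$values < 0)) stop("input bins must be >= 0", call. = FALSE)
  tot <- sum(x$values)
  if (total_counts == 0 || tot == 0) {
    return(transient(x$grid, rep(0, x$grid$n_bins), kind = "counts",
                     rho = x$rho, wavelength = x$wavelength, scale = 1))
  }
  lam <- x$values * (total_counts / tot)
  counts <- with_seed(seed, rpois(length(lam), lam))
  transient(x$grid, counts, kind = "counts", rho = x$rho,
            wavelength = x$wavelength, scale = total_counts / tot)
}

# evaluate expr with a temporary RNG state (NULL seed = use current stream)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
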