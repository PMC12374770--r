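#' Hemoglobin extinction-coefficient table
#'
#' Loads a tabulated compilation of molar extinction coefficients of
#' oxygenated and deoxygenated hemoglobin (decadic convention, 1/cm per
#' mol/L). The bundled default, \code{hb_extinction_synthetic.csv}, is a
#' synthetic compilation constructed to match the magnitude and shape of the
#' standard published NIR hemoglobin spectra (600-1000 nm, 10 nm spacing,
#' isosbestic crossing near 800 nm); it is adequate for simulation and for
#' relative-concentration / TOI work, but is not a measured reference
#' spectrum.
#'
#' @param file delimited text file with columns
#'   \code{wavelength_nm,eps_hbo2,eps_hb}.
#' @param convention \code{"decadic"} (base-10 extinction, default) or
#'   \code{"natural"}.
#' @return Object of class \code{"extinction_table"}: a data frame with the
#'   three columns and a \code{convention} attribute.
#' @export
extinction_table <- function(file = system.file("extdata",
                                                "hb_extinction_synthetic.csv",
                                                package = "layertof"),
                             convention = c("decadic", "natural")) {
  convention <- match.arg(convention)
  d <- read.csv(file)
  stopifnot(all(c("wavelength_nm", "eps_hbo2", "eps_hb") %in% names(d)))
  if (is.unsorted(d$wavelength_nm, strictly = TRUE))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(d$eps_hbo2 <= 0) || any(d$eps_hb <= 0))
    stop("extinction coefficients must be positive", call. = FALSE)
  structure(d, convention = convention, class = c("extinction_table",
                                                  "data.frame"))
}

# interpolated (eps_hbo2, eps_hb) at a wavelength; error outside coverage
.eps_at <- function(table, wavelength) {
  rng <- range(table$wavelength_nm)
  if (wavelength < rng[1] || wavelength > rng[2])
    stop(sprintf("wavelength %g nm outside table coverage [%g, %g]",
                 wavelength, rng[1], rng[2]), call. = FALSE)
  c(hbo2 = approx(table$wavelength_nm, table$eps_hbo2, xout = wavelength)$y,
    hb = approx(table$wavelength_nm, table$eps_hb, xout = wavelength)$y)
}

# ln(10) for decadic tables, 1 for natural-log tables
.log_factor <- function(table) {
  if (identical(attr(table, "convention"), "natural")) 1 else log(10)
}

#' Hemodynamic state: hemoglobin concentrations and TOI
#'
#' @param c_hbo2,c_hb concentrations of oxygenated and deoxygenated
#'   hemoglobin (mol/L, or any common relative unit); both >= 0.
#' @param background optional wavelength-independent background absorption
#'   offset, 1/cm.
#' @return Object of class \code{"hemodynamic_state"} with the tissue
#'   oxygenation index \code{toi} = 100 c_hbo2 / (c_hbo2 + c_hb) in percent.
#' @examples
#' hemodynamic_state(6e-5 * 0.4, 6e-5 * 0.6)$toi # 40
#' @export
hemodynamic_state <- function(c_hbo2, c_hb, background = 0) {
  stopifnot(is.numeric(c_hbo2), is.numeric(c_hb), c_hbo2 >= 0, c_hb >= 0)
  tot <- c_hbo2 + c_hb
  toi <- if (tot > 0) 100 * c_hbo2 / tot else NA_real_
  structure(list(c_hbo2 = c_hbo2, c_hb = c_hb, toi = toi,
                 background = background),
            class = "hemodynamic_state")
}

#' @export
print.hemodynamic_state <- function(x, ...) {
  cat(sprintf("<hemodynamic_state> HbO2 = %.4g, Hb = %.4g, TOI = %s%%\n",
              x$c_hbo2, x$c_hb,
              if (is.na(x$toi)) "NA" else sprintf("%.2f", x$toi)))
  invisible(x)
}

#' Absorption coefficient of a hemodynamic state
#'
#' Beer-Lambert mixing: for a decadic extinction table,
#' \deqn{\mu_a(\lambda) = \ln(10) (\epsilon_{HbO_2}(\lambda) c_{HbO_2} +
#'   \epsilon_{Hb}(\lambda) c_{Hb}) + \mu_{a,bg}.}
#' Linear in each concentration.
#'
#' @param state a \code{\link{hemodynamic_state}}.
#' @param table an \code{\link{extinction_table}}.
#' @param wavelength wavelength, nm (within the table coverage; linear
#'   interpolation between rows).
#' @return Absorption coefficient, 1/cm.
#' @export
mua_from_state <- function(state, table, wavelength) {
  stopifnot(inherits(state, "hemodynamic_state"),
            inherits(table, "extinction_table"))
  eps <- .eps_at(table, wavelength)
  unname(.log_factor(table) * (eps[["hbo2"]] * state$c_hbo2 +
                                 eps[["hb"]] * state$c_hb) + state$background)
}

#' Unmix two-wavelength absorption into hemoglobin concentrations and TOI
#'
#' Solves the 2x2 linear Beer-Lambert system
#' \eqn{\mu_a(\lambda_j) = \ln(10) [\epsilon_{HbO_2}(\lambda_j) c_{HbO_2} +
#' \epsilon_{Hb}(\lambda_j) c_{Hb}]} for the two concentrations, then
#' \eqn{TOI = 100 c_{HbO_2}/(c_{HbO_2}+c_{Hb})}. The two wavelengths must
#' straddle the isosbestic point so the extinction matrix is nonsingular.
#' Negative solved concentrations are retained in the returned record and
#' flagged, but the TOI is set to \code{NA} (clipping would silently bias
#' oxygenation estimates).
#'
#' @param mua_1,mua_2 absorption coefficients at the two wavelengths, 1/cm.
#' @param table an \code{\link{extinction_table}}.
#' @param wavelengths the two wavelengths, nm (default 740 and 850).
#' @return A list with \code{c_hbo2}, \code{c_hb}, \code{toi} (percent, or
#'   \code{NA} when a concentration is negative) and \code{negative} flag.
#' @examples
#' tab <- extinction_table()
#' st <- hemodynamic_state(4.8e-5 * 0.4, 4.8e-5 * 0.6)
#' unmix_two_wavelengths(mua_from_state(st, tab, 740),
#'                       mua_from_state(st, tab, 850), tab)$toi
#' @export
unmix_two_wavelengths <- function(mua_1, mua_2, table,
                                  wavelengths = c(740, 850)) {
  stopifnot(inherits(table, "extinction_table"), length(wavelengths) == 2L)
  e1 <- .eps_at(table, wavelengths[1])
  e2 <- .eps_at(table, wavelengths[2])
  E <- .log_factor(table) * rbind(e1, e2)
  if (abs(det(E)) < .Machine$double.eps * max(abs(E))^2)
    stop("extinction matrix is singular at the chosen wavelengths",
         call. = FALSE)
  cc <- solve(E, c(mua_1, mua_2))
  negative <- any(cc < 0)
  toi <- if (negative || sum(cc) <= 0) NA_real_ else 100 * cc[1] / sum(cc)
  list(c_hbo2 = unname(cc[1]), c_hb = unname(cc[2]), toi = unname(toi),
       negative = negative)
}

#' TOI time series from paired per-wavelength fit results
#'
#' Pairs per-frame absorption estimates at two wavelengths by timestamp and
#' unmixes each pair into hemoglobin concentrations and TOI. Frames whose fit
#' did not converge propagate as missing values; frames present at only one
#' wavelength raise an error listing the offenders.
#'
#' @param fits a data frame with columns \code{time} (s), \code{wavelength}
#'   (nm), \code{mua} (1/cm) and logical \code{converged}; exactly one row
#'   per (time, wavelength).
#' @param table an \code{\link{extinction_table}}.
#' @param wavelengths the two wavelengths to pair, nm.
#' @return Data frame with one row per frame: \code{time}, \code{c_hbo2},
#'   \code{c_hb}, \code{toi} (NA where a fit failed or a concentration was
#'   negative).
#' @export
toi_timeseries <- function(fits, table, wavelengths = c(740, 850)) {
  stopifnot(is.data.frame(fits),
            all(c("time", "wavelength", "mua", "converged") %in% names(fits)))
  f1 <- fits[fits$wavelength == wavelengths[1], ]
  f2 <- fits[fits$wavelength == wavelengths[2], ]
  unpaired <- c(setdiff(f1$time, f2$time), setdiff(f2$time, f1$time))
  if (length(unpaired) > 0)
    stop("unpaired frames at time(s): ",
         paste(sort(unique(unpaired)), collapse = ", "), call. = FALSE)
  f1 <- f1[order(f1$time), ]
  f2 <- f2[order(f2$time), ]
  out <- data.frame(time = f1$time, c_hbo2 = NA_real_, c_hb = NA_real_,
                    toi = NA_real_)
  for (i in seq_len(nrow(f1))) {
    if (!isTRUE(f1$converged[i]) || !isTRUE(f2$converged[i])) next
    u <- unmix_two_wavelengths(f1$mua[i], f2$mua[i], table, wavelengths)
    out$c_hbo2[i] <- u$c_hbo2
    out$c_hb[i] <- u$c_hb
    out$toi[i] <- u$toi
  }
  out
}

#' Write a TOI time series as delimited text
#'
#' @param series data frame from \code{\link{toi_timeseries}}.
#' @param file output path (columns \code{time_s,c_hbo2,c_hb,toi_pct}).
#' @export
write_toi_series <- function(series, file) {
  d <- data.frame(time_s = series$time, c_hbo2 = series$c_hbo2,
                  c_hb = series$c_hb, toi_pct = series$toi)
  write.csv(d, file, row.names = FALSE)
  invisible(file)
}
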