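#' Fetal-layer optical properties at different tissue oxygenation levels
#'
#' The five fetal-layer conditions used by the estimation-accuracy
#' simulations: absorption coefficients at tissue oxygenation indices of 20
#' to 60\% with constant reduced scattering, under the standard maternal
#' layer (\eqn{\mu_a} = 0.11/cm, \eqn{\mu_s'} = 11.19/cm, 9.6 mm).
#'
#' @return Data frame with columns \code{toi} (percent), \code{mua} and
#'   \code{musp} (1/cm).
#' @export
fetal_conditions <- function() {
  data.frame(toi = c(20, 30, 40, 50, 60),
             mua = c(0.08488, 0.08910, 0.09333, 0.09755, 0.1018),
             musp = rep(9.551, 5))
}

#' Standard maternal layer
#'
#' @param thickness maternal-layer thickness, cm (default 0.96).
#' @return An \code{\link{optical_layer}} with \eqn{\mu_a} = 0.11/cm and
#'   \eqn{\mu_s'} = 11.19/cm.
#' @export
maternal_layer <- function(thickness = 0.96) {
  optical_layer(0.11, 11.19, thickness = thickness)
}

.study_report <- function(study, table, summary, config) {
  structure(list(study = study, table = table, summary = summary,
                 config = config,
                 provenance = list(package_version =
                                     as.character(utils::packageVersion("layertof")),
                                   r_version = R.version.string)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: %s> %d rows\n", x$study, nrow(x$table)))
  cat("summary:\n")
  print(x$summary)
  invisible(x)
}

#' Write a study report as delimited text plus a JSON summary
#'
#' @param report a \code{study_report}.
#' @param dir output directory (created if needed).
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$table, file.path(dir, paste0(report$study, "_table.csv")),
            row.names = FALSE)
  jsonlite::write_json(list(study = report$study, summary = report$summary,
                            provenance = report$provenance),
                       file.path(dir, paste0(report$study, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

# one TD recovery: forward -> Poisson -> two-layer fit; returns estimates
.td_recover_once <- function(medium, rho, grid, total_counts, seed,
                             nquad = 256) {
  model <- td_two_layer(medium, rho = rho, grid = grid, nquad = nquad)
  obs <- sample_counts(model, total_counts, seed = seed)
  fit <- fit_two_layer_td(obs, top_thickness = medium$top$thickness,
                          n = medium$top$n,
                          n_ambient = medium$n_ambient, nquad = nquad)
  fit
}

#' Deep-layer absorption recovery study
#'
#' Simulation analog of the two-layer phantom characterization: synthetic
#' two-layer transients (standard maternal layer over one fetal condition)
#' at a single source-detector separation with Poisson shot noise, inverted
#' by the two-layer TD fit with the top thickness fixed; reports the
#' per-seed relative error of the recovered deep-layer absorption
#' coefficient and its median.
#'
#' @param seeds integer vector of seeds (one synthetic measurement each).
#' @param fetal_toi which fetal condition to use (TOI percent, one of
#'   \code{fetal_conditions()$toi}).
#' @param rho source-detector separation, cm.
#' @param total_counts expected total detected photons per transient.
#' @param t_end,n_bins transient grid (ns, bins).
#' @param thickness maternal thickness, cm.
#' @param nquad Hankel quadrature order of the forward model.
#' @param noise if \code{FALSE}, fit the noise-free model transient
#'   (consistency check).
#' @return A \code{study_report}; \code{summary$median_rel_err_pct} is the
#'   median relative error of the deep-layer absorption coefficient in
#'   percent.
#' @export
run_recovery_study <- function(seeds = 1:5, fetal_toi = 40, rho = 2,
                               total_counts = 1e6, t_end = 5, n_bins = 250,
                               thickness = 0.96, nquad = 256, noise = TRUE) {
  fc <- fetal_conditions()
  row <- fc[fc$toi == fetal_toi, ]
  if (nrow(row) != 1L) stop("unknown fetal condition", call. = FALSE)
  medium <- two_layer_medium(maternal_layer(thickness),
                             optical_layer(row$mua, row$musp))
  grid <- time_grid(t_end = t_end, n_bins = n_bins)
  rows <- lapply(seeds, function(s) {
    res <- tryCatch({
      if (noise) {
        fit <- .td_recover_once(medium, rho, grid, total_counts, s,
                                nquad = nquad)
      } else {
        model <- td_two_layer(medium, rho = rho, grid = grid, nquad = nquad)
        fit <- fit_two_layer_td(model, top_thickness = thickness,
                                nquad = nquad)
      }
      cf <- coef(fit)
      data.frame(seed = s, mua2_hat = cf[["mua2"]], musp2_hat = cf[["musp2"]],
                 mua1_hat = cf[["mua1"]], musp1_hat = cf[["musp1"]],
                 rel_err_mua2_pct = 100 * abs(cf[["mua2"]] - row$mua) / row$mua,
                 converged = fit$converged, error = NA_character_)
    }, error = function(e) {
      data.frame(seed = s, mua2_hat = NA, musp2_hat = NA, mua1_hat = NA,
                 musp1_hat = NA, rel_err_mua2_pct = NA, converged = FALSE,
                 error = conditionMessage(e))
    })
    res
  })
  tab <- do.call(rbind, rows)
  summ <- list(median_rel_err_pct = median(tab$rel_err_mua2_pct, na.rm = TRUE),
               iqr_rel_err_pct = unname(diff(quantile(tab$rel_err_mua2_pct,
                                                      c(0.25, 0.75),
                                                      na.rm = TRUE))),
               n_failed = sum(!tab$converged),
               mua2_true = row$mua)
  .study_report("recovery", tab,  summ,
                list(seeds = seeds, fetal_toi = fetal_toi, rho = rho,
                     total_counts = total_counts, t_end = t_end,
                     n_bins = n_bins, thickness = thickness, nquad = nquad,
                     noise = noise))
}

#' CW-versus-TD estimation accuracy study
#'
#' For each fetal condition and seed: synthesize a TD transient at one
#' distance and CW intensities at several distances with matched photon
#' budgets (the same exposure for every CW detector, calibrated so the
#' detector at \code{rho_td} collects \code{total_counts} photons at
#' baseline), apply Poisson noise, fit both models, and record the relative
#' error of the deep-layer absorption coefficient for each method. The CW
#' fit uses the known simulated exposure as a fixed amplitude so both
#' methods solve a four-parameter problem.
#'
#' @param seeds integer seeds.
#' @param rho_td TD source-detector separation, cm.
#' @param rhos_cw CW detector distances, cm.
#' @param total_counts photon budget of the TD transient (and of the CW
#'   detector at \code{rho_td}).
#' @param noise set \code{FALSE} for the noise-free consistency check.
#' @param nquad_cw Hankel quadrature order for the CW model (the larger
#'   distances need more nodes than the TD path at \code{rho_td}).
#' @inheritParams run_recovery_study
#' @return A \code{study_report}; the summary holds per-condition median
#'   relative errors for both methods and the number of conditions where the
#'   TD median error is less than or equal to the CW one.
#' @export
run_cw_vs_td_study <- function(seeds = 1:20, rho_td = 2, rhos_cw = 1:4,
                               total_counts = 1e6, t_end = 5, n_bins = 250,
                               thickness = 0.96, nquad = 256, nquad_cw = 512, noise = TRUE) {
  fc <- fetal_conditions()
  grid <- time_grid(t_end = t_end, n_bins = n_bins)
  rows <- list()
  for (ci in seq_len(nrow(fc))) {
    medium <- two_layer_medium(maternal_layer(thickness),
                               optical_layer(fc$mua[ci], fc$musp[ci]))
    td_model <- td_two_layer(medium, rho = rho_td, grid = grid, nquad = nquad)
    cw_model <- cw_two_layer(medium, rhos = rhos_cw, nquad = nquad_cw)
    # exposure: counts per unit model intensity, anchored at rho_td
    cw_at_td <- cw_two_layer(medium, rhos = rho_td, nquad = nquad_cw)
    exposure <- total_counts / cw_at_td
    for (s in seeds) {
      row <- tryCatch({
        if (noise) {
          obs_td <- sample_counts(td_model, total_counts, seed = s)
          cw_counts <- with_seed(s + 10000L,
                                 rpois(length(cw_model), exposure * cw_model))
          if (any(cw_counts <= 0)) stop("CW detector with zero counts")
        } else {
          obs_td <- td_model
          cw_counts <- exposure * cw_model
        }
        fit_td <- fit_two_layer_td(obs_td, top_thickness = thickness,
                                   nquad = nquad)
        fit_cw <- fit_two_layer_cw(cw_counts, rhos = rhos_cw,
                                   top_thickness = thickness,
                                   amplitude = "fixed",
                                   amplitude_value = exposure,
                                   nquad = nquad_cw)
        data.frame(toi = fc$toi[ci], seed = s,
                   mua2_true = fc$mua[ci],
                   mua2_td = coef(fit_td)[["mua2"]],
                   mua2_cw = coef(fit_cw)[["mua2"]],
                   err_td_pct = 100 * abs(coef(fit_td)[["mua2"]] - fc$mua[ci]) / fc$mua[ci],
                   err_cw_pct = 100 * abs(coef(fit_cw)[["mua2"]] - fc$mua[ci]) / fc$mua[ci],
                   converged_td = fit_td$converged,
                   converged_cw = fit_cw$converged,
                   error = NA_character_)
      }, error = function(e) {
        data.frame(toi = fc$toi[ci], seed = s, mua2_true = fc$mua[ci],
                   mua2_td = NA, mua2_cw = NA, err_td_pct = NA,
                   err_cw_pct = NA, converged_td = FALSE,
                   converged_cw = FALSE, error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  per_cond <- do.call(rbind, lapply(split(tab, tab$toi), function(d) {
    data.frame(toi = d$toi[1],
               median_err_td_pct = median(d$err_td_pct, na.rm = TRUE),
               median_err_cw_pct = median(d$err_cw_pct, na.rm = TRUE))
  }))
  per_cond$td_not_worse <- per_cond$median_err_td_pct <= per_cond$median_err_cw_pct
  summ <- list(per_condition = per_cond,
               n_td_not_worse = sum(per_cond$td_not_worse),
               n_conditions = nrow(per_cond))
  .study_report("cw_vs_td", tab, summ,
                list(seeds = seeds, rho_td = rho_td, rhos_cw = rhos_cw,
                     total_counts = total_counts, t_end = t_end,
                     n_bins = n_bins, thickness = thickness, nquad = nquad,
                     noise = noise))
}

#' Time-gating benefit study
#'
#' Runs the pulsatile simulation for several seeds (sharing one baseline
#' Monte Carlo run) and compares the fetal-frequency signal-to-background
#' ratio under full integration and under the late gate.
#'
#' @param seeds integer seeds (shot-noise realizations).
#' @param cfg a \code{\link{pulsatile_config}}; its own seed drives the
#'   baseline Monte Carlo run.
#' @param gate the late \code{\link{gate_spec}} to compare against full
#'   integration.
#' @param band SBR exclusion band half-width, Hz.
#' @return A \code{study_report}; the per-seed table holds SBR at the fetal
#'   frequency for both gates plus the full-integration power at both
#'   modulation frequencies.
#' @export
run_gating_study <- function(seeds = 1:20, cfg = pulsatile_config(),
                             gate = gate_spec("late", q = 0.7),
                             band = 0.25) {
  layers <- list(as_mc_layer(cfg$baseline$top),
                 as_mc_layer(cfg$baseline$bottom))
  mc <- run_layered_mc(layers, mc_config(
    n_photons = cfg$n_photons, seed = cfg$seed, rho = cfg$rho,
    max_time = cfg$max_time, n_bins = cfg$n_bins),
    n_ambient = cfg$baseline$n_ambient)
  f_m <- cfg$freqs[1]; f_f <- cfg$freqs[2]
  rows <- lapply(seeds, function(s) {
    cfg_s <- cfg
    cfg_s$seed <- as.integer(s)
    stream <- simulate_pulsatile_stream(cfg_s, mc = mc)
    full_series <- gate_integrate(stream, gate_spec("full"))
    late_series <- gate_integrate(stream, gate)
    sp_full <- power_spectrum(full_series, cfg$frame_rate)
    sp_late <- power_spectrum(late_series, cfg$frame_rate)
    excl <- cfg$freqs
    # frequency of the strongest gated bin outside the maternal band
    off_m <- abs(sp_late$freq - f_m) > band & sp_late$freq > 0
    peak <- sp_late$freq[off_m][which.max(sp_late$power[off_m])]
    data.frame(seed = s,
               sbr_full = signal_to_background(sp_full, f_f, excl, band),
               sbr_late = signal_to_background(sp_late, f_f, excl, band),
               p_maternal_full = sp_full$power[which.min(abs(sp_full$freq - f_m))],
               p_fetal_full = sp_full$power[which.min(abs(sp_full$freq - f_f))],
               gated_peak_freq = peak)
  })
  tab <- do.call(rbind, rows)
  summ <- list(median_sbr_full = median(tab$sbr_full),
               median_sbr_late = median(tab$sbr_late),
               gating_benefit = median(tab$sbr_late) > median(tab$sbr_full),
               maternal_dominant_full = all(tab$p_maternal_full > tab$p_fetal_full))
  .study_report("gating", tab, summ,
                list(seeds = seeds, cfg = cfg[setdiff(names(cfg), "baseline")],
                     gate = unclass(gate), band = band))
}

#' Synthetic occlusion trajectory
#'
#' Piecewise-linear tissue-oxygenation trajectory emulating an arterial
#' occlusion protocol: a baseline plateau, a ramp down during the occlusion,
#' a rapid post-release overshoot and recovery back to baseline.
#'
#' @param t times, s.
#' @param baseline_toi,occlusion_toi,overshoot_toi TOI levels, percent.
#' @param t_occl_on,t_occl_off occlusion window, s.
#' @param t_overshoot time of the overshoot peak after release, s.
#' @param t_recovered time at which baseline is reached again, s.
#' @return Numeric TOI (percent) at each time.
#' @export
occlusion_trajectory <- function(t, baseline_toi = 60, occlusion_toi = 35,
                                 overshoot_toi = 70, t_occl_on = 120,
                                 t_occl_off = 300, t_overshoot = 20,
                                 t_recovered = 120) {
  breaks_t <- c(-Inf, t_occl_on, t_occl_off, t_occl_off + t_overshoot,
                t_occl_off + t_recovered, Inf)
  vals <- c(baseline_toi, baseline_toi, occlusion_toi, overshoot_toi,
            baseline_toi, baseline_toi)
  approx(x = c(0, t_occl_on, t_occl_off, t_occl_off + t_overshoot,
               t_occl_off + t_recovered, max(max(t), t_occl_off + t_recovered) + 1),
         y = vals, xout = pmax(t, 0), rule = 2)$y
}

#' Occlusion-demonstration TOI pipeline study
#'
#' Exercises the full estimation pipeline on a synthetic occlusion:
#' a TOI trajectory drives the deep-layer absorption at two wavelengths
#' (through the bundled extinction table at a fixed total hemoglobin
#' concentration), two-layer transients are synthesized and Poisson-sampled
#' per frame and wavelength, fitted, and unmixed back to a TOI series. The
#' report records whether the TOI minimum falls inside the occlusion window
#' and the maximum within 30 s after release.
#'
#' @param seeds integer seeds.
#' @param frame_period seconds between frames.
#' @param duration total record, s.
#' @param counts_per_frame expected detected photons per frame and
#'   wavelength.
#' @param c_hbt total hemoglobin concentration of the deep layer, mol/L
#'   (default anchored so the 850 nm absorption at TOI 40\% matches the
#'   standard fetal condition).
#' @param wavelengths the two wavelengths, nm.
#' @param flat if \code{TRUE}, hold the trajectory at its baseline (control).
#' @param ... trajectory parameters passed to
#'   \code{\link{occlusion_trajectory}}.
#' @inheritParams run_recovery_study
#' @return A \code{study_report} whose table has one row per seed
#'   (\code{ordering_ok}: min inside occlusion and max within 30 s after
#'   release); the fitted TOI series of the last seed is attached as
#'   \code{$series}.
#' @export
run_occlusion_demo <- function(seeds = 1, frame_period = 15, duration = 540,
                               counts_per_frame = 1e6, rho = 2,
                               thickness = 0.96, t_end = 5, n_bins = 250,
                               c_hbt = NULL, wavelengths = c(740, 850),
                               nquad = 256, flat = FALSE, ...) {
  tab_ext <- extinction_table()
  traj_args <- list(...)
  if (is.null(c_hbt)) {
    e850 <- .eps_at(tab_ext, 850)
    c_hbt <- 0.09333 / (log(10) * (0.4 * e850[["hbo2"]] + 0.6 * e850[["hb"]]))
  }
  grid <- time_grid(t_end = t_end, n_bins = n_bins)
  times <- seq(0, duration - frame_period, by = frame_period)
  toi_true <- if (flat) rep(60, length(times))
              else do.call(occlusion_trajectory, c(list(t = times), traj_args))
  t_on <- traj_args$t_occl_on %||% 120
  t_off <- traj_args$t_occl_off %||% 300

  # per-frame forward models are wavelength- and TOI-dependent; cache by mua2
  model_cache <- new.env(parent = emptyenv())
  model_for <- function(mua2, musp2) {
    key <- sprintf("%.10g_%.10g", mua2, musp2)
    if (is.null(model_cache[[key]])) {
      med <- two_layer_medium(maternal_layer(thickness),
                              optical_layer(mua2, musp2))
      model_cache[[key]] <- td_two_layer(med, rho = rho, grid = grid,
                                         nquad = nquad)
    }
    model_cache[[key]]
  }
  musp2 <- 9.551
  rows <- list()
  series_last <- NULL
  for (s in seeds) {
    fits <- list()
    for (k in seq_along(times)) {
      st <- hemodynamic_state(c_hbt * toi_true[k] / 100,
                              c_hbt * (1 - toi_true[k] / 100))
      for (wl in wavelengths) {
        mua2 <- mua_from_state(st, tab_ext, wl)
        model <- model_for(mua2, musp2)
        obs <- sample_counts(model, counts_per_frame,
                             seed = s * 100000L + k * 10L + match(wl, wavelengths))
        fit <- tryCatch(
          fit_two_layer_td(obs, top_thickness = thickness, nquad = nquad),
          error = function(e) NULL)
        fits[[length(fits) + 1L]] <- data.frame(
          time = times[k], wavelength = wl,
          mua = if (is.null(fit)) NA_real_ else coef(fit)[["mua2"]],
          converged = !is.null(fit) && fit$converged)
      }
    }
    fits <- do.call(rbind, fits)
    series <- toi_timeseries(fits, tab_ext, wavelengths)
    series$toi_true <- toi_true
    series_last <- series
    ok <- !is.na(series$toi)
    i_min <- series$time[ok][which.min(series$toi[ok])]
    i_max <- series$time[ok][which.max(series$toi[ok])]
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s,
      t_min = i_min, t_max = i_max,
      ordering_ok = (i_min >= t_on && i_min <= t_off) &&
        (i_max > t_off && i_max <= t_off + 30),
      n_missing = sum(!ok),
      max_abs_toi_err = max(abs(series$toi[ok] - series$toi_true[ok])))
  }
  tab <- do.call(rbind, rows)
  summ <- list(n_ordering_ok = sum(tab$ordering_ok), n_seeds = nrow(tab),
               median_max_abs_toi_err = median(tab$max_abs_toi_err))
  rep <- .study_report("occlusion_demo", tab, summ,
                       list(seeds = seeds, frame_period = frame_period,
                            duration = duration,
                            counts_per_frame = counts_per_frame, rho = rho,
                            thickness = thickness, c_hbt = c_hbt,
                            wavelengths = wavelengths, flat = flat))
  rep$series <- series_last
  rep
}
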