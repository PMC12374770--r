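# builds a raw TCSPC histogram from the model of `ref` shifted by t0_ns and
# scaled to `total` counts (Poisson noise optional)
make_raw <- function(ref, t0_ns = 0.5, total = 3e6, channel_ps = 16,
                     nch = 400, rho = 2, noise = FALSE, seed = NULL) {
  grid <- time_grid(t_end = nch * channel_ps / 1e3, n_bins = nch)
  model <- td_semi_infinite(ref, rho, grid)$values
  k <- round(t0_ns / (channel_ps / 1e3))
  shifted <- c(rep(0, k), model)[1:nch]
  lam <- total * shifted / sum(shifted)
  counts <- if (noise) with_seed(seed, rpois(nch, lam)) else round(lam)
  raw_histogram(counts, channel_ps, rho = rho)
}

test_that("calibration recovers a known shift and scale from noise-free
           data", {
  ref <- optical_layer(0.1, 10)
  raw <- make_raw(ref, t0_ns = 0.5)
  cal <- estimate_calibration(raw, ref, rho = 2)
  expect_lt(abs(cal$t0 - 0.5), 0.016) # one channel width
  # amplitude maps model density to counts: check by reapplying
  grid <- time_grid(4, 200)
  tr <- apply_calibration(raw, cal, grid)
  model <- td_semi_infinite(ref, 2, grid)$values
  win <- fit_window(model)
  sc <- sum(tr$values[win] * model[win]) / sum(model[win]^2)
  expect_equal(tr$values[win] / sc, model[win], tolerance = 0.03)

  # zero shift: t0 at channel resolution
  cal0 <- estimate_calibration(make_raw(ref, t0_ns = 0), ref, rho = 2)
  expect_lt(abs(cal0$t0), 0.016)
})

test_that("calibration fails cleanly on flat histograms", {
  ref <- optical_layer(0.1, 10)
  flat <- raw_histogram(rep(3L, 100), 16, rho = 2)
  expect_error(estimate_calibration(flat, ref, rho = 2),
               "calibration failure")
})

test_that("t0 stays within two channels under Poisson noise across seeds", {
  ref <- optical_layer(0.1, 10)
  errs <- vapply(1:10, function(s) {
    raw <- make_raw(ref, t0_ns = 0.5, total = 1e6, noise = TRUE, seed = s)
    abs(estimate_calibration(raw, ref, rho = 2)$t0 - 0.5)
  }, numeric(1))
  expect_true(all(errs <= 2 * 0.016))
})

test_that("calibrated rebinning conserves counts and warns when the grid
           overruns the data", {
  ref <- optical_layer(0.1, 10)
  raw <- make_raw(ref, t0_ns = 0)
  cal <- structure(list(t0 = 0, amplitude_factor = 1, residual = 0, rho = 2,
                        wavelength = NA_real_),
                   class = "instrument_calibration")
  grid <- time_grid(t_end = 6.4, n_bins = 160) # same span, 40 ps bins
  tr <- apply_calibration(raw, cal, grid, subtract_background = FALSE)
  expect_lt(abs(sum(tr$values) - sum(raw$counts)), 1)
  expect_warning(
    apply_calibration(raw, cal, time_grid(t_end = 20, n_bins = 100),
                      subtract_background = FALSE),
    "beyond")
})

test_that("crop_and_rebin conserves counts within the window", {
  g <- time_grid(5, 100)
  tr <- transient(g, rpois(100, 100), kind = "counts", rho = 2)
  ident <- crop_and_rebin(tr, window = NULL, factor = 1)
  expect_identical(ident$values, tr$values)

  r2 <- crop_and_rebin(tr, factor = 2)
  expect_identical(r2$grid$n_bins, 50L)
  expect_equal(sum(r2$values), sum(tr$values))

  cropped <- crop_and_rebin(tr, window = c(1, 3))
  expect_equal(sum(cropped$values),
               sum(tr$values[g$centers >= 1 & g$centers <= 3]))
  expect_error(crop_and_rebin(tr, window = c(10, 11)), "empty window")
})
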