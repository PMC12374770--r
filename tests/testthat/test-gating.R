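# fast pulsatile config sharing a cached baseline Monte Carlo run
gating_cfg <- function(...) {
  pulsatile_config(n_photons = 3e5, seed = 2, n_bins = 50, ...)
}

gating_mc <- function() mc_two_layer_small()

test_that("gate integration is additive and the full gate equals the total
           counts", {
  cfg <- gating_cfg(duration = 10)
  stream <- simulate_pulsatile_stream(cfg, mc = gating_mc())
  full <- gate_integrate(stream, gate_spec("full"))
  expect_equal(full, rowSums(stream$counts))
  tsplit <- 1.1
  early <- gate_integrate(stream, gate_spec("late", start_ns = 0,
                                            end_ns = tsplit))
  late <- gate_integrate(stream, gate_spec("late", start_ns = tsplit + 1e-9))
  expect_equal(early + late, full)
  expect_error(gate_integrate(stream, gate_spec("late", start_ns = 4.99,
                                                end_ns = 4.992)),
               "no bins")
})

test_that("the periodogram locates pure tones, satisfies Parseval and
           handles degenerate input", {
  fr <- 20
  t <- (0:1199) / fr
  x <- 3 + 2 * sin(2 * pi * 1.3 * t)
  sp <- power_spectrum(x, fr)
  expect_equal(sp$freq[which.max(sp$power)], 1.3, tolerance = 0.02)
  # Parseval: one-sided power sums to the windowed series energy
  n <- length(x)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  expect_equal(sum(sp$power), sum(((x - mean(x)) * win)^2),
               tolerance = 1e-6)

  flat <- power_spectrum(rep(5, 128), fr)
  expect_true(all(flat$power == 0))
  expect_error(power_spectrum(rnorm(32), fr), "64")
})

test_that("SBR is near one for white noise and large for a tone", {
  fr <- 20
  set.seed(11)
  sp_noise <- power_spectrum(rnorm(1200), fr)
  expect_gt(signal_to_background(sp_noise, 2.1, exclude = c(1.3, 2.1)), 0.2)
  expect_lt(signal_to_background(sp_noise, 2.1, exclude = c(1.3, 2.1)), 5)

  t <- (0:1199) / fr
  sp_tone <- power_spectrum(sin(2 * pi * 2.1 * t) + 0.01 * rnorm(1200), fr)
  expect_gt(signal_to_background(sp_tone, 2.1, exclude = c(1.3, 2.1)), 100)
  expect_error(signal_to_background(sp_noise, 2.1, exclude = c(1.3, 2.1),
                                    band = 20), "whole grid")
})

test_that("unmodulated streams show no spurious power at the heart-rate
           frequencies", {
  cfg <- gating_cfg(delta_mua = c(0, 0), duration = 30)
  stream <- simulate_pulsatile_stream(cfg, mc = gating_mc())
  sp <- power_spectrum(gate_integrate(stream, gate_spec("full")),
                       cfg$frame_rate)
  bg <- median(sp$power[-1])
  for (f in c(1.3, 2.1)) {
    i <- which.min(abs(sp$freq - f))
    expect_lt(sp$power[i], 5 * bg)
  }
})

test_that("maternal-only modulation peaks at the maternal frequency in both
           gates", {
  cfg <- gating_cfg(delta_mua = c(0.02 * 0.11, 0), duration = 60)
  stream <- simulate_pulsatile_stream(cfg, mc = gating_mc())
  for (gate in list(gate_spec("full"), gate_spec("late", q = 0.7))) {
    sp <- power_spectrum(gate_integrate(stream, gate), cfg$frame_rate)
    expect_equal(sp$freq[which.max(sp$power[-1]) + 1], 1.3,
                 tolerance = 0.02)
  }
})

test_that("sampling-theorem and gate-specification contracts are enforced", {
  expect_error(pulsatile_config(frame_rate = 4), "twice")
  expect_error(gate_spec("late", start_ns = 3, end_ns = 2), "before")
  expect_error(gate_spec("late", q = 1.2), "q < 1")
})
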