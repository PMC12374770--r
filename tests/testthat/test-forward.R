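test_that("semi-infinite reflectance is causal, decays, and obeys the
           time-domain Beer-Lambert scaling exactly", {
  g <- time_grid(5, 200)
  lay <- optical_layer(0.1, 10)
  tr <- td_semi_infinite(lay, rho = 2, grid = g)
  expect_true(all(tr$values >= 0))
  # vanishes at both ends: early bins before photons can arrive, late bins
  # killed by absorption
  expect_lt(tr$values[1] / max(tr$values), 1e-12)
  expect_lt(tr$values[g$n_bins] / max(tr$values), 1e-2)
  expect_gt(which.max(tr$values), 1)

  d <- 0.04
  tr2 <- td_semi_infinite(optical_layer(0.1 + d, 10), rho = 2, grid = g)
  v <- 29.9792458 / 1.4
  pos <- tr$values > 0
  expect_equal(tr2$values[pos], tr$values[pos] * exp(-v * d * g$centers[pos]),
               tolerance = 1e-12)
})

test_that("an unreachable deep layer reduces the two-layer solution to the
           homogeneous solution of the top layer", {
  g <- time_grid(5, 200)
  top <- optical_layer(0.11, 11.19, thickness = 10)
  med <- two_layer_medium(top, optical_layer(0.22, 11.19))
  t2 <- td_two_layer(med, rho = 2, grid = g)
  hom <- td_semi_infinite(optical_layer(0.11, 11.19), rho = 2, grid = g)
  i <- hom$values > 1e-4 * max(hom$values)
  expect_lt(max(abs(t2$values[i] - hom$values[i]) / hom$values[i]), 1e-3)
})

test_that("late-time reflectance falls with deeper absorption while the
           rising edge stays put", {
  g <- time_grid(5, 250)
  med_lo <- std_medium()
  med_hi <- two_layer_medium(med_lo$top, optical_layer(0.13, 9.551))
  lo <- td_two_layer(med_lo, rho = 2, grid = g)
  hi <- td_two_layer(med_hi, rho = 2, grid = g)
  tp <- g$centers[which.max(lo$values)]
  late <- g$centers > 2 * tp & lo$values > 1e-6 * max(lo$values)
  expect_true(all(hi$values[late] < lo$values[late]))
  # first bins of the rising edge barely react (superficial photons)
  rise <- which(lo$values > 0.05 * max(lo$values))[1:3]
  expect_lt(max(abs(hi$values[rise] - lo$values[rise]) / lo$values[rise]),
            0.01)
})

test_that("time-integrated reflectance decreases as either layer absorbs
           more", {
  g <- time_grid(10, 250)
  base <- std_medium()
  tot <- function(m) sum(td_two_layer(m, rho = 2, grid = g)$values)
  t0 <- tot(base)
  up_top <- two_layer_medium(optical_layer(0.13, 11.19, thickness = 0.96),
                             base$bottom)
  up_bot <- two_layer_medium(base$top, optical_layer(0.12, 9.551))
  expect_lt(tot(up_top), t0)
  expect_lt(tot(up_bot), t0)
})

test_that("CW reflectance is the time integral of the TD solution and decays
           with distance", {
  med <- std_medium()
  rhos <- 1:4
  cw <- cw_two_layer(med, rhos)
  expect_true(all(diff(cw) < 0))
  g <- time_grid(30, 1500)
  ti <- vapply(rhos, function(r)
    sum(td_two_layer(med, rho = r, grid = g, nquad = 512)$values) * g$dt,
    numeric(1))
  expect_equal(cw, ti, tolerance = 0.02)

  # identical layers: matches the closed-form time integral
  medh <- two_layer_medium(optical_layer(0.11, 11.19, thickness = 0.96),
                           optical_layer(0.11, 11.19))
  ti_h <- sum(td_semi_infinite(optical_layer(0.11, 11.19), 2, g)$values) * g$dt
  expect_equal(cw_two_layer(medh, 2), ti_h, tolerance = 0.01)
})

test_that("the quadrature convergence check reports non-convergence", {
  med <- std_medium()
  g <- time_grid(5, 100)
  expect_error(td_two_layer(med, rho = 2, grid = g, nquad = 32, check = TRUE),
               "quadrature")
  expect_silent(td_two_layer(med, rho = 2, grid = g, nquad = 512,
                             check = TRUE))
  expect_error(cw_two_layer(med, rhos = 4, nquad = 48, check = TRUE),
               "quadrature")
})
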