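test_that("the bundled extinction table satisfies its structural
           invariants", {
  tab <- extinction_table()
  expect_true(all(diff(tab$wavelength_nm) > 0))
  expect_true(all(tab$eps_hbo2 > 0) && all(tab$eps_hb > 0))
  expect_true(min(tab$wavelength_nm) <= 740 && max(tab$wavelength_nm) >= 850)
  # exactly one isosbestic crossing in [780, 820]
  d <- tab$eps_hbo2 - tab$eps_hb
  win <- tab$wavelength_nm >= 780 & tab$wavelength_nm <= 820
  expect_identical(sum(diff(sign(d[win])) != 0), 1L)
})

test_that("absorption mixing is linear in the concentrations", {
  tab <- extinction_table()
  zero <- hemodynamic_state(0, 0)
  expect_equal(mua_from_state(zero, tab, 800), 0)
  st <- hemodynamic_state(3e-5, 2e-5)
  st3 <- hemodynamic_state(9e-5, 6e-5)
  expect_equal(mua_from_state(st3, tab, 760), 3 * mua_from_state(st, tab, 760))
  bg <- hemodynamic_state(3e-5, 2e-5, background = 0.02)
  expect_equal(mua_from_state(bg, tab, 760),
               mua_from_state(st, tab, 760) + 0.02)
  expect_error(mua_from_state(st, tab, 1500), "outside")
})

test_that("unmixing inverts mixing exactly for 100 random states", {
  tab <- extinction_table()
  set.seed(42)
  for (i in 1:100) {
    c1 <- runif(1, 1e-6, 2e-4)
    toi <- runif(1, 1, 99)
    st <- hemodynamic_state(c1 * toi / 100, c1 * (1 - toi / 100))
    u <- unmix_two_wavelengths(mua_from_state(st, tab, 740),
                               mua_from_state(st, tab, 850), tab)
    expect_equal(u$toi, toi, tolerance = 1e-9)
    expect_equal(u$c_hbo2 + u$c_hb, c1, tolerance = 1e-9 * c1)
  }
})

test_that("a pure-oxyhemoglobin absorption ratio unmixes to 100% TOI and
           inconsistent inputs are flagged, not clipped", {
  tab <- extinction_table()
  e740 <- layertof:::.eps_at(tab, 740)
  e850 <- layertof:::.eps_at(tab, 850)
  k <- 1e-4 * log(10)
  u <- unmix_two_wavelengths(k * e740[["hbo2"]], k * e850[["hbo2"]], tab)
  expect_equal(u$toi, 100, tolerance = 1e-6)
  expect_equal(u$c_hb, 0, tolerance = 1e-12)

  # absorption pair outside the positive cone: negative concentration
  bad <- unmix_two_wavelengths(0.3, 0.01, tab)
  expect_true(bad$negative)
  expect_true(is.na(bad$toi))
  expect_lt(bad$c_hbo2, 0) # retained in the record
})

test_that("TOI is invariant to total-hemoglobin scaling", {
  for (k in c(0.5, 2, 10)) {
    a <- hemodynamic_state(2e-5, 3e-5)
    b <- hemodynamic_state(k * 2e-5, k * 3e-5)
    expect_equal(a$toi, b$toi)
  }
})

test_that("TOI time series pair frames, propagate failures and reject
           unpaired frames", {
  tab <- extinction_table()
  st <- hemodynamic_state(3e-5, 2e-5)
  mk <- function(t, wl, conv = TRUE)
    data.frame(time = t, wavelength = wl,
               mua = mua_from_state(st, tab, wl), converged = conv)
  fits <- rbind(mk(0:4, 740), mk(0:4, 850))
  ser <- toi_timeseries(fits, tab)
  expect_equal(nrow(ser), 5)
  expect_true(all(abs(ser$toi - 60) < 1e-9))

  fits$converged[fits$time == 2 & fits$wavelength == 740] <- FALSE
  ser2 <- toi_timeseries(fits, tab)
  expect_true(is.na(ser2$toi[ser2$time == 2]))
  expect_true(all(!is.na(ser2$toi[ser2$time != 2])))

  expect_error(toi_timeseries(rbind(mk(0:4, 740), mk(0:3, 850)), tab),
               "unpaired")
})
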