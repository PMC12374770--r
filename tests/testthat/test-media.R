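test_that("layer and medium constructors validate their inputs", {
  expect_error(optical_layer(-0.1, 10), "mua")
  expect_error(optical_layer(0.1, 0), "musp")
  expect_error(optical_layer(0.1, 10, n = 0.9), "'n'")
  expect_error(optical_layer(0.1, 10, thickness = 0), "thickness")
  expect_warning(optical_layer(12, 10), "diffusion approximation")

  top <- optical_layer(0.11, 11.19, thickness = 0.96)
  bot <- optical_layer(0.09, 9.5)
  expect_s3_class(two_layer_medium(top, bot), "two_layer_medium")
  expect_error(two_layer_medium(bot, bot), "finite thickness")
  expect_error(two_layer_medium(top, top), "semi-infinite")
})

test_that("boundary factor A is exact for matched indices and matches the
           standard tissue/air value", {
  expect_identical(boundary_A(1), 1)
  # Fresnel-integral value for n_rel = 1.4 (internal reflection factor)
  expect_equal(boundary_A(1.4), 2.945, tolerance = 0.02)
  expect_gt(boundary_A(1.5), boundary_A(1.3)) # grows with the mismatch
})

test_that("medium configuration files round-trip through YAML", {
  med <- std_medium()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_medium_config(med, f, rho = 2, wavelength = 740)
  back <- read_medium_config(f)
  expect_equal(back$medium$top$mua, med$top$mua)
  expect_equal(back$medium$top$thickness, med$top$thickness)
  expect_identical(back$medium$bottom$thickness, Inf)
  expect_equal(back$rho, 2)
  expect_equal(back$wavelength, 740)
})

test_that("transients validate values and round-trip through CSV + sidecar", {
  g <- time_grid(5, 100)
  expect_error(transient(g, rep(-1, 100)), ">= 0")
  expect_error(transient(g, rep(0.5, 100), kind = "counts"), "integers")
  tr <- transient(g, rpois(100, 50), kind = "counts", rho = 2,
                  wavelength = 850)
  f <- withr::local_tempfile(fileext = ".csv")
  write_transient(tr, f)
  back <- read_transient(f)
  expect_equal(back$values, tr$values)
  expect_equal(back$grid$centers, tr$grid$centers)
  expect_identical(back$kind, "counts")
  expect_equal(back$wavelength, 850)
})
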