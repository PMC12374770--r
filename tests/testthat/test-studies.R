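test_that("study reports are byte-identical under identical configuration
           and their summaries recompute from the tables", {
  run <- function() run_recovery_study(seeds = 1:2, total_counts = 3e5,
                                       t_end = 4, n_bins = 160, nquad = 192)
  a <- run()
  b <- run()
  expect_identical(a$table, b$table)
  expect_identical(a$summary, b$summary)
  expect_equal(a$summary$median_rel_err_pct, median(a$table$rel_err_mua2_pct))
  expect_true(all(a$table$converged))

  d <- withr::local_tempdir()
  write_study_report(a, d)
  expect_true(file.exists(file.path(d, "recovery_table.csv")))
  expect_true(file.exists(file.path(d, "recovery_summary.json")))
  back <- read.csv(file.path(d, "recovery_table.csv"))
  expect_equal(back$rel_err_mua2_pct, a$table$rel_err_mua2_pct)
})

test_that("noise-free CW and TD pipelines are both model-consistent", {
  rep <- run_cw_vs_td_study(seeds = 1, noise = FALSE, n_bins = 160,
                            t_end = 4, nquad = 192)
  expect_true(all(rep$table$err_td_pct < 0.5))
  expect_true(all(rep$table$err_cw_pct < 0.5))
  pc <- rep$summary$per_condition
  expect_identical(nrow(pc), 5L)
  # summary recomputes from the per-seed table
  agg <- aggregate(err_td_pct ~ toi, rep$table, median)
  expect_equal(pc$median_err_td_pct, agg$err_td_pct)
})

test_that("a flat hemodynamic trajectory yields a flat, in-range TOI
           series", {
  rep <- run_occlusion_demo(seeds = 1, frame_period = 60, duration = 240,
                            counts_per_frame = 1e6, n_bins = 160, t_end = 4,
                            nquad = 192, flat = TRUE)
  ser <- rep$series
  expect_true(all(!is.na(ser$toi)))
  expect_true(all(ser$toi >= 0 & ser$toi <= 100))
  # flat to within the per-frame estimation noise at this photon budget
  expect_lt(max(abs(ser$toi - 60)), 5)
  expect_lt(diff(range(ser$toi)), 5)
})

test_that("the occlusion protocol is recovered: TOI minimum inside the
           occlusion and the overshoot right after release", {
  rep <- run_occlusion_demo(seeds = 1, frame_period = 30, duration = 320,
                            counts_per_frame = 1e6, n_bins = 160, t_end = 4,
                            nquad = 192,
                            t_occl_on = 60, t_occl_off = 180,
                            t_overshoot = 20, t_recovered = 100)
  expect_identical(rep$summary$n_ordering_ok, 1L)
  ser <- rep$series
  expect_true(all(ser$toi >= 0 & ser$toi <= 100, na.rm = TRUE))
  # tracks the programmed trajectory closely at this photon budget
  expect_lt(median(abs(ser$toi - ser$toi_true), na.rm = TRUE), 3)
})
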