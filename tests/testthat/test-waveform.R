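test_that("waveform hits its extremes and is periodic and positive", {
  wf <- synth_waveform()
  # the constructor normalizes extremes on this grid; by construction they
  # are hit exactly there
  tt <- seq(0, wf$period, length.out = 8193)[-8193]
  u <- wf$u_fun(tt)
  expect_equal(max(u), wf$u_peak, tolerance = 1e-12)
  expect_equal(min(u), wf$u_dia, tolerance = 1e-12)
  expect_true(all(u > 0))
  expect_lt(abs(wf$u_fun(0) - wf$u_fun(wf$period)), 1e-12)
  # peak value attained at the detected peak-systole marker
  expect_equal(wf$u_fun(wf$phases[["t_peak_sys"]]), wf$u_peak,
               tolerance = 1e-6)
  # stored cycle mean matches an independent quadrature of the signal
  expect_equal(mean(wf$u_fun(seq(0, wf$period, length.out = 20001)[-20001])),
               wf$u_cycle_mean, tolerance = 1e-6)
})

test_that("phase markers are strictly ordered within one period", {
  for (sf in c(0.25, 0.35, 0.45)) {
    wf <- synth_waveform(systole_fraction = sf)
    ph <- wf$phases
    expect_true(all(diff(ph) > 0))
    expect_lt(ph[["t_early_dia"]] - ph[["t_max_accel"]], wf$period)
  }
})

test_that("markers are stable under 10x finer resampling", {
  wf <- synth_waveform(n_samples = 256)
  fine_n <- 2560
  tt <- seq(0, wf$period, length.out = fine_n + 1)[seq_len(fine_n)]
  ph_fine <- detect_phases(tt, wf$u_fun(tt), wf$period)
  drift <- abs(ph_fine - wf$phases) %% wf$period
  drift <- pmin(drift, wf$period - drift)
  expect_true(all(drift < wf$period / 256))
})

test_that("degenerate waveforms are rejected", {
  expect_error(synth_waveform(u_dia = 0.4, u_peak = 0.4), "constant")
  expect_error(synth_waveform(u_dia = -0.1), "positive")
  expect_error(synth_waveform(n_samples = 32), "64")
  expect_error(detect_phases(1:100 / 100, rep(1, 100), 1), "constant")
})

test_that("waveform CSV export is a two-column time/velocity table", {
  wf <- synth_waveform(n_samples = 64)
  f <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(wf, f)
  d <- read.csv(f)
  expect_named(d, c("time", "u_mean"))
  expect_equal(nrow(d), 64)
  expect_equal(d$u_mean, wf$u_mean, tolerance = 1e-12)
})
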