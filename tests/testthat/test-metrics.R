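test_that("window statistics on analytic series are exact", {
  tt <- seq(0, 48, by = 0.01)
  tr <- synthetic_trajectory(tt, rep(2, length(tt)))
  ws <- window_stats(tr, "eda", c(0, 24), reference = 2)
  expect_equal(ws$mean, 2)
  expect_equal(ws$median, 2)
  expect_equal(ws$sd, 0)
  expect_equal(ws$mean_pct, 0)
  expect_equal(ws$median_pct, 0)

  tr3 <- synthetic_trajectory(c(1, 2, 3), c(1, 2, 3))
  expect_equal(window_stats(tr3, "eda", c(0, 3))$median, 2)

  # percent-above transform is affine and order-preserving
  a <- window_stats(tr, "eda", c(0, 24), reference = 1)
  expect_equal(a$mean_pct, 100)
  # sd is invariant to the reference shift
  expect_equal(a$sd, ws$sd)
})

test_that("moving statistics of periodic series are flat after one window", {
  tt <- seq(0, 96, by = 0.02)
  tr <- synthetic_trajectory(tt, sin(2 * pi * tt / 24) + 2)
  mv <- moving_window_stats(tr, "eda", width = 24, stride = 1)
  expect_lt(diff(range(mv$mean)), 1e-6)
  expect_lt(diff(range(mv$median)), 1e-4)

  trc <- synthetic_trajectory(tt, rep(1.5, length(tt)))
  mvc <- moving_window_stats(trc, "eda", width = 24, stride = 1)
  expect_true(all(mvc$mean == 1.5 & mvc$sd == 0))
})

test_that("peak timing recovers the maximum of a known periodic signal", {
  tt <- seq(0, 72, by = 0.01)
  # the TH forcing curve itself peaks 18 h into the day
  tr <- synthetic_trajectory(tt, c_th(tt))
  expect_equal(peak_time_in_cycle(tr, "eda"), 18, tolerance = 1e-4)
  # non-periodic input warns and falls back to the final-cycle argmax
  tr2 <- synthetic_trajectory(tt, tt / 10)
  expect_warning(peak_time_in_cycle(tr2, "eda"), "not cycle-periodic")
})

test_that("period and amplitude estimates are exact on sinusoids", {
  for (per in c(1, 4.6, 12)) {
    tt <- seq(0, 12 * per, by = 0.005)
    tr <- synthetic_trajectory(tt, sin(2 * pi * tt / per))
    os <- estimate_period_amplitude(tr, "eda", discard = per)
    expect_true(os$oscillatory)
    expect_equal(os$period, per, tolerance = 5e-3)
    expect_equal(os$amplitude, 2, tolerance = 1e-3)
  }
})

test_that("trajectories relaxing to a fixed point are declared non-oscillatory", {
  tt <- seq(0, 100, by = 0.01)
  tr <- synthetic_trajectory(tt, 1 + 1e-3 * exp(-tt) * sin(2 * pi * tt / 4))
  os <- estimate_period_amplitude(tr, "eda", discard = 60)
  expect_false(os$oscillatory)
  expect_equal(os$amplitude, 0)

  # a short record with visible cycles but fewer than 3 peaks is an error
  tts <- seq(0, 7, by = 0.01)
  trs <- synthetic_trajectory(tts, sin(2 * pi * tts / 4))
  expect_error(estimate_period_amplitude(trs, "eda"), "fewer than 3 peaks")
})

test_that("vesicular fraction behaves across its domain", {
  expect_equal(vesicular_fraction(c(cda = 1, vda = 1)), 0.5)
  expect_equal(vesicular_fraction(c(cda = 0, vda = 5)), 1)
  expect_error(vesicular_fraction(c(cda = 0, vda = 0)), "positive")
})
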