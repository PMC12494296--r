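test_that("an equilibrium initial state stays put without forcing", {
  mod <- model_nofc()
  eq <- eq_nominal()
  tr <- integrate_model(mod, c(0, 24), init = eq, dt_out = 0.1)
  for (v in c("ldopa", "cda", "vda", "eda"))
    expect_lt(max(abs(tr[[v]] - eq[[v]])) / eq[[v]], 1e-6)
})

test_that("trajectories remain non-negative and converge to the equilibrium", {
  mod <- model_nofc()
  eq <- eq_nominal()
  tr <- integrate_model(mod, c(0, 50), init = eq * c(3, 0.2, 0.5, 4),
                        dt_out = 0.05, settings = fast_settings)
  expect_true(all(as.matrix(tr[c("ldopa", "cda", "vda", "eda")]) >= 0))
  end <- as.numeric(tr[nrow(tr), c("ldopa", "cda", "vda", "eda")])
  expect_equal(end, as.numeric(eq), tolerance = 1e-4)
})

test_that("the forced trajectory is 24 h-periodic after burn-in", {
  tr <- run_protocol(model_circ(), days = 2, burn_in = 240, dt_out = 0.02)
  for (v in c("ldopa", "cda", "vda", "eda")) {
    x1 <- tr[[v]][tr$time <= 24 + 1e-9]
    x2 <- tr[[v]][tr$time >= 24 - 1e-9]
    k <- min(length(x1), length(x2))
    expect_lt(max(abs(x1[1:k] - x2[1:k])) / max(x1), 1e-4)
  }
})

test_that("dose events restart the integrator with an exact occupancy jump", {
  mod <- model_circ()
  sch <- dose_schedule(0.5, times = 18, half_life = 15)
  tr <- run_protocol(mod, schedule = sch, days = 2, burn_in = 240,
                     dt_out = 0.01)
  # occupancy column reflects the closed form, jump included
  expect_identical(max(tr$x_dose), 0.5)
  i <- which(tr$time == 18)
  expect_length(i, 1L)
  expect_identical(tr$x_dose[i], 0.5)
  expect_equal(tr$x_dose[i - 1], 0, tolerance = 1e-12)
  # eda rises sharply right after the dose
  post <- tr$eda[tr$time > 18 & tr$time <= 19]
  pre <- tr$eda[tr$time == 18]
  expect_gt(max(post) / pre, 1.1)
})

test_that("results self-converge under tolerance refinement", {
  mod <- model_circ()
  sch <- dose_schedule(0.5, times = 6, half_life = 15)
  med <- sapply(list(solver_settings(rel_tol = 1e-6, abs_tol = 1e-8),
                     solver_settings(rel_tol = 1e-9, abs_tol = 1e-11)),
                function(st) {
    tr <- run_protocol(mod, schedule = sch, days = 2, burn_in = 48,
                       settings = st, dt_out = 0.01)
    window_stats(tr, "eda", c(6, 30))$median
  })
  expect_lt(abs(med[1] - med[2]) / med[2], 1e-3)
})

test_that("uniform resampling preserves constants, medians and grid size", {
  tt <- seq(0, 48, by = 0.01)
  tr <- synthetic_trajectory(tt, rep(3.5, length(tt)))
  rs <- resample_uniform(tr, 0.5)
  expect_true(all(rs$eda == 3.5))
  expect_equal(nrow(rs), 48 / 0.5 + 1)
  expect_error(resample_uniform(tr, 100), "span")

  # grid-refinement: medians from dt and dt/2 agree closely
  mod <- model_circ()
  tr <- run_protocol(mod, days = 1, burn_in = 120, dt_out = 0.02)
  m1 <- window_stats(resample_uniform(tr, 0.02), "eda", c(0, 24))$median
  m2 <- window_stats(resample_uniform(tr, 0.01), "eda", c(0, 24))$median
  expect_lt(abs(m1 - m2) / m2, 5e-4)
})
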