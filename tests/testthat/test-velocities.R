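p_tab <- reduced_params()

test_that("autoreceptor factor is normalised, bounded and decreasing", {
  cal <- autoreceptor_calibration()
  # exactly 1 at the reference steady-state eda
  expect_equal(autoreceptor_factor(cal$eda_ref, cal), 1, tolerance = 1e-9)
  # limits: b as eda -> Inf, a/d + b at eda = 0
  expect_equal(autoreceptor_factor(1e6, cal), cal$b, tolerance = 1e-6)
  expect_equal(autoreceptor_factor(0, cal), cal$a / cal$d + cal$b)
  # strictly decreasing
  ee <- seq(0, 0.02, by = 1e-4)
  expect_true(all(diff(autoreceptor_factor(ee, cal)) < 0))
  expect_error(autoreceptor_factor(-1e-3, cal), "non-negative")

  # the unnormalised classic coefficients give ~1.0613 at eda = 0
  cal2 <- autoreceptor_calibration(a = 4.58, b = 0.5)
  expect_equal(cal2$d, 8.16, tolerance = 1e-12)
  expect_equal(autoreceptor_factor(0, cal2), 4.58 / 8.16 + 0.5)
  expect_equal(autoreceptor_factor(cal2$eda_ref, cal2), 1, tolerance = 1e-9)
})

test_that("TH velocity follows the three-factor closed form", {
  # at the printed equilibrium cda with unit feedback:
  # 0.56/(1 + 126/160) * Vmax 125*126*319 / denominator = 0.3133 * 87.09
  v <- v_th(2.65, factor = 1, params = p_tab, cth = 1)
  expect_equal(v, 0.3133 * 87.09, tolerance = 2e-3)
  # balances the AADC flux at the steady-state ldopa within 2%
  expect_equal(v, v_aadc(0.3557, p_tab), tolerance = 0.02)
  # vanishes as cda diverges; scales linearly in the circadian multiplier
  expect_lt(v_th(1e9, 1, p_tab), 1e-3)
  expect_equal(v_th(2.65, 1, p_tab, cth = 1.25), 1.25 * v)
  expect_error(v_th(-1, 1, p_tab), "non-negative")
})

test_that("Michaelis-Menten velocities match their closed forms", {
  # AADC: zero at zero substrate, half-saturation at Km, ~30 uM/hr near
  # the steady-state ldopa
  expect_identical(v_aadc(0, p_tab), 0)
  expect_equal(v_aadc(130, p_tab), 5000)
  expect_equal(v_aadc(0.36, p_tab), 10000 * 0.36 / 130.36)
  expect_equal(v_aadc(0.36, p_tab), 30, tolerance = 0.1)

  # MAT: net of forward packaging and vesicular leak; ~80 uM/hr at the
  # nominal equilibrium, negative when leak dominates
  expect_identical(v_mat(0, 0, p_tab), 0)
  expect_equal(v_mat(0, 1, p_tab), -40)
  expect_equal(v_mat(2.65, 80.96, p_tab), 80, tolerance = 0.05)

  # DAT: ~80.15 uM/hr at the reference eda; blockade and zero substrate
  expect_equal(v_dat(0.002024, p_tab, s = 1), 8000 * 0.002024 / 0.202024)
  expect_identical(v_dat(0.5, p_tab, s = 0), 0)
  expect_identical(v_dat(0, p_tab), 0)
  expect_error(v_dat(0.5, p_tab, s = 1.2), "\\[0, 1\\]")

  # catabolism: linear in the MAO multiplier
  expect_equal(v_catab(0.002024, p_tab), 30 * 0.002024 / 3.002024)
  expect_identical(v_catab(0, p_tab), 0)
  expect_equal(v_catab(0.1, p_tab, cmao = 0.75),
               0.75 * v_catab(0.1, p_tab))
})

test_that("derivatives satisfy the internal-transport cancellation identity", {
  mod <- model_nofc()
  set.seed(42)
  for (i in 1:20) {
    st <- c(ldopa = runif(1, 0, 2), cda = runif(1, 0, 10),
            vda = runif(1, 0, 150), eda = runif(1, 0, 0.05))
    dv <- model_derivatives(mod, st, velocities = TRUE)
    v <- dv$velocities
    # cda' + vda' + eda' = VAADC - k_cda cda - VCATAB - k_eda eda
    expect_equal(sum(dv$deriv[c("cda", "vda", "eda")]),
                 v[["v_aadc"]] - 10 * st[["cda"]] - v[["v_catab"]] -
                   400 * st[["eda"]],
                 tolerance = 1e-9)
  }
})

test_that("doubling the firing rate instantaneously raises eda from rest", {
  mod <- model_nofc()
  eq <- eq_nominal()
  mod2 <- model_nofc(fire = 2)
  d <- model_derivatives(mod2, eq)
  expect_gt(d[["eda"]], 0)
  expect_error(model_derivatives(mod, eq - 1), "non-negative")
})
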