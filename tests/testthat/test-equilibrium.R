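test_that("nominal equilibrium reproduces the published steady state", {
  eq <- eq_nominal()
  expect_equal(eq[["ldopa"]], 0.36, tolerance = 0.015)
  expect_equal(eq[["cda"]], 2.65, tolerance = 0.005)
  expect_equal(eq[["vda"]], 80.96, tolerance = 5e-4)
  expect_equal(eq[["eda"]], 0.002024, tolerance = 5e-4)
  expect_lt(attr(eq, "residual"), 1e-10)
  # equilibrium identity: derivatives vanish when plugged back in
  d <- model_derivatives(model_nofc(), eq)
  expect_lt(max(abs(d)), 1e-8)
})

test_that("independent damped-Newton root finder agrees with the scalar solve", {
  # oracle: full 4-dimensional Newton iteration on the vector field with
  # the finite-difference Jacobian, started from a rounded guess
  mod <- model_nofc()
  y <- c(0.4, 2.5, 80, 0.002)
  for (it in 1:50) {
    f <- as.numeric(model_derivatives(mod, y))
    if (max(abs(f)) < 1e-12) break
    J <- numeric_jacobian(mod, y)
    y <- pmax(y - solve(J, f), 1e-12)
  }
  expect_equal(as.numeric(eq_nominal()), unname(y), tolerance = 1e-8)
})

test_that("reuptake inhibition raises equilibrium eda", {
  mod <- model_nofc()
  e1 <- find_equilibrium(mod, s_dat = 1)[["eda"]]
  e05 <- find_equilibrium(mod, s_dat = 0.5)[["eda"]]
  expect_gt(e05, e1)
})

test_that("equilibrium AADC flux is invariant to AADC capacity", {
  # doubling Vmax_ldopa leaves the flux balance unchanged: the
  # equilibrium AADC velocity is set by the TH side, and ldopa roughly
  # halves to compensate (far from saturation)
  mod <- model_nofc()
  mod2 <- model_nofc(params = reduced_params(Vmax_ldopa = 20000))
  eq1 <- find_equilibrium(mod)
  eq2 <- find_equilibrium(mod2)
  expect_equal(v_aadc(eq2[["ldopa"]], mod2$params),
               v_aadc(eq1[["ldopa"]], mod$params), tolerance = 1e-6)
  expect_equal(eq2[["ldopa"]] / eq1[["ldopa"]], 0.5, tolerance = 0.01)
  expect_equal(eq2[["eda"]], eq1[["eda"]], tolerance = 1e-6)
})

test_that("autoreceptors buffer equilibrium eda against firing-rate changes", {
  hf <- homeostasis_firing(model_nofc(), fire_grid = c(1, 2))
  # without autoreceptors: ~proportional response (2x firing -> ~2x eda)
  expect_equal(hf$pct_noauto[2], 200, tolerance = 0.05)
  # with autoreceptors: strongly damped
  expect_lt(hf$pct_auto[2], 150)
})

test_that("analytic Jacobian matches central finite differences", {
  mod <- model_nofc()
  eq <- eq_nominal()
  J <- model_jacobian(mod, eq)
  Jn <- numeric_jacobian(mod, eq)
  expect_lt(max(abs(J - Jn) / (abs(Jn) + 1e-4)), 1e-6)

  # also at a non-equilibrium point with frozen forcing
  st <- c(0.5, 3, 60, 0.004)
  J <- model_jacobian(mod, st, cth = 1.2, cmao = 0.8, s_dat = 0.6)
  Jn <- numeric_jacobian(mod, st, cth = 1.2, cmao = 0.8, s_dat = 0.6)
  expect_lt(max(abs(J - Jn) / (abs(Jn) + 1e-4)), 1e-6)

  # release term enters the eda row linearly with slope fire
  expect_equal(J["eda", "vda"], 1)
})

test_that("eigenvalues satisfy the characteristic polynomial", {
  mod <- model_circ()
  rep <- equilibrium_report(mod, s_dat = 0.7, phase = 9)
  J <- rep$jacobian
  n <- nrow(J)
  for (lam in rep$eigenvalues) {
    expect_lt(Mod(det(J - lam * diag(n))), 1e-8 * norm(J, "F")^n)
  }
})

test_that("DUO equilibrium satisfies the linear-chain balance", {
  dm <- duo_model(duo_preset("dat_sensitive", s_dat = 0.5))
  eq <- find_equilibrium(dm)
  dp <- dm$duo
  expect_equal(eq[["edapool"]],
               dp$k1_pool / dp$k2_pool * eq[["eda"]], tolerance = 1e-10)
  expect_equal(eq[["D2"]],
               dp$k3_pool / dp$k4_pool * eq[["edapool"]], tolerance = 1e-10)
  expect_lt(attr(eq, "residual"), 1e-10)

  # pool rows of the Jacobian are the constant linear coefficients
  J <- model_jacobian(dm, eq, s_dat = 0.5)
  expect_equal(J["edapool", "eda"], dp$k1_pool)
  expect_equal(J["edapool", "edapool"], -dp$k2_pool)
  expect_equal(J["D2", "edapool"], dp$k3_pool)
  expect_equal(J["D2", "D2"], -dp$k4_pool)
  # small step: the D2 sigmoid is steep (m = 0.01) at a large D2 value
  Jn <- numeric_jacobian(dm, eq, s_dat = 0.5, h = 1e-9)
  expect_lt(max(abs(J - Jn) / (abs(Jn) + 1e-4)), 1e-5)
})
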