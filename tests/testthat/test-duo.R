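test_that("the D2 sigmoid has the stated midpoint, limits and adaptation", {
  dp <- duo_preset("dat_sensitive")
  mid <- dp$gamma * (2 - dp$s_dat)
  expect_equal(a_of_d2(mid, dp), dp$alpha + dp$beta / 2)
  # plateaus, evaluated overflow-safely at extreme arguments
  expect_equal(a_of_d2(1e9, dp), dp$alpha)
  expect_equal(a_of_d2(0, dp), dp$alpha + dp$beta)
  expect_false(any(is.nan(a_of_d2(c(-1e8, 0, 1e8), dp))))
  # strictly decreasing in D2
  d2 <- seq(mid - 0.2, mid + 0.2, length.out = 101)
  expect_true(all(diff(a_of_d2(d2, dp)) < 0))
  # lowering s_dat shifts the midpoint right by gamma * delta
  expect_equal(a_of_d2(mid + dp$gamma * 0.5, dp, s_dat = 0.5),
               dp$alpha + dp$beta / 2)
})

test_that("DUO presets carry the published coupling constants", {
  a <- duo_preset("ultradian")
  expect_equal(unlist(a[c("k1_pool", "k2_pool", "k3_pool", "k4_pool",
                          "alpha", "beta", "gamma", "m")]),
               c(k1_pool = 4519.93, k2_pool = 0.38, k3_pool = 22.3,
                 k4_pool = 2.34, alpha = 0.5, beta = 0.5,
                 gamma = 193.93, m = 1.1))
  b <- duo_preset("dat_sensitive")
  expect_equal(unlist(b[c("k1_pool", "k2_pool", "k3_pool", "k4_pool",
                          "alpha", "beta", "gamma", "m")]),
               c(k1_pool = 21118.5, k2_pool = 1.89, k3_pool = 34.45,
                 k4_pool = 0.47, alpha = 0.5, beta = 4.5,
                 gamma = 2139.25, m = 0.01))
  expect_error(duo_params(k1_pool = -1, k2_pool = 1, k3_pool = 1,
                          k4_pool = 1, alpha = 1, beta = 1, gamma = 1,
                          m = 1), "positive")
  expect_error(duo_preset("ultradian", s_dat = 1.4), "\\[0, 1\\]")
})

test_that("a weakly coupled pool decouples the oscillator", {
  # with negligible pool input the latent variables drain to zero and the
  # first four equations reduce to a constant-factor reduced model
  dp <- duo_params(k1_pool = 1e-9, k2_pool = 1, k3_pool = 1, k4_pool = 1,
                   alpha = 0.5, beta = 0.5, gamma = 193.93, m = 1.1)
  dm <- duo_model(dp)
  st <- c(as.numeric(eq_nominal()), edapool = 0.2, D2 = 0.5)
  d <- model_derivatives(dm, st)
  expect_lt(d[["edapool"]], 0)
  expect_lt(d[["D2"]], 0)
})

test_that("Latin hypercube designs are stratified, bounded and reproducible", {
  n <- 10
  s1 <- lhs_sample_duo(n, seed = 7)
  s2 <- lhs_sample_duo(n, seed = 7)
  s3 <- lhs_sample_duo(n, seed = 8)
  expect_identical(attr(s1, "design"), attr(s2, "design"))
  expect_false(identical(attr(s1, "design"), attr(s3, "design")))

  # every parameter occupies n distinct equal-probability strata
  u <- attr(s1, "design")
  for (j in seq_len(ncol(u)))
    expect_setequal(findInterval(u[, j], seq(0, 1, length.out = n + 1),
                                 rightmost.closed = TRUE), seq_len(n))

  # mapped values honour the printed bounds
  rg <- lhs_ranges()
  for (nm in names(rg)) {
    vals <- vapply(s1, function(p) p[[nm]], numeric(1))
    expect_true(all(vals >= rg[[nm]][1] & vals <= rg[[nm]][2]))
  }
})

test_that("limit-cycle screening keeps only oscillatory parameter sets", {
  # small LHS batch classified by integration; retained sets must show
  # sustained oscillations when re-examined over a longer horizon
  samples <- lhs_sample_duo(6, seed = 3)
  classify <- function(dp, hours) {
    m <- duo_model(dp)
    eq <- tryCatch(find_equilibrium(m), error = function(e) NULL)
    if (is.null(eq)) return(FALSE)
    tr <- integrate_model(m, c(0, hours), init = eq * 1.05,
                          settings = fast_settings, dt_out = 0.02)
    os <- tryCatch(estimate_period_amplitude(tr, "eda",
                                             discard = hours / 2),
                   error = function(e) list(oscillatory = FALSE))
    isTRUE(os$oscillatory) && os$amplitude > 1e-6
  }
  keep <- vapply(samples, classify, logical(1), hours = 96)
  expect_length(keep, length(samples))
  for (dp in samples[keep])
    expect_true(classify(dp, hours = 192))
})
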