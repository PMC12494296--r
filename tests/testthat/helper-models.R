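# shared fixtures: models and solver settings reused across test files

model_nofc <- function(...) {
  dopamine_model(circadian = circadian_config(enabled = FALSE), ...)
}

model_circ <- function(...) dopamine_model(...)

# nominal drug-free, circadian-free equilibrium (computed once per run)
eq_nominal <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- find_equilibrium(model_nofc())
    val
  }
})

# moderately relaxed tolerances for tests that only need qualitative
# trajectories, to keep the suite fast
fast_settings <- solver_settings(rel_tol = 1e-7, abs_tol = 1e-9)

# build a synthetic uniform trajectory around an analytic signal
synthetic_trajectory <- function(times, values, variable = "eda") {
  df <- data.frame(time = times)
  df[[variable]] <- values
  dt <- times[2] - times[1]
  structure(df, class = c("da_trajectory", "data.frame"),
            model = model_nofc(), schedule = NULL, dt = dt, uniform = TRUE)
}
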