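#' Nominal steady-state reference concentration
#'
#' The drug-free, circadian-free equilibrium of the model, used as the
#' reference level ("percent above steady state") in all dose metrics.
#'
#' @param model a \code{\link{dopamine_model}}.
#' @param variable state variable name.
#' @return Reference concentration (uM).
#' @export
nominal_reference <- function(model, variable = "eda") {
  find_equilibrium(model, cth = 1, cmao = 1)[[variable]]
}

# forced limit cycle of the drug-free model, burnt in, covering [0, hours];
# shared starting point for the dose-timing experiments
drug_free_cycle <- function(model, hours = 24, burn_in = 240,
                            settings = solver_settings(), dt_out = 0.01) {
  run_protocol(model, schedule = NULL, days = ceiling(hours / 24),
               burn_in = burn_in, settings = settings, dt_out = dt_out)
}

#' Dose-timing sweep for a single DRI administration
#'
#' For each dose size and administration time, applies a single dose on
#' the burnt-in circadian limit cycle and summarises extracellular
#' dopamine over the following 24 hours (half-open window), as percent
#' above the nominal steady state.  The burn-in is shared across all dose
#' times: each run restarts from the limit-cycle state at its own
#' administration time.
#'
#' @param model a \code{\link{dopamine_model}} with circadian forcing on.
#' @param doses initial DAT occupancy fraction(s) in [0, 1].
#' @param dose_times administration times in hours (circadian time).
#' @param half_life drug half-life in hours.
#' @param burn_in spin-up before the first possible dose (hours).
#' @param dt_out output grid spacing for the statistics.
#' @param settings a \code{\link{solver_settings}}.
#' @return Long-format data frame with one row per (dose, dose_time):
#'   window statistics of eda and their percent-above-steady-state
#'   transforms.
#' @export
dose_time_sweep <- function(model, doses = 0.5,
                            dose_times = seq(0, 24, by = 0.5),
                            half_life = 15, burn_in = 240, dt_out = 0.01,
                            settings = solver_settings()) {
  ref <- nominal_reference(model, "eda")
  base <- drug_free_cycle(model, hours = max(dose_times) + 1e-9,
                          burn_in = burn_in, settings = settings,
                          dt_out = dt_out)
  sn <- state_names(model)
  rows <- list()
  for (dose in doses) {
    for (td in dose_times) {
      i0 <- which.min(abs(base$time - td))
      init <- as.numeric(base[i0, sn])
      if (dose > 0) {
        sch <- dose_schedule(dose, times = td, half_life = half_life)
      } else {
        sch <- NULL
      }
      tr <- integrate_model(model, c(td, td + 24), init = init,
                            schedule = sch, settings = settings,
                            dt_out = dt_out)
      ws <- window_stats(tr, "eda", window = c(td, td + 24),
                         reference = ref)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(dose = dose, dose_time = td,
                         half_life = half_life), ws)
    }
  }
  do.call(rbind, rows)
}

#' Repeated daily dosing experiment
#'
#' Administers the same dose at the same circadian time each day for
#' \code{days} days on the burnt-in limit cycle, and returns the
#' trajectory together with trailing 24-hour moving statistics and the
#' peak excursion of eda relative to the nominal steady state.
#'
#' @inheritParams dose_time_sweep
#' @param dose initial DAT occupancy per administration.
#' @param dose_time daily administration time in [0, 24).
#' @param days number of daily doses.
#' @return List with elements \code{trajectory} (\code{da_trajectory}),
#'   \code{moving} (moving-window statistics of eda, percent columns
#'   included), \code{peak_pct} (max eda excursion, percent above steady
#'   state) and \code{reference}.
#' @export
repeated_dose_experiment <- function(model, dose = 0.2, dose_time = 18,
                                     days = 7, half_life = 15,
                                     burn_in = 240, dt_out = 0.01,
                                     settings = solver_settings()) {
  stopifnot(dose_time >= 0, dose_time < 24, days >= 1)
  ref <- nominal_reference(model, "eda")
  sch <- dose_schedule(dose, times = dose_time + 24 * (seq_len(days) - 1),
                       half_life = half_life)
  tr <- run_protocol(model, schedule = sch, days = days + 1,
                     burn_in = burn_in, settings = settings,
                     dt_out = dt_out)
  post <- tr$time > dose_time
  peak_pct <- (max(tr$eda[post]) / ref - 1) * 100
  mv <- moving_window_stats(tr, "eda", width = 24, reference = ref)
  list(trajectory = tr, moving = mv, peak_pct = peak_pct, reference = ref)
}

#' Mean eda surface over drug half-life and dose
#'
#' Repeated daily dosing at a fixed circadian time for a grid of
#' half-lives and doses; reports mean extracellular dopamine over the
#' whole protocol, relative to the nominal steady state.
#'
#' @inheritParams repeated_dose_experiment
#' @param half_lives vector of half-lives (hours).
#' @param doses vector of dose fractions in [0, 1].
#' @return Data frame with columns \code{half_life, dose, mean_eda,
#'   mean_pct}.
#' @export
halflife_dose_grid <- function(model, half_lives = seq(1, 24, length.out = 6),
                               doses = seq(0, 1, length.out = 6),
                               dose_time = 6, days = 7, burn_in = 240,
                               dt_out = 0.02,
                               settings = solver_settings()) {
  ref <- nominal_reference(model, "eda")
  sn <- state_names(model)
  base <- drug_free_cycle(model, hours = 24, burn_in = burn_in,
                          settings = settings, dt_out = dt_out)
  i0 <- which.min(abs(base$time - dose_time))
  init <- as.numeric(base[i0, sn])
  times <- dose_time + 24 * (seq_len(days) - 1)
  rows <- list()
  for (hl in half_lives) {
    for (dose in doses) {
      sch <- if (dose > 0) dose_schedule(dose, times, half_life = hl)
        else NULL
      tr <- integrate_model(model, c(dose_time, dose_time + 24 * days),
                            init = init, schedule = sch,
                            settings = settings, dt_out = dt_out)
      m <- mean(tr$eda[tr$time > dose_time])
      rows[[length(rows) + 1L]] <-
        data.frame(half_life = hl, dose = dose, mean_eda = m,
                   mean_pct = (m / ref - 1) * 100)
    }
  }
  do.call(rbind, rows)
}

#' Homeostatic response of equilibrium eda to firing rate
#'
#' Steady-state extracellular dopamine as a function of a constant
#' release-rate multiplier, with the autoreceptor feedback active and with
#' the factor pinned to 1.  Without autoreceptors eda scales essentially
#' in proportion to firing rate; with them the response is strongly
#' damped.
#'
#' @param model a \code{\link{dopamine_model}}.
#' @param fire_grid positive release-rate multipliers.
#' @return Data frame with columns \code{fire, eda_auto, eda_noauto,
#'   pct_auto, pct_noauto} (percent of the respective nominal value).
#' @export
homeostasis_firing <- function(model, fire_grid = seq(0.5, 2, by = 0.25)) {
  m_no <- model; m_no$autoreceptors <- FALSE
  ref_a <- find_equilibrium(model, fire = 1)[["eda"]]
  ref_n <- find_equilibrium(m_no, fire = 1)[["eda"]]
  rows <- lapply(fire_grid, function(f) {
    ea <- find_equilibrium(model, fire = f)[["eda"]]
    en <- find_equilibrium(m_no, fire = f)[["eda"]]
    data.frame(fire = f, eda_auto = ea, eda_noauto = en,
               pct_auto = ea / ref_a * 100, pct_noauto = en / ref_n * 100)
  })
  do.call(rbind, rows)
}

#' Equilibrium eda over a TH x DAT maximal-activity grid
#'
#' Scales the maximal velocities of the TH and DAT reactions over a grid
#' (fractions of nominal, e.g. 0 to 1.5) and records the equilibrium
#' extracellular dopamine as percent of its nominal value.  Grid points
#' with no feasible equilibrium are flagged with NA.
#'
#' @param model a \code{\link{dopamine_model}}.
#' @param th_scales,dat_scales non-negative multipliers on
#'   \code{Vmax_tyr} and \code{Vmax_eda}.
#' @return Data frame with columns \code{th_scale, dat_scale, eda,
#'   eda_pct}.
#' @export
homeostasis_vmax_grid <- function(model,
                                  th_scales = seq(0.25, 1.5, by = 0.25),
                                  dat_scales = seq(0.25, 1.5, by = 0.25)) {
  ref <- find_equilibrium(model)[["eda"]]
  rows <- list()
  for (a in th_scales) {
    for (b in dat_scales) {
      m <- model
      m$params$Vmax_tyr <- model$params$Vmax_tyr * a
      m$params$Vmax_eda <- model$params$Vmax_eda * b
      eda <- tryCatch(find_equilibrium(m)[["eda"]],
                      error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(th_scale = a, dat_scale = b, eda = eda,
                   eda_pct = eda / ref * 100)
    }
  }
  do.call(rbind, rows)
}

#' One-at-a-time sensitivity of the DUO oscillation
#'
#' Scales each DUO coupling parameter individually over a range of
#' multipliers, integrates the model, and records the period and
#' amplitude of the eda oscillation over the final recording window.
#' Non-oscillatory points are recorded with amplitude 0, not treated as
#' failures.
#'
#' @param model a \code{\link{duo_model}}.
#' @param scale_range numeric length-2 multiplier range.
#' @param n_scales number of multipliers per parameter.
#' @param sim_days simulated duration per run (days).
#' @param record_days final window used for period/amplitude (days).
#' @param dt_out output grid spacing over the recording window.
#' @param settings a \code{\link{solver_settings}}.
#' @return Data frame with columns \code{parameter, scale, period,
#'   amplitude, oscillatory}.
#' @export
sensitivity_ridge <- function(model, scale_range = c(0.75, 1.25),
                              n_scales = 11, sim_days = 100,
                              record_days = 4, dt_out = 0.01,
                              settings = solver_settings(max_step = 0.5)) {
  pars <- c("k1_pool", "k2_pool", "k3_pool", "k4_pool",
            "alpha", "beta", "gamma", "m")
  scales <- seq(scale_range[1], scale_range[2], length.out = n_scales)
  burn <- (sim_days - record_days) * 24
  rows <- list()
  for (pn in pars) {
    for (sc in scales) {
      m <- model
      m$duo[[pn]] <- model$duo[[pn]] * sc
      eq <- tryCatch(find_equilibrium(m), error = function(e) NULL)
      init <- if (is.null(eq)) NULL else eq * 1.02
      # coarse output over the transient, fine output over the record window
      pre <- integrate_model(m, c(0, burn), init = init,
                             settings = settings, dt_out = 0.25)
      y0 <- as.numeric(pre[nrow(pre), state_names(m)])
      tr <- integrate_model(m, c(burn, burn + record_days * 24),
                            init = y0, settings = settings,
                            dt_out = dt_out)
      os <- tryCatch(
        estimate_period_amplitude(tr, "eda", discard = 0),
        error = function(e)
          list(oscillatory = FALSE, period = NA_real_, amplitude = 0))
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = pn, scale = sc,
                   period = if (os$oscillatory) os$period else NA_real_,
                   amplitude = os$amplitude,
                   oscillatory = os$oscillatory)
    }
  }
  do.call(rbind, rows)
}
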