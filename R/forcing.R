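#' Circadian forcing configuration
#'
#' Sinusoidal multipliers imposed on enzyme activities by the molecular
#' clock: TH activity is multiplied by
#' \code{baseline_th * (amplitude * sin(pi/12 * (t - phase_th)) + 1)} and
#' extracellular catabolism (MAO) by the analogous curve with
#' \code{phase_mao}.  At the defaults both curves range over [0.75, 1.25],
#' TH activity peaks 18 h into the 24-h cycle and MAO activity peaks 8 h
#' later.  The baseline scales support robustness runs with the whole curve
#' shifted to 0.75x or 1.25x of nominal.
#'
#' @param amplitude relative amplitude in [0, 1).
#' @param period forcing period (hours).
#' @param phase_th,phase_mao phase offsets (hours); the sine crosses zero
#'   rising at these times, so each curve peaks a quarter period later.
#' @param baseline_th,baseline_mao multiplicative baseline shifts.
#' @param enabled logical; when \code{FALSE} both multipliers are constant 1.
#' @return Object of class \code{"circadian_config"}.
#' @export
circadian_config <- function(amplitude = 0.25, period = 24,
                             phase_th = 12, phase_mao = 20,
                             baseline_th = 1, baseline_mao = 1,
                             enabled = TRUE) {
  stopifnot(amplitude >= 0, amplitude < 1, period > 0,
            baseline_th > 0, baseline_mao > 0, is.logical(enabled))
  structure(list(amplitude = amplitude, period = period,
                 phase_th = phase_th, phase_mao = phase_mao,
                 baseline_th = baseline_th, baseline_mao = baseline_mao,
                 enabled = enabled),
            class = "circadian_config")
}

#' Circadian multiplier on TH activity
#'
#' @param t time (hours); vectorised.
#' @param cfg a \code{\link{circadian_config}}.
#' @return Dimensionless multiplier(s).
#' @export
c_th <- function(t, cfg = circadian_config()) {
  if (!cfg$enabled) return(rep(1, length(t)))
  cfg$baseline_th *
    (cfg$amplitude * sin(2 * pi / cfg$period * (t - cfg$phase_th)) + 1)
}

#' Circadian multiplier on extracellular catabolism (MAO)
#'
#' @inheritParams c_th
#' @return Dimensionless multiplier(s).
#' @export
c_mao <- function(t, cfg = circadian_config()) {
  if (!cfg$enabled) return(rep(1, length(t)))
  cfg$baseline_mao *
    (cfg$amplitude * sin(2 * pi / cfg$period * (t - cfg$phase_mao)) + 1)
}

#' Dopamine reuptake inhibitor dose schedule
#'
#' Each administration instantaneously occupies an additional fraction
#' \code{dose} of dopamine transporters; occupancy decays exponentially with
#' rate \code{r = log(2) / half_life}.  Times are in circadian time (CT);
#' \code{t = 0} coincides with CT0.
#'
#' @param dose occupancy fraction(s) in [0, 1], recycled to the length of
#'   \code{times}.
#' @param times administration times (hours), non-decreasing.
#' @param half_life drug half-life (hours).
#' @return Object of class \code{"dose_schedule"}.
#' @export
dose_schedule <- function(dose, times, half_life = 15) {
  if (length(times) == 0) {
    dose <- numeric(0)
  } else {
    dose <- rep_len(dose, length(times))
  }
  if (any(dose < 0 | dose > 1)) stop("dose_schedule: doses must lie in [0, 1]")
  if (is.unsorted(times)) stop("dose_schedule: times must be non-decreasing")
  stopifnot(half_life > 0)
  structure(list(dose = as.numeric(dose), times = as.numeric(times),
                 half_life = half_life, r = log(2) / half_life),
            class = "dose_schedule")
}

#' Transporter occupancy trajectory
#'
#' Closed-form solution of the occupancy equation
#' \code{x' = -r x + sum_i Dose_i delta(t - t_i)}: a right-continuous sum of
#' decaying exponentials with a jump of exactly \code{Dose_i} at each
#' administration time.
#'
#' @param schedule a \code{\link{dose_schedule}} (or \code{NULL} for no drug).
#' @param t time(s) in hours.
#' @return Occupancy \code{x_dose(t)} (dimensionless, >= 0); may exceed 1
#'   when doses stack, in which case the effective DAT activity is clamped
#'   at 0 by \code{\link{s_dat_effective}}.
#' @export
x_dose_at <- function(schedule, t) {
  if (is.null(schedule) || length(schedule$times) == 0)
    return(rep(0, length(t)))
  vapply(t, function(ti) {
    on <- schedule$times <= ti
    sum(schedule$dose[on] * exp(-schedule$r * (ti - schedule$times[on])))
  }, numeric(1))
}

#' Effective fractional DAT activity under a dose schedule
#'
#' @inheritParams x_dose_at
#' @param baseline constant baseline DAT activity scaling in [0, 1].
#' @return \code{baseline * max(1 - x_dose(t), 0)}, always in [0, 1].
#' @export
s_dat_effective <- function(schedule, t, baseline = 1) {
  baseline * pmax(1 - x_dose_at(schedule, t), 0)
}
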