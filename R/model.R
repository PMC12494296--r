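#' Reduced four-variable dopamine model
#'
#' Bundles the kinetic parameters, autoreceptor calibration, circadian
#' forcing and release-rate/DAT scaling of the reduced model of dopamine
#' synthesis, vesicular packaging, release and reuptake.  State variables
#' (all uM): levodopa (\code{ldopa}), cytosolic dopamine (\code{cda}),
#' vesicular dopamine (\code{vda}) and extracellular dopamine (\code{eda}).
#'
#' @param params a \code{\link{reduced_params}}.
#' @param calib an \code{\link{autoreceptor_calibration}}.
#' @param circadian a \code{\link{circadian_config}}.
#' @param fire constant vesicular release-rate multiplier (1/hr scale,
#'   nominal 1).
#' @param s_dat constant baseline fractional DAT activity in [0, 1]; dose
#'   schedules multiply this by \code{max(1 - x_dose, 0)}.
#' @param autoreceptors logical; \code{FALSE} pins the autoreceptor factor
#'   to 1 (used in homeostasis comparisons).
#' @return Object of class \code{"dopamine_model"} with \code{kind =
#'   "reduced"}.
#' @examples
#' mod <- dopamine_model(circadian = circadian_config(enabled = FALSE))
#' find_equilibrium(mod)
#' @export
dopamine_model <- function(params = reduced_params(),
                           calib = autoreceptor_calibration(),
                           circadian = circadian_config(),
                           fire = 1, s_dat = 1, autoreceptors = TRUE) {
  stopifnot(inherits(params, "reduced_params"),
            inherits(calib, "autoreceptor_calibration"),
            inherits(circadian, "circadian_config"),
            fire > 0, s_dat >= 0, s_dat <= 1, is.logical(autoreceptors))
  structure(list(kind = "reduced", params = params, calib = calib,
                 circadian = circadian, fire = fire, s_dat = s_dat,
                 autoreceptors = autoreceptors),
            class = "dopamine_model")
}

#' Dopamine Ultradian Oscillator (DUO) model
#'
#' Six-variable extension of the reduced model: local extracellular
#' dopamine feeds a shared pool of dopaminergic tone (\code{edapool}),
#' which drives latent D2 autoreceptor signalling (\code{D2}); the D2
#' signal replaces the eda-based autoreceptor factor inside the TH
#' velocity through the adaptive sigmoid \code{\link{a_of_d2}}.  The DAT
#' activity level \code{s_dat} is a fixed constant of the parameter set,
#' not a decaying dose trajectory.
#'
#' @param params a \code{\link{duo_params}} (see \code{\link{duo_preset}}).
#' @param circadian a \code{\link{circadian_config}}; disabled by default
#'   to study the intrinsic (free-running) ultradian rhythm.
#' @param fire constant release-rate multiplier.
#' @return Object of class \code{"dopamine_model"} with \code{kind = "duo"}.
#' @export
duo_model <- function(params = duo_preset("ultradian"),
                      circadian = circadian_config(enabled = FALSE),
                      fire = 1) {
  stopifnot(inherits(params, "duo_params"),
            inherits(circadian, "circadian_config"), fire > 0)
  structure(list(kind = "duo", params = params$reduced, duo = params,
                 calib = autoreceptor_calibration(),
                 circadian = circadian, fire = fire, s_dat = params$s_dat,
                 autoreceptors = TRUE),
            class = "dopamine_model")
}

state_names <- function(model) {
  if (model$kind == "duo")
    c("ldopa", "cda", "vda", "eda", "edapool", "D2")
  else c("ldopa", "cda", "vda", "eda")
}

#' Time derivatives of the model state
#'
#' Evaluates the right-hand side of the reduced (4-ODE) or DUO (6-ODE)
#' system at a given time and state.  Circadian multipliers are taken from
#' the model's forcing configuration at time \code{t}; a dose schedule, if
#' supplied, scales the DAT velocity by \code{max(1 - x_dose(t), 0)} in
#' both the \code{cda} and \code{eda} equations.  Frozen multipliers can be
#' supplied explicitly (for quasi-static analyses) via \code{cth},
#' \code{cmao} and \code{s_dat}, which override the time-dependent forcing.
#'
#' @param model a \code{\link{dopamine_model}} or \code{\link{duo_model}}.
#' @param state named or ordered state vector (see \code{state_names});
#'   components must be >= 0 (a tolerance of -1e-9 absorbs solver
#'   round-off).
#' @param t time in hours.
#' @param schedule optional \code{\link{dose_schedule}}.
#' @param cth,cmao,s_dat optional frozen multipliers overriding the
#'   time-dependent forcing.
#' @param velocities logical; also return the reaction velocities.
#' @return Named vector of derivatives (uM/hr; pool variables 1/hr); with
#'   \code{velocities = TRUE}, a list with elements \code{deriv} and
#'   \code{velocities}.
#' @export
model_derivatives <- function(model, state, t = 0, schedule = NULL,
                              cth = NULL, cmao = NULL, s_dat = NULL,
                              velocities = FALSE) {
  sn <- state_names(model)
  y <- as.numeric(state)[seq_along(sn)]
  if (any(y < -1e-9))
    stop("model_derivatives: state components must be non-negative")
  y <- pmax(y, 0)
  if (is.null(cth)) cth <- c_th(t, model$circadian)
  if (is.null(cmao)) cmao <- c_mao(t, model$circadian)
  if (is.null(s_dat))
    s_dat <- s_dat_effective(schedule, t, baseline = model$s_dat)
  d <- rhs_core(model, y, cth, cmao, model$fire, s_dat,
                velocities = velocities)
  if (velocities) {
    names(d$deriv) <- sn
    d
  } else {
    names(d) <- sn
    d
  }
}

# core RHS shared by user-facing evaluation and the integrator.
# y is a clipped non-negative numeric vector; multipliers are scalars.
rhs_core <- function(model, y, cth, cmao, fire, s, velocities = FALSE) {
  p <- model$params
  ldopa <- y[1]; cda <- y[2]; vda <- y[3]; eda <- y[4]
  factor <- if (!model$autoreceptors) {
    1
  } else if (model$kind == "duo") {
    a_of_d2(y[6], model$duo)
  } else {
    cal <- model$calib
    cal$a / ((eda / cal$eda_ref)^cal$hill + cal$d) + cal$b
  }
  # velocities inlined (the integrator calls this thousands of times)
  vth <- cth * 0.56 / (1 + p$tyr / p$Ki_tyr) * factor *
    p$Vmax_tyr * p$tyr * p$bh4 /
    (p$tyr * p$bh4 + p$K_tyr * p$bh4 +
       p$K_tyr * p$K_bh4 * (1 + cda / p$Ki_cda))
  vaadc <- p$Vmax_ldopa * ldopa / (p$Km_ldopa + ldopa)
  vmat <- p$Vmax_cda * cda / (p$Km_cda + cda) - p$k_out * vda
  vdat <- s * p$Vmax_eda * eda / (p$Km_eda + eda)
  vcat <- cmao * p$Vmax_catab * eda / (p$Km_catab + eda)
  d <- c(vth - vaadc,
         vaadc - vmat + vdat - p$k_cda * cda,
         vmat - fire * vda,
         fire * vda - vdat - vcat - p$k_eda * eda)
  if (model$kind == "duo") {
    dp <- model$duo
    d <- c(d,
           dp$k1_pool * eda - dp$k2_pool * y[5],
           dp$k3_pool * y[5] - dp$k4_pool * y[6])
  }
  d <- unname(d)
  if (velocities)
    list(deriv = d,
         velocities = c(v_th = unname(vth), v_aadc = unname(vaadc),
                        v_mat = unname(vmat), v_dat = unname(vdat),
                        v_catab = unname(vcat),
                        autoreceptor = unname(factor)))
  else d
}

#' @export
print.dopamine_model <- function(x, ...) {
  cat(sprintf("<dopamine_model: %s (%d state variables)>\n",
              if (x$kind == "duo") "Dopamine Ultradian Oscillator"
              else "reduced synthesis/release/reuptake model",
              length(state_names(x))))
  cat(sprintf("  circadian forcing: %s",
              if (x$circadian$enabled)
                sprintf("on (amplitude %.2f, TH peak at t = %g h)",
                        x$circadian$amplitude,
                        (x$circadian$phase_th + x$circadian$period / 4) %%
                          x$circadian$period)
              else "off"), "\n")
  cat(sprintf("  fire = %g, baseline s_dat = %g, autoreceptors %s\n",
              x$fire, x$s_dat, if (x$autoreceptors) "active" else "pinned to 1"))
  invisible(x)
}
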