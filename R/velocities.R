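#' Autoreceptor feedback factor as a function of extracellular dopamine
#'
#' Decreasing Hill-type inhibition of TH by extracellular dopamine through
#' presynaptic D2 autoreceptors: \code{a / ((eda/c)^h + d) + b}.  Equals 1
#' at the reference steady state \code{eda_ref}, tends to \code{b} as eda
#' grows large and to \code{a/d + b} at eda = 0.
#'
#' @param eda extracellular dopamine (uM), vectorised, >= 0.
#' @param calib an \code{\link{autoreceptor_calibration}}.
#' @return Dimensionless multiplier on TH velocity.
#' @export
autoreceptor_factor <- function(eda, calib = autoreceptor_calibration()) {
  if (any(eda < 0)) stop("autoreceptor_factor: eda must be non-negative")
  calib$a / ((eda / calib$eda_ref)^calib$hill + calib$d) + calib$b
}

#' Tyrosine hydroxylase velocity
#'
#' \code{v_th = cth * [0.56 / (1 + tyr/Ki_tyr)] * factor *
#' [Vmax_tyr tyr bh4 / (tyr bh4 + K_tyr bh4 + K_tyr K_bh4 (1 + cda/Ki_cda))]}
#' with tyrosine and BH4 held at their fixed values.  The first factor is a
#' constant substrate-inhibition term; \code{factor} carries the
#' autoreceptor feedback (from \code{\link{autoreceptor_factor}} in the
#' reduced model or \code{\link{a_of_d2}} in the DUO); the third factor is
#' inhibited weakly by cytosolic dopamine.
#'
#' @param cda cytosolic dopamine (uM), >= 0.
#' @param factor autoreceptor feedback multiplier (> 0).
#' @param params a \code{\link{reduced_params}}.
#' @param cth circadian multiplier on TH activity (> 0).
#' @return Velocity in uM/hr; decreasing in \code{cda}.
#' @export
v_th <- function(cda, factor = 1, params = reduced_params(), cth = 1) {
  if (any(cda < 0)) stop("v_th: cda must be non-negative")
  stopifnot(all(factor > 0), all(cth > 0))
  c1 <- 0.56 / (1 + params$tyr / params$Ki_tyr)
  den <- params$tyr * params$bh4 + params$K_tyr * params$bh4 +
    params$K_tyr * params$K_bh4 * (1 + cda / params$Ki_cda)
  cth * c1 * factor * params$Vmax_tyr * params$tyr * params$bh4 / den
}

#' Aromatic amino acid decarboxylase velocity (Michaelis-Menten)
#'
#' @param ldopa levodopa concentration (uM), >= 0.
#' @param params a \code{\link{reduced_params}}.
#' @return \code{Vmax_ldopa * ldopa / (Km_ldopa + ldopa)} in uM/hr.
#' @export
v_aadc <- function(ldopa, params = reduced_params()) {
  if (any(ldopa < 0)) stop("v_aadc: ldopa must be non-negative")
  params$Vmax_ldopa * ldopa / (params$Km_ldopa + ldopa)
}

#' Net vesicular monoamine transporter velocity
#'
#' Forward Michaelis-Menten packaging of cytosolic dopamine minus a linear
#' leak from the vesicular pool; may be negative when leak dominates.
#'
#' @param cda,vda cytosolic and vesicular dopamine (uM), >= 0.
#' @param params a \code{\link{reduced_params}}.
#' @return \code{Vmax_cda cda/(Km_cda + cda) - k_out vda} in uM/hr.
#' @export
v_mat <- function(cda, vda, params = reduced_params()) {
  if (any(cda < 0) || any(vda < 0)) stop("v_mat: inputs must be non-negative")
  params$Vmax_cda * cda / (params$Km_cda + cda) - params$k_out * vda
}

#' Dopamine transporter (reuptake) velocity
#'
#' @param eda extracellular dopamine (uM), >= 0.
#' @param params a \code{\link{reduced_params}}.
#' @param s effective fractional DAT activity in [0, 1] (1 = no drug).
#' @return \code{s * Vmax_eda eda/(Km_eda + eda)} in uM/hr.
#' @export
v_dat <- function(eda, params = reduced_params(), s = 1) {
  if (any(eda < 0)) stop("v_dat: eda must be non-negative")
  if (any(s < 0 | s > 1)) stop("v_dat: s must lie in [0, 1]")
  s * params$Vmax_eda * eda / (params$Km_eda + eda)
}

#' Extracellular catabolism velocity
#'
#' @param eda extracellular dopamine (uM), >= 0.
#' @param params a \code{\link{reduced_params}}.
#' @param cmao circadian multiplier on MAO activity (> 0).
#' @return \code{cmao * Vmax_catab eda/(Km_catab + eda)} in uM/hr.
#' @export
v_catab <- function(eda, params = reduced_params(), cmao = 1) {
  if (any(eda < 0)) stop("v_catab: eda must be non-negative")
  stopifnot(all(cmao > 0))
  cmao * params$Vmax_catab * eda / (params$Km_catab + eda)
}

#' D2-signalling autoreceptor factor of the DUO
#'
#' Sigmoid replacement for the eda-based autoreceptor factor:
#' \deqn{A(D2) = alpha + beta / (1 + exp((D2 - gamma (2 - s_dat)) / m)),}
#' strictly decreasing in the latent D2 signal, with midpoint
#' \code{gamma * (2 - s_dat)}: lowering DAT activity shifts the midpoint
#' right, adapting the feedback to the elevated dopaminergic tone.
#' Evaluated overflow-safely via the logistic CDF.
#'
#' @param D2 latent autoreceptor signal (dimensionless), vectorised.
#' @param params a \code{\link{duo_params}}.
#' @param s_dat optional override of the DAT activity stored in
#'   \code{params}.
#' @return Dimensionless multiplier in (alpha, alpha + beta).
#' @export
a_of_d2 <- function(D2, params, s_dat = NULL) {
  if (is.null(s_dat)) s_dat <- params$s_dat
  mid <- params$gamma * (2 - s_dat)
  params$alpha +
    params$beta * stats::plogis((mid - D2) / params$m)
}

# derivative of the eda-based autoreceptor factor wrt eda (finite at 0)
autoreceptor_factor_deriv <- function(eda, calib) {
  u <- (eda / calib$eda_ref)^calib$hill
  -calib$a * calib$hill * (eda / calib$eda_ref)^(calib$hill - 1) /
    (calib$eda_ref * (u + calib$d)^2)
}

# derivative of a_of_d2 wrt D2
a_of_d2_deriv <- function(D2, params, s_dat = NULL) {
  if (is.null(s_dat)) s_dat <- params$s_dat
  z <- (params$gamma * (2 - s_dat) - D2) / params$m
  -params$beta / params$m * stats::plogis(z) * stats::plogis(-z)
}
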