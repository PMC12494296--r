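#' Equilibrium of the model under frozen forcing
#'
#' Solves the steady state of the reduced or DUO system with all
#' time-dependent multipliers frozen at constant values (the quasi-static
#' view used for stability analysis).  The full system is reduced
#' analytically to a single scalar equation in extracellular dopamine: at
#' equilibrium the eda balance gives \code{vda} explicitly, the vesicular
#' balance inverts to \code{cda}, the cda balance gives the required AADC
#' flux and hence \code{ldopa}, and the remaining residual is the levodopa
#' balance \code{cth * v_th - v_aadc}.  That residual is strictly
#' decreasing in eda, so the biologically feasible equilibrium is unique;
#' it is located by bisection (\code{uniroot}) to near machine precision.
#' For the DUO, the pool variables at equilibrium obey the linear-chain
#' balance \code{edapool* = (k1/k2) eda*}, \code{D2* = (k3/k4) edapool*}.
#'
#' @param model a \code{\link{dopamine_model}} or \code{\link{duo_model}}.
#' @param cth,cmao frozen circadian multipliers (> 0).
#' @param fire frozen release-rate multiplier (> 0); defaults to the
#'   model's constant.
#' @param s_dat frozen fractional DAT activity in [0, 1]; defaults to the
#'   model's baseline.
#' @param check_unique scan the residual on a grid and error if more than
#'   one sign change is seen.
#' @return Named state vector at equilibrium with attributes
#'   \code{"residual"} (max |rhs| relative to the dominant flux) and
#'   \code{"velocities"}.
#' @export
find_equilibrium <- function(model, cth = 1, cmao = 1, fire = NULL,
                             s_dat = NULL, check_unique = FALSE) {
  stopifnot(cth > 0, cmao > 0)
  if (is.null(fire)) fire <- model$fire
  if (is.null(s_dat)) s_dat <- model$s_dat
  stopifnot(fire > 0, s_dat >= 0, s_dat <= 1)
  p <- model$params

  factor_fun <- if (!model$autoreceptors) {
    function(eda) 1
  } else if (model$kind == "duo") {
    dp <- model$duo
    chain <- dp$k1_pool / dp$k2_pool * dp$k3_pool / dp$k4_pool
    function(eda) a_of_d2(chain * eda, dp, s_dat = s_dat)
  } else {
    function(eda) autoreceptor_factor(eda, model$calib)
  }

  vdat_f <- function(eda) s_dat * p$Vmax_eda * eda / (p$Km_eda + eda)
  vcat_f <- function(eda) cmao * p$Vmax_catab * eda / (p$Km_catab + eda)
  vda_f <- function(eda) (vdat_f(eda) + vcat_f(eda) + p$k_eda * eda) / fire
  q_f <- function(eda) (fire + p$k_out) * vda_f(eda)

  # residual of the levodopa balance as a function of eda alone
  g <- function(eda) {
    q <- q_f(eda)
    cda <- p$Km_cda * q / (p$Vmax_cda - q)
    req <- fire * vda_f(eda) - vdat_f(eda) + p$k_cda * cda
    cth * v_th(cda, factor_fun(eda), p, cth = 1) - req
  }

  # upper end of the feasible eda range: vesicular packaging capacity
  eda_cap <- uniroot(function(e) q_f(e) - 0.999999 * p$Vmax_cda,
                     c(0, p$Vmax_cda / p$k_eda * (fire + p$k_out) / fire),
                     tol = 1e-14)$root
  lo <- 1e-14
  hi <- eda_cap * (1 - 1e-9)
  glo <- g(lo); ghi <- g(hi)
  if (!(glo > 0 && ghi < 0))
    stop(sprintf(paste0("find_equilibrium: no feasible root bracketed ",
                        "(residual %.3g at eda=%.3g, %.3g at eda=%.3g)"),
                 glo, lo, ghi, hi))
  if (check_unique) {
    grid <- exp(seq(log(lo), log(hi), length.out = 200))
    sg <- sign(vapply(grid, g, numeric(1)))
    if (sum(diff(sg[sg != 0]) != 0) > 1)
      stop("find_equilibrium: multiple feasible equilibria detected")
  }
  eda <- uniroot(g, c(lo, hi), tol = .Machine$double.eps)$root

  vda <- vda_f(eda)
  q <- q_f(eda)
  cda <- p$Km_cda * q / (p$Vmax_cda - q)
  req <- fire * vda - vdat_f(eda) + p$k_cda * cda
  if (req <= 0 || req >= p$Vmax_ldopa)
    stop("find_equilibrium: required AADC flux outside (0, Vmax_ldopa)")
  ldopa <- p$Km_ldopa * req / (p$Vmax_ldopa - req)

  st <- c(ldopa = ldopa, cda = cda, vda = vda, eda = eda)
  if (model$kind == "duo") {
    dp <- model$duo
    pool <- dp$k1_pool / dp$k2_pool * eda
    st <- c(st, edapool = pool, D2 = dp$k3_pool / dp$k4_pool * pool)
  }
  if (any(st <= 0))
    stop("find_equilibrium: equilibrium has non-positive components")
  dv <- rhs_core(model_with_sdat(model, s_dat), st, cth, cmao, fire, s_dat,
                 velocities = TRUE)
  scale <- max(abs(dv$velocities[c("v_th", "v_mat", "v_dat")]), 1)
  structure(st, residual = max(abs(dv$deriv)) / scale,
            velocities = dv$velocities)
}

# clone of the model with a frozen DUO s_dat (a_of_d2 reads it from duo)
model_with_sdat <- function(model, s_dat) {
  if (model$kind == "duo") model$duo$s_dat <- s_dat
  model$s_dat <- min(s_dat, 1)
  model
}

#' Analytic Jacobian of the model right-hand side
#'
#' Exact partial derivatives of the reduced (4x4) or DUO (6x6) vector
#' field at a given state with frozen multipliers.  The pool rows of the
#' DUO Jacobian are constant (\code{k1_pool, -k2_pool, k3_pool, -k4_pool});
#' all Michaelis-Menten and sigmoid terms are differentiated in closed
#' form.  Entries are in 1/hr.
#'
#' @inheritParams find_equilibrium
#' @param state state vector at which to evaluate (e.g. an equilibrium
#'   from \code{\link{find_equilibrium}}).
#' @return Square numeric matrix with state names on both dimensions.
#' @seealso \code{\link{numeric_jacobian}} for the finite-difference
#'   cross-check.
#' @export
model_jacobian <- function(model, state, cth = 1, cmao = 1, fire = NULL,
                           s_dat = NULL) {
  if (is.null(fire)) fire <- model$fire
  if (is.null(s_dat)) s_dat <- model$s_dat
  p <- model$params
  sn <- state_names(model)
  y <- as.numeric(state)[seq_along(sn)]
  ldopa <- y[1]; cda <- y[2]; vda <- y[3]; eda <- y[4]

  c1 <- 0.56 / (1 + p$tyr / p$Ki_tyr)
  den <- p$tyr * p$bh4 + p$K_tyr * p$bh4 +
    p$K_tyr * p$K_bh4 * (1 + cda / p$Ki_cda)
  G <- p$Vmax_tyr * p$tyr * p$bh4 / den
  dG_dcda <- -G * (p$K_tyr * p$K_bh4 / p$Ki_cda) / den

  if (!model$autoreceptors) {
    fac <- 1; dfac_deda <- 0; dfac_dD2 <- 0
  } else if (model$kind == "duo") {
    fac <- a_of_d2(y[6], model$duo, s_dat = s_dat)
    dfac_deda <- 0
    dfac_dD2 <- a_of_d2_deriv(y[6], model$duo, s_dat = s_dat)
  } else {
    fac <- autoreceptor_factor(eda, model$calib)
    dfac_deda <- autoreceptor_factor_deriv(eda, model$calib)
    dfac_dD2 <- 0
  }

  dAADC <- p$Vmax_ldopa * p$Km_ldopa / (p$Km_ldopa + ldopa)^2
  dMAT_dcda <- p$Vmax_cda * p$Km_cda / (p$Km_cda + cda)^2
  dDAT <- s_dat * p$Vmax_eda * p$Km_eda / (p$Km_eda + eda)^2
  dCAT <- cmao * p$Vmax_catab * p$Km_catab / (p$Km_catab + eda)^2

  dTH_dcda <- cth * c1 * fac * dG_dcda
  dTH_deda <- cth * c1 * dfac_deda * G

  n <- length(sn)
  J <- matrix(0, n, n, dimnames = list(sn, sn))
  J["ldopa", "ldopa"] <- -dAADC
  J["ldopa", "cda"] <- dTH_dcda
  J["ldopa", "eda"] <- dTH_deda
  J["cda", "ldopa"] <- dAADC
  J["cda", "cda"] <- -dMAT_dcda - p$k_cda
  J["cda", "vda"] <- p$k_out
  J["cda", "eda"] <- dDAT
  J["vda", "cda"] <- dMAT_dcda
  J["vda", "vda"] <- -p$k_out - fire
  J["eda", "vda"] <- fire
  J["eda", "eda"] <- -dDAT - dCAT - p$k_eda
  if (model$kind == "duo") {
    dp <- model$duo
    J["ldopa", "D2"] <- cth * c1 * dfac_dD2 * G
    J["edapool", "eda"] <- dp$k1_pool
    J["edapool", "edapool"] <- -dp$k2_pool
    J["D2", "edapool"] <- dp$k3_pool
    J["D2", "D2"] <- -dp$k4_pool
  }
  J
}

#' Finite-difference Jacobian (verification oracle)
#'
#' Central-difference approximation of the Jacobian of the frozen-forcing
#' vector field, used to cross-validate \code{\link{model_jacobian}}.
#'
#' @inheritParams model_jacobian
#' @param h relative step size.
#' @return Square numeric matrix.
#' @export
numeric_jacobian <- function(model, state, cth = 1, cmao = 1, fire = NULL,
                             s_dat = NULL, h = 1e-6) {
  if (is.null(fire)) fire <- model$fire
  if (is.null(s_dat)) s_dat <- model$s_dat
  m <- model_with_sdat(model, s_dat)
  sn <- state_names(model)
  y <- as.numeric(state)[seq_along(sn)]
  f <- function(z) rhs_core(m, z, cth, cmao, fire, s_dat)
  n <- length(y)
  J <- matrix(0, n, n, dimnames = list(sn, sn))
  for (j in seq_len(n)) {
    dh <- h * max(abs(y[j]), 1e-8)
    yp <- y; ym <- y
    yp[j] <- y[j] + dh; ym[j] <- max(y[j] - dh, 0)
    J[, j] <- (f(yp) - f(ym)) / (yp[j] - ym[j])
  }
  J
}
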