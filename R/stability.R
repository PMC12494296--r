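#' Equilibrium, Jacobian and spectrum at frozen forcing
#'
#' Solves the quasi-static equilibrium at a given DAT activity level and
#' circadian phase (multipliers frozen at \code{c_th(phase)},
#' \code{c_mao(phase)}), evaluates the analytic Jacobian there, and
#' returns its eigenvalues.
#'
#' @param model a \code{\link{dopamine_model}} or \code{\link{duo_model}}.
#' @param s_dat frozen fractional DAT activity in [0, 1].
#' @param phase circadian phase in hours (ignored when the model's
#'   circadian forcing is disabled).
#' @return Object of class \code{"equilibrium_report"}: list with
#'   \code{s_dat, phase, equilibrium, jacobian, eigenvalues, max_real}.
#' @export
equilibrium_report <- function(model, s_dat = 1, phase = 0) {
  cth <- c_th(phase, model$circadian)
  cmao <- c_mao(phase, model$circadian)
  eq <- find_equilibrium(model, cth = cth, cmao = cmao, s_dat = s_dat)
  J <- model_jacobian(model, eq, cth = cth, cmao = cmao, s_dat = s_dat)
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(s_dat = s_dat, phase = phase, equilibrium = eq,
                 jacobian = J, eigenvalues = ev,
                 max_real = max(Re(ev))),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("Equilibrium at s_dat = %g, phase = %g h:\n", x$s_dat, x$phase))
  print(signif(unclass(x$equilibrium), 4))
  cat(sprintf("max Re(eigenvalue) = %.4g /hr (%s)\n", x$max_real,
              if (x$max_real < 0) "locally stable" else "unstable"))
  invisible(x)
}

#' Quasi-static stability map over DAT activity and circadian phase
#'
#' For every pair on the grid, freezes the circadian multipliers at the
#' given phase, solves the feasible equilibrium, and records its
#' concentrations and the largest real part of the Jacobian eigenvalues.
#' Failures at individual grid points are flagged (\code{feasible =
#' FALSE}, NA values) rather than fatal.
#'
#' @param model a \code{\link{dopamine_model}}.
#' @param s_dat_grid DAT activity values in [0, 1].
#' @param phase_grid circadian phases in hours (default hourly over a day).
#' @return Long-format data frame with columns \code{s_dat, phase,
#'   max_real}, the equilibrium concentrations, and \code{feasible}.
#' @export
stability_map <- function(model, s_dat_grid = seq(0.01, 1, length.out = 25),
                          phase_grid = 0:23) {
  sn <- state_names(model)
  grid <- expand.grid(phase = phase_grid, s_dat = s_dat_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rep <- tryCatch(
      equilibrium_report(model, s_dat = grid$s_dat[i],
                         phase = grid$phase[i]),
      error = function(e) NULL)
    if (is.null(rep)) {
      out <- as.list(stats::setNames(rep(NA_real_, length(sn)), sn))
      c(list(s_dat = grid$s_dat[i], phase = grid$phase[i],
             max_real = NA_real_), out, list(feasible = FALSE))
    } else {
      c(list(s_dat = rep$s_dat, phase = rep$phase,
             max_real = rep$max_real),
        as.list(rep$equilibrium), list(feasible = TRUE))
    }
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Locate a Hopf bifurcation in DAT activity by eigenvalue bisection
#'
#' Bisection on the sign of the largest real part of the Jacobian
#' eigenvalues at the \code{s_dat}-dependent equilibrium of the DUO.  The
#' endpoints of the interval must bracket a sign change, and the dominant
#' eigenvalue pair at the crossing must have nonzero imaginary part for
#' the crossing to be classified as a Hopf point.
#'
#' @param model a \code{\link{duo_model}} (circadian forcing off).
#' @param interval numeric length-2 bracket in [0, 1] with
#'   \code{interval[1] < interval[2]}.
#' @param tol bisection tolerance on \code{s_dat}.
#' @return Critical \code{s_dat} with attributes \code{"max_real"} and
#'   \code{"imag_at_crossing"} (imaginary part of the dominant pair).
#' @export
hopf_locate <- function(model, interval = c(0.05, 0.9), tol = 1e-3) {
  stopifnot(length(interval) == 2)
  if (interval[1] >= interval[2])
    stop("hopf_locate: empty or degenerate interval")
  maxre <- function(s) {
    rep <- equilibrium_report(model, s_dat = s, phase = 0)
    ev <- rep$eigenvalues
    dom <- ev[which.max(Re(ev))]
    c(re = max(Re(ev)), im = Im(dom))
  }
  lo <- interval[1]; hi <- interval[2]
  flo <- maxre(lo); fhi <- maxre(hi)
  if (sign(flo["re"]) == sign(fhi["re"]))
    stop(sprintf(paste0("hopf_locate: no sign change of max Re(eigenvalue) ",
                        "on [%g, %g] (%.3g and %.3g)"),
                 lo, hi, flo["re"], fhi["re"]))
  fmid <- NULL
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fmid <- maxre(mid)
    if (sign(fmid["re"]) == sign(flo["re"])) {
      lo <- mid; flo <- fmid
    } else {
      hi <- mid; fhi <- fmid
    }
  }
  s_crit <- (lo + hi) / 2
  fc <- maxre(s_crit)
  if (abs(fc["im"]) < 1e-8)
    stop("hopf_locate: dominant eigenvalue real at the crossing; ",
         "not a Hopf bifurcation")
  structure(s_crit, max_real = unname(fc["re"]),
            imag_at_crossing = unname(fc["im"]))
}

#' Oscillation amplitude and period of the DUO across DAT activity levels
#'
#' For each \code{s_dat}, integrates the DUO (circadian off) from a small
#' perturbation of its equilibrium and summarises the attractor: sustained
#' limit cycles yield a period and peak-to-trough amplitude; below the
#' Hopf point the trajectory relaxes back to the stable equilibrium and
#' the amplitude is reported as 0.
#'
#' @param model a \code{\link{duo_model}}.
#' @param s_dat_grid DAT activity values in [0, 1].
#' @param sim_hours integration length per point (hours).
#' @param discard_frac fraction of the run discarded as transient.
#' @param dt_out output grid spacing.
#' @param settings a \code{\link{solver_settings}}.
#' @return Data frame with columns \code{s_dat, oscillatory, period,
#'   amplitude}.
#' @export
amplitude_curve_duo <- function(model, s_dat_grid,
                                sim_hours = 240, discard_frac = 0.5,
                                dt_out = 0.01,
                                settings = solver_settings()) {
  rows <- lapply(s_dat_grid, function(s) {
    m <- model
    m$duo$s_dat <- s
    m$s_dat <- s
    eq <- find_equilibrium(m, s_dat = s)
    tr <- integrate_model(m, c(0, sim_hours), init = eq * 1.02,
                          settings = settings, dt_out = dt_out)
    os <- tryCatch(
      estimate_period_amplitude(tr, "eda",
                                discard = sim_hours * discard_frac),
      error = function(e)
        list(oscillatory = FALSE, period = NA_real_, amplitude = 0))
    data.frame(s_dat = s, oscillatory = os$oscillatory,
               period = if (os$oscillatory) os$period else NA_real_,
               amplitude = os$amplitude)
  })
  do.call(rbind, rows)
}
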