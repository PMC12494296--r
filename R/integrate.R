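#' Stiff solver settings
#'
#' @param rel_tol,abs_tol relative and absolute integration tolerances.
#' @param max_step largest internal step (hours); kept at or below 0.1 h so
#'   circadian forcing and the fast extracellular transients (rate
#'   constants up to 400/hr) are resolved.
#' @param stiff use a stiffness-switching solver (\code{lsoda}) with the
#'   analytic Jacobian; \code{FALSE} selects explicit Runge-Kutta.
#' @return Object of class \code{"solver_settings"}.
#' @export
solver_settings <- function(rel_tol = 1e-8, abs_tol = 1e-10,
                            max_step = 0.1, stiff = TRUE) {
  stopifnot(rel_tol > 0, abs_tol > 0, max_step > 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 max_step = max_step, stiff = stiff),
            class = "solver_settings")
}

#' Integrate the model over a time span
#'
#' Integrates the reduced or DUO system with \code{deSolve}, splitting the
#' span at dose administration times so the discontinuity in the effective
#' DAT activity is handled by an integrator restart rather than smoothed
#' over.  The occupancy \code{x_dose(t)} itself is evaluated in closed form
#' (sum of decaying exponentials with exact jumps), so the model state is
#' continuous and only its vector field jumps at dose times.
#'
#' @param model a \code{\link{dopamine_model}} or \code{\link{duo_model}}.
#' @param t_span numeric length-2, start and end times in hours.
#' @param init initial state; defaults to the equilibrium at the forcing
#'   values of the start time (drug-free).
#' @param schedule optional \code{\link{dose_schedule}}.
#' @param settings a \code{\link{solver_settings}}.
#' @param dt_out output grid spacing (hours).
#' @return A \code{da_trajectory}: a data frame with columns \code{time},
#'   the state variables, \code{x_dose}, \code{s_dat_eff}, \code{c_th} and
#'   \code{c_mao}, carrying the model and grid spacing as attributes.
#' @export
integrate_model <- function(model, t_span, init = NULL, schedule = NULL,
                            settings = solver_settings(), dt_out = 0.01) {
  stopifnot(length(t_span) == 2, t_span[1] < t_span[2])
  sn <- state_names(model)
  if (is.null(init)) {
    init <- find_equilibrium(model,
                             cth = c_th(t_span[1], model$circadian),
                             cmao = c_mao(t_span[1], model$circadian))
  }
  y <- as.numeric(init)[seq_along(sn)]
  names(y) <- sn

  breaks <- numeric(0)
  if (!is.null(schedule))
    breaks <- schedule$times[schedule$times > t_span[1] &
                               schedule$times < t_span[2]]
  edges <- sort(unique(c(t_span, breaks)))

  func <- function(t, y, parms) {
    y <- pmax(y, 0)
    s <- s_dat_effective(schedule, t, baseline = model$s_dat)
    list(rhs_core(model, y, c_th(t, model$circadian),
                  c_mao(t, model$circadian), model$fire, s))
  }
  jacf <- function(t, y, parms) {
    s <- s_dat_effective(schedule, t, baseline = model$s_dat)
    model_jacobian(model, pmax(y, 0), cth = c_th(t, model$circadian),
                   cmao = c_mao(t, model$circadian), fire = model$fire,
                   s_dat = s)
  }

  segs <- vector("list", length(edges) - 1L)
  for (k in seq_along(segs)) {
    a <- edges[k]; b <- edges[k + 1L]
    times <- unique(c(seq(a, b, by = dt_out), b))
    sol <- if (settings$stiff) {
      deSolve::lsoda(y, times, func, parms = NULL, jacfunc = jacf,
                     jactype = "fullusr", rtol = settings$rel_tol,
                     atol = settings$abs_tol, hmax = settings$max_step)
    } else {
      deSolve::ode(y, times, func, parms = NULL, method = "ode45",
                   rtol = settings$rel_tol, atol = settings$abs_tol,
                   hmax = settings$max_step)
    }
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("integrate_model: solver failed on [%g, %g]", a, b))
    m <- as.data.frame(unclass(sol))
    names(m) <- c("time", sn)
    if (min(as.matrix(m[sn])) < -1e-6)
      stop("integrate_model: state integrity violated (component < -1e-6)")
    m[sn] <- pmax(as.matrix(m[sn]), 0)
    segs[[k]] <- if (k > 1) m[-1, , drop = FALSE] else m
    y <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    names(y) <- sn
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out$x_dose <- x_dose_at(schedule, out$time)
  out$s_dat_eff <- model$s_dat * pmax(1 - out$x_dose, 0)
  out$c_th <- c_th(out$time, model$circadian)
  out$c_mao <- c_mao(out$time, model$circadian)
  new_trajectory(out, model = model, schedule = schedule, dt = dt_out)
}

new_trajectory <- function(df, model, schedule = NULL, dt = NULL,
                           uniform = TRUE) {
  structure(df, class = c("da_trajectory", "data.frame"),
            model = model, schedule = schedule, dt = dt, uniform = uniform)
}

#' Resample a trajectory onto a uniform grid
#'
#' Linear interpolation of every column onto \code{seq(t0, t1, by = dt)}.
#' Trajectories produced by \code{\link{integrate_model}} are already on a
#' uniform grid except for extra points inserted at dose times; resampling
#' restores exact uniformity for statistics.
#'
#' @param traj a \code{da_trajectory}.
#' @param dt grid spacing in hours; must not exceed the trajectory span.
#' @return A uniform \code{da_trajectory}.
#' @export
resample_uniform <- function(traj, dt) {
  stopifnot(dt > 0)
  t0 <- traj$time[1]; t1 <- traj$time[nrow(traj)]
  if (dt > t1 - t0) stop("resample_uniform: dt exceeds trajectory span")
  grid <- seq(t0, t1, by = dt)
  if (grid[length(grid)] < t1) grid <- c(grid, t1)
  cols <- setdiff(names(traj), "time")
  out <- data.frame(time = grid)
  for (cl in cols)
    out[[cl]] <- stats::approx(traj$time, traj[[cl]], xout = grid,
                               rule = 2)$y
  new_trajectory(out, model = attr(traj, "model"),
                 schedule = attr(traj, "schedule"), dt = dt)
}

#' Simulate a dosing protocol after spin-up to the forced limit cycle
#'
#' Integrates the drug-free model for \code{burn_in} hours (ending at
#' \code{t = 0}, so circadian phase is preserved) to remove transients,
#' then simulates the dosing protocol from the resulting state.  With no
#' schedule this returns the forced limit cycle itself.
#'
#' @param model a \code{\link{dopamine_model}} or \code{\link{duo_model}}.
#' @param schedule optional \code{\link{dose_schedule}} with times in
#'   [0, \code{days * 24}).
#' @param days protocol length in days.
#' @param burn_in spin-up duration in hours (discarded).
#' @param settings a \code{\link{solver_settings}}.
#' @param dt_out output grid spacing (hours).
#' @param init optional initial state for the spin-up.
#' @return A \code{da_trajectory} covering [0, \code{days * 24}].
#' @export
run_protocol <- function(model, schedule = NULL, days = 1, burn_in = 240,
                         settings = solver_settings(), dt_out = 0.01,
                         init = NULL) {
  stopifnot(days >= 1)
  state0 <- if (burn_in > 0) {
    pre <- integrate_model(model, c(-burn_in, 0), init = init,
                           schedule = NULL, settings = settings,
                           dt_out = max(dt_out, 0.05))
    as.numeric(pre[nrow(pre), state_names(model)])
  } else {
    init
  }
  integrate_model(model, c(0, days * 24), init = state0,
                  schedule = schedule, settings = settings, dt_out = dt_out)
}

#' @export
print.da_trajectory <- function(x, ...) {
  sn <- state_names(attr(x, "model"))
  cat(sprintf("<da_trajectory: %d samples over [%g, %g] h, %s model>\n",
              nrow(x), x$time[1], x$time[nrow(x)],
              attr(x, "model")$kind))
  print(utils::head(as.data.frame(x)[c("time", sn)], 4), ...)
  cat("...\n")
  invisible(x)
}

#' Plot a trajectory variable against time
#'
#' @param x a \code{da_trajectory}.
#' @param variable column to plot.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.da_trajectory <- function(x, variable = "eda", ...) {
  graphics::plot(x$time, x[[variable]], type = "l",
                 xlab = "time (h)", ylab = variable, ...)
  invisible(x)
}

#' Simulate method for dopamine models
#'
#' Thin wrapper around \code{\link{run_protocol}} conforming to the
#' \code{\link[stats]{simulate}} generic.  The model is deterministic, so
#' \code{nsim} and \code{seed} are accepted for interface compatibility
#' but ignored beyond seeding.
#'
#' @param object a \code{\link{dopamine_model}}.
#' @param nsim ignored (deterministic model).
#' @param seed optional seed (recorded only).
#' @param ... passed to \code{\link{run_protocol}}.
#' @return A \code{da_trajectory}.
#' @export
simulate.dopamine_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  run_protocol(object, ...)
}
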