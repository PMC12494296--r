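#' Windowed summary statistics of a trajectory variable
#'
#' Mean, median and standard deviation of one variable over the half-open
#' window \code{(start, end]}, computed on the trajectory's uniform grid.
#' When a reference concentration is supplied (typically the drug-free,
#' circadian-free nominal equilibrium), the mean and median are also
#' expressed as percent above that reference and the SD as percent of it.
#'
#' @param traj a uniform \code{da_trajectory} (see
#'   \code{\link{resample_uniform}}).
#' @param variable column name.
#' @param window numeric length-2, \code{c(start, end)} in hours.
#' @param reference reference level in the variable's units, or
#'   \code{NULL}.
#' @return One-row data frame with columns \code{variable, start, end,
#'   mean, median, sd} and, given a reference, \code{mean_pct, median_pct,
#'   sd_pct}.
#' @export
window_stats <- function(traj, variable = "eda", window, reference = NULL) {
  if (!isTRUE(attr(traj, "uniform")))
    stop("window_stats: resample the trajectory onto a uniform grid first")
  stopifnot(length(window) == 2, window[2] > window[1])
  eps <- 1e-9
  idx <- traj$time > window[1] + eps & traj$time <= window[2] + eps
  if (!any(idx)) stop("window_stats: window outside trajectory span")
  x <- traj[[variable]][idx]
  out <- data.frame(variable = variable, start = window[1], end = window[2],
                    mean = mean(x), median = stats::median(x),
                    sd = stats::sd(x))
  if (!is.null(reference)) {
    out$reference <- reference
    out$mean_pct <- (out$mean / reference - 1) * 100
    out$median_pct <- (out$median / reference - 1) * 100
    out$sd_pct <- out$sd / reference * 100
  }
  out
}

#' Trailing moving-window statistics
#'
#' Trailing mean/median/SD over windows of fixed width, evaluated at a
#' stride of output times along the trajectory's uniform grid.  The first
#' evaluation time is one full window after the trajectory start.
#'
#' @inheritParams window_stats
#' @param width window width in hours.
#' @param stride spacing of evaluation times in hours.
#' @return Data frame with columns \code{time, mean, median, sd} (and
#'   percent columns given a reference); \code{time} marks the trailing
#'   edge (window end).
#' @export
moving_window_stats <- function(traj, variable = "eda", width = 24,
                                reference = NULL, stride = 0.25) {
  if (!isTRUE(attr(traj, "uniform")))
    stop("moving_window_stats: resample onto a uniform grid first")
  dt <- attr(traj, "dt")
  x <- traj[[variable]]
  n <- nrow(traj)
  w <- round(width / dt)
  if (w + 1 > n) stop("moving_window_stats: window wider than trajectory")
  step <- max(1L, round(stride / dt))
  ends <- seq(w + 1L, n, by = step)
  stats_at <- vapply(ends, function(i) {
    v <- x[(i - w + 1L):i]
    c(mean(v), stats::median(v), stats::sd(v))
  }, numeric(3))
  out <- data.frame(time = traj$time[ends], mean = stats_at[1, ],
                    median = stats_at[2, ], sd = stats_at[3, ])
  if (!is.null(reference)) {
    out$mean_pct <- (out$mean / reference - 1) * 100
    out$median_pct <- (out$median / reference - 1) * 100
    out$sd_pct <- out$sd / reference * 100
  }
  out
}

# indices of local maxima with peak-to-adjacent-saddle prominence above
# a threshold: candidate maxima from derivative sign changes, prominence
# measured against the deepest minima separating a peak from its
# neighbours (or the record boundary)
find_local_peaks <- function(x, min_prominence) {
  n <- length(x)
  dx <- diff(x)
  sgn <- sign(dx)
  # collapse flats onto their left edge
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  cand <- which(diff(sgn) < 0) + 1L
  cand <- cand[cand > 1 & cand < n]
  if (!length(cand)) return(integer(0))
  bounds <- c(1L, cand, n)
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    left_min <- min(x[bounds[k]:cand[k]])
    right_min <- min(x[cand[k]:bounds[k + 2L]])
    keep[k] <- x[cand[k]] - max(left_min, right_min) >= min_prominence
  }
  cand[keep]
}

# quadratic (three-point) refinement of a sampled maximum
refine_peak <- function(tm, dt, y_prev, y_max, y_next) {
  denom <- y_prev - 2 * y_max + y_next
  if (denom >= 0) return(tm)  # flat or degenerate
  tm + dt / 2 * (y_prev - y_next) / denom
}

#' Time of day at which a variable peaks on the forced limit cycle
#'
#' Takes the final full forcing cycle of the trajectory, locates the
#' sampled maximum of the variable and refines it by local quadratic
#' interpolation.  A warning is issued if the trajectory is not
#' cycle-periodic at the 0.1% level (transient not yet decayed).
#'
#' @inheritParams window_stats
#' @param cycle_length forcing period in hours.
#' @return Peak time in hours, reduced modulo the cycle length.
#' @export
peak_time_in_cycle <- function(traj, variable = "eda", cycle_length = 24) {
  if (!isTRUE(attr(traj, "uniform")))
    stop("peak_time_in_cycle: resample onto a uniform grid first")
  dt <- attr(traj, "dt")
  t1 <- traj$time[nrow(traj)]
  last <- traj$time > t1 - cycle_length - 1e-9
  x <- traj[[variable]][last]
  tt <- traj$time[last]
  prev <- traj$time > t1 - 2 * cycle_length - 1e-9 &
    traj$time <= t1 - cycle_length + 1e-9
  if (any(prev)) {
    xp <- traj[[variable]][prev]
    k <- min(length(xp), length(x))
    if (max(abs(xp[seq_len(k)] - x[seq_len(k)])) >
        1e-3 * max(abs(x), 1e-12))
      warning("peak_time_in_cycle: trajectory not cycle-periodic; ",
              "reporting argmax of the final cycle")
  }
  i <- which.max(x)
  tp <- if (i > 1 && i < length(x))
    refine_peak(tt[i], dt, x[i - 1], x[i], x[i + 1])
  else tt[i]
  tp %% cycle_length
}

#' Period and amplitude of a sustained oscillation
#'
#' Discards an initial transient, detects local maxima of the variable by
#' prominence, and summarises the oscillation: period as the mean
#' peak-to-peak interval (peak times refined by quadratic interpolation)
#' and amplitude as the mean peak-to-trough excursion (cycle maximum minus
#' cycle minimum between successive peaks).  A trajectory whose residual
#' fluctuation after the transient falls below \code{min_prominence} is
#' declared non-oscillatory with amplitude 0 and period \code{NA}.
#'
#' @inheritParams window_stats
#' @param discard transient to drop from the start (hours).
#' @param min_prominence minimum peak prominence, in the variable's units,
#'   for a maximum to count as a cycle.
#' @return Object of class \code{"oscillation_summary"}: list with
#'   \code{oscillatory}, \code{period}, \code{amplitude},
#'   \code{n_cycles} and \code{peak_times}.
#' @export
estimate_period_amplitude <- function(traj, variable = "eda", discard = 0,
                                      min_prominence = 1e-6) {
  if (!isTRUE(attr(traj, "uniform")))
    stop("estimate_period_amplitude: resample onto a uniform grid first")
  dt <- attr(traj, "dt")
  keep <- traj$time >= traj$time[1] + discard
  x <- traj[[variable]][keep]
  tt <- traj$time[keep]
  if (max(x) - min(x) < min_prominence)
    return(structure(list(oscillatory = FALSE, period = NA_real_,
                          amplitude = 0, n_cycles = 0L,
                          peak_times = numeric(0)),
                     class = "oscillation_summary"))
  idx <- find_local_peaks(x, min_prominence)
  if (length(idx) < 1)
    return(structure(list(oscillatory = FALSE, period = NA_real_,
                          amplitude = 0, n_cycles = 0L,
                          peak_times = numeric(0)),
                     class = "oscillation_summary"))
  if (length(idx) < 3)
    stop("estimate_period_amplitude: fewer than 3 peaks after discard; ",
         "integrate longer or reduce the transient discard")
  ptimes <- vapply(idx, function(i) {
    if (i > 1 && i < length(x))
      refine_peak(tt[i], dt, x[i - 1], x[i], x[i + 1])
    else tt[i]
  }, numeric(1))
  amps <- vapply(seq_len(length(idx) - 1L), function(k) {
    seg <- x[idx[k]:idx[k + 1L]]
    max(seg) - min(seg)
  }, numeric(1))
  structure(list(oscillatory = TRUE,
                 period = mean(diff(ptimes)),
                 amplitude = mean(amps),
                 n_cycles = length(idx) - 1L,
                 peak_times = ptimes),
            class = "oscillation_summary")
}

#' @export
print.oscillation_summary <- function(x, ...) {
  if (x$oscillatory)
    cat(sprintf("Oscillation: period %.4g h, amplitude %.4g (%d cycles)\n",
                x$period, x$amplitude, x$n_cycles))
  else cat("Non-oscillatory (converges to a fixed point)\n")
  invisible(x)
}

#' Fraction of intracellular dopamine stored in vesicles
#'
#' @param state named state vector with \code{cda} and \code{vda}
#'   components (e.g. from \code{\link{find_equilibrium}}).
#' @return \code{vda / (cda + vda)}, dimensionless.
#' @export
vesicular_fraction <- function(state) {
  cda <- state[["cda"]]; vda <- state[["vda"]]
  if (cda + vda <= 0)
    stop("vesicular_fraction: cda + vda must be positive")
  vda / (cda + vda)
}
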