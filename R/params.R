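#' Kinetic parameters of the reduced dopamine model
#'
#' Constructs the full set of kinetic constants for the four-variable model
#' of dopamine synthesis (tyrosine hydroxylase, TH), decarboxylation (AADC),
#' vesicular packaging (MAT), reuptake (DAT) and catabolism (MAO/COMT), plus
#' the fixed substrate/cofactor concentrations of tyrosine and
#' tetrahydrobiopterin.  Units: Michaelis/inhibition constants in uM, maximal
#' velocities in uM/hr, first-order rate constants in 1/hr.
#'
#' @param Ki_tyr substrate-inhibition constant of TH for tyrosine (uM).
#' @param Vmax_tyr maximal TH velocity (uM/hr).
#' @param K_tyr,K_bh4 TH Michaelis constants for tyrosine and BH4 (uM).
#' @param Ki_cda inhibition constant of TH by cytosolic dopamine (uM).
#' @param Vmax_ldopa,Km_ldopa AADC kinetics (uM/hr, uM).
#' @param Vmax_cda,Km_cda forward vesicular packaging kinetics (uM/hr, uM).
#' @param k_out vesicular leak rate constant (1/hr).
#' @param Vmax_eda,Km_eda DAT reuptake kinetics (uM/hr, uM).
#' @param Vmax_catab,Km_catab extracellular catabolism kinetics (uM/hr, uM).
#' @param k_cda intracellular catabolism rate constant (1/hr).
#' @param k_eda extracellular removal rate constant (1/hr).
#' @param tyr,bh4 fixed tyrosine and tetrahydrobiopterin concentrations (uM).
#' @return An object of class \code{"reduced_params"} (named list).
#' @export
reduced_params <- function(Ki_tyr = 160, Vmax_tyr = 125, K_tyr = 46,
                           K_bh4 = 60, Ki_cda = 110,
                           Vmax_ldopa = 10000, Km_ldopa = 130,
                           Vmax_cda = 7082, Km_cda = 3, k_out = 40,
                           Vmax_eda = 8000, Km_eda = 0.2,
                           Vmax_catab = 30, Km_catab = 3,
                           k_cda = 10, k_eda = 400,
                           tyr = 126, bh4 = 319) {
  p <- list(Ki_tyr = Ki_tyr, Vmax_tyr = Vmax_tyr, K_tyr = K_tyr,
            K_bh4 = K_bh4, Ki_cda = Ki_cda, Vmax_ldopa = Vmax_ldopa,
            Km_ldopa = Km_ldopa, Vmax_cda = Vmax_cda, Km_cda = Km_cda,
            k_out = k_out, Vmax_eda = Vmax_eda, Km_eda = Km_eda,
            Vmax_catab = Vmax_catab, Km_catab = Km_catab,
            k_cda = k_cda, k_eda = k_eda, tyr = tyr, bh4 = bh4)
  bad <- names(p)[!vapply(p, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    stop("reduced_params: fields must be single positive numbers: ",
         paste(bad, collapse = ", "))
  structure(p, class = "reduced_params")
}

#' Calibration of the eda-based autoreceptor feedback factor
#'
#' The presynaptic D2 autoreceptor feedback on TH is modelled as a
#' decreasing Hill-type function of extracellular dopamine,
#' \deqn{f(eda) = a / ((eda/c)^h + d) + b,}
#' normalised so that \eqn{f} equals exactly 1 at the reference steady-state
#' concentration \eqn{c} (the nominal equilibrium eda): with \code{d}
#' unspecified it is set to the unique value \eqn{d = a/(1-b) - 1}
#' satisfying that constraint.
#'
#' The default coefficients are the classic ones (4.58 and 0.5 around a
#' unit-denominator Hill term) rescaled by the factor's value at the
#' reference concentration, 4.58/2 + 0.5 = 2.79.  This keeps the
#' functional shape and the relative feedback gain
#' \eqn{\mathrm{d}\log f/\mathrm{d} eda} of the original term while
#' pinning \eqn{f} to 1 at equilibrium, so the nominal steady state is
#' left untouched by the feedback.  The unnormalised variant is available
#' as \code{autoreceptor_calibration(a = 4.58, b = 0.5)} (which yields
#' d = 8.16 and a much weaker relative gain).
#'
#' @param a amplitude of the feedback term (dimensionless).
#' @param b lower asymptote as eda grows large (dimensionless).
#' @param eda_ref reference extracellular dopamine concentration (uM) at
#'   which the factor equals 1.
#' @param d inner denominator constant; defaults to the unique value making
#'   the factor equal 1 at \code{eda_ref}.
#' @param hill Hill exponent.
#' @return An object of class \code{"autoreceptor_calibration"}.
#' @export
autoreceptor_calibration <- function(a = 4.58 / 2.79, b = 0.5 / 2.79,
                                     eda_ref = 0.002024,
                                     d = NULL, hill = 4) {
  if (is.null(d)) d <- a / (1 - b) - 1
  stopifnot(a > 0, b >= 0, b < 1, eda_ref > 0, d > 0, hill > 0)
  structure(list(a = a, b = b, eda_ref = eda_ref, d = d, hill = hill),
            class = "autoreceptor_calibration")
}

#' Parameters of the Dopamine Ultradian Oscillator (DUO)
#'
#' Extends the reduced model with a shared extracellular dopamine pool
#' (dopaminergic tone) and latent D2 autoreceptor signalling.  The pool
#' variables are dimensionless; the coupling constants \code{k1_pool} to
#' \code{k4_pool} are in 1/hr.  The sigmoid replacing the eda-based
#' autoreceptor factor is parameterised by \code{alpha}, \code{beta},
#' \code{gamma} (midpoint scale) and \code{m} (steepness).
#'
#' @param k1_pool,k2_pool,k3_pool,k4_pool linear coupling rates (1/hr).
#' @param alpha lower plateau of the D2 sigmoid.
#' @param beta sigmoid amplitude (upper plateau is \code{alpha + beta}).
#' @param gamma midpoint scale; the sigmoid midpoint sits at
#'   \code{gamma * (2 - s_dat)}.
#' @param m sigmoid steepness (smaller is steeper).
#' @param s_dat fixed fractional DAT activity in [0, 1].
#' @param reduced embedded \code{\link{reduced_params}} object.
#' @return Object of class \code{"duo_params"}.
#' @seealso \code{\link{duo_preset}} for the two published parameter sets.
#' @export
duo_params <- function(k1_pool, k2_pool, k3_pool, k4_pool,
                       alpha, beta, gamma, m, s_dat = 1,
                       reduced = reduced_params()) {
  rates <- c(k1_pool = unname(k1_pool), k2_pool = unname(k2_pool),
             k3_pool = unname(k3_pool), k4_pool = unname(k4_pool),
             alpha = unname(alpha), beta = unname(beta),
             gamma = unname(gamma), m = unname(m))
  if (!all(is.finite(rates)) || any(rates <= 0))
    stop("duo_params: all coupling constants must be positive")
  if (!is.finite(s_dat) || s_dat < 0 || s_dat > 1)
    stop("duo_params: s_dat must lie in [0, 1]")
  stopifnot(inherits(reduced, "reduced_params"))
  structure(c(as.list(rates), list(s_dat = s_dat, reduced = reduced)),
            class = "duo_params")
}

#' Published DUO parameter presets
#'
#' Two parameter sets used throughout the analyses:
#' \describe{
#'   \item{\code{"ultradian"}}{an oscillator with a free-running period of
#'     about 4.6 hours that persists under circadian modulation.}
#'   \item{\code{"dat_sensitive"}}{an oscillator whose period is strongly
#'     shaped by the DAT activity level \code{s_dat} (roughly 4 h at
#'     \code{s_dat = 1} rising towards 12 h at \code{s_dat = 0.3}), with a
#'     Hopf bifurcation near \code{s_dat = 0.26}.}
#' }
#'
#' @param name preset name.
#' @param s_dat fractional DAT activity for the returned parameter set.
#' @param reduced embedded \code{\link{reduced_params}}.
#' @return Object of class \code{"duo_params"}.
#' @export
duo_preset <- function(name = c("ultradian", "dat_sensitive"), s_dat = 1,
                       reduced = reduced_params()) {
  name <- match.arg(name)
  switch(name,
    ultradian = duo_params(k1_pool = 4519.93, k2_pool = 0.38,
                           k3_pool = 22.3, k4_pool = 2.34,
                           alpha = 0.5, beta = 0.5, gamma = 193.93,
                           m = 1.1, s_dat = s_dat, reduced = reduced),
    dat_sensitive = duo_params(k1_pool = 21118.5, k2_pool = 1.89,
                               k3_pool = 34.45, k4_pool = 0.47,
                               alpha = 0.5, beta = 4.5, gamma = 2139.25,
                               m = 0.01, s_dat = s_dat, reduced = reduced))
}

#' Latin hypercube sampling ranges for the DUO coupling parameters
#'
#' Default search box for oscillatory parameter sets: the pool input rate
#' \code{k1_pool} exceeds the extracellular removal rate (400/hr) and spans
#' two orders of magnitude; parameters whose range spans two or more orders
#' of magnitude are sampled log-uniformly.
#'
#' @return Named list of \code{c(lower, upper)} ranges with a
#'   \code{"log"} attribute naming the log-uniform parameters.
#' @export
lhs_ranges <- function() {
  r <- list(k1_pool = c(400, 40000), k2_pool = c(0.1, 40),
            k3_pool = c(0.1, 40), k4_pool = c(0.1, 40),
            alpha = c(0.5, 4.5), beta = c(0.5, 4.5),
            gamma = c(100, 10000), m = c(0.005, 5))
  attr(r, "log") <- c("k1_pool", "gamma", "m")
  r
}

#' Latin hypercube sample of DUO parameter sets
#'
#' Draws a maximin-free random Latin hypercube design over the printed
#' ranges and maps each row to a \code{\link{duo_params}} object.  Sampling
#' is log-uniform for parameters flagged in \code{attr(ranges, "log")} and
#' uniform otherwise; identical seeds give identical designs.
#'
#' @param n number of parameter sets.
#' @param seed integer seed for the design.
#' @param ranges range list as returned by \code{\link{lhs_ranges}}.
#' @param s_dat fixed DAT activity assigned to every sample.
#' @return List of \code{duo_params}; the raw unit design is attached as
#'   attribute \code{"design"}.
#' @export
lhs_sample_duo <- function(n, seed = 1L, ranges = lhs_ranges(), s_dat = 1) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n, length(ranges))
  colnames(u) <- names(ranges)
  logs <- attr(ranges, "log")
  vals <- u
  for (j in names(ranges)) {
    rg <- ranges[[j]]
    vals[, j] <- if (j %in% logs)
      exp(log(rg[1]) + u[, j] * (log(rg[2]) - log(rg[1])))
    else rg[1] + u[, j] * (rg[2] - rg[1])
  }
  out <- lapply(seq_len(n), function(i)
    duo_params(k1_pool = vals[i, "k1_pool"], k2_pool = vals[i, "k2_pool"],
               k3_pool = vals[i, "k3_pool"], k4_pool = vals[i, "k4_pool"],
               alpha = vals[i, "alpha"], beta = vals[i, "beta"],
               gamma = vals[i, "gamma"], m = vals[i, "m"], s_dat = s_dat))
  attr(out, "design") <- u
  out
}

#' @export
print.reduced_params <- function(x, ...) {
  cat("Reduced dopamine model parameters (uM, uM/hr, 1/hr):\n")
  print(unlist(x), ...)
  invisible(x)
}

#' @export
print.duo_params <- function(x, ...) {
  cat("DUO coupling parameters (pool rates 1/hr, sigmoid dimensionless):\n")
  print(unlist(x[c("k1_pool", "k2_pool", "k3_pool", "k4_pool",
                   "alpha", "beta", "gamma", "m", "s_dat")]), ...)
  cat("embedded reduced-model parameters: Table of",
      length(unclass(x$reduced)), "constants\n")
  invisible(x)
}
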