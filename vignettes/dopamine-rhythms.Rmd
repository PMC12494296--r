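---
title: "Modelling circadian and ultradian dopamine dynamics with dopadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling circadian and ultradian dopamine dynamics with dopadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopadyn)
```

## The model

`dopadyn` simulates a four-variable kinetic model of a dopaminergic
terminal.  The state variables, all in µM, are levodopa (`ldopa`),
cytosolic dopamine (`cda`), vesicular dopamine (`vda`) and extracellular
dopamine (`eda`):

$$
\begin{aligned}
ldopa' &= V_{TH}(cda, eda) - V_{AADC}(ldopa)\\
cda'   &= V_{AADC}(ldopa) - V_{MAT}(cda, vda) + V_{DAT}(eda) - k_{cda}\,cda\\
vda'   &= V_{MAT}(cda, vda) - fire(t)\,vda\\
eda'   &= fire(t)\,vda - V_{DAT}(eda) - V_{CATAB}(eda) - k_{eda}\,eda
\end{aligned}
$$

$V_{AADC}$, $V_{DAT}$ and $V_{CATAB}$ are Michaelis–Menten velocities;
$V_{MAT}$ is forward Michaelis–Menten packaging minus a linear vesicular
leak $k_{out}\,vda$, so it can run backwards when the vesicular pool is
overfull.  Tyrosine (126 µM) and tetrahydrobiopterin (319 µM) are held
fixed, which makes the tyrosine hydroxylase (TH) velocity a product of
three factors: a constant substrate-inhibition term
$0.56/(1 + tyr/K_{i,tyr})$, the autoreceptor feedback factor (below), and
a saturating term weakly inhibited by cytosolic dopamine,
$V_{max,tyr}\,tyr\,bh4 / (tyr\,bh4 + K_{tyr}\,bh4 +
K_{tyr} K_{bh4}(1 + cda/K_{i,cda}))$.  All kinetic constants are exposed
through `reduced_params()`; the defaults are the standard literature
values for this terminal model.

Timescales are deliberately heterogeneous: the extracellular removal rate
$k_{eda} = 400$/hr and the AADC capacity $V_{max,ldopa} = 10{,}000$
µM/hr make `eda` and `ldopa` fast slave variables of the slowly turning
vesicular store.  This stiffness is why the solver defaults matter (see
*Numerics*).

### Autoreceptor feedback and its calibration

Presynaptic D2 autoreceptors inhibit TH when extracellular dopamine is
elevated.  The feedback factor is a decreasing Hill-type function

$$ f(eda) = \frac{a}{(eda/c)^4 + d} + b, \qquad c = 0.002024\ \mu M, $$

required to equal exactly 1 at the reference steady state $c$, so that
feedback does not displace the nominal equilibrium.  The classic
coefficients $4.58$ and $0.5$ around a unit-denominator Hill term give
$4.58/2 + 0.5 = 2.79$ at $eda = c$, violating that normalisation.  Two
one-parameter repairs exist:

* rescale the inner constant to $d = a/(1-b) - 1 = 8.16$, which keeps the
  printed coefficients but shrinks the *relative* feedback gain
  $\mathrm{d}\log f/\mathrm{d}\,eda$ at the operating point roughly
  7.5-fold; or
* rescale the whole term by its value at the reference point
  ($a = 4.58/2.79$, $b = 0.5/2.79$, $d = 1$), which preserves the shape
  and the relative gain exactly.

`dopadyn` uses the second as its default, because the relative gain is
what the dynamics feel: with it, the forced limit cycle peaks and the
homeostatic damping agree closely with the behaviour this model family is
known for (ldopa peaking ≈ 17.3 h into the circadian cycle with the
downstream variables ≈ 1.5 h later, as the acceptance suite computes).
The first variant remains available as
`autoreceptor_calibration(a = 4.58, b = 0.5)` and is exercised in the
tests.  With the factor pinned to 1
(`dopamine_model(autoreceptors = FALSE)`), a doubling of the release rate
doubles equilibrium `eda`; with feedback active the response drops to
≈ 1.35×.

### Circadian forcing

The molecular clock is not modelled mechanistically; its output is
imposed as sinusoidal multipliers
$C_{TH}(t) = 0.25\sin(\tfrac{\pi}{12}(t - 12)) + 1$ on $V_{TH}$ and
$C_{MAO}(t) = 0.25\sin(\tfrac{\pi}{12}(t - 20)) + 1$ on $V_{CATAB}$,
ranging over [0.75, 1.25] with TH activity peaking at $t = 18$ h and MAO
activity 8 h later.  `circadian_config()` exposes amplitude, phases and
baseline scales (the 0.75×/1.25× baseline shifts used for robustness
checks).  $C_{MAO}$ multiplies only the extracellular catabolism
velocity; the intracellular clearance $k_{cda}\,cda$ is deliberately not
modulated.

### Reuptake inhibitors

A dopamine reuptake inhibitor (DRI) is modelled as a fractional
transporter occupancy $x_{dose}$ that jumps by `Dose` at each
administration time and decays exponentially with rate
$r = \ln 2 / t_{1/2}$ (15 h by default, modafinil-like).  The DAT
velocity is scaled by $\max(1 - x_{dose}(t), 0)$ in both equations where
it appears.  Because the occupancy equation is linear, `dopadyn`
evaluates $x_{dose}(t)$ in closed form and restarts the integrator at
each administration, so dose jumps are exact rather than smoothed
delta-functions.  Time is circadian time: $t = 0$ is CT0.

### The Dopamine Ultradian Oscillator (DUO)

The six-variable extension couples the terminal to a shared extracellular
dopamine pool and latent D2 signalling:

$$ edapool' = k_{1}^{pool}\,eda - k_{2}^{pool}\,edapool, \qquad
   D2' = k_{3}^{pool}\,edapool - k_{4}^{pool}\,D2, $$

with the eda-based autoreceptor factor replaced by the adaptive sigmoid

$$ \mathcal{A}(D2) = \alpha +
   \frac{\beta}{1 + \exp\!\big((D2 - \gamma(2 - s_{DAT}))/m\big)}. $$

`edapool` and `D2` are dimensionless latent variables; no physical units
are assigned to them.  The linear chain introduces the delay that turns
the negative feedback into a relaxation oscillator.  The sigmoid midpoint
$\gamma(2 - s_{DAT})$ shifts right as DAT activity falls, modelling
autoreceptor adaptation to elevated tone.  Evaluation goes through the
logistic CDF so extreme arguments saturate instead of overflowing —
essential for the `dat_sensitive` preset, whose steepness $m = 0.01$
makes the sigmoid nearly a switch.  In the DUO, $s_{DAT}$ is a fixed
constant of the parameter set rather than a decaying dose trajectory:
ultradian period and amplitude vary strongly across parameter sets, and a
fixed activity level isolates the steady-state effect of reuptake
inhibition from dose-timing confounds.

Two presets ship with the package: `duo_preset("ultradian")`, a
free-running oscillator with period ≈ 4.4 h (the acceptance script
computes 4.38 h) that persists under circadian modulation, and
`duo_preset("dat_sensitive")`, whose period stretches from under 4 h at
$s_{DAT} = 1$ towards 9–12 h at $s_{DAT} = 0.3$ and which loses its limit
cycle in a Hopf bifurcation at $s_{DAT} \approx 0.265$.

## Equilibria and stability

`find_equilibrium()` does not iterate on the full system.  At steady
state the `eda` balance yields `vda` explicitly, the vesicular balance
inverts to `cda` (subject to the packaging-capacity bound
$q < V_{max,cda}$, which delimits the feasible `eda` range), and the
`cda` balance fixes the required AADC flux and hence `ldopa`.  What
remains is a single scalar residual in `eda` — the levodopa balance —
which is strictly decreasing because every feedback path (autoreceptor,
cda-inhibition of TH) is monotone.  The root is bracketed and bisected to
near machine precision; the feasible equilibrium is therefore unique by
construction, and an optional grid scan (`check_unique = TRUE`) verifies
the sign pattern.  For the DUO the pool variables collapse onto the
linear-chain balance $edapool^* = (k_1/k_2)\,eda^*$,
$D2^* = (k_3/k_4)\,edapool^*$, so the same scalar reduction applies.

Jacobians are derived analytically (`model_jacobian()`), including the
Hill and sigmoid derivatives, and cross-validated against central finite
differences in the tests.  `stability_map()` freezes the circadian
multipliers at each phase (the quasi-static approximation: the clock
moves much more slowly than the terminal kinetics), solves the
equilibrium over an $(s_{DAT}, \phi)$ grid and records the dominant
eigenvalue; across $s_{DAT} \in [0.01, 1]$ and all phases the dominant
eigenvalue stays below $-0.45$/hr.  At $s_{DAT} = 0$ the package finds
all-real negative spectra at every phase as well — there is no mechanism
for a sign change there, since every feedback loop is negative and
extracellular decay is fast; reports of instability at that corner in
this model family do not reproduce from the analytic Jacobian.
`hopf_locate()` bisects the dominant real part over an $s_{DAT}$ bracket
(tolerance $10^{-3}$) and verifies a nonzero imaginary pair at the
crossing.

## Numerics

* **Integration**: `deSolve::lsoda` with the analytic Jacobian
  (`jactype = "fullusr"`), `rtol = 1e-8`, `atol = 1e-10`, and a maximum
  internal step of 0.1 h so the circadian forcing and the fast `eda`
  transients are always resolved.  The tests check self-convergence of
  dose metrics under tolerance refinement (< 0.1% drift).
* **Negative round-off**: states are clipped at $-10^{-9}$ inside the
  integrator; any component below $-10^{-6}$ aborts with an integrity
  error.  User-facing velocity functions reject negative inputs outright.
* **Burn-in**: 240 h (ten forced periods) before any protocol metric.
  The slowest system eigenvalue is ≈ −0.65/hr, so transients decay by
  more than a factor of $10^{60}$ over the burn-in; the forced trajectory
  is 24 h-periodic to < $10^{-4}$ relative afterwards.
* **Output grid**: 0.01 h for medians, percentiles and peak timing; this
  resolves the fast `eda` transient well enough that halving the grid
  changes 24-h medians by < 0.05%.  Peak times are refined by local
  quadratic interpolation of the sampled maximum.
* **Statistics windows**: the post-dose window is the half-open interval
  $(t_{dose}, t_{dose} + 24]$; moving statistics are trailing windows
  evaluated every 0.25 h.  "Percent above steady state" is always
  relative to the drug-free, circadian-free nominal equilibrium
  ($eda^* \approx 0.002023$ µM).
* **Oscillation metrics**: local maxima are detected by
  peak-to-adjacent-saddle prominence (threshold $10^{-6}$ µM); the period
  is the mean refined peak-to-peak interval and the amplitude the mean
  peak-to-trough excursion per cycle.  Trajectories relaxing to a fixed
  point report amplitude 0; records with visible cycles but fewer than
  three detected peaks raise an error rather than guessing.  Amplitude is
  defined peak-to-trough throughout; only internal consistency of this
  convention matters for the non-monotonicity analyses.
* **Tie-breaking**: optima over dose-time grids take the earliest time.

## Experiment design choices

* Dose-timing sweeps share one burnt-in drug-free limit cycle and restart
  each dosed run from the cycle state at its own administration time,
  which makes the 49-point half-hourly sweep cheap without changing any
  result.
* The firing-rate homeostasis sweep uses constant release-rate
  multipliers (steady-state response per multiplier); no temporal firing
  profile is assumed.
* Latin hypercube search (`lhs_sample_duo()`) samples `k1_pool`, `gamma`
  and `m` log-uniformly — their printed ranges span two to three orders
  of magnitude — and the remaining parameters uniformly.  Only the
  design consumes randomness, and a single seed threads through
  `run_manifest()` for reproducibility.
* DUO runs start from the model's own equilibrium (pool variables at
  their chain-balance values) perturbed by 2%, which shortens transients
  without biasing the attractor.
* The published sensitivity protocol (each parameter scaled 0.75–1.25×,
  100 simulated days, final 4 days recorded) is the default of
  `sensitivity_ridge()`; the test suite runs a shorter variant (10 days,
  3 recorded) that states its own burn-in and is used only as a
  regression check, not for the headline figures.
* Desk-scale grids (e.g. 3×3 half-life × dose, 25×24 stability map) are
  the package defaults; full published-resolution grids are reached by
  passing the finer grids explicitly.

## What the synthetic protocols do and do not show

All inputs are generated by the package itself — parameter tables,
sinusoidal forcing, dose schedules — so every published-figure experiment
is reproducible from a config file and a seed, with no external data.
The flip side is that agreement of these simulations with the published
numbers validates the implementation, not the biology: the circadian
drive is a clean sinusoid rather than measured enzyme rhythms,
inter-individual variability enters only through baseline shifts, dose
kinetics are single-compartment with instantaneous absorption, and the
`eda` pool is a well-mixed latent variable with no spatial structure.
Known limitations worth keeping in mind: the full nine-variable parent
model is not runnable here (its blood-tyrosine input is unspecified, and
homovanillic-acid bookkeeping is omitted); melatonin coupling and
upstream molecular-clock mechanisms are out of scope; and the DUO's
latent variables have no measurement units, so its amplitudes are
comparable only within the model.

## Reproducing the headline numbers

```{r, eval = FALSE}
# nominal equilibrium (µM): ldopa 0.356, cda 2.646, vda 80.958, eda 0.002023
find_equilibrium(dopamine_model(circadian = circadian_config(enabled = FALSE)))

# circadian peak timing: ldopa at ~17.27 h, downstream ~1.53 h later
tr <- run_protocol(dopamine_model(), days = 1, burn_in = 240)
peak_time_in_cycle(tr, "ldopa")

# Hopf point of the DAT-sensitive DUO: s_dat ~ 0.2646
hopf_locate(duo_model(duo_preset("dat_sensitive")), c(0.05, 0.9))
```

The full set of headline quantities is recomputed from scratch by
`scripts/acceptance.R` (see the README).
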