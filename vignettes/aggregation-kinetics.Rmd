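---
title: "Models and methods: fibril proliferation and oligomer dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: fibril proliferation and oligomer dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggkin)
```

## The scientific question

Amyloid fibrils can multiply through several microscopic routes: new
fibrils can nucleate directly from monomers (primary nucleation), existing
fibrils can break (fragmentation), and fibril surfaces can catalyse the
formation of new aggregates from monomers (secondary nucleation). Bulk
aggregation curves alone often cannot distinguish the last two, because
both produce autocatalytic proliferation with the same half-time scaling.
`aggkin` implements the combination of measurements that does separate
them: global fitting of bulk kinetics, an independent bound on
fragmentation from fibril lengths in the plateau phase, and the population
dynamics of transient oligomers.

## The bulk model

The package works with the standard moment equations for the fibril number
concentration $P$ and mass concentration $M$ (both in monomer-equivalent
µM), with free monomer $m = m_\mathrm{tot} - M$:

$$\frac{dP}{dt} = k_n m^{n_c} + k_2 m^{n_2} M + k_- M, \qquad
  \frac{dM}{dt} = 2 k_+ m P.$$

Design choices in this formulation:

* The factor 2 in the elongation term assumes growth at both fibril ends.
* Monomer consumed by nucleation events themselves is neglected in the
  mass balance; nuclei are mass-negligible compared with elongation.
* Saturated secondary nucleation -- monomer attachment to the fibril
  surface fast, conversion/release rate limiting -- is encoded simply as
  reaction order $n_2 = 0$, not through an explicit Michaelis constant.
  With $n_2 = 0$ the secondary term $k_2 M$ has exactly the same form as
  the fragmentation term $k_- M$, which is why bulk data alone cannot
  separate the two mechanisms and an independent fragmentation measurement
  is needed.
* Units are hours and µM everywhere inside the package; per-second rates
  appear only where results are reported against literature values.

Two effective rates summarize the network at a given initial monomer
concentration $m_0$: the primary pathway rate
$\lambda = \sqrt{2 k_+ k_n m_0^{n_c}}$ and the proliferation rate
$\kappa = \sqrt{2 k_+ (k_2 m_0^{n_2} + k_-) m_0}$. These composites, not
the individual constants, are what bulk data determine.

`simulate_fibril_mass()` integrates the system with `deSolve::lsoda`
(absolute tolerance $10^{-9} m_\mathrm{tot}$, relative $10^{-8}$).
Trajectories satisfy mass conservation $m + M = m_\mathrm{tot}$ to within
$10^{-6} m_\mathrm{tot}$ by construction and are checked for monotonicity
in the tests.

## The analytical approximation

Fitting needs thousands of forward evaluations, so
`closed_form_fibril_mass()` provides a fast fixed-point solution. Holding
$m$ at $m_0$ makes the moment system linear, with solution

$$M_\mathrm{lin}(t)/m_0 = \frac{2 k_+ P_0}{\kappa}\sinh(\kappa t)
  + \left(\frac{\lambda^2}{\kappa^2} + \frac{M_0}{m_0}\right)
    \cosh(\kappa t) - \frac{\lambda^2}{\kappa^2},$$

and substituting this growth back into the monomer balance gives
$m(t) = m_0 \exp\{-(M_\mathrm{lin}(t) - M_0)/m_0\}$. That single
iteration reproduces half-times to a few percent but overshoots
mid-transition (sup-norm error up to ~8% in the regimes of interest). The
package therefore performs one further Picard step: the nucleation fluxes
are re-evaluated along the first iterate and the monomer balance is
re-integrated by trapezoidal quadrature on a dense internal grid (10-fold
refinement of the requested grid, minimum 200 points). The refined
solution agrees with the stiff ODE integration to within 1.5% sup-norm --
comfortably inside the 5% band asserted by the test suite -- for
$\lambda/\kappa \le 0.1$ and seed loads up to 2%, and is exact in the
pure-elongation limit. The $\kappa \to 0$ (primary-only) limit is handled
by a stable series branch.

## Curve descriptors and the scaling exponent

`half_time()` and `lag_time()` locate the first crossing of 50% and 25%
aggregation by linear interpolation (ties resolved to the first
crossing); a curve that starts above the lag threshold has lag 0.
`scaling_exponent()` is the least-squares slope of $\log_{10} t_{1/2}$
against $\log_{10} m_\mathrm{tot}$.

For proliferation through either order-0 secondary nucleation or
fragmentation, $\kappa \propto \sqrt{m_\mathrm{tot}}$, and the exponent is
$-1/2$; for primary-only kinetics it is $-n_c/2$. A subtlety fixed one
default: the half-time is $t_{1/2} = F(\lambda/\kappa)/\kappa$, so the
exponent is exactly $-1/2$ only if $\lambda/\kappa$ is
concentration-independent, i.e. $n_c = n_2 + 1$. The package's default
$n_c = 1$ (with $n_2 = 0$) realizes the clean $-1/2$ scaling that the
assay class shows, and is consistent with primary nucleation being an
effectively low-order heterogeneous (surface-assisted) process. With
$n_c = 2$ the logarithmic correction would drag the apparent exponent to
about $-0.55$ to $-0.6$ unless $\lambda/\kappa$ were absurdly small.

## Normalization and global fitting

Raw plate-reader signal is assumed proportional to fibril mass, whether it
rises (ThT binding) or falls (dye quenching). `normalize_trace()` maps the
signal affinely to [0, 1] using the means of the first and last 5% of
points; the same formula flips decreasing traces, and the map is exactly
idempotent. A trace whose range is below 5 estimated noise SDs is
rejected as having no transition. Because normalization anchors on the
observed transition, the model prediction is compared on the same scale,
$(f - f_0)/(1 - f_0)$ with $f_0$ the seed mass fraction.

`global_fit()` minimizes the summed squared residuals over all traces
(unweighted: the assay provides no per-point error model) with
`minpack.lm::nls.lm` in log10 space over the composites
$k_+ k_n$ and $k_+ k_2$ (or $k_+ k_-$). Individual constants are not
identifiable from bulk data, and reporting therefore centres on $\kappa$
and $\lambda$ at a reference concentration (default 100 µM). Two details
matter in practice:

* **Seeds.** Seed number is derived from seed mass through a configurable
  mean seed length (default 2000 monomers, the order of an unsonicated
  micron-long fibril at ~0.5 nm axial rise per monomer). The seeded
  closed form involves $k_+ P_0$, which is not a function of the two
  composites alone, so when seeded traces are present $k_+$ is fitted (or
  fixed) as a third log-scale parameter; the paired seeded/unseeded design
  makes it identifiable.
* **Starts.** The optimizer is run from `n_starts` (default 5) starting
  points: two deterministic bases -- a secondary-dominated guess with
  $\kappa$ from the steepest observed slope, and a primary-dominated guess
  with $\lambda$ set by the observed half-time -- plus seeded random
  perturbations of them. The best objective wins; ties go to the smaller
  parameter norm. Non-convergence is warned about, never silently
  accepted.

`compare_primary_vs_secondary()` fits both model variants and declares
secondary processes required when the primary-only objective exceeds the
secondary one by a configurable factor (default 5). The factor is a
package default chosen because the misfit of a primary-only model to
autocatalytic data is typically gross (orders of magnitude, not tens of
percent); ratios between 1 and the factor are reported as indeterminate
rather than forced into a verdict. `fit_with_fragmentation_fixed()` pins
the proliferation composite to an externally measured
$\kappa_\mathrm{frag}$ so that the fragmentation-only hypothesis can be
confronted with the bulk data.

## Fragmentation from plateau fibril lengths

In the plateau phase the fibril mass is constant at $M_\infty$ while
fragmentation keeps cutting, so $dP/dt = k_- M_\infty$ and the mean length
decays as $L(t) = 1/(k_- t + 1/L_\mathrm{plateau})$. `fit_length_series()`
fits this law to per-timepoint mean lengths, weighted by $1/\mathrm{SEM}^2$,
with both parameters free. $L_\mathrm{plateau}$ is estimated jointly with
$k_-$ rather than plugged in from a steady-state expression; joint fitting
uses strictly more of the data and reduces to the plug-in estimate when
the first timepoint dominates. The product
$\kappa_\mathrm{frag} = L_\mathrm{plateau} k_-$ -- with lengths in monomer
units this is directly a rate in h$^{-1}$ -- is an upper bound on
proliferation through fragmentation alone, and is invariant to the length
unit used. Uncertainty comes from a percentile bootstrap over fibrils
within timepoints (parametric-exponential when only means are stored).

Individual lengths are modelled as exponentially distributed within a
timepoint. Since fitting uses only the means, this choice affects noise
realism, not the estimator; it also sets SEM = mean$/\sqrt{n}$ when only
summary data are available. Capture bias on the microscope grid (long and
short fibrils adsorbing unequally) is not modelled.

## Oligomer population dynamics

Two linear-in-$S$ balances describe the transient oligomer mass
concentration: formation from monomers with solution-phase dissociation
(primary origin), or fibril-catalysed formation and dissociation
(secondary origin, both terms proportional to $M(t)$). The bulk
trajectory supplies $m(t)$ and $M(t)$. `integrate_oligomers()` advances
the balance with an exponential-integrator step (exact for locally
constant source and sink) on a refined grid, which is unconditionally
stable under the fast dissociation this system shows; the steady state
$S^* = (k_\mathrm{form}/k_\mathrm{diss}) m^{n_o}$ is reproduced to
integrator tolerance.

Fitting choices:

* Reaction order $n_o = 1$ by default (configurable); the data do not
  constrain it independently.
* The series scale is taken as-is rather than fitting a separate
  relative-to-absolute factor: such a factor would multiply
  $k_\mathrm{form}$ and is exactly degenerate with it. Because
  single-molecule counting after dilution detects at most a fraction of
  the oligomer mass, the fitted formation rate is a lower bound on the
  true rate, and is reported per µM fibril mass at 100 µM monomer in both
  h$^{-1}$ and s$^{-1}$.
* $S_0 = 0$: no oligomers at reaction start.
* Weighted least squares with $1/\mathrm{sem}^2$ where replicate SEMs
  exist; a residual sign-bias diagnostic flags systematic misfit (e.g.
  when dissociation is wrongly suppressed).

`select_oligomer_model()` fits both origins jointly across paired
unseeded and seeded conditions with shared rate constants and selects the
lower objective; objectives within 10% of each other are declared
indeterminate. The pairing is what gives the test its power: seeding
shifts the fibril mass curve in time, and only the fibril-catalysed model
shifts the oligomer peak with it. `oligomer_peak_time()` locates the peak
by parabolic interpolation and reports it relative to the bulk half-time
(below 1 when oligomers peak first, the signature of a fibril-catalysed
origin); a maximum on the series boundary is flagged instead of
interpolated.

## Photon-burst quantification

`estimate_oligomer_signal()` turns a binned confocal photon timetrace into
a relative oligomer mass: background mean and SD are estimated after
excluding the brightest 1% of bins, the threshold is set at mean +
`k_sigma` SD, maximal runs of supra-threshold bins count as events, and
the summed photon excess above threshold per unit time is the estimate.
The default `k_sigma = 8` at 1 ms bins is calibration-pinned: on pure
Poisson background of ~5 counts/bin it yields fewer than one false event
per minute, while typical bursts (tens to hundreds of photons) clear the
threshold easily. The estimator is deliberately relative -- proportional
to oligomer concentration, with an unknown detection prefactor -- so all
downstream use is ratio-based. `aggregate_positions()` pools positions or
replicates into a mean with SEM, leaving the SEM absent for single
measurements.

The matching simulator draws Poisson background, Poisson-timed burst
arrivals proportional to oligomer concentration, and log-normal burst
brightness (heavy-tailed, emulating heterogeneous oligomer sizes). An
optional uniform per-burst detection-efficiency factor emulates the
non-uniform confocal profile; it is off by default.

## The synthetic-data generators

The generators produce every input the pipeline consumes, at the study
conditions as their defaults: 100 µM monomer, seeds 0/0.25/1% of mass,
$\kappa = 0.4$ h$^{-1}$ with $\lambda/\kappa = 0.01$ (unseeded half-times
near 24 h on a 40 h acquisition at 10 min reads), fragmentation pair
$k_- = 10^{-5}$ h$^{-1}$, $L_\mathrm{plateau} = 1000$ monomers (product
0.01 h$^{-1}$, 5 plateau timepoints over 100 h, 700 fibrils each),
fibril-catalysed oligomers at $4\times10^{-5}$ s$^{-1}$ per µM fibril
mass at 100 µM with fast dissociation, 8 replicates per timepoint.
Bulk noise is additive Gaussian at 1% of the dynamic range
(plate-reader-like); oligomer noise is multiplicative log-normal at 10%
(counting-statistics-like). The elongation constant behind the defaults
is $k_+ = 10$ µM$^{-1}$h$^{-1}$, which together with the 2000-monomer
seed length gives seeded half-times of roughly 9--13 h, i.e. a clear
seed-concentration-dependent acceleration without collapsing the lag
phase entirely.

Every generator takes an explicit RNG seed, restores the caller's RNG
state, is bit-reproducible under the same seed, and attaches its full
ground truth as metadata.

What the generators deliberately do not emulate: baseline drift and
well-to-well gain variation in plate readers, non-exponential length
distributions and capture bias in microscopy, detector afterpulsing and
diffusion-shaped burst profiles in the photon traces, and any biological
seeding matrices. Passing tests on these generators therefore validate
the estimators' correctness and calibration under the model's own
assumptions, not robustness to every artefact of real instruments.

## Problem sizes and numerical tolerances

The validation suite runs on deliberately modest sizes: 241-point kinetic
traces, three to four conditions per fit, 20--40 replicate fits in the
model-selection harnesses, 700 fibrils per length timepoint, 60 s photon
traces at 1 ms bins. Optimizer tolerances are `nls.lm` defaults with a
200-iteration cap; bootstrap CIs use 100--200 resamples. Degenerate
inputs (flat traces, all-zero series, boundary maxima, zero-fragmentation
length series) are rejected or flagged explicitly rather than returned as
numbers.

## Known limitations

* Bulk fitting returns composite rates only; individual microscopic
  constants require orthogonal experiments (e.g. seeded elongation
  assays constrain $k_+$).
* The closed form is an approximation; outside its validity regime
  (primary-dominated yet strongly seeded corners) `global_fit()` can be
  switched to the exact ODE forward model at ~10-fold cost.
* The fragmentation bound inherits any bias in mean-length estimation.
* Absolute oligomer concentrations are not recoverable from relative
  series; only rates and model discrimination are.
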