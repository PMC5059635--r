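---
title: "From umbrella windows to binding free energies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From umbrella windows to binding free energies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfbind)
```

## The model

`pmfbind` treats drug binding to an ion-channel pore as diffusion of the
ligand centre of mass along a single reaction coordinate z (Å), measured
relative to an anchor at the base of the selectivity filter; more negative
z is deeper toward the intracellular gate, and the bulk aqueous phase lies
at the most negative end of the profile. The free-energy profile along z
is the potential of mean force w(z). Lateral motion is not modelled
explicitly: a flat-bottom cylindrical restraint of radius R confines the
ligand, and the restrained volume enters the dissociation constant
analytically,

$$K_D \;=\; \Big[\pi R^2\, N_A\, 10^{-27} \int_{\text{site}}
e^{-w(z)/k_BT}\,dz\Big]^{-1}, \qquad
\Delta G \;=\; k_BT\,\ln\!\big(K_D/c^0\big),$$

with w in kcal/mol anchored to zero in bulk, the integral in Å (the
10⁻²⁷ converts Å³ to litres) and $c^0 = 1$ M. This is an *effective*,
one-dimensional estimate: no orientational or conformational restraint
corrections are applied, and every report the package writes repeats that
caveat. The constants are pinned
($k_B = 1.9872041\times10^{-3}$ kcal mol⁻¹ K⁻¹,
$N_A = 6.02214076\times10^{23}$ mol⁻¹) so conversions are reproducible
bit-for-bit; defaults are T = 310.15 K and R = 10 Å.

For the ionizable amine carried by many pore blockers, the cationic
fraction follows Henderson–Hasselbalch for a base,
$f = 1/(1+10^{\,pH-pK_a})$. The pKa is a property of the particular
drug, so `protonated_fraction()` takes it as an explicit argument and
ships no default.

## What the synthetic-data generator emulates

Umbrella sampling restrains the ligand in windows along z with a harmonic
bias $U_i(z) = \tfrac{k}{2}(z-z_i)^2$ (a `bias_half = FALSE` switch
selects the $k(z-z_i)^2$ dialect some WHAM tools assume). The standard
layouts are windows every 0.5 Å with k = 10 kcal mol⁻¹ Å⁻²: 85 windows
on [−49.5, −7.5] for an open pore and 60 on [−38, −8.5] for an
open-inactivated pore, each corresponding to 22 ns of simulation of which
the first 2 ns are discarded.

The generator replaces MD with exact sampling of the biased Boltzmann law
on analytic ground-truth potentials:

* **Presets.** `open-like` has two separated wells of −8 and −7 kcal/mol
  (two tentative intra-cavity sites); `inactivated-like` has a single
  deep −18 kcal/mol well plus a shallow outer minimum near the gate —
  the qualitative signature of lock-in binding; `flat`, `harmonic` and
  `square-well` exist for closed-form checks. All presets with a bulk
  plateau are zero there, at the gate-side (most negative) end of the
  domain.
* **Sampler.** The default scheme is random-walk Metropolis with Gaussian
  proposals of width $\sqrt{2D\,dt}$ on a finely tabulated copy of the
  potential (0.01 Å grid, linear interpolation). Metropolis acceptance
  makes the stationary law *exactly* the biased Boltzmann density of the
  tabulated potential at any step size and any temperature — which is
  what downstream WHAM checks need — whereas a Metropolis-adjusted
  Langevin proposal gains little here and its drift term diverges in the
  low-temperature limit we use as a degenerate-input test. An uncorrected
  overdamped-Langevin scheme is provided for contrast; it carries the
  usual O(dt) discretization bias and a divergence guard (a walker
  leaving the domain by more than 5 Å aborts with a smaller-`dt` hint).
* **Time units.** Reduced: one recorded sample stands in for one saved
  frame. The 22-ns window maps to the default 2.2×10⁵ samples per window
  (one sample per 0.1 ps of nominal trajectory — a free choice, since no
  colvar output frequency is implied by the physical setup; only the
  relative amount of sampling matters to WHAM). The proposal scale
  (dt = 0.02, D = 1, hence sd ≈ 0.2 Å) keeps per-window autocorrelation
  times at a few samples.
* **Measurement curves.** `generate_hill_data()`,
  `generate_exponential_block()` and `generate_gv_data()` produce the
  three patch-clamp observables (fractional block vs concentration,
  normalized current vs time, normalized conductance vs voltage) with
  additive Gaussian noise; block fractions are clipped to [0, 1].

What the generator does **not** emulate: three-dimensional ligand and
side-chain motion, slow conformational gating coupled to z, force-field
error, or the heavy-tailed correlation structure of real MD colvar
series. Passing tests therefore demonstrate the *estimators* are correct
and well-calibrated on data that satisfy their assumptions — not that a
22-ns-per-window MD campaign is converged.

## WHAM

With per-bin counts $n_{im}$, window totals $N_i$, and bias factors
$c_{im} = e^{-U_i(z_m)/k_BT}$, the self-consistent equations are

$$\rho_m = \frac{\sum_i n_{im}}{\sum_i N_i\, e^{f_i/k_BT}\, c_{im}},
\qquad f_i = -k_BT \ln \sum_m \rho_m\, c_{im},$$

and $w(z_m) = -k_BT\ln\rho_m$ up to a constant. Numerical choices:

* **Bins.** Width 0.1 Å by default — at least five bins per 0.5-Å window
  spacing, preserving PMF curvature. Bins are half-open [left, right)
  with the last bin right-closed, so counts are conserved exactly; a bin
  needs ≥ 1 sample (`min_count`) to be supported, and unsupported bins
  are reported as missing (`NA`), never interpolated to zero.
* **Burn-in.** The first `ceiling(f·n)` samples of each window are
  dropped; the default f = 2/22 mirrors discarding the first 2 ns of a
  22-ns window. Out-of-range samples are counted and reported, never
  silently lost.
* **Gauge and convergence.** $f_1 = 0$ fixes the additive constant. The
  iteration stops when $\max_i |\Delta f_i|$ between sweeps falls to the
  tolerance (default 10⁻⁷ kcal/mol). The tolerance is applied to the
  $f_i$, the quantity with kcal/mol units that the stopping rule
  naturally lives on. Unconverged runs return a flagged solution rather
  than raising, so the CLI can print diagnostics; `max_iter` defaults to
  10⁵.
* **Acceleration.** Plain fixed-point WHAM is slow near convergence, so
  the solver wraps it in Anderson acceleration (depth 5). Any
  accelerated step that goes non-finite falls back to the plain update,
  so the fixed point reached is the plain iteration's; the test suite
  verifies agreement with an independent, unaccelerated fixed-point
  implementation to 10⁻⁶ kcal/mol.
* **Connectivity.** Windows must overlap into one connected component
  (sharing a populated bin); otherwise the relative $f_i$ are undefined
  and the error lists the disconnected groups.

## Uncertainties

Per-bin standard errors come from a bootstrap over *effective* samples:
each window's statistical inefficiency $g = 1 + 2\sum_t \hat\rho(t)$
(initial-positive-sequence windowing on the integrated autocorrelation)
converts its n samples into n/g effective ones; replicates redraw each
window's histogram as a multinomial of size n/g over the observed bin
frequencies, re-solve WHAM warm-started from the reference solution,
re-anchor to bulk per replicate (so the anchor's own fluctuation is
included), and the per-bin standard deviation across replicates is the
reported error. This is a standard decorrelation-aware bootstrap chosen
as a pragmatic stand-in for analytic umbrella-sampling error formulas;
it is documented as such rather than claimed to be any specific published
estimator. Series shorter than ten correlation times are flagged.
`propagate_dg_error()` pushes per-bin errors through the nonlinear K_D
integral by Gaussian perturbation; treating bins as independent there is
slightly conservative for smooth profiles.

## Site bounds and quadrature

The binding-site integral needs bounds. The profile never states them, so
the default (`auto_site_bounds()`) takes the cavity-side end of the
supported profile down to the z where, walking from the global minimum
toward bulk, w first rises above $-1\,k_BT$. Because the integrand is
$e^{-w/k_BT}$, bins within a k_BT of zero contribute at most factors of
e relative to the well bottom — for the deep wells of interest the result
is insensitive to the exact cutoff, which a sensitivity sweep makes easy
to confirm for any given profile:

```{r sensitivity, eval = FALSE}
cuts <- seq(-2, 0, 0.25) # cutoff in units of kBT
sapply(cuts, function(ct) {
  zmin <- pmf$z[which.min(pmf$w)]
  lo <- max(pmf$z[pmf$z < zmin & pmf$w > ct * kBT(310.15)])
  as.numeric(kd_from_pmf(pmf, thermo_params(), c(lo, max(pmf$z))))
})
```

The chosen bounds are always recorded on the result and echoed into
reports. Quadrature is trapezoidal on the bin-centre grid; the exact end
points are placed by linear interpolation between centres, with constant
extension across the outermost half-bin cells (a bin's count represents
its whole cell). The tests include a step-halving (Richardson-style)
check against adaptive quadrature of the analytic potential.

## Curve fits

The three measurement models are fitted by Levenberg–Marquardt
(`minpack.lm`), with deterministic data-driven multi-starts when no start
is supplied, so fits depend only on the data (and are invariant to row
order):

* **Hill**: block $= 1/(1+(IC_{50}/c)^{n_H})$, parameterized as block
  rather than residual current; `block_from_current()` adapts raw tail
  currents as $1 - I/I_{baseline}$.
* **Exponential**: $I(t) = A e^{-t/\tau} + C$. The steady-state offset C
  is included by default and switchable; the choice is recorded in the
  result's model name. Non-decaying data flag `converged = FALSE`.
* **Boltzmann**: $g/g_{max} = 1/(1+e^{(V_{1/2}-V)/k_s})$ with positive
  slope meaning activation on depolarization; fitting $g_{max}$ is
  optional. One-sided data are flagged, not refused.

Noise-free generator→fit round trips recover parameters to at least six
significant digits for all three models (tested). `compare_conditions()`
performs a Welch t test on per-cell parameter estimates — one planned
comparison, no multiplicity correction, matching how single pre-specified
contrasts are reported in this literature. Concentration–response data
can be fitted pooled or per cell; the caller chooses and the comparison
operates on whatever per-cell estimates it is given.

## Problem sizes and calibration checks

The suite validates the chain at the standard study scale: the 85-window
open-pore layout at the default 2.2×10⁵ samples per window reconstructs
its preset PMF with RMS error ≤ 0.2 kcal/mol, and the resulting K_D lands
within a factor of 2 of the preset's closed form (an RMS PMF error of
ε kcal/mol can amplify to $e^{\varepsilon/k_BT}$ in K_D, which bounds
that factor). Smaller fixtures cover the exact identities: analytic-count
histograms, ≤ 5-window oracle agreement, √n error scaling at quadrupled
i.i.d. sampling, and a 300-replicate bias check of the IC50 estimator at
a realistic design (5 half-log concentrations, 5 % noise, |relative
bias| < 5 %).

## Known limitations

* Strictly 1-D: no 2-D/multidimensional WHAM, no replica exchange, and
  MBAR is not offered as an estimator.
* The effective K_D omits restraint-release and orientational
  corrections; absolute affinities from deep wells are best read as
  rank-order and state-difference statements.
* The bootstrap error model assumes the inefficiency estimate captures
  the series' correlation; strongly non-stationary windows (unequilibrated
  starts beyond the burn-in) violate that and are only caught by the
  short-series flag.
* Raw electrophysiology traces (leak, capacitance, measurement windows)
  are out of scope; inputs are reduced tidy tables.
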