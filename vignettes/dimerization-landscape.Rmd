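---
title: "Methods: a calibrated dimerization landscape and its estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a calibrated dimerization landscape and its estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model behind
the synthetic reference landscape, the definitions of every estimator, the
numerical choices that were genuinely open, and what the passing tests do
and do not demonstrate about real data.

## The problem

Amphotericin B (AmB) self-associates in water at sub-micromolar
concentrations, and its aggregation state is believed to control how it
discriminates between ergosterol- and cholesterol-containing membranes.
The quantities of interest are the free-energy landscape of dimerization
as a function of the interchromophore distance ξ and the inter-monomer
angle θ, the standard dimerization free energy ΔG°, the concentration
dependence of the dimeric fraction, the diffusion-controlled association
rate, and the parallel↔antiparallel flipping time.  In the original
molecular-dynamics workflow these came from umbrella sampling over
4 < ξ < 25 Å in 17 windows followed by WHAM.  No trajectories are
deposited for the system, so this package replaces the MD engine with a
calibrated analytic landscape plus Brownian-dynamics samplers, and
implements the complete analysis chain as reusable, tested code.

## The reference surface

`reference_surface()` defines

$$G(\xi,\theta) = S(\xi)\Big[\varepsilon\,
  e^{-(\xi - \xi_w)/\lambda} - A\,q(\xi)
  + \sum_{b=1}^4 d_b\, e^{-(\xi-\xi_b)^2/2\sigma_{\xi,b}^2}
      \,e^{-(\theta-\theta_b)^2/2\sigma_{\theta}^2}\Big] + G_\infty$$

with a repulsive exponential wall below ~4 Å, a monotone attraction
shoulder $-A\,q(\xi)$ that decays smoothly to zero at 20 Å (so monomers
feel attraction out to 20 Å but the unbound plateau is flat), four
Gaussian basins (two antiparallel, centered at θ = 150°; two parallel at
30°), and a C¹ switching function $S(\xi)$ that takes the surface exactly
to the plateau level for ξ ≥ 20 Å.  The plateau-zero convention
($G \equiv 0$ beyond 20 Å) anchors every profile.

The Boltzmann factor $e^{-\beta G}$ is defined as directly proportional to
the sampled density in (ξ, θ): no radial Jacobian is built into the
landscape.  The Jacobian appears only where 3D rate theory needs it (see
*Association rate* below).

Units are kcal/mol, Å, degrees, and ns throughout, with
$k_B = 0.0019872$ kcal mol⁻¹ K⁻¹ and T = 300 K by default.

### Calibration

`calibrate_surface()` fits the free parameters — the four basin depths,
the two ξ-widths (shared between basins at the same distance), and the
attraction depth — by Nelder–Mead least squares on residuals scaled by the
target tolerances.  The targets are the published landscape features:
1D minima at 4.5 and 6.5 Å (±0.15 Å) of depth −5.5 kcal/mol (±0.2), an
inter-minimum barrier of 1.5 kcal/mol (±0.3), basin populations
20/32/21/26 % (±2 points), and ΔG° = −7.1 kcal/mol (±0.1) evaluated with
the simulation-box volume of a 62.5 Å cube.  Every residual is computed by
dense trapezoidal quadrature on the analytic surface, so the calibration
is deterministic.  The basin centers are pinned at
(4.5, 150°), (6.5, 150°), (4.5, 30°), (6.5, 30°): the printed minima
positions and the parallel/antiparallel split leave them no freedom.

Two parameters are deliberately *not* fitted:

* **θ-width (35°).**  Left free, the optimizer drifts to ~24°, which makes
  the parallel↔antiparallel saddle ≈5.6 kcal/mol deep; biased trajectories
  then flip every ~2 µs and cannot equilibrate the orientation within a
  window.  At 35° the four minima remain well separated while flipping
  occurs every ~30 ns, which is also consistent with the sub-microsecond
  flipping the landscape is meant to emulate.
* **Wall parameters.**  The wall only has to keep the walker off ξ → 0;
  its exact shape is immaterial to every target.

The shipped `default_surface()` is the archived output of one such
calibration; `calibrate_surface()` re-derives it from the generic initial
guess (closed-form double-well algebra for widths and depth, population
log-ratios for the depth offsets) in ~half a minute, and errors with a
residual report if any target cannot be met.

## Synthetic trajectories

`generate_window()` integrates overdamped Langevin dynamics
$d\xi = -\beta D_\xi\, \partial_\xi (G + w_i)\,dt + \sqrt{2D_\xi dt}\,\eta$
(and the analogous unbiased equation for θ) under a harmonic bias
$w_i(\xi) = k(\xi-\xi_i)^2/2$ on ξ only, with reflecting boundaries.

**Integrator.**  The propagator is stochastic Heun: an Euler–Maruyama
predictor followed by a trapezoidal drift correction with the same noise
realization.  Plain Euler–Maruyama was measured to distort the stationary
density visibly at usable time steps (the θ coordinate relaxes in a few
steps at dt = 5 ps with $D_\theta$ = 3800 deg²/ns), biasing the WHAM
free energy by up to ~1 kcal/mol; the Heun corrector removes the O(dt)
term so the dt = 5 ps default is accurate.  Steps larger than a quarter of
the domain abort with an explicit instability error rather than silently
reflecting.

**Ladder defaults** (`ladder_config()`): 17 evenly spaced windows over
4–25 Å (the published protocol), shared force constant
k = 4 kcal mol⁻¹ Å⁻², 8·10⁶ steps per window at dt = 5 ps (40 µs),
storing every 400th step (20 000 samples/window), $D_\xi$ = 0.1 Å²/ns and
$D_\theta$ = 3800 deg²/ns (the published rotational diffusion
coefficient).  The force constant and trajectory length are the two
settings that were tuned *as generator design choices, on the generator's
own statistics*: at k = 2 the windows sitting on the steep shoulder of the
landscape (slope up to ~4 kcal/mol/Å) are bimodal and hop on a ~20 ns
timescale, inflating the statistical inefficiency to g ≈ 200 and the
seed-to-seed scatter of ΔG° to ±0.5 kcal/mol; k = 4 convexifies the
shoulder while the ~0.39 Å bias width still overlaps the 1.31 Å spacing.
Window length is set by the orientational flip statistics: each bound
window must harvest hundreds of parallel↔antiparallel flips for the basin
populations to stabilize to ~1 percentage point.

**What the generator emulates, and what it does not.**  It reproduces the
statistical structure of restrained MD output — correlated samples from
$e^{-\beta(G+w_i)}$, slow orientational interconversion, window-dependent
relaxation times — so WHAM, reweighting, inefficiency correction and the
diffusion estimator face realistic difficulties.  It does *not* contain
atomistic noise sources (solvent friction memory, force-field anharmonicity,
barostat artifacts), sampling is exactly Markovian and overdamped, and the
true landscape is available in closed form.  Passing tests therefore
demonstrate estimator correctness and statistical calibration, not
robustness to force-field or sampling pathologies of real MD.

**Oracles.**  `generate_ou()` samples the exact OU transition density (so
variance and relaxation time are exact by construction),
`generate_wobble()` does Brownian dynamics of a polar angle including the
geometric sin θ weight, and `simulate_first_passage()` runs absorbing/
reflecting first-passage replicas in a tabulated potential.  These are the
bias-free references the estimators are validated against.

## WHAM and reweighting

`solve_wham()` iterates the standard self-consistent equations on 200 bins
over 4–25 Å to a tolerance of 10⁻⁷ kcal/mol on the window offsets (up to
10⁵ iterations), tracking the WHAM negative log-likelihood, which must
decrease monotonically (the iteration is an EM algorithm).  Per-window
counts are divided by the statistical inefficiency
$g = 1 + 2\sum_k \rho_k$ by default; correlated Langevin samples otherwise
overstate precision.  The autocorrelation sum is truncated at the earlier
of the first negative autocorrelation and Sokal's self-consistent window
(first lag M ≥ 6 τ(M)); the bare first-negative rule occasionally
integrates a long chance-positive noise tail and was measured to miss an
OU oracle by 13 % at n = 10⁵, outside the estimator's 10 % contract.

`reweight_2d()` assigns each sample the binless unbiased weight
$w_s = g_{i(s)}^{-1} / \sum_j N_j^{\mathrm{eff}}
e^{-\beta(w_j(\xi_s) - f_j)}$ and bins it on a 75 × 60 (ξ, θ) grid.  The
$1/g$ factor keeps the numerator on the same effective-count scale as the
denominator; omitting it skews basin populations by ~2 points toward
high-inefficiency windows (caught by comparing against i.i.d. sampling
from the exact biased densities).  Unsampled bins are masked, never
imputed.  Basin regions default to rectangles meeting at the midlines
ξ = 5.5 Å and θ = 90°, and populations are normalized over the bound
region ξ < 11 Å — the four published percentages sum to ~1, which is only
consistent with bound-region normalization.

`locate_minima()` smooths with a 5-bin moving average (off for analytic
profiles), takes local minima below −0.5 kcal/mol (statistical ripples on
the plateau otherwise count as minima), refines positions sub-bin by
parabolic interpolation, and reports the barrier as the maximum between
the two deepest minima minus the shallower one.

## Thermodynamics

The profile integral uses the plateau-zero convention re-applied
internally, so a constant shift of the input cancels exactly.  The
dimerization constant is

$$K = \frac{V_{\mathrm{box}}}{V_0}\,\frac{P_b}{1-P_b},\qquad
P_b = \frac{\int_{\xi<R} e^{-\beta G}\,d\xi}{\int e^{-\beta G}\,d\xi},$$

with R = 11 Å, $V_0 = 10^{27}/N_A$ Å³ ≈ 1661 Å³ (1 M standard state,
always computed from constants), and $V_{\mathrm{box}}$ the volume the
profile was sampled in (the 62.5 Å cubic box for the calibration
fixture).  This is the standard finite-box two-molecule relation for an
angular-integrated profile; no symmetry-number factor for the identical
monomers is applied, and the calibration absorbs the convention, so all
downstream numbers are convention-consistent.  The convention string is
recorded in every result object.  Quadrature is trapezoidal with the
boundary bin split exactly at R; doubling the grid moves K by < 1 %.

The two-state mass balance 2M ⇌ D gives
$[M] = (-1+\sqrt{1+8Kc})/(4K)$, the dimeric fraction $2[D]/c$, and the
closed-form onset concentration $c = f/(2(1-f)^2K)$.  Higher-order
aggregation is explicitly out of scope.

## Kinetics

**Diffusion.**  $D = \sigma^2/\tau_A$ per window, with burn-in 10 % and a
block bootstrap (10 contiguous blocks, 200 resamples) for the standard
error.  The estimator is required to recover OU oracles within 10 % at
n = 10⁵ across a 3 × 3 grid of (k, D).  Per-window estimates are
interpolated linearly at intermediate distances and extrapolated as
constants beyond the sampled interval.

**Association rate.**  The steady-state Smoluchowski flux solution with an
absorbing inner boundary and an equilibrium outer reservoir:
$k_{on} = N_A\big[\int_{\xi_a}^{\xi_b} e^{+\beta w}/(4\pi\xi^2 D)\,
d\xi\big]^{-1}$ where w is the Jacobian-free radial potential of mean
force.  `jacobian_mode = "integrated"` (default) treats the input G as an
angular-integrated profile whose density already contains the 4πξ² volume
growth and restores $w = G + (2/\beta)\ln(\xi/\xi_b)$; `"bare"` uses G as
w directly.  The free-diffusion limit $4\pi D \xi_a N_A$ anchors the
implementation analytically.  The Brownian-dynamics cross-check simulates
the radial process (linear density ∝ ξ²e^{-βw}) from the outer boundary:
at outer radii comparable to the absorbing radius, the inverse MFPT and the
steady-state rate genuinely differ by an O(a/b) term (34 % at b = 25 Å for
free diffusion, ~6 % at b = 100 Å), so the cross-check extends the profile
to b = 100 Å — exactly zero there by the plateau convention — where the
residual geometric term sits well inside the Monte-Carlo 3-s.e. band of a
400-replica oracle.

The published association rate of the real system depends on the authors'
unpublished D(ξ) and is not a prediction target of the synthetic
landscape; the pipeline's k_on is an internally consistent output of the
calibrated surface and the generator's diffusion settings.

**Flipping.**  The Zwanzig mean first-passage time
$\tau = D^{-1}\int_{\theta_0}^{\theta_1} e^{\beta F(\theta')}
\int_a^{\theta'} e^{-\beta F(\theta'')}\,d\theta''\,d\theta'$ on the
bound-region angular free energy, with the reflecting barrier at 0° or
180° (the mirrored geometry is handled by coordinate reflection).  The
rotational diffusion coefficient comes from the wobbling-in-a-cone method
in its small-wobble closed form: the apparent relaxation time is the
integrated autocorrelation time of $P_2(\cos\theta)$, the cone width σ is
a Gaussian fit to the entropy-corrected distribution $p(\theta)/\sin\theta$
(moment-based starting values, explicit failure on non-unimodal input),
and $D = \sigma^2/\tau_{P_2}$ — the identification exact in the
small-amplitude limit where the restricted diffusion relaxes as a
single-well OU process.  The estimator recovers generator inputs within
15 % in the regime used (cone width ~8°, center away from both poles and
from 90°, where the first-order term of $P_2$ vanishes).  The
parallel↔antiparallel barrier height along θ is not constrained by any
published number, so the 200 ns flipping time is exercised only through
the exact identity with its 5·10⁶ s⁻¹ rate and through Zwanzig-vs-BD
cross-validation, never as a landscape prediction.

## Spectra

`gaussian_broaden()` convolves stick spectra with area-preserving
Gaussians (default FWHM 12 nm — a typical exciton band width; the value is
cosmetic and every test is FWHM-parametric) and normalizes per molecule;
`population_weight()` forms the population-weighted composite.  Quantum-
chemical excitation calculations are out of scope; sticks are read from
two-column text files.

## Problem sizes and tolerances

The default pipeline (17 × 8·10⁶ steps, 3.4·10⁵ stored samples) runs in
about a minute on one core and delivers, across seeds, ΔG° within ±0.1
kcal/mol (s.e.), basin-II population within ±1 point, and minima depths
within ±0.1 kcal/mol — comfortably inside the recovery tolerances asserted
by the test suite (±0.3 kcal/mol, ±3 points, ±0.4 kcal/mol).  The reduced
fixtures used by the unit tests trade precision for speed and assert
correspondingly wider, sampling-limited tolerances.

## Known limitations

* The landscape is a four-Gaussian caricature: no ξ–θ coupling beyond the
  basin placement, no second angular coordinate (the reweighting machinery
  accepts any angle column, but no calibrated φ-surface is shipped).
* WHAM error bars come from temporal-half splits and block bootstraps,
  not from a Bayesian posterior.
* The kinetics module treats ξ as a radial coordinate only through the
  4πξ² Jacobian of the rate integral; hydrodynamic coupling between ξ and
  θ is absent.
* The wobbling estimator's small-cone closed form degrades for wide cones
  (σ ≳ 20°) or centers near 90°, where $P_2$ loses first-order
  sensitivity.
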