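---
title: "Microcanonical fragmentation and non-ergodic energy deposition in cluster CID"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microcanonical fragmentation and non-ergodic energy deposition in cluster CID}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidfrag)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the synthetic-data design, and the places
where a genuine design choice had to be made.

## The statistical fragmentation model

A precursor ion with internal energy $E$ is assumed to explore all
fragmentation channels $c$ (multisets of database species conserving atoms
and charge) with probabilities proportional to each channel's total
density of states,

$$P(c \mid E) \;=\; \frac{\Omega_c(E)}{\sum_{c'} \Omega_{c'}(E)},
\qquad
\Omega_c(E) \;=\;
\Big[\circledast_{f \in c}\,(\rho^{\text{vib}}_f \circledast
\rho^{\text{rot}}_f)\Big] \circledast \rho^{\text{trans}}_c
\;\Big|_{E - \Delta E_c},$$

with $\Delta E_c = \sum_f E_f - E_{\text{parent}}$ the channel threshold
(electronic energies including zero-point corrections, on a common
reference) and the convolution evaluated at the excess energy. Identical
fragments divide the channel weight by the permutation factor
$\prod_j n_j!$. The ensemble replaces time averages by statistical
averages; no rate theory (and hence no kinetic shift) is involved.

Ingredients:

* **Vibrations** — exact harmonic direct counts (Beyer–Swinehart). Off-grid
  wavenumbers are handled by fractional strides: each oscillator is counted
  as a linear interpolation between the two adjacent integer-bin combs, so
  the effective quantum is exact and the count is unbiased to first order.
  When every frequency is a multiple of the bin width (the synthetic
  fixtures snap their draws to 1 meV multiples), the count is exact on the
  default grid and on every refinement of it.
* **Rotations** — classical rigid rotors: $\rho(\varepsilon) = 1/(\sigma B)$
  for a linear rotor and $2\sqrt{\varepsilon/(ABC)}/\sigma$ for a nonlinear
  one. Rotational quanta are far below the grid resolution, so a quantum
  count would change nothing. Total angular momentum is *not* conserved
  (the ensemble is microcanonical in energy only); no J-resolved treatment
  is attempted.
* **Relative translation** — free motion of $n$ fragments in a container
  volume $V$ per extra fragment:
  $\rho(\varepsilon) = C_n\,\varepsilon^{3(n-1)/2 - 1}$ with
  $C_n = (2\pi/h^2)^{3(n-1)/2}\,(\prod_i m_i/M)^{3/2}\,
  V^{\,n-1}/\Gamma(3(n-1)/2)$. The container is a genuinely free parameter
  of this model class (branching ratios depend on it), so it is an explicit
  argument everywhere and is recorded in every result object. The default
  is a sphere of radius 10 Å.

### Numerical route

Channel densities span tens of orders of magnitude across a 15 eV grid.
FFT convolution is therefore unusable for them: the absolute error of an
FFT is set by the largest entries and obliterates the threshold region,
which is exactly where the physics happens. `cidfrag` instead combines all
classical factors analytically — every rotor and the translational factor
is a power law, and convolutions of power laws are closed-form — and then
folds the vibrational combs into that kernel with a seeded Beyer–Swinehart
pass. Every operation adds positive numbers, so each bin retains full
relative accuracy. The generic `dos_convolve()` (FFT) remains available
for state functions of modest dynamic range.

The energy grid is uniform and zero-anchored with values at bin left
edges; the default is 1 meV bins to 15 eV, which resolves the
0.8–1.8 eV water-loss threshold ladder. Coarser grids (5 meV) are used
where speed matters (sampling, repeated fitting); the breakdown
probabilities are ratio quantities and are stable at that resolution.

### Energy partitioning

`energy_partition()` reports microcanonical means of the translational,
rotational and vibrational energy of the fragments plus the
*intermolecular* energy $\sum_c P(c|E)\,\Delta E_c$ (electronic energy
stored in separation). The translational and rotational means come from
energy-weighted convolutions of the same factors; the vibrational mean is
the remainder, which closes the energy balance to within one bin by
construction.

### Metropolis sampler

`breakdown_metropolis()` estimates the same branching ratios by a random
walk over (channel, energy-sharing) configurations. Two details differ
from the plain textbook walk, both forced by measured mixing failures on
the cluster fixtures:

* a **transfer move** (a split immediately recombined — moving a subunit
  between fragments at fixed multiplicity) complements split and merge;
  without it, clustered-loss and sequential-loss channels are connected
  only through intermediates whose statistical weight is
  $\sim e^{-11}$ of the endpoints, and the walk is trapped for practical
  run lengths. The proposal mix is 0.15 split / 0.15 merge / 0.30 transfer
  / 0.40 energy reshuffle.
* channel jumps are accepted on the ratio of the **marginal** channel
  densities at the total energy (the sharing coordinates integrated out),
  a collapsed Metropolis-within-Gibbs scheme; the sharing coordinates are
  updated by a local random walk on the integrand within the current
  channel. Uniform sharing proposals essentially never land in the typical
  set once a channel has hundreds of active bins, which froze the original
  joint walk.

Channel visit frequencies then target the exact microcanonical
probabilities; agreement with `breakdown_exact()` on the trihydrate
fixture is at the $3\times10^{-3}$ total-variation level at $2\times10^5$
steps.

## The forward collision model

The centre-of-mass energy $E_{\rm cm} = E_{\rm lab}\,m_{\rm gas}/(m_{\rm
gas}+m_{\rm ion})$ bounds what a single collision can deposit. The
deposited internal energy is modelled as a two-component mixture: a
discrete non-ergodic point (weight $w_{\rm ne}$ at energy $E_{\rm ne}$)
and an ergodic Gaussian $N(\mu, \sigma)$ truncated at zero. The predicted
fragment pattern is

$$I_f \;\propto\; w_{\rm ne}\,P_f(E_{\rm ne}) \;+\;
(1-w_{\rm ne})\int N(E;\mu,\sigma)\,P_f(E)\,\mathrm{d}E,$$

renormalized over the non-parent fragments (precursor intensities are
excluded from pattern analysis, since precursors are detected with much
higher efficiency than fragments).

A design decision worth recording: the discrete component is mapped
**through the breakdown curve** at $E_{\rm ne}$, rather than being wired
directly to the single-water-loss fragment. The two formulations predict
nearly the same pattern on the fixtures — the breakdown curve at 1.25 eV
is dominated by single-water loss — but only the former makes $E_{\rm ne}$
an estimable quantity: a hard-wired indicator leaves the predicted pattern
independent of $E_{\rm ne}$, and no fit can then locate the discrete
point. It is also the natural counterpart of fitting measured patterns by
fragmentation probabilities at individual internal energies.

Instrument effects are applied last: fragments below the m/z transmission
cutoff (default 40) are removed, per-fragment detection efficiencies
applied, and the pattern renormalized.

## Inverse analyses

**Appearance energies.** A flat baseline and a straight line through the
rising part of a fragment yield curve; the appearance energy is their
intersection, with uncertainty from the fit covariance and baseline
variance by the delta method. Exact on noise-free piecewise-linear input,
unbiased under Poisson noise at realistic count rates.

**Deposition distribution.** Weighted least squares on relative
intensities (weights are inverse Poisson variances when counts are given,
else uniform), with a bounded quasi-Newton optimizer and a multi-start
grid ($\mu \in \{0.25, 0.5, 0.75\}\,E_{\rm cm}$, $\sigma \in \{0.1,
0.3\}$ eV, $w_{\rm ne} \in \{0.1, 0.5\}$) because the discrete component
creates local minima. The objective and weighting are this package's own
reconstruction of the published analysis, whose fitting details are not
public; this is stated rather than hidden.

Identifiability drove the series design. A single fragmentation pattern
has only a handful of informative intensities; fitting
$(w_{\rm ne}, \mu, \sigma)$ per collision energy leaves zero residual
degrees of freedom, and under counting noise spurious optima beat the
truth. `fit_deposition_series()` therefore shares across collision
energies exactly the quantities that are physically shared — the
discrete-point energy $E_{\rm ne}$ (one impulsive mechanism) and the
Gaussian width $\sigma$ (a property of the collision kinematics, not of
one panel) — leaving $(w_{\rm ne}, \mu)$ per energy, each panel
overdetermined. The per-panel mean is bounded by $\mu \le E_{\rm cm}$: the
ergodic component cannot contain more energy than the collision supplied.
A two-dimensional Nelder–Mead search over the shared parameters profiles
out the per-panel fits with warm starts. With only one open fragmentation
channel the fit warns that the parameters are not identifiable.
`fit_deposition()` also reports a corrected-AIC comparison against a
Gaussian-only model, so the need for the discrete component is a
model-selection statement, not an assumption.

**Ergodic summary.** Ordinary least squares of the fitted $\mu$ against
$E_{\rm cm}$ (slope), plus the mean ergodic fraction $\mu/E_{\rm cm}$ and
the trajectory of $w_{\rm ne}$. The headline quantities are evaluated on
the 1–5 eV centre-of-mass window, the range in which the experimental
analysis is meaningful (total ion signal collapses above 5 eV).

## The synthetic-data generator

No experimental data for this system are deposited, so the generator *is*
the study's data source, with known ground truth. What it emulates:

* **Energetics** (`fixture_spec()`, `synthetic_cluster_db()`): the parent
  ion sits at 0 eV; the minimum-energy (clustered-loss) channel thresholds
  reproduce the calculated appearance-energy ladder exactly (0.94, 1.00,
  1.10, 1.50, 1.80 eV for the canonical hexahydrate; analogous ladders for
  the protonated form and the trihydrates). The first-water threshold,
  experimentally below the detection limit, is a fixture choice of
  0.80 eV — below every two-water value, far above 0.5 eV (no
  fragmentation there), with the first channel opening just below 1 eV.
  Neutral water clusters are bound relative to monomers by a stepwise
  ladder (0.32, 0.40, 0.36, 0.20, 0.30 eV for dimer→hexamer growth): a
  weakly bound dimer, then cooperative ring closure. Positivity and
  superadditivity of the cumulative binding are validated at construction;
  they guarantee that shipping lost waters as one cluster is always the
  threshold minimum, while the ladder's detailed shape staggers the
  *sequential*-loss channels across 1–4 eV. Ionization energies put the
  charge on the cysteine fragment (8.01 eV versus 12.6223 eV for water and
  11.21 eV for its dimer; larger clusters carry flagged interpolations).
* **Densities of states**: frequencies and rotational constants are
  *templates calibrated for density-of-states behaviour, not
  spectroscopy*. The parent keeps a stiff librational cage
  (600–1000 cm⁻¹); partially stripped ions are floppier (60–250 cm⁻¹),
  a crude stand-in for the multi-minimum landscape of rearranged
  products; the free dimer is stiffer than the larger rings
  (250–450 versus 60–250 cm⁻¹); water-cluster rotational constants form a
  calibrated ladder. These choices were fixed once, by requiring the
  breakdown curve to reproduce the study system's qualitative behaviour —
  no fragmentation at 0.5 eV, survival collapsing just above 1 eV,
  single-water loss dominant around 1.25 eV, two-water loss dominant at
  1.5 eV with minor one- and three-water contributions, progressively
  larger losses at higher energy, low translational share, and a mean
  vibrational energy that grows monotonically over 1–5 eV — and were not
  revisited afterwards.
* **Yield curves** (`simulate_yield_curves()`): the lab energy grid
  8–106 eV converted to the centre of mass, the two-component deposition
  truth ($w_{\rm ne} = 1/3$, $E_{\rm ne} = 1.25$ eV, $\mu$ linear in
  $E_{\rm cm}$ with slope 0.35 and intercept set so the mean ergodic
  fraction over the 1–5 eV window is 2/3, $\sigma = 0.3$ eV), Poisson
  counting noise, the m/z < 40 cutoff, and optionally the overlapping
  He-tagged water-cluster contaminant series — present in the exported
  spectra, masked out of the per-fragment yield matrix, mirroring how the
  overlapping series is excluded from analysis. The width is a fixture
  choice: narrower widths make the Gaussian degenerate with the discrete
  point and destroy identifiability, which is a statement about the
  estimator, not about the experiment.
* **Trajectories** (`simulate_trajectory()`): geometrically consistent
  multi-frame XYZ output (0–500 fs) in which a designated fragment —
  one water, an intact small water cluster, or a covalent CH₃S-composition
  piece — separates beyond the 2.5 Å bond criterion by the final frame,
  with per-atom charges placed on the cysteine moiety. The standard
  ensemble is 225 trajectories (9 deposition energies × 25 runs).

What passing tests on these fixtures do **not** show: that real
cysteine–water DFT energetics produce these particular branching curves;
that real cluster frequencies are anywhere near the templates; or that
the real experiment's noise is purely Poisson. What they do show: the
statistical machinery counts states correctly (exhaustive-enumeration and
closed-form oracles), conserves probability and energy, enumerates
channels completely (integer-partition oracle), and that the inverse
analyses recover known ground truth blind, at realistic counting noise,
including the location of the discrete non-ergodic component and the
slope and level of the ergodic mean.

## Numerical choices and degenerate inputs

* Ties in channel ordering break lexicographically by product names;
  everything stochastic requires an explicit integer seed, and generators
  restore the caller's RNG state.
* Bin 0 of the power-law densities stores the bin average, so the origin
  carries its correct weight and the parent channel is well-defined at
  E = 0; below the lowest threshold the parent survives with probability
  exactly 1.
* A flat yield curve raises "no onset detected" instead of returning a
  spurious intersection; windows with fewer than four points are
  rejected.
* Channels with thresholds above the sampling window are pruned
  (default: the top of the grid; 15 eV covers every centre-of-mass energy
  in scope).
* Composition splits with no valid charge assignment are dropped with a
  warning, never silently.

## Problem sizes

The shipped analyses use the full 14-point collision-energy grid, a
15 eV / 5 meV fitting grid (3001 bins), 50 noisy replicates at
10⁴ counts per energy for the recovery studies, 10⁵–10⁶ Metropolis steps,
and 225-trajectory ensembles — a few minutes end to end on one core.

## Known limitations

* Harmonic vibrations only; no anharmonicity, hindered rotors, or quantum
  rotational counts.
* No angular-momentum conservation and no rate theory: a channel open in
  energy is open in the model, however slowly it would drain in time.
* One database entry per species: isomer ladders are collapsed to the
  most stable form.
* The non-ergodic component is a single discrete energy shared across
  collision energies; a per-energy E_ne is available behind a flag but is
  not identifiable from single panels.
* The trajectory generator produces caricature geometries adequate for
  testing recognition and classification logic, not dynamics.
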