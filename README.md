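# cidfrag

Statistical fragmentation and energy partitioning in collision-induced
dissociation (CID) of hydrated cluster ions.

## The problem

Tandem mass spectrometry activates a mass-selected ion by collision with an
inert gas and reads out its fragments. For weakly bound clusters such as the
microhydrated cysteine cations Cys(H₂O)ₙ⁺ and Cys(H₂O)ₙH⁺ (n = 3, 6)
colliding with Ar, two questions drive the analysis:

1. **Where do fragmentation channels open?** Water can leave one molecule at
   a time or as an intact small cluster, and the two routes have very
   different energy costs. Appearance energies extracted from ion-yield
   curves are compared with channel thresholds ΔE_c = ΣE(products) −
   E(parent) computed from a fragment thermochemistry database.
2. **How much of the collision energy is actually randomized?** A purely
   statistical (ergodic) model predicts the fragmentation pattern from the
   internal energy E through microcanonical branching ratios
   P(c|E) = Ω_c(E) / Σ_c′ Ω_c′(E), where Ω_c is the total density of states
   of channel c (vibrational ⊛ rotational ⊛ translational, offset by
   ΔE_c). Observed patterns are reproduced only by a **two-component
   deposited-energy distribution**: an ergodic Gaussian N(μ, σ) carrying
   roughly two thirds of the centre-of-mass collision energy, plus a
   **discrete non-ergodic point** at E_ne ≈ 1.25 eV describing the prompt
   ejection of a single water molecule that carries away the rest.

The package implements the full computational chain for both questions:
vibrational state counting by the Beyer–Swinehart direct count, classical
rotor and free-translation densities, exhaustive channel enumeration
(clustered *and* sequential water loss), exact and Metropolis Monte Carlo
breakdown curves, mean energy partitioning (translational / rotational /
vibrational / intermolecular), the forward collision model with instrument
effects (m/z < 40 cutoff, detection efficiencies), the inverse fits
(appearance energies; deposition-distribution recovery with shared E_ne and
σ across collision energies), trajectory post-analysis with the 2.5 Å
broken-bond criterion, and synthetic-data generators with known ground
truth for every step.

## Worked example

```r
library(cidfrag)

# a validated fixture database anchored to the calculated threshold ladder
spec <- fixture_spec(n_waters = 6, protonated = FALSE)
db   <- synthetic_cluster_db(spec)

# minimum-energy channel for losing two waters: a single (H2O)2 cluster
compute_threshold(db, c("Cys(H2O)4+", "(H2O)2"), "Cys(H2O)6+")
#> [1] 0.94

# fully sequential loss of all six waters is much dearer
compute_threshold(db, c("Cys+", rep("H2O", 6)), "Cys(H2O)6+")
#> [1] 3.38

# microcanonical breakdown curve and the 1.5 eV pattern
bc <- breakdown_exact(db, "Cys(H2O)6+", grid = energy_grid(15, 5e-3))
round(fragment_probs_at(bc, 1.5)[1, ], 3)
#> Cys(H2O)6+ Cys(H2O)5+ Cys(H2O)4+ Cys(H2O)3+ Cys(H2O)2+ Cys(H2O)1+  Cys+
#>      0.000      0.332      0.575      0.088      0.005      0.000  0.000

# forward model and blind inverse fit at the experiment's energy grid
ens   <- experiment_energies(e_cm_max = Inf)      # lab 8..106 eV -> CM
truth <- deposition_truth(ens[ens <= 5])          # w_ne = 1/3, E_ne = 1.25
yc    <- simulate_yield_curves(bc, db, truth, ens,
                               counts_per_point = 1e4, seed = 1)
fit   <- fit_deposition_series(yc$intensities, bc, ens, counts = yc$counts)
round(fit$e_ne, 4)
#> [1] 1.2492
sel <- ens <= 5   # the 1-5 eV window the analysis focuses on
ergodic_summary(lapply(fit$fits[sel], function(f) f$model), ens[sel])
#> <ergodic_summary> slope d(mu)/d(E_cm) = 0.320 +- 0.023; mean mu/E_cm = 0.691
#>   non-ergodic weights: 0.34 0.68 0.39 0.33 0.32 0.34
```

The breakdown curve shows no fragmentation at 0.5 eV, single-water loss
dominating near 1.25 eV, and two-water loss dominating at 1.5 eV; the
inverse fit recovers the discrete point at ≈1.25 eV, an ergodic fraction
near two thirds, and a slope of the ergodic mean versus collision energy
near 0.35, even though each replicate only sees Poisson-noisy relative
intensities (averaging over replicates, as `scripts/acceptance.R` does,
tightens the single-seed numbers shown here).

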