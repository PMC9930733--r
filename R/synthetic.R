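# Synthetic-data generators: fixture species databases anchored to the
# calculated water-loss threshold ladder, noisy ion-yield curves from the
# forward model, and dissociation trajectories with known outcomes.

# Calculated appearance-energy ladders (eV) for cumulative loss of
# k = 1..n waters. Values for k >= 2 are the quantum-chemical thresholds
# reported for the cysteine-water systems; the first-water threshold is a
# fixture choice (experimentally below the detection limit; chosen below
# every k = 2 value and consistent with no fragmentation at 0.5 eV and a
# first channel opening near 1 eV).
.default_ladders <- list(
  "6+FALSE" = c(0.80, 0.94, 1.00, 1.10, 1.50, 1.80),
  "6+TRUE"  = c(0.80, 0.95, 1.10, 1.20, 1.50, 1.80),
  "3+FALSE" = c(0.80, 1.10, 1.44),
  "3+TRUE"  = c(0.80, 1.04, 1.40)
)

# stepwise binding energies of neutral water clusters, dimer -> hexamer
# growth (fixture values: a weakly bound dimer, then cooperative ring
# closure; calibrated so the staircase of sequential-loss channels opens
# progressively across 1-4 eV while clustered loss stays the threshold
# minimum)
.default_binding <- c(0.32, 0.40, 0.36, 0.20, 0.30)

#' Fixture specification for a synthetic cluster database
#'
#' Collects and validates the ground-truth energetics of a synthetic
#' cysteine-water cluster fixture: the cumulative water-loss threshold
#' ladder (defaults to the calculated appearance energies for the chosen
#' precursor), the stepwise binding energies of the neutral water clusters,
#' and the frequency-template parameters. Positive cluster binding
#' energies guarantee that the minimum-energy channel ships lost waters as
#' a single cluster rather than as free molecules.
#'
#' @param n_waters number of waters on the precursor (3 or 6 have default
#'   ladders; other sizes need an explicit `thresholds`).
#' @param protonated protonated (`Cys(H2O)nH+`) or canonical radical-cation
#'   (`Cys(H2O)n+`) precursor.
#' @param thresholds threshold ladder, eV, one value per cumulative water
#'   lost; strictly increasing.
#' @param binding_energies stepwise water-cluster binding energies, eV
#'   (dimer growth onward), all positive.
#' @param soft_range_parent wavenumber range, cm^-1, of the parent ion's
#'   water librations (the parent sits in its tight global-minimum
#'   hydrogen-bond network).
#' @param soft_range_ion wavenumber range, cm^-1, of the intermolecular
#'   modes of the product (partially stripped) ions, softer than the
#'   parent's: water loss leaves a rearranged, floppier network, a crude
#'   stand-in for the multi-minimum landscape of the products.
#' @param soft_range_cluster wavenumber range, cm^-1, of the intermolecular
#'   modes of free neutral water clusters (trimer and larger).
#' @param soft_range_dimer wavenumber range, cm^-1, of the water dimer's
#'   intermolecular modes (stiffer than the larger rings: one hydrogen
#'   bond, no cooperative network).
#' @param container_radius radius, Angstrom, of the per-extra-fragment
#'   container this fixture is calibrated for; pass
#'   `default_volume(spec$container_radius)` as `volume` downstream.
#' @param seed integer seed for the deterministic frequency draws.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_waters = 6, protonated = FALSE,
                         thresholds = NULL,
                         binding_energies = .default_binding,
                         soft_range_parent = c(600, 1000),
                         soft_range_ion = c(60, 250),
                         soft_range_cluster = c(60, 250),
                         soft_range_dimer = c(250, 450),
                         container_radius = 10, seed = 1L) {
  if (is.null(thresholds)) {
    key <- paste0(n_waters, "+", protonated)
    thresholds <- .default_ladders[[key]]
    if (is.null(thresholds)) {
      stop("no default threshold ladder for n_waters = ", n_waters,
           "; supply `thresholds`")
    }
  }
  stopifnot(length(thresholds) == n_waters)
  if (any(diff(thresholds) <= 0)) {
    stop("threshold ladder must be strictly increasing with waters lost")
  }
  if (any(binding_energies <= 0)) {
    stop("water-cluster binding energies must be positive")
  }
  if (length(binding_energies) < n_waters - 1) {
    stop("need ", n_waters - 1, " stepwise binding energies")
  }
  # cumulative binding B_k of (H2O)k relative to k monomers
  bcum <- c(0, cumsum(binding_energies))[seq_len(n_waters)]
  # single-cluster loss must be the energy minimum for every k: B must be
  # superadditive over all partitions of k
  for (k in seq_len(n_waters)) {
    for (part in integer_partitions(k)) {
      if (length(part) > 1 && sum(bcum[part]) >= bcum[k] - 1e-12) {
        stop("binding ladder not superadditive: partition (",
             paste(part, collapse = ","), ") of ", k,
             " is not dearer than the single cluster")
      }
    }
  }
  structure(list(n_waters = n_waters, protonated = protonated,
                 thresholds = thresholds,
                 binding_energies = binding_energies[seq_len(n_waters - 1)],
                 binding_cumulative = bcum,
                 soft_range_parent = soft_range_parent,
                 soft_range_ion = soft_range_ion,
                 soft_range_cluster = soft_range_cluster,
                 soft_range_dimer = soft_range_dimer,
                 container_radius = container_radius,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' All integer partitions of n
#'
#' Exhaustive recursive enumeration (parts in non-increasing order); the
#' independent oracle for water-loss channel counting: the channels
#' reaching the bare ion from an n-water precursor are exactly these
#' partitions.
#'
#' @param n non-negative integer.
#' @param max_part largest allowed part.
#' @return List of integer vectors; `p(6) = 11`.
#' @export
integer_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (p in seq_len(min(n, max_part))) {
    for (rest in integer_partitions(n - p, p)) {
      out[[length(out) + 1L]] <- c(p, rest)
    }
  }
  out
}

# --- frequency / rotational-constant templates ---------------------------

.water_modes <- c(1595, 3657, 3756)
.water_rot <- c(27.88, 14.51, 9.28)

# rotational-constant templates (cm^-1) of the neutral water clusters.
# These are density-of-states shaping parameters of the synthetic fixture,
# calibrated (together with the binding ladder and the mode ranges below)
# so that the breakdown curve reproduces the study system's qualitative
# behaviour: single-water loss first, two-water loss dominant at 1.5 eV,
# then progressively larger losses. They are not spectroscopic constants.
.water_cluster_rot <- list(
  `2` = c(0.18, 0.018, 0.015),
  `3` = c(0.5, 0.4, 0.33),
  `4` = c(0.08, 0.06, 0.05),
  `5` = c(0.002, 0.002, 0.001),
  `6` = c(0.03, 0.03, 0.015)
)

# 36 vibrational modes of the cysteine skeleton (3*14 - 6)
.cys_core_modes <- function() {
  sort(c(seq(60, 1700, length.out = 27), 2600,
         seq(2950, 3650, length.out = 8)))
}

# spherical-top rotational constant from a liquid-water-density radius
.sphere_rot <- function(mass) {
  r <- 1.7 * (mass / 18.015)^(1 / 3)
  inertia <- 0.4 * mass * r^2           # (2/5) M r^2, amu A^2
  b <- 16.8576 / inertia                # cm^-1
  c(b, b, b)
}

.jitter <- function(x, amount) x + stats::runif(length(x), -amount, amount)

# snap wavenumbers to exact 1 meV multiples: the direct state count is then
# exact on the default 1 meV grid and on every refinement of it, so grid
# halving leaves the fixture's channel densities unchanged
.snap_modes <- function(w_cm) {
  ev <- pmax(round(w_cm * 1.239841984e-4 / 1e-3), 1) * 1e-3
  ev / 1.239841984e-4
}

#' Build a synthetic cluster species database
#'
#' Constructs a validated species database for a cysteine-water cluster
#' precursor in which the minimum-energy (clustered-water-loss) channel
#' thresholds reproduce the fixture's ladder exactly. The energy reference
#' puts the parent ion and the neutral monomers (H2O, CO) at 0 eV; water
#' clusters sit below separated monomers by their cumulative binding
#' energy, and the hydrated-ion energies are solved from the ladder. So the
#' fully sequential channel to the bare ion costs the ladder top plus the
#' sum of all stepwise cluster binding energies. Frequencies are drawn
#' deterministically from the fixture seed within the template ranges
#' (water clusters carry soft intermolecular modes; these, not
#' spectroscopic accuracy, govern the downstream densities of states).
#' Ionization energies: Cys 8.01 eV, H2O 12.6223 eV, (H2O)2 11.21 eV;
#' larger water clusters carry flagged fixture interpolations.
#'
#' @param spec a [fixture_spec()] (or arguments forwarded to it).
#' @param include_molecular also add the covalent-fragmentation species
#'   C2H6NS+ (m/z 76) and CO, with the C2H6NS+ energy set so that the
#'   channel `C2H6NS+ + CO + H2O + (H2O)n` reproduces its calculated
#'   3.24 eV threshold (protonated hexahydrate fixture).
#' @param ... forwarded to [fixture_spec()] when `spec` is missing.
#' @return A [species_db()] whose reference species is the parent ion.
#' @export
synthetic_cluster_db <- function(spec = fixture_spec(...),
                                 include_molecular = FALSE, ...) {
  n <- spec$n_waters
  bcum <- spec$binding_cumulative
  cys_comp <- c(C = 3, H = 7, N = 1, O = 2, S = 1)
  ion_comp0 <- if (spec$protonated) c(C = 3, H = 8, N = 1, O = 2, S = 1)
               else cys_comp
  ion_name <- function(k) {
    base <- if (spec$protonated) {
      if (k == 0) "CysH+" else paste0("Cys(H2O)", k, "H+")
    } else {
      if (k == 0) "Cys+" else paste0("Cys(H2O)", k, "+")
    }
    base
  }
  water_name <- function(m) if (m == 1) "H2O" else paste0("(H2O)", m)

  with_seed(spec$seed, {
    sp <- list()
    core <- .cys_core_modes()
    # the extra proton of the protonated form adds one atom: three more
    # skeletal modes (X-H bend/stretch region)
    ion_core <- if (spec$protonated) c(core, 1250, 1450, 2600) else core
    # hydrated ions, k = 0..n waters retained; ladder: threshold for losing
    # j = n - k waters as one cluster is T_j = E(ion_k) + E((H2O)_j), with
    # E((H2O)_j) = -B_j  =>  E(ion_k) = T_j + B_j  (parent at 0)
    for (k in n:0) {
      j <- n - k
      energy <- if (j == 0) 0 else spec$thresholds[j] + bcum[j]
      comp <- ion_comp0 + c(C = 0, H = 2 * k, N = 0, O = k, S = 0)
      rng <- if (k == n) spec$soft_range_parent else spec$soft_range_ion
      modes <- c(.jitter(ion_core, 20),
                 if (k > 0) .jitter(rep(.water_modes, k), 30),
                 if (k > 0) stats::runif(6 * k, rng[1], rng[2]))
      sp[[length(sp) + 1L]] <- species(
        name = ion_name(k), composition = comp, charge = 1L,
        energy = energy, frequencies = sort(.snap_modes(modes)),
        rot_constants = .sphere_rot(composition_mass(comp)),
        symmetry_number = 1L)
    }
    # neutral water clusters, E((H2O)_m) = -B_m
    for (m in seq_len(n)) {
      comp <- c(H = 2 * m, O = m)
      crng <- if (m == 2) spec$soft_range_dimer else spec$soft_range_cluster
      modes <- if (m == 1) .water_modes else {
        c(.jitter(rep(.water_modes, m), 30),
          stats::runif(6 * (m - 1), crng[1], crng[2]))
      }
      ie <- if (m == 1) 12.6223 else if (m == 2) 11.21
            else 11.21 - 0.1 * (m - 2)   # fixture interpolation
      sp[[length(sp) + 1L]] <- species(
        name = water_name(m), composition = comp, charge = 0L,
        energy = if (m == 1) 0 else -bcum[m],
        frequencies = sort(.snap_modes(modes)),
        rot_constants = if (m == 1) .water_rot
                        else .water_cluster_rot[[as.character(m)]],
        symmetry_number = if (m == 1) 2L else 1L,
        ionization_energy = ie)
    }
    # neutral cysteine: the bare ion minus its ionization energy
    bare_e <- spec$thresholds[n] + bcum[n]
    sp[[length(sp) + 1L]] <- species(
      name = "Cys", composition = cys_comp, charge = 0L,
      energy = bare_e - 8.01,
      frequencies = sort(.snap_modes(.jitter(core, 20))),
      rot_constants = .sphere_rot(composition_mass(cys_comp)),
      symmetry_number = 1L, ionization_energy = 8.01)
    if (include_molecular) {
      if (!spec$protonated) {
        stop("the molecular-fragment extension is defined for the ",
             "protonated fixture")
      }
      # Cys(H2O)nH+ -> C2H6NS+ + CO + H2O + (H2O)n at 3.24 eV:
      # E(C2H6NS+) = 3.24 - E(CO) - E(H2O) - E((H2O)n) = 3.24 + B_n
      frag_comp <- c(C = 2, H = 6, N = 1, S = 1)
      sp[[length(sp) + 1L]] <- species(
        name = "C2H6NS+", composition = frag_comp, charge = 1L,
        energy = 3.24 + spec$binding_cumulative[n],
        frequencies = sort(.snap_modes(
          stats::runif(3 * sum(frag_comp) - 6, 200, 3100))),
        rot_constants = .sphere_rot(composition_mass(frag_comp)),
        symmetry_number = 1L)
      sp[[length(sp) + 1L]] <- species(
        name = "CO", composition = c(C = 1, O = 1), charge = 0L,
        energy = 0, frequencies = .snap_modes(2143),
        rot_constants = 1.93, symmetry_number = 1L,
        ionization_energy = 14.01)
    }
    species_db(sp, reference = ion_name(n))
  })
}

# --- ion-yield curves ----------------------------------------------------

#' Deposition ground truth matching the reported fit
#'
#' The configuration used throughout for synthetic yield curves: a
#' non-ergodic weight of one third with the discrete point at 1.25 eV, and
#' an ergodic Gaussian mean rising linearly in the centre-of-mass collision
#' energy with slope 0.35, the intercept chosen so that the mean ergodic
#' fraction mu/E_cm over the supplied energies is two thirds.
#'
#' @param energies centre-of-mass collision energies, eV.
#' @param w_ne,e_ne,slope,sigma override individual components.
#' @return List with `w_ne`, `e_ne`, `mu_intercept`, `mu_slope`, `sigma`
#'   and the function `mu(e_cm)`.
#' @export
deposition_truth <- function(energies, w_ne = 1 / 3, e_ne = 1.25,
                             slope = 0.35, sigma = 0.3) {
  a <- (2 / 3 - slope) / mean(1 / energies)
  list(w_ne = w_ne, e_ne = e_ne, mu_intercept = a, mu_slope = slope,
       sigma = sigma, mu = function(e_cm) a + slope * e_cm)
}

#' Centre-of-mass collision-energy grid of the experiment
#'
#' Laboratory collision energies 8..106 eV converted to the CM frame for a
#' given precursor mass and Ar collision gas, optionally truncated to the
#' 1-5 eV range the analysis focuses on.
#'
#' @param m_ion precursor mass, amu.
#' @param e_lab laboratory energies, eV.
#' @param e_cm_max keep only CM energies at or below this (default 5 eV).
#' @return Numeric vector of CM energies, eV.
#' @export
experiment_energies <- function(m_ion = 229,
                                e_lab = c(8, 11, 16, 21, 26, 31, 36, 46,
                                          56, 66, 76, 86, 96, 106),
                                e_cm_max = 5) {
  e <- lab_to_cm(e_lab, m_ion, 40)
  e[e <= e_cm_max]
}

# He-tagged water-cluster contaminant series: water-loss fragments of
# He3(H2O)12H+ / He8(H2O)11+, whose m/z overlap the precursor region
.contaminant_peaks <- function(protonated) {
  if (protonated) {
    base <- 3 * 4.0026 + 12 * 18.015 + 1.008
    mz <- round(base - 18.015 * (0:8))
  } else {
    base <- 8 * 4.0026 + 11 * 18.015
    mz <- round(base - 18.015 * (0:8))
  }
  data.frame(mz = as.integer(mz), rel = 0.6^(0:8))
}

#' Simulate ion-yield curves from the forward model
#'
#' Evaluates the two-component deposition model through the breakdown
#' curve at each collision energy, samples Poisson counts, applies the
#' instrument m/z cutoff, and optionally adds the overlapping He-tagged
#' water-cluster contaminant series to the exported spectra (the
#' contaminant peaks are kept out of the per-fragment yield matrix by the
#' m/z mask, mirroring how the overlapping series is excluded from
#' analysis). Ground truth is stored alongside the data.
#'
#' @param curve a [breakdown_exact()] result for the precursor.
#' @param db the [species_db()] behind `curve` (for m/z values).
#' @param truth a [deposition_truth()] list.
#' @param energies centre-of-mass collision energies, eV.
#' @param counts_per_point expected total fragment counts per energy;
#'   `Inf` for noise-free expected-value mode.
#' @param contaminants add the contaminant series to the spectra.
#' @param mz_cutoff instrument transmission cutoff (default 40).
#' @param seed integer seed (required unless noise-free).
#' @return Object of class `ion_yield_curve`: `energies`, `fragments`,
#'   `intensities` (energies x fragments, normalized, parent excluded),
#'   `counts`, `mz`, per-energy `spectra` (peak lists), and `truth`.
#' @export
simulate_yield_curves <- function(curve, db, truth = NULL,
                                  energies = experiment_energies(),
                                  counts_per_point = 1e4,
                                  contaminants = FALSE, mz_cutoff = 40,
                                  seed = NULL) {
  if (is.null(truth)) truth <- deposition_truth(energies)
  if (!is.finite(counts_per_point)) {
    noise_free <- TRUE
  } else {
    noise_free <- FALSE
    if (is.null(seed)) stop("Poisson sampling needs an explicit seed")
  }
  frag_names <- setdiff(colnames(curve$fragment_probabilities), curve$parent)
  mz <- vapply(frag_names, function(nm) species_mz(db, nm), integer(1))
  keep <- mz >= mz_cutoff
  expected <- t(vapply(energies, function(e) {
    dep <- deposition_model(truth$w_ne, truth$e_ne, truth$mu(e),
                            truth$sigma)
    predict_pattern(curve, dep)[frag_names]
  }, numeric(length(frag_names))))
  colnames(expected) <- frag_names
  if (any(expected[, !keep] > 0)) {
    message("fragments below m/z ", mz_cutoff, " removed: ",
            paste(frag_names[!keep], collapse = ", "))
  }
  expected <- expected[, keep, drop = FALSE]
  expected <- expected / rowSums(expected)
  frag_names <- colnames(expected)
  mz <- mz[keep]

  run <- function() {
    counts <- NULL
    if (!noise_free) {
      counts <- matrix(stats::rpois(length(expected),
                                    counts_per_point * expected),
                       nrow = nrow(expected), dimnames = dimnames(expected))
    }
    intens <- if (noise_free) expected else {
      sweep(counts, 1, pmax(rowSums(counts), 1), "/")
    }
    spectra <- lapply(seq_along(energies), function(i) {
      pk <- data.frame(mz = as.integer(mz),
                       counts = if (noise_free) expected[i, ] * 1e6
                                else counts[i, ],
                       source = frag_names)
      if (contaminants) {
        cont <- .contaminant_peaks(grepl("H\\+$", curve$parent))
        lam <- (if (noise_free) 1e6 else counts_per_point) * 0.05 * cont$rel
        ck <- data.frame(mz = cont$mz,
                         counts = if (noise_free) lam
                                  else stats::rpois(nrow(cont), lam),
                         source = "contaminant")
        pk <- rbind(pk, ck)
      }
      pk <- pk[pk$mz >= mz_cutoff, ]
      pk[order(pk$mz), ]
    })
    list(counts = counts, intens = intens, spectra = spectra)
  }
  r <- if (noise_free) run() else with_seed(seed, run())
  structure(list(energies = energies, fragments = frag_names,
                 intensities = r$intens, counts = r$counts, mz = mz,
                 spectra = r$spectra, truth = truth,
                 parent = curve$parent, seed = seed,
                 counts_per_point = counts_per_point),
            class = "ion_yield_curve")
}

#' @export
print.ion_yield_curve <- function(x, ...) {
  cat(sprintf(
    "<ion_yield_curve> %s: %d energies (%.2f..%.2f eV CM), %d fragments%s\n",
    x$parent, length(x$energies), min(x$energies), max(x$energies),
    length(x$fragments),
    if (is.finite(x$counts_per_point))
      sprintf(", ~%g counts/point", x$counts_per_point)
    else ", noise-free"))
  invisible(x)
}

# --- trajectories --------------------------------------------------------

.water_atoms <- function(center) {
  list(symbols = c("O", "H", "H"),
       coords = rbind(center,
                      center + c(0.76, 0.59, 0),
                      center + c(-0.76, 0.59, 0)))
}

#' Simulate a dissociation trajectory with a known outcome
#'
#' Builds geometrically consistent frames for a cysteine-water cluster in
#' which the designated fragment separates beyond the 2.5 Angstrom bond
#' criterion by the final frame (or never, for `intact`). Per-atom charges
#' put the charge on the cysteine moiety; time stamps run 0-500 fs.
#'
#' @param outcome one of `"intact"`, `"single water loss"`,
#'   `"clustered water loss"`, `"covalent fragmentation"`.
#' @param n_waters waters on the precursor.
#' @param n_lost cluster size detached for `"clustered water loss"`.
#' @param protonated protonated precursor (one extra H on the moiety).
#' @param n_frames number of frames.
#' @param seed integer seed for coordinate jitter.
#' @return An `xyz_trajectory`.
#' @export
simulate_trajectory <- function(outcome = c("intact", "single water loss",
                                            "clustered water loss",
                                            "covalent fragmentation"),
                                n_waters = 3, n_lost = 2,
                                protonated = FALSE, n_frames = 11,
                                seed = 1L) {
  outcome <- match.arg(outcome)
  if (outcome == "single water loss") n_lost <- 1L
  if (outcome == "clustered water loss" && n_lost < 2) {
    stop("clustered water loss needs n_lost >= 2")
  }
  if (outcome %in% c("single water loss", "clustered water loss") &&
      n_lost > n_waters) {
    stop("cannot detach more waters than the precursor carries")
  }
  with_seed(seed, {
    # compact cysteine moiety: heavy atoms + hydrogens on a 1.2 A grid
    heavy <- c("C", "C", "C", "N", "O", "O", "S")
    hs <- rep("H", if (protonated) 8 else 7)
    core_sym <- c(heavy, hs)
    k <- seq_along(core_sym) - 1
    core_xyz <- cbind(1.2 * (k %% 3), 1.2 * ((k %/% 3) %% 3),
                      1.2 * (k %/% 9)) +
      matrix(stats::runif(3 * length(core_sym), -0.1, 0.1), ncol = 3)
    # waters on a ring around the moiety, within bonding distance of it
    ctr <- colMeans(core_xyz)
    waters <- lapply(seq_len(n_waters), function(w) {
      ang <- 2 * pi * (w - 1) / max(n_waters, 1)
      .water_atoms(ctr + c(2.9 * cos(ang), 2.9 * sin(ang), 0))
    })

    if (outcome == "covalent fragmentation") {
      # detach a CH3S-composition piece of the moiety
      lost_sel <- c(which(core_sym == "S")[1],
                    which(core_sym == "C")[1],
                    which(core_sym == "H")[1:3])
      lost_sym <- core_sym[lost_sel]
      lost_xyz <- cbind(c(0, 1.2, -1.2, 0.8, -0.8),
                        c(0, 0.4, 0.4, -0.9, -0.9), 0)
      core_sym <- core_sym[-lost_sel]
      core_xyz <- core_xyz[-lost_sel, , drop = FALSE]
      lost_anchor <- c(max(core_xyz[, 1]) + 1.8, 1.2, 0.6)
    } else if (outcome != "intact") {
      lost_sym <- character(0); lost_xyz <- NULL
      for (w in seq_len(n_lost)) {
        wa <- .water_atoms(c(2.4 * (w - 1), 0, 0))
        lost_sym <- c(lost_sym, wa$symbols)
        lost_xyz <- rbind(lost_xyz, wa$coords)
      }
      waters <- waters[seq_len(n_waters - n_lost)]
      lost_anchor <- c(max(core_xyz[, 1]) + 1.8, 1.2, 0.6)
    } else {
      lost_sym <- character(0); lost_xyz <- NULL
    }

    stay_sym <- c(core_sym, unlist(lapply(waters, `[[`, "symbols")))
    stay_xyz <- rbind(core_xyz,
                      do.call(rbind, lapply(waters, `[[`, "coords")))
    n_core <- length(core_sym)
    n_stay <- length(stay_sym)
    n_lost_atoms <- length(lost_sym)
    charges <- c(rep(0.95 / n_core, n_core),
                 rep(0.05 / max(n_stay - n_core + n_lost_atoms, 1),
                     n_stay - n_core + n_lost_atoms))

    times <- seq(0, 500, length.out = n_frames)
    frames <- lapply(seq_len(n_frames), function(f) {
      prog <- (f - 1) / max(n_frames - 1, 1)
      xyz <- stay_xyz
      sym <- stay_sym
      if (n_lost_atoms > 0) {
        shift <- lost_anchor + c(prog * 7.5, 0, 0)
        xyz <- rbind(xyz, sweep(lost_xyz, 2, shift, "+"))
        sym <- c(sym, lost_sym)
      }
      dimnames(xyz) <- NULL
      list(symbols = sym, coords = xyz, charges = charges, time = times[f])
    })
    structure(frames, class = "xyz_trajectory")
  })
}

#' Simulate an ensemble of dissociation trajectories
#'
#' Draws outcomes from a stated mix for a grid of deposition energies
#' (default 9 energies x 25 trajectories, the ensemble size used for the
#' trihydrate dynamics), generates one trajectory per draw, and returns
#' the generator's bookkeeping so recovered outcome frequencies can be
#' compared exactly.
#'
#' @param outcome_probs named probabilities over the four outcome labels.
#' @param n_energies,n_per_energy ensemble layout.
#' @param n_waters waters on the precursor.
#' @param seed integer seed.
#' @return List with `trajectories`, `outcomes` (generator truth) and
#'   `energies` (index grid).
#' @export
simulate_trajectory_ensemble <- function(outcome_probs = c(
                                           "intact" = 0.4,
                                           "single water loss" = 0.3,
                                           "clustered water loss" = 0.2,
                                           "covalent fragmentation" = 0.1),
                                         n_energies = 9, n_per_energy = 25,
                                         n_waters = 3, seed = 1L) {
  stopifnot(abs(sum(outcome_probs) - 1) < 1e-9)
  n <- n_energies * n_per_energy
  with_seed(seed, {
    outcomes <- sample(names(outcome_probs), n, replace = TRUE,
                       prob = outcome_probs)
    sub_seeds <- sample.int(.Machine$integer.max, n)
    trajectories <- lapply(seq_len(n), function(i) {
      simulate_trajectory(outcomes[i], n_waters = n_waters,
                          n_lost = min(2, n_waters), seed = sub_seeds[i])
    })
    list(trajectories = trajectories, outcomes = outcomes,
         energies = rep(seq_len(n_energies), each = n_per_energy))
  })
}
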