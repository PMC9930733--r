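# Sums and densities of states on a shared uniform energy grid.
#
# All state functions live on a zero-anchored uniform grid: point i (1-based
# index) represents energy (i-1)*bin_width, the left edge of the half-open
# bin [(i-1)*dE, i*dE). Left-edge alignment makes discrete convolution exact
# for comb-like vibrational counts (quanta are integer numbers of bins) and
# keeps channel thresholds on-grid.

#' Uniform internal-energy grid
#'
#' @param e_max top of the grid, eV.
#' @param bin_width bin width, eV (default 1 meV, fine enough to resolve the
#'   0.9-1.8 eV water-loss threshold ladder).
#' @return Object of class `energy_grid` with fields `e_max`, `bin_width`,
#'   `n_bins` and the vector `energies` of bin left edges.
#' @export
energy_grid <- function(e_max = 15, bin_width = 1e-3) {
  stopifnot(bin_width > 0, e_max > bin_width)
  n <- as.integer(round(e_max / bin_width)) + 1L
  structure(list(e_max = e_max, bin_width = bin_width, n_bins = n,
                 energies = (seq_len(n) - 1) * bin_width),
            class = "energy_grid")
}

#' @export
print.energy_grid <- function(x, ...) {
  cat(sprintf("<energy_grid> 0..%g eV, %d bins of %g eV\n",
              x$e_max, x$n_bins, x$bin_width))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$bin_width, b$bin_width)) && a$n_bins == b$n_bins
}

state_function <- function(grid, values, kind = c("density", "sum")) {
  kind <- match.arg(kind)
  stopifnot(length(values) == grid$n_bins, all(values >= 0))
  structure(list(grid = grid, values = as.numeric(values), kind = kind),
            class = "state_function")
}

#' @export
print.state_function <- function(x, ...) {
  cat(sprintf("<state_function> %s on %d bins (max %.3g)\n",
              x$kind, x$grid$n_bins, max(x$values)))
  invisible(x)
}

# delta distribution at E = 0: identity element of dos_convolve
delta_dos <- function(grid) {
  v <- numeric(grid$n_bins)
  v[1] <- 1 / grid$bin_width
  state_function(grid, v)
}

#' Vibrational density of states by Beyer-Swinehart direct count
#'
#' Exact direct count of harmonic-oscillator states per energy bin, energies
#' measured from the zero-point level. Off-grid wavenumbers are counted by
#' fractional strides (linear interpolation between the two adjacent
#' integer-bin combs), which keeps the effective quantum exact; a frequency
#' below one bin width triggers a "grid too coarse" warning and is counted
#' as one bin. An empty frequency list (an atom) gives a single state in
#' bin 0.
#'
#' @param frequencies harmonic wavenumbers, cm^-1.
#' @param grid an [energy_grid()].
#' @return A `state_function` of kind `"density"` (states per eV; counts per
#'   bin divided by the bin width). Use [sum_of_states()] for the cumulative
#'   count.
#' @export
vib_states <- function(frequencies, grid) {
  state_function(grid, bs_pass(frequencies, grid) / grid$bin_width)
}

#' Classical rotational density of states
#'
#' Linear rotor: rho(e) = 1/(sigma*B); nonlinear rotor:
#' rho(e) = 2*sqrt(e/(A*B*C))/sigma; atom: delta at zero. Constants are
#' converted from cm^-1 to eV internally. Bin 0 of a nonlinear rotor stores
#' the bin average so that the origin carries its correct (nonzero) weight.
#'
#' @param rot_constants 0 (atom), 1 (linear) or 3 (nonlinear) rotational
#'   constants, cm^-1.
#' @param symmetry_number rotational symmetry number.
#' @param grid an [energy_grid()].
#' @return A `state_function` of kind `"density"` (states per eV).
#' @export
rot_dos <- function(rot_constants, symmetry_number, grid) {
  if (length(rot_constants) > 0 && any(rot_constants <= 0)) {
    stop("rotational constants must be positive")
  }
  b <- rot_constants * .cidfrag_const$cm1_eV
  s <- symmetry_number
  n <- grid$n_bins
  de <- grid$bin_width
  if (length(b) == 0) return(delta_dos(grid))
  if (length(b) == 1) {
    return(state_function(grid, rep(1 / (s * b), n)))
  }
  abc <- prod(b)
  v <- 2 * sqrt(grid$energies / abc) / s
  v[1] <- (4 / 3) * sqrt(de / abc) / s   # bin average over [0, dE)
  state_function(grid, v)
}

#' Translational density of states of separated fragments
#'
#' Density of states of the relative translational motion of `n` fragments
#' confined to a container volume V per extra fragment:
#' rho(e) = C_n * e^(3(n-1)/2 - 1), with
#' C_n = (2 pi / h^2)^(3(n-1)/2) * (prod(m_i)/M)^(3/2) * V^(n-1) /
#' Gamma(3(n-1)/2). Units: masses in amu, V in Angstrom^3, energies in eV.
#' A single fragment gives the delta identity (no relative translation).
#'
#' @param masses fragment masses, amu.
#' @param volume container volume per extra fragment, Angstrom^3.
#' @param grid an [energy_grid()].
#' @return A `state_function` of kind `"density"`.
#' @export
trans_dos <- function(masses, volume, grid) {
  n_frag <- length(masses)
  stopifnot(n_frag >= 1, all(masses > 0), volume > 0)
  if (n_frag == 1) return(delta_dos(grid))
  s <- 3 * (n_frag - 1) / 2
  cn <- .cidfrag_const$kappa^s * (prod(masses) / sum(masses))^1.5 *
    volume^(n_frag - 1) / gamma(s)
  v <- cn * grid$energies^(s - 1)
  de <- grid$bin_width
  v[1] <- cn * de^(s - 1) / s            # bin average over [0, dE)
  state_function(grid, v)
}

#' Convolve two state functions
#'
#' Discrete convolution with bin-width weighting,
#' (a (*) b)[k] = dE * sum_i a[i] b[k-i], computed by FFT. The delta at zero
#' is the exact identity; the operation is associative and commutative to
#' numerical tolerance.
#'
#' @param a,b `state_function`s on the same grid.
#' @return A `state_function` on the common grid.
#' @export
dos_convolve <- function(a, b) {
  if (!same_grid(a$grid, b$grid)) stop("grid mismatch in dos_convolve")
  n <- a$grid$n_bins
  conv <- stats::convolve(a$values, rev(b$values), type = "open")[seq_len(n)]
  conv <- pmax(conv, 0) * a$grid$bin_width
  state_function(a$grid, conv)
}

#' Cumulative sum of states
#'
#' Integral of a density of states from 0 to each grid energy; for a
#' vibrational direct count this is the exact integer number of states at or
#' below each energy.
#'
#' @param sf a `state_function` of kind `"density"`.
#' @return A `state_function` of kind `"sum"` (dimensionless).
#' @export
sum_of_states <- function(sf) {
  state_function(sf$grid, cumsum(sf$values) * sf$grid$bin_width, kind = "sum")
}

# ---- cancellation-free channel-DOS machinery ----------------------------
#
# Channel densities span tens of orders of magnitude over the grid, which
# rules out FFT convolution (absolute FFT error at the top of the grid
# swamps the threshold region). Instead every classical factor (rotations,
# relative translation) is a power law c*eps^a whose mutual convolutions
# are closed-form, and the vibrational combs are folded in by running the
# Beyer-Swinehart recursion seeded with that kernel: only additions of
# positives, so every bin keeps full relative accuracy.

# Beyer-Swinehart pass over `frequencies`, seeded with `seed` (the delta
# comb if NULL): returns seed (*) direct-count comb of the oscillators.
bs_pass <- function(frequencies, grid, seed = NULL) {
  n <- grid$n_bins
  g <- if (is.null(seed)) c(1, numeric(n - 1)) else seed
  stride <- function(g, k) {
    if (k >= n) return(g)
    for (r in seq_len(k)) {
      idx <- seq.int(r, n, by = k)
      g[idx] <- cumsum(g[idx])
    }
    g
  }
  for (w in frequencies) {
    x <- w * .cidfrag_const$cm1_eV / grid$bin_width
    k <- as.integer(floor(x))
    if (k < 1) {
      warning("frequency ", w, " cm^-1 below one bin width: grid too coarse")
      g <- stride(g, 1L)
      next
    }
    alpha <- (k + 1) - x
    # fractional stride: interpolate between the adjacent integer combs so
    # the effective quantum equals the exact frequency (exact when the
    # frequency sits on the grid; removes the rounding bias otherwise)
    g <- if (alpha >= 1) stride(g, k)
         else alpha * stride(g, k) + (1 - alpha) * stride(g, k + 1L)
  }
  g
}

# a power-law density c * eps^a as (a, c); NULL stands for the delta
.rot_factor <- function(sp) {
  b <- sp$rot_constants * .cidfrag_const$cm1_eV
  s <- sp$symmetry_number
  if (length(b) == 0) return(NULL)
  if (length(b) == 1) return(c(a = 0, c = 1 / (s * b)))
  c(a = 0.5, c = 2 / (s * sqrt(prod(b))))
}

.trans_factor <- function(masses, volume) {
  m <- length(masses)
  if (m == 1) return(NULL)
  s <- 3 * (m - 1) / 2
  cn <- .cidfrag_const$kappa^s * (prod(masses) / sum(masses))^1.5 *
    volume^(m - 1) / gamma(s)
  c(a = s - 1, c = cn)
}

# closed-form convolution of power-law densities:
# conv_i (c_i eps^(a_i)) = [prod c_i Gamma(a_i+1) / Gamma(A+1)] * eps^A,
# A = sum(a_i + 1) - 1 (delta factors drop out)
.power_law_combine <- function(factors) {
  factors <- Filter(Negate(is.null), factors)
  if (length(factors) == 0) return(NULL)
  a <- vapply(factors, `[[`, numeric(1), 1)
  cc <- vapply(factors, `[[`, numeric(1), 2)
  a_tot <- sum(a + 1) - 1
  log_c <- sum(log(cc)) + sum(lgamma(a + 1)) - lgamma(a_tot + 1)
  c(a = a_tot, c = exp(log_c))
}

# evaluate a power-law density on the grid (bin 0 holds the bin average)
.power_law_array <- function(factor, grid) {
  if (is.null(factor)) {
    v <- numeric(grid$n_bins); v[1] <- 1 / grid$bin_width
    return(v)
  }
  a <- factor[1]; cc <- factor[2]
  v <- cc * grid$energies^a
  v[1] <- cc * grid$bin_width^a / (a + 1)
  v
}

# total channel DOS (unshifted, per eV) plus the ingredients reused by the
# sampler and the energy partition
.channel_dos_parts <- function(db, channel, grid, volume,
                               partition = FALSE) {
  prods <- channel$products
  sps <- lapply(prods, function(nm) db_get(db, nm))
  for (sp in sps) {
    if (sum(sp$composition) > 1 && length(sp$frequencies) == 0) {
      stop("species '", sp$name, "' has no frequencies")
    }
  }
  freqs <- unlist(lapply(sps, `[[`, "frequencies"))
  rot_factors <- lapply(sps, .rot_factor)
  rot_f <- .power_law_combine(rot_factors)
  masses <- vapply(sps, `[[`, numeric(1), "mass")
  trans_f <- .trans_factor(masses, volume)
  kernel_f <- .power_law_combine(list(rot_f, trans_f))
  omega <- bs_pass(freqs, grid, .power_law_array(kernel_f, grid))
  if (is.null(kernel_f)) omega <- omega / grid$bin_width  # delta seed
  out <- list(freqs = freqs, rot_f = rot_f, trans_f = trans_f,
              omega_unshifted = omega)
  if (partition) {
    # numerators of <e_trans> and <e_rot>: weight one factor by eps
    out$num_t <- if (is.null(trans_f)) NULL else {
      f <- .power_law_combine(list(rot_f, c(trans_f[1] + 1, trans_f[2])))
      bs_pass(freqs, grid, .power_law_array(f, grid))
    }
    out$num_r <- if (is.null(rot_f)) NULL else {
      f <- .power_law_combine(list(trans_f, c(rot_f[1] + 1, rot_f[2])))
      bs_pass(freqs, grid, .power_law_array(f, grid))
    }
  }
  out
}

# shift a value vector up in energy by `threshold` (zero below it)
shift_by_threshold <- function(values, grid, threshold) {
  k <- as.integer(round(threshold / grid$bin_width))
  n <- length(values)
  out <- numeric(n)
  if (k < 0) k <- 0L
  if (k < n) out[(k + 1):n] <- values[seq_len(n - k)]
  out
}

#' Total density of states of a fragmentation channel
#'
#' Convolves the rovibrational densities of all product fragments with the
#' relative translational density and shifts the result up by the channel
#' threshold: Omega_c(E) = [(*)_fragments (rho_vib (*) rho_rot)] (*)
#' rho_trans evaluated at E - dE_c, zero below the threshold. Multisets with
#' repeated fragments are divided by the permutation factor prod(n_j!)
#' (identical fragments are indistinguishable).
#'
#' @param db a [species_db()].
#' @param channel a channel from [enumerate_channels()].
#' @param grid an [energy_grid()].
#' @param volume container volume per extra fragment, Angstrom^3 (default: a
#'   sphere of radius 10 Angstrom). Branching ratios depend on it, so it is
#'   carried in all outputs.
#' @return A `state_function` with Omega_c on the grid.
#' @export
channel_dos <- function(db, channel, grid, volume = default_volume()) {
  parts <- .channel_dos_parts(db, channel, grid, volume)
  perm <- prod(factorial(table(channel$products)))
  vals <- shift_by_threshold(parts$omega_unshifted / perm, grid,
                             channel$threshold)
  state_function(grid, vals)
}

#' Default container volume
#'
#' Volume of a sphere of radius 10 Angstrom, the per-extra-fragment
#' container used in the translational density of states.
#'
#' @param radius sphere radius, Angstrom.
#' @return Volume in Angstrom^3.
#' @export
default_volume <- function(radius = 10) 4 / 3 * pi * radius^3
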