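# Microcanonical breakdown curves and energy partitioning by exact
# channel-DOS enumeration.

# Enumerate channels, prune above e_max, and precompute all per-channel DOS
# ingredients shared by breakdown_exact(), energy_partition() and the
# Metropolis sampler.
channel_pieces <- function(db, parent, grid, volume = default_volume(),
                           max_fragments = 7L, e_max_prune = grid$e_max,
                           partition = FALSE) {
  channels <- enumerate_channels(db, parent, max_fragments)
  keep <- vapply(channels, function(ch) ch$threshold <= e_max_prune,
                 logical(1))
  channels <- channels[keep]
  pieces <- lapply(channels, function(ch) {
    parts <- .channel_dos_parts(db, ch, grid, volume, partition = partition)
    perm <- prod(factorial(table(ch$products)))
    omega_unshifted <- parts$omega_unshifted / perm
    c(parts, list(channel = ch, perm = perm,
                  omega_unshifted = omega_unshifted,
                  omega = shift_by_threshold(omega_unshifted, grid,
                                             ch$threshold)))
  })
  list(channels = channels, pieces = pieces, grid = grid, volume = volume,
       parent = parent)
}

#' Breakdown curve by exact channel enumeration
#'
#' Fragmentation probabilities as a function of the precursor's internal
#' energy: P(c|E) = Omega_c(E) / sum_c' Omega_c'(E), the microcanonical
#' ensemble over all enumerated fragmentation channels (the trivial channel
#' `{parent}` included). Per-charged-fragment marginals sum the channels
#' sharing a charged product. Below the lowest dissociation threshold the
#' parent survives with probability one.
#'
#' @param db a [species_db()].
#' @param parent parent species name.
#' @param grid an [energy_grid()] (default 1 meV bins to 15 eV).
#' @param volume container volume per extra fragment, Angstrom^3.
#' @param max_fragments maximum products per channel.
#' @param e_max_prune channels with thresholds above this are dropped from
#'   sampling (default: top of the grid).
#' @return Object of class `breakdown_curve` with the energy grid, the
#'   channel list, the per-channel probability matrix `probabilities`
#'   (bins x channels), and `fragment_probabilities` (bins x charged
#'   fragments, parent column included and named).
#' @export
breakdown_exact <- function(db, parent, grid = energy_grid(),
                            volume = default_volume(), max_fragments = 7L,
                            e_max_prune = grid$e_max) {
  cp <- channel_pieces(db, parent, grid, volume, max_fragments, e_max_prune)
  omega <- vapply(cp$pieces, `[[`, numeric(grid$n_bins), "omega")
  tot <- rowSums(omega)
  bad <- tot <= 0 & cp$grid$energies > 0
  if (any(bad)) {
    stop("all channel densities vanish at E = ",
         signif(cp$grid$energies[which(bad)[1]], 4),
         " eV: inconsistent database")
  }
  tot[tot <= 0] <- 1           # E = 0 edge bin: parent defined below
  prob <- omega / tot
  if (any(rowSums(omega) <= 0)) {
    i0 <- which(rowSums(omega) <= 0)
    parent_col <- which(vapply(cp$channels, function(ch) {
      length(ch$products) == 1 && ch$products == parent
    }, logical(1)))
    prob[i0, ] <- 0
    prob[i0, parent_col] <- 1
  }
  frag_names <- vapply(cp$channels, `[[`, character(1), "charged_product")
  frags <- unique(frag_names)
  fp <- vapply(frags, function(f) {
    cols <- which(frag_names == f)
    rowSums(prob[, cols, drop = FALSE])
  }, numeric(grid$n_bins))
  colnames(fp) <- frags
  structure(list(grid = grid, channels = cp$channels, parent = parent,
                 volume = cp$volume, probabilities = prob,
                 fragment_probabilities = fp,
                 thresholds = vapply(cp$channels, `[[`, numeric(1),
                                     "threshold")),
            class = "breakdown_curve")
}

#' @export
print.breakdown_curve <- function(x, ...) {
  cat(sprintf(
    "<breakdown_curve> parent %s: %d channels, %d charged fragments\n",
    x$parent, length(x$channels), ncol(x$fragment_probabilities)))
  cat(sprintf("  grid 0..%g eV (%g eV bins), container volume %.0f A^3\n",
              x$grid$e_max, x$grid$bin_width, x$volume))
  cat(sprintf("  lowest threshold %.3f eV\n",
              min(x$thresholds[x$thresholds > 0])))
  invisible(x)
}

#' Fragment probabilities at given internal energies
#'
#' Linear interpolation of the per-charged-fragment marginals of a
#' breakdown curve.
#'
#' @param curve a [breakdown_exact()] result.
#' @param energies internal energies, eV.
#' @return Matrix (length(energies) x fragments).
#' @export
fragment_probs_at <- function(curve, energies) {
  fp <- curve$fragment_probabilities
  out <- vapply(colnames(fp), function(f) {
    stats::approx(curve$grid$energies, fp[, f], xout = energies,
                  rule = 2)$y
  }, numeric(length(energies)))
  matrix(out, nrow = length(energies),
         dimnames = list(NULL, colnames(fp)))
}

#' Plot a breakdown curve
#'
#' @param x a `breakdown_curve`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.breakdown_curve <- function(x, ...) {
  graphics::matplot(x$grid$energies, x$fragment_probabilities, type = "l",
                    lty = 1, xlab = "internal energy (eV)",
                    ylab = "probability", ...)
  graphics::legend("right", legend = colnames(x$fragment_probabilities),
                   col = seq_len(ncol(x$fragment_probabilities)), lty = 1,
                   cex = 0.7)
  invisible(x)
}

#' Mean partitioning of internal energy over cluster degrees of freedom
#'
#' Microcanonical expectations, at each internal energy, of the
#' translational, vibrational and rotational energy of the fragments and of
#' the intermolecular energy (the channel-probability-weighted sum of
#' dissociation thresholds, i.e. the electronic energy stored in separated
#' fragments). Components are non-negative and sum to E within one bin
#' width. Below the lowest threshold the intermolecular and translational
#' components vanish and vibration plus rotation carry all of E.
#'
#' @inheritParams breakdown_exact
#' @return Object of class `energy_partition`: the grid plus a `components`
#'   matrix (bins x {translational, rotational, vibrational,
#'   intermolecular}).
#' @export
energy_partition <- function(db, parent, grid = energy_grid(),
                             volume = default_volume(), max_fragments = 7L,
                             e_max_prune = grid$e_max) {
  cp <- channel_pieces(db, parent, grid, volume, max_fragments, e_max_prune,
                       partition = TRUE)
  n <- grid$n_bins
  e <- grid$energies
  omega <- vapply(cp$pieces, `[[`, numeric(n), "omega")
  tot <- rowSums(omega)
  tot[tot <= 0] <- 1
  prob <- omega / tot

  etrans <- matrix(0, n, length(cp$pieces))
  erot <- matrix(0, n, length(cp$pieces))
  for (j in seq_along(cp$pieces)) {
    pc <- cp$pieces[[j]]
    om <- pc$omega_unshifted * pc$perm   # numerators carry no perm factor
    ok <- om > 0
    et <- numeric(n); er <- numeric(n)
    if (!is.null(pc$num_t)) et[ok] <- pc$num_t[ok] / om[ok]
    if (!is.null(pc$num_r)) er[ok] <- pc$num_r[ok] / om[ok]
    etrans[, j] <- shift_by_threshold(et, grid, pc$channel$threshold)
    erot[, j] <- shift_by_threshold(er, grid, pc$channel$threshold)
  }
  thr <- vapply(cp$channels, `[[`, numeric(1), "threshold")
  inter <- as.numeric(prob %*% thr)
  mt <- rowSums(prob * etrans)
  mr <- rowSums(prob * erot)
  # excess energy E - dE_c per channel, then vibration as the remainder:
  # guarantees exact closure sum(components) = E
  excess <- outer(e, thr, `-`)
  mv <- rowSums(prob * pmax(excess, 0)) - mt - mr
  mv <- pmax(mv, 0)
  components <- cbind(translational = mt, rotational = mr, vibrational = mv,
                      intermolecular = inter)
  structure(list(grid = grid, parent = parent, volume = volume,
                 components = components),
            class = "energy_partition")
}

#' @export
print.energy_partition <- function(x, ...) {
  cat(sprintf("<energy_partition> parent %s on 0..%g eV\n", x$parent,
              x$grid$e_max))
  i <- which.min(abs(x$grid$energies - min(3, x$grid$e_max / 2)))
  cat(sprintf("  at %.2f eV: trans %.3f, rot %.3f, vib %.3f, inter %.3f eV\n",
              x$grid$energies[i], x$components[i, 1], x$components[i, 2],
              x$components[i, 3], x$components[i, 4]))
  invisible(x)
}

#' Plot mean energy components against internal energy
#'
#' @param x an `energy_partition`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.energy_partition <- function(x, ...) {
  graphics::matplot(x$grid$energies, x$components, type = "l", lty = 1,
                    xlab = "internal energy (eV)",
                    ylab = "mean component energy (eV)", ...)
  graphics::legend("topleft", legend = colnames(x$components),
                   col = seq_len(ncol(x$components)), lty = 1, cex = 0.8)
  invisible(x)
}
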