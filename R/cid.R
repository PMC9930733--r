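# Forward model: centre-of-mass collision energy -> deposited internal
# energy -> fragmentation pattern -> instrument-observed pattern.

#' Laboratory to centre-of-mass collision energy
#'
#' Only the centre-of-mass fraction of the laboratory collision energy is
#' available for internal excitation: e_cm = e_lab * m_gas/(m_gas + m_ion).
#'
#' @param e_lab laboratory collision energy, eV.
#' @param m_ion ion mass, amu (229 for Cys(H2O)6+).
#' @param m_gas collision-gas mass, amu (40 for Ar).
#' @return Centre-of-mass collision energy, eV.
#' @examples
#' lab_to_cm(8, 229, 40)   # 1.190 eV
#' @export
lab_to_cm <- function(e_lab, m_ion, m_gas) {
  stopifnot(m_ion > 0, m_gas > 0)
  e_lab * m_gas / (m_gas + m_ion)
}

#' Two-component energy-deposition model
#'
#' The internal energy deposited by a single collision is modelled as a
#' mixture of a discrete non-ergodic component (weight `w_ne`, all mass at
#' `e_ne`; physically the impulsive ejection of a single water molecule
#' that bypasses statistical energy redistribution) and an ergodic Gaussian
#' component (mean `mu`, width `sigma`, truncated at zero and
#' renormalized).
#'
#' @param w_ne weight of the discrete component, in `[0, 1]`.
#' @param e_ne energy of the discrete component, eV (>= 0).
#' @param mu mean of the Gaussian component, eV.
#' @param sigma standard deviation of the Gaussian component, eV (> 0).
#' @return Object of class `deposition_model`.
#' @export
deposition_model <- function(w_ne, e_ne, mu, sigma) {
  stopifnot(w_ne >= 0, w_ne <= 1, e_ne >= 0, sigma > 0)
  structure(list(w_ne = w_ne, e_ne = e_ne, mu = mu, sigma = sigma),
            class = "deposition_model")
}

#' @export
print.deposition_model <- function(x, ...) {
  cat(sprintf(
    "<deposition_model> w_ne = %.3f at E_ne = %.3f eV; Gaussian mu = %.3f, sigma = %.3f eV\n",
    x$w_ne, x$e_ne, x$mu, x$sigma))
  invisible(x)
}

# density of the truncated-at-zero Gaussian component on the grid,
# normalized to unit mass
.gauss_weights <- function(grid, mu, sigma) {
  w <- stats::dnorm(grid$energies, mu, sigma)
  tot <- sum(w)
  if (tot <= 0) return(w)
  w / tot
}

#' Predict a fragmentation pattern from a deposition model
#'
#' Maps the deposited-energy distribution through the breakdown curve:
#' for every charged fragment f (parent excluded, as precursor intensities
#' are excluded from CID pattern analysis),
#' I_f = w_ne * P_f(E_ne) + (1 - w_ne) * Int N(E; mu, sigma) P_f(E) dE,
#' renormalized over the non-parent fragments. Both mixture components are
#' mapped through the same microcanonical fragmentation probabilities
#' P_f(E); the discrete component therefore predicts the pattern of the
#' breakdown curve at E_ne, which for the cluster fixtures is dominated by
#' single-water loss. Before renormalization the pattern is linear in the
#' mixture weight.
#'
#' @param curve a [breakdown_exact()] result.
#' @param dep a [deposition_model()].
#' @param include_parent keep the surviving-parent column instead of
#'   excluding and renormalizing (default `FALSE`).
#' @return Named intensity vector summing to 1.
#' @export
predict_pattern <- function(curve, dep, include_parent = FALSE) {
  grid <- curve$grid
  if (dep$mu + 4 * dep$sigma > grid$e_max || dep$e_ne > grid$e_max) {
    stop("breakdown grid too short for the deposition model (extend e_max)")
  }
  fp <- curve$fragment_probabilities
  w <- .gauss_weights(grid, dep$mu, dep$sigma)
  ergodic <- as.numeric(t(fp) %*% w)
  names(ergodic) <- colnames(fp)
  ne <- fragment_probs_at(curve, dep$e_ne)[1, ]
  pat <- dep$w_ne * ne + (1 - dep$w_ne) * ergodic
  if (!include_parent) pat <- pat[setdiff(names(pat), curve$parent)]
  tot <- sum(pat)
  if (tot <= 0) return(pat)
  pat / tot
}

#' Apply instrument effects to a fragmentation pattern
#'
#' Removes fragments below the m/z transmission cutoff of the analyser
#' (m/z < 40 for the orthogonal TOF used for the cluster measurements,
#' which is why e.g. NH4+ at m/z 18 is undetectable), applies per-fragment
#' detection efficiencies, and renormalizes. Removals are reported via a
#' message.
#'
#' @param pattern named intensity vector.
#' @param mz named integer vector of fragment m/z values (names covering
#'   the pattern).
#' @param mz_cutoff fragments with m/z strictly below this are removed.
#' @param efficiency named (or scalar) detection-efficiency factors.
#' @return Renormalized named intensity vector.
#' @export
apply_instrument <- function(pattern, mz, mz_cutoff = 40, efficiency = 1) {
  stopifnot(all(names(pattern) %in% names(mz)))
  if (length(efficiency) == 1) {
    efficiency <- setNames(rep(efficiency, length(pattern)), names(pattern))
  }
  keep <- mz[names(pattern)] >= mz_cutoff
  if (!any(keep)) stop("all fragments fall below the m/z cutoff")
  if (any(!keep)) {
    message("removed below m/z ", mz_cutoff, ": ",
            paste(names(pattern)[!keep], collapse = ", "))
  }
  out <- pattern[keep] * efficiency[names(pattern)[keep]]
  out / sum(out)
}
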