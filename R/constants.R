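# Physical constants (CODATA 2018) and standard atomic weights (IUPAC 2021).
# Internal energy unit is eV, length unit is Angstrom, mass unit is amu.

#' @keywords internal
.cidfrag_const <- local({
  h_eVs   <- 4.135667696e-15            # Planck constant, eV s
  eV_J    <- 1.602176634e-19            # 1 eV in J
  amu_kg  <- 1.66053906660e-27          # 1 amu in kg
  # 1 amu expressed in eV s^2 / Angstrom^2 (mass unit consistent with eV, A)
  amu_eV  <- amu_kg / eV_J * 1e-20
  list(
    h_eVs    = h_eVs,
    cm1_eV   = 1.239841984e-4,          # 1 cm^-1 in eV
    amu_eV   = amu_eV,
    # 2*pi*m/h^2 for m = 1 amu, in 1/(eV A^2); enters the translational DOS
    kappa    = 2 * pi * amu_eV / h_eVs^2
  )
})

# Standard atomic weights, IUPAC 2021 (conventional values).
.atomic_weights <- c(
  H = 1.008, He = 4.0026, C = 12.011, N = 14.007, O = 15.999,
  S = 32.06, P = 30.974, Na = 22.990, K = 39.098, Cl = 35.45,
  F = 18.998, Ar = 39.95
)

#' Molecular mass from an elemental composition
#'
#' Sums IUPAC 2021 standard atomic weights over an element -> count map.
#'
#' @param composition named integer vector, e.g. `c(H = 2, O = 1)`.
#' @return Mass in amu.
#' @examples
#' composition_mass(c(H = 2, O = 1))   # 18.015
#' @export
composition_mass <- function(composition) {
  stopifnot(length(composition) > 0, !is.null(names(composition)))
  unknown <- setdiff(names(composition), names(.atomic_weights))
  if (length(unknown) > 0) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  }
  sum(.atomic_weights[names(composition)] * as.numeric(composition))
}

# Run code with a temporary RNG state seeded from `seed`; restores the
# caller's .Random.seed afterwards so generators do not disturb user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# format a composition as a canonical string (fixed element order)
format_composition <- function(composition) {
  ord <- intersect(names(.atomic_weights), names(composition))
  paste0(ord, composition[ord], collapse = " ")
}
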