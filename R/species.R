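#' Construct a species record
#'
#' A species is one entry of the fragment thermochemistry database: a
#' molecule, cluster or ion with its elemental composition, charge, relative
#' electronic energy (including zero-point energy) on the database's common
#' reference, harmonic vibrational wavenumbers, rotational constants and
#' symmetry number. The mass is derived from the composition with standard
#' atomic weights.
#'
#' Geometry is inferred from the number of rotational constants: 0 for an
#' atom, 1 for a linear rotor, 3 for a nonlinear rotor. The number of
#' harmonic frequencies must equal 0, 3N-5 or 3N-6 respectively, for N
#' atoms.
#'
#' @param name identifier, unique within a database.
#' @param composition named integer vector of element counts.
#' @param charge integer charge in elementary charges.
#' @param energy relative electronic energy incl. ZPE, eV.
#' @param frequencies harmonic wavenumbers, cm^-1 (empty for an atom).
#' @param rot_constants rotational constants, cm^-1 (0, 1 or 3 values).
#' @param symmetry_number rotational symmetry number, positive integer.
#' @param ionization_energy adiabatic ionization energy, eV, or `NA`.
#' @return An object of class `cid_species`.
#' @export
species <- function(name, composition, charge, energy, frequencies,
                    rot_constants, symmetry_number = 1,
                    ionization_energy = NA_real_) {
  composition <- composition[composition > 0]
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("species name must be a non-empty string")
  }
  n_atoms <- sum(composition)
  n_rot <- length(rot_constants)
  expected_freqs <- switch(as.character(n_rot),
    "0" = 0L,
    "1" = max(3L * n_atoms - 5L, 0L),
    "3" = 3L * n_atoms - 6L,
    stop("species '", name, "': rot_constants must have length 0, 1 or 3")
  )
  if (n_rot == 0 && n_atoms > 1) {
    stop("species '", name, "': polyatomic species needs rotational constants")
  }
  if (length(frequencies) != expected_freqs) {
    stop("species '", name, "': expected ", expected_freqs,
         " frequencies for ", n_atoms, " atoms, got ", length(frequencies))
  }
  if (any(frequencies <= 0)) {
    stop("species '", name, "': frequencies must be positive")
  }
  if (n_rot > 0 && any(rot_constants <= 0)) {
    stop("species '", name, "': rotational constants must be positive")
  }
  if (symmetry_number < 1 || symmetry_number != round(symmetry_number)) {
    stop("species '", name, "': symmetry_number must be a positive integer")
  }
  if (!is.finite(energy)) stop("species '", name, "': energy must be finite")
  mass <- composition_mass(composition)
  structure(list(
    name = name,
    composition = composition,
    charge = as.integer(charge),
    energy = as.numeric(energy),
    frequencies = as.numeric(frequencies),
    rot_constants = as.numeric(rot_constants),
    symmetry_number = as.integer(symmetry_number),
    ionization_energy = as.numeric(ionization_energy),
    mass = mass
  ), class = "cid_species")
}

#' @export
print.cid_species <- function(x, ...) {
  cat(sprintf("<species> %s  [%s]  q=%+d  E=%.4f eV  m=%.3f amu  %d modes\n",
              x$name, format_composition(x$composition), x$charge,
              x$energy, x$mass, length(x$frequencies)))
  invisible(x)
}

#' Assemble a species database
#'
#' @param species_list list of [species()] records.
#' @param reference name of the species that anchors the energy scale
#'   (energy 0), typically the parent cluster ion of the study.
#' @return Object of class `species_db`.
#' @export
species_db <- function(species_list, reference = NULL) {
  nm <- vapply(species_list, function(s) s$name, character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate species name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(species_list) <- nm
  if (!is.null(reference) && !reference %in% nm) {
    stop("reference species '", reference, "' not in database")
  }
  structure(list(species = species_list, reference = reference,
                 schema_version = 1L),
            class = "species_db")
}

#' @export
print.species_db <- function(x, ...) {
  cat(sprintf("<species_db> %d species (reference: %s)\n",
              length(x$species),
              if (is.null(x$reference)) "none" else x$reference))
  for (s in x$species) print(s)
  invisible(x)
}

#' @export
length.species_db <- function(x) length(x$species)

db_get <- function(db, name) {
  s <- db$species[[name]]
  if (is.null(s)) stop("species '", name, "' not in database")
  s
}

#' Load a species database from JSON or YAML
#'
#' The file format is a single document with keys `schema_version`,
#' `reference` (optional) and `species`, a list of records with fields
#' `name`, `composition` (element -> count map), `charge`, `energy_eV`,
#' `frequencies_cm1`, `rot_constants_cm1`, `symmetry_number` and optional
#' `ionization_energy_eV`. All invariants of [species()] are validated and
#' duplicate names are rejected.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A [species_db()] object.
#' @export
load_species_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE),
    yaml = , yml = yaml::read_yaml(path),
    stop("unsupported database format '.", ext, "' (use .json or .yaml)")
  )
  if (is.null(raw$species)) stop("malformed database file: no 'species' key")
  sp <- lapply(seq_along(raw$species), function(i) {
    r <- raw$species[[i]]
    required <- c("name", "composition", "charge", "energy_eV",
                  "symmetry_number")
    missing <- setdiff(required, names(r))
    if (length(missing) > 0) {
      stop("record ", i, if (!is.null(r$name)) paste0(" ('", r$name, "')"),
           ": missing field(s) ", paste(missing, collapse = ", "))
    }
    species(
      name = r$name,
      composition = unlist(r$composition),
      charge = r$charge,
      energy = r$energy_eV,
      frequencies = as.numeric(unlist(r$frequencies_cm1)),
      rot_constants = as.numeric(unlist(r$rot_constants_cm1)),
      symmetry_number = r$symmetry_number,
      ionization_energy =
        if (is.null(r$ionization_energy_eV)) NA_real_
        else r$ionization_energy_eV
    )
  })
  species_db(sp, reference = raw$reference)
}

#' Write a species database to JSON or YAML
#'
#' Inverse of [load_species_db()]. Output is deterministic (fixed field
#' order, 10 significant digits), so identical databases produce
#' byte-identical files.
#'
#' @param db a [species_db()].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_species_db <- function(db, path) {
  recs <- lapply(unname(db$species), function(s) {
    r <- list(
      name = s$name,
      composition = as.list(s$composition),
      charge = s$charge,
      energy_eV = signif(s$energy, 10),
      frequencies_cm1 = as.list(signif(s$frequencies, 10)),
      rot_constants_cm1 = as.list(signif(s$rot_constants, 10)),
      symmetry_number = s$symmetry_number
    )
    if (!is.na(s$ionization_energy)) {
      r$ionization_energy_eV <- signif(s$ionization_energy, 10)
    }
    r
  })
  doc <- list(schema_version = 1L, reference = db$reference, species = recs)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path, precision = 10)
  } else {
    stop("unsupported database format '.", ext, "'")
  }
  invisible(path)
}
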