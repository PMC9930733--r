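#' Dissociation threshold of a fragmentation channel
#'
#' The threshold is the relative electronic energy of the separated products
#' with respect to the parent ion, `sum(E_products) - E_parent`. Energy is a
#' state function, so thresholds are additive under refinement of a channel.
#' A negative threshold is possible only for an inconsistent database and is
#' flagged with a warning.
#'
#' @param db a [species_db()].
#' @param products character vector of product species names (a multiset;
#'   repeats allowed).
#' @param parent parent species name.
#' @return Threshold in eV.
#' @export
compute_threshold <- function(db, products, parent) {
  p <- db_get(db, parent)
  e <- vapply(products, function(nm) db_get(db, nm)$energy, numeric(1))
  thr <- sum(e) - p$energy
  if (thr < -1e-9) {
    warning("negative threshold (", signif(thr, 4), " eV) for ",
            paste(products, collapse = " + "), ": inconsistent database?")
  }
  thr
}

#' Locate the charge among neutral-precursor fragments
#'
#' For a singly charged parent the charge ends up on the fragment with the
#' lowest adiabatic ionization energy (for cysteine-water clusters that is
#' always the cysteine-containing fragment: IE(Cys) = 8.01 eV lies below
#' water, 12.6223 eV, and the water dimer, 11.21 eV). Ties break
#' lexicographically by name.
#'
#' @param db a [species_db()].
#' @param fragments character vector of fragment species names.
#' @return The name of the charge-carrying fragment.
#' @export
assign_charge <- function(db, fragments) {
  stopifnot(length(fragments) >= 1)
  ie <- vapply(fragments, function(nm) db_get(db, nm)$ionization_energy,
               numeric(1))
  if (anyNA(ie)) {
    stop("missing ionization energy for: ",
         paste(fragments[is.na(ie)], collapse = ", "))
  }
  ord <- order(ie, fragments)
  fragments[ord[1]]
}

# composition of a species list as a matrix row-sum helper
.comp_vector <- function(composition, elements) {
  v <- setNames(numeric(length(elements)), elements)
  v[names(composition)] <- composition
  v
}

#' Enumerate fragmentation channels of a parent ion
#'
#' Returns every multiset of database species with at most `max_fragments`
#' members whose element counts and total charge equal the parent's,
#' including the trivial channel `{parent}`. For a singly charged parent
#' exactly one product must be charged; composition-conserving multisets
#' that cannot satisfy the charge constraint are omitted with a warning.
#' Channels are ordered by ascending threshold, ties broken
#' lexicographically by concatenated product names.
#'
#' For a precursor with n waters and all water-cluster sizes in the
#' database, the channels reaching the bare ion are exactly the integer
#' partitions of n: clustered water loss is enumerated alongside fully
#' sequential loss.
#'
#' @param db a [species_db()].
#' @param parent parent species name.
#' @param max_fragments maximum number of product fragments (>= 1).
#' @return List of channels; each has `products` (sorted character vector),
#'   `threshold` (eV), `n_fragments`, and `charged_product`.
#' @export
enumerate_channels <- function(db, parent, max_fragments = 7L) {
  stopifnot(max_fragments >= 1)
  p <- db_get(db, parent)
  elements <- unique(unlist(lapply(db$species, function(s) names(s$composition))))
  target <- .comp_vector(p$composition, elements)

  nms <- sort(names(db$species))
  comp <- vapply(nms, function(nm) .comp_vector(db$species[[nm]]$composition,
                                                elements),
                 numeric(length(elements)))
  comp <- matrix(comp, nrow = length(elements), dimnames = list(elements, nms))

  results <- list()
  recurse <- function(i, remaining, chosen, slots) {
    if (all(remaining == 0)) {
      results[[length(results) + 1L]] <<- chosen
      return(invisible())
    }
    if (i > length(nms) || slots == 0L) return(invisible())
    ci <- comp[, i]
    # max copies of species i that fit the remaining composition
    kmax <- if (any(ci > 0)) floor(min(remaining[ci > 0] / ci[ci > 0])) else 0
    kmax <- min(kmax, slots)
    for (k in kmax:0) {
      recurse(i + 1L, remaining - k * ci,
              c(chosen, rep(nms[i], k)), slots - k)
    }
    invisible()
  }
  recurse(1L, target, character(0), as.integer(max_fragments))

  # group multisets by their composition split (ignoring charge state); a
  # split is reported as omitted only if no charge assignment satisfies
  # conservation with exactly one charged product
  split_key <- vapply(results, function(prods) {
    paste(sort(vapply(prods, function(nm) {
      format_composition(db$species[[nm]]$composition)
    }, character(1))), collapse = " | ")
  }, character(1))
  valid <- vapply(results, function(prods) {
    q <- vapply(prods, function(nm) db$species[[nm]]$charge, integer(1))
    sum(q) == p$charge && (abs(p$charge) != 1 || sum(q != 0) == 1)
  }, logical(1))
  omitted <- length(setdiff(unique(split_key), unique(split_key[valid])))

  channels <- lapply(results[valid], function(prods) {
    q <- vapply(prods, function(nm) db$species[[nm]]$charge, integer(1))
    structure(list(
      products = sort(prods),
      threshold = compute_threshold(db, prods, parent),
      n_fragments = length(prods),
      charged_product = prods[q != 0][1]
    ), class = "cid_channel")
  })
  if (omitted > 0) {
    warning(omitted, " composition split(s) omitted: no valid ",
            "charge assignment among database species")
  }
  key <- vapply(channels, function(ch) paste(ch$products, collapse = "+"),
                character(1))
  thrs <- vapply(channels, `[[`, numeric(1), "threshold")
  channels[order(thrs, key)]
}

#' @export
print.cid_channel <- function(x, ...) {
  cat(sprintf("<channel> %s  dE = %.4f eV  (%d fragments, charge on %s)\n",
              paste(x$products, collapse = " + "), x$threshold,
              x$n_fragments, x$charged_product))
  invisible(x)
}

#' Integer m/z of a species
#'
#' Mass over absolute charge, rounded to the nearest integer (the
#' convention used for peak labels such as 229 for Cys(H2O)6+).
#'
#' @param sp a [species()] or a [species_db()] plus `name`.
#' @param name species name when `sp` is a database.
#' @return Integer m/z; `NA` for a neutral.
#' @export
species_mz <- function(sp, name = NULL) {
  if (inherits(sp, "species_db")) sp <- db_get(sp, name)
  if (sp$charge == 0) return(NA_integer_)
  as.integer(round(sp$mass / abs(sp$charge)))
}
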