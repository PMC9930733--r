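# Post-analysis of dissociation-dynamics trajectories: multi-frame XYZ
# input, fragment recognition by a distance cutoff, outcome classification.

#' Read a multi-frame (extended) XYZ trajectory
#'
#' Standard multi-frame XYZ: repeated blocks of an atom count, a comment
#' line, and one `symbol x y z [charge]` line per atom. A fifth numeric
#' column is read as per-atom partial charges (extended XYZ); a comment
#' line containing `time = <t>` (or `t = <t>`) sets the frame time stamp in
#' fs. All frames must share the same atom count.
#'
#' @param path path to an `.xyz` file.
#' @return Object of class `xyz_trajectory`: a list of frames, each with
#'   `symbols`, `coords` (N x 3 matrix, Angstrom), optional `charges`, and
#'   `time` (fs or `NA`).
#' @export
read_xyz_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  frames <- list()
  i <- 1L
  n_atoms_ref <- NULL
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) {
      stop("frame ", length(frames) + 1L, ": expected an atom count at line ",
           i)
    }
    if (is.null(n_atoms_ref)) n_atoms_ref <- n
    if (n != n_atoms_ref) {
      stop("frame ", length(frames) + 1L, ": atom count ", n,
           " differs from first frame (", n_atoms_ref, ")")
    }
    if (i + 1L + n > length(lines)) {
      stop("frame ", length(frames) + 1L, " is truncated")
    }
    comment <- lines[i + 1L]
    tm <- NA_real_
    m <- regmatches(comment,
                    regexec("t(?:ime)?\\s*=\\s*([-0-9.eE+]+)", comment))[[1]]
    if (length(m) == 2) tm <- as.numeric(m[2])
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    ntok <- lengths(toks)
    if (any(ntok < 4)) {
      stop("frame ", length(frames) + 1L, ": malformed atom line")
    }
    symbols <- vapply(toks, `[[`, character(1), 1)
    coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    charges <- NULL
    if (all(ntok >= 5)) {
      charges <- vapply(toks, function(tk) as.numeric(tk[5]), numeric(1))
      if (anyNA(charges)) charges <- NULL
    }
    frames[[length(frames) + 1L]] <- list(symbols = symbols, coords = coords,
                                          charges = charges, time = tm)
    i <- i + 2L + n
  }
  structure(frames, class = "xyz_trajectory")
}

#' Write a multi-frame XYZ trajectory
#'
#' @param traj an `xyz_trajectory` (or list of frames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj) {
    writeLines(as.character(length(fr$symbols)), con)
    writeLines(sprintf("time = %.1f fs", if (is.na(fr$time)) 0 else fr$time),
               con)
    for (a in seq_along(fr$symbols)) {
      ln <- sprintf("%-2s %14.6f %14.6f %14.6f", fr$symbols[a],
                    fr$coords[a, 1], fr$coords[a, 2], fr$coords[a, 3])
      if (!is.null(fr$charges)) ln <- sprintf("%s %10.5f", ln, fr$charges[a])
      writeLines(ln, con)
    }
  }
  invisible(path)
}

#' @export
print.xyz_trajectory <- function(x, ...) {
  cat(sprintf("<xyz_trajectory> %d frames, %d atoms%s\n", length(x),
              length(x[[1]]$symbols),
              if (!is.null(x[[1]]$charges)) ", with charges" else ""))
  invisible(x)
}

#' Fragment recognition by distance cutoff
#'
#' Atom pairs closer than the cutoff are bonded; fragments are the
#' connected components of the resulting graph (pairs at a distance larger
#' than the cutoff are treated as broken bonds). The cutoff applies
#' uniformly to all element pairs. Labels are deterministic: fragments are
#' numbered by their first atom index.
#'
#' @param frame one frame of an `xyz_trajectory` (fields `symbols`,
#'   `coords`, optional `charges`).
#' @param cutoff bond-breaking distance, Angstrom (default 2.5).
#' @return Object of class `fragment_assignment`: per-atom integer
#'   `labels`, a list `compositions` of element-count vectors, and
#'   `charges` (per-fragment summed partial charge, when available).
#' @export
detect_fragments <- function(frame, cutoff = 2.5) {
  n <- length(frame$symbols)
  stopifnot(n >= 1)
  d <- as.matrix(stats::dist(frame$coords))
  adj <- d <= cutoff   # distances larger than the cutoff are broken bonds
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  # relabel by first atom index
  first <- tapply(seq_len(n), memb, min)
  relabel <- match(memb, memb[sort(first)])
  compositions <- lapply(seq_len(max(relabel)), function(k) {
    tab <- table(frame$symbols[relabel == k])
    setNames(as.integer(tab), names(tab))
  })
  charges <- if (!is.null(frame$charges)) {
    vapply(seq_len(max(relabel)), function(k) {
      sum(frame$charges[relabel == k])
    }, numeric(1))
  }
  structure(list(labels = as.integer(relabel),
                 compositions = compositions, charges = charges,
                 cutoff = cutoff),
            class = "fragment_assignment")
}

#' @export
print.fragment_assignment <- function(x, ...) {
  cat(sprintf("<fragment_assignment> %d fragment(s) at cutoff %.2f A\n",
              length(x$compositions), x$cutoff))
  for (k in seq_along(x$compositions)) {
    cat(sprintf("  %d: %s%s\n", k, format_composition(x$compositions[[k]]),
                if (!is.null(x$charges)) sprintf("  q = %+.2f", x$charges[k])
                else ""))
  }
  invisible(x)
}

.is_water_cluster <- function(comp) {
  els <- names(comp)[comp > 0]
  setequal(els, c("H", "O")) && comp[["H"]] == 2 * comp[["O"]]
}

#' Classify the outcome of a dissociation trajectory
#'
#' Classification uses the final frame only (the analysis applied at the
#' last dynamical step of each trajectory): `intact` (one fragment),
#' `single water loss` (exactly one detached fragment with composition
#' H2O), `clustered water loss` (detached pure water with a cluster of at
#' least two molecules), `covalent fragmentation` (any detached fragment
#' that is neither pure water nor the parent minus intact waters). When
#' per-atom charges are present, the charge-carrying fragment (largest
#' absolute summed charge, ties to the larger fragment) is reported.
#'
#' @param traj an `xyz_trajectory`.
#' @param parent_composition named element-count vector of the parent.
#' @param cutoff bond-breaking distance, Angstrom.
#' @return Object of class `trajectory_outcome` with `outcome`,
#'   `n_fragments`, `n_waters_lost`, `charged_fragment` (index or `NA`) and
#'   the final-frame `fragments`.
#' @export
classify_outcome <- function(traj, parent_composition, cutoff = 2.5) {
  stopifnot(length(traj) >= 1)
  final <- traj[[length(traj)]]
  total <- table(final$symbols)
  total <- setNames(as.integer(total), names(total))
  pc <- parent_composition[parent_composition > 0]
  if (!identical_comp(total, pc)) {
    stop("trajectory composition does not match the declared parent (",
         format_composition(total), " vs ", format_composition(pc), ")")
  }
  fr <- detect_fragments(final, cutoff)
  comps <- fr$compositions
  n_frag <- length(comps)
  water_idx <- which(vapply(comps, .is_water_cluster, logical(1)))
  other_idx <- setdiff(seq_len(n_frag), water_idx)
  n_waters_lost <- sum(vapply(comps[water_idx],
                              function(cc) cc[["O"]], numeric(1)))
  outcome <- if (n_frag == 1) {
    "intact"
  } else if (length(other_idx) > 1) {
    "covalent fragmentation"
  } else if (length(other_idx) == 1) {
    # remainder must be the parent minus the lost waters, else covalent
    rest <- comps[[other_idx]]
    lost <- c(H = 2 * n_waters_lost, O = n_waters_lost)
    if (identical_comp(.comp_add(rest, lost), pc)) {
      sizes <- vapply(comps[water_idx], function(cc) cc[["O"]], numeric(1))
      if (length(sizes) == 1 && sizes == 1) "single water loss"
      else "clustered water loss"
    } else "covalent fragmentation"
  } else {
    "covalent fragmentation"   # only water fragments: parent mismatch
  }
  charged <- NA_integer_
  if (!is.null(fr$charges)) {
    sz <- vapply(comps, sum, numeric(1))
    ord <- order(-abs(fr$charges), -sz)
    charged <- ord[1]
  }
  structure(list(outcome = outcome, n_fragments = n_frag,
                 n_waters_lost = as.integer(n_waters_lost),
                 charged_fragment = charged, fragments = fr),
            class = "trajectory_outcome")
}

#' @export
print.trajectory_outcome <- function(x, ...) {
  cat(sprintf("<trajectory_outcome> %s (%d fragments, %d water(s) detached)\n",
              x$outcome, x$n_fragments, x$n_waters_lost))
  invisible(x)
}
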