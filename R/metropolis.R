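# Metropolis Monte Carlo estimate of fragmentation branching ratios at a
# fixed total internal energy. The state is (channel c, translational
# energy bin i, rotational energy bin j); the vibrational energy is the
# remainder E - dE_c - e_t - e_r. The stationary weight of a state is the
# integrand of the channel density of states,
#   W(c, i, j) = rho_trans(e_i) * rho_rot(e_j) * rho_vib(e_k) * dE^2
# (one dE per continuous sharing coordinate; channels without relative
# translation have a delta factor and one fewer coordinate), so channel
# visit frequencies converge to P(c|E) = Omega_c(E)/sum Omega(E).

# split/merge adjacency between channel product multisets: two channels are
# split-neighbours if one is obtained from the other by splitting a single
# fragment into two database species of the same total composition.
channel_adjacency <- function(db, channels) {
  keys <- vapply(channels, function(ch) paste(ch$products, collapse = "+"),
                 character(1))
  nch <- length(channels)
  split_nb <- vector("list", nch)
  merge_nb <- vector("list", nch)
  comp_of <- function(nm) db$species[[nm]]$composition
  for (a in seq_len(nch)) {
    for (b in seq_len(nch)) {
      if (channels[[b]]$n_fragments != channels[[a]]$n_fragments + 1) next
      # b must contain a's products minus one fragment, plus two that sum
      # to that fragment's composition
      pa <- channels[[a]]$products
      pb <- channels[[b]]$products
      extra <- pb
      missing <- character(0)
      for (nm in pa) {
        hit <- match(nm, extra)
        if (is.na(hit)) missing <- c(missing, nm) else extra <- extra[-hit]
      }
      if (length(missing) == 1 && length(extra) == 2) {
        csum <- .comp_add(comp_of(extra[1]), comp_of(extra[2]))
        if (identical_comp(csum, comp_of(missing))) {
          qa <- db$species[[missing]]$charge
          qb <- db$species[[extra[1]]]$charge + db$species[[extra[2]]]$charge
          if (qa == qb) {
            split_nb[[a]] <- c(split_nb[[a]], b)
            merge_nb[[b]] <- c(merge_nb[[b]], a)
          }
        }
      }
    }
  }
  # transfer adjacency: same fragment count, two fragments replaced by two
  # others with the same total composition and charge (a split immediately
  # recombined: moves a subunit between fragments); symmetric
  transfer_nb <- vector("list", nch)
  for (a in seq_len(nch)) {
    for (b in seq_len(nch)) {
      if (b == a) next
      if (channels[[b]]$n_fragments != channels[[a]]$n_fragments) next
      pa <- channels[[a]]$products
      pb <- channels[[b]]$products
      extra <- pb
      removed <- character(0)
      for (nm in pa) {
        hit <- match(nm, extra)
        if (is.na(hit)) removed <- c(removed, nm) else extra <- extra[-hit]
      }
      if (length(removed) == 2 && length(extra) == 2) {
        ca <- .comp_add(comp_of(removed[1]), comp_of(removed[2]))
        cb <- .comp_add(comp_of(extra[1]), comp_of(extra[2]))
        qa <- sum(vapply(removed, function(nm) db$species[[nm]]$charge,
                         integer(1)))
        qb <- sum(vapply(extra, function(nm) db$species[[nm]]$charge,
                         integer(1)))
        if (identical_comp(ca, cb) && qa == qb) {
          transfer_nb[[a]] <- c(transfer_nb[[a]], b)
        }
      }
    }
  }
  list(split = split_nb, merge = merge_nb, transfer = transfer_nb,
       keys = keys)
}

.comp_add <- function(a, b) {
  els <- union(names(a), names(b))
  v <- setNames(numeric(length(els)), els)
  v[names(a)] <- v[names(a)] + a
  v[names(b)] <- v[names(b)] + b
  v
}

identical_comp <- function(a, b) {
  els <- union(names(a), names(b))
  va <- setNames(numeric(length(els)), els); va[names(a)] <- a
  vb <- setNames(numeric(length(els)), els); vb[names(b)] <- b
  all(va == vb)
}

#' Breakdown probabilities by Metropolis Monte Carlo
#'
#' Random walk over (channel, energy-sharing) configurations with three
#' move types: split one fragment into two database species, merge two
#' fragments into one, and reshuffle the translational/rotational/
#' vibrational energy sharing. The sampler is a Metropolis-within-Gibbs
#' hybrid: split/merge jumps are accepted on the ratio of the channel
#' densities of states at the total energy (the energy-sharing integrand
#' summed over the sharing coordinates), with Hastings corrections for the
#' neighbourhood sizes, so channel visit frequencies target the exact
#' microcanonical branching ratios; the sharing coordinates are updated by
#' a local random walk on the integrand within the current channel.
#' Results are reproducible for a given seed.
#'
#' @param db a [species_db()].
#' @param parent parent species name.
#' @param e_total internal energy, eV.
#' @param n_steps number of Monte Carlo steps (>= 1e4); the first 10% are
#'   discarded as burn-in.
#' @param seed integer seed (required; all stochastic operations in this
#'   package take explicit seeds).
#' @param grid an [energy_grid()]; a coarser grid than the exact-enumeration
#'   default is fine for sampling (default 5 meV bins).
#' @param volume container volume per extra fragment, Angstrom^3.
#' @param max_fragments maximum products per channel.
#' @param p_split,p_merge,p_transfer,p_shuffle move-type proposal
#'   probabilities (default 0.15/0.15/0.3/0.4; the transfer move, a split
#'   immediately recombined, moves a subunit between fragments and is what
#'   lets the walk hop between clustered and sequential channels without
#'   passing through improbable intermediates).
#' @return Object of class `metropolis_breakdown`: per-channel visit
#'   frequencies `probabilities` with batch-means standard errors,
#'   per-charged-fragment marginals, and the acceptance rate.
#' @export
breakdown_metropolis <- function(db, parent, e_total, n_steps = 1e5, seed,
                                 grid = energy_grid(bin_width = 5e-3),
                                 volume = default_volume(),
                                 max_fragments = 7L,
                                 p_split = 0.15, p_merge = 0.15,
                                 p_transfer = 0.3, p_shuffle = 0.4) {
  stopifnot(e_total >= 0, n_steps >= 1e4)
  if (missing(seed)) stop("an explicit integer seed is required")
  cp <- channel_pieces(db, parent, grid, volume, max_fragments,
                       e_max_prune = min(grid$e_max, e_total))
  nch <- length(cp$channels)
  de <- grid$bin_width
  adj <- channel_adjacency(db, cp$channels)

  parent_idx <- which(vapply(cp$channels, function(ch) {
    ch$n_fragments == 1 && ch$products == parent
  }, logical(1)))
  # reachability of every channel through the split/merge graph
  edges <- do.call(rbind, c(list(cbind(parent_idx, parent_idx)),
    lapply(seq_len(nch), function(a) {
      nb <- adj$split[[a]]
      if (length(nb) == 0) NULL else cbind(a, nb)
    })))
  g <- igraph::make_empty_graph(n = nch, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  comp_id <- igraph::components(g)$membership
  unreachable <- which(comp_id != comp_id[parent_idx])
  if (length(unreachable) > 0) {
    stop("non-ergodic move graph; unreachable channel(s): ",
         paste(adj$keys[unreachable], collapse = ", "))
  }

  # per-channel tables: channel density at the total energy (sharing
  # integrated out), log sharing densities, and the sharing-triangle size
  e_idx <- min(grid$n_bins, 1L + as.integer(round(e_total / de)))
  tabs <- lapply(cp$pieces, function(pc) {
    m <- as.integer(floor((e_total - pc$channel$threshold) / de))
    has_trans <- !is.null(pc$trans_f)
    list(
      lomega = log(pc$omega[e_idx]),
      lt = log(.power_law_array(pc$trans_f, grid)),
      lr = log(.power_law_array(pc$rot_f, grid)),
      lv = log(bs_pass(pc$freqs, grid) / de),
      m = m, has_trans = has_trans
    )
  })

  logw <- function(c, i, j) {
    tb <- tabs[[c]]
    k <- tb$m - i - j
    if (k < 0 || i < 0 || j < 0) return(-Inf)
    lw <- tb$lr[j + 1] + tb$lv[k + 1]
    if (tb$has_trans) lw <- lw + tb$lt[i + 1]
    lw
  }
  mid_share <- function(c) {
    tb <- tabs[[c]]
    i <- if (tb$has_trans) tb$m %/% 3L else 0L
    c(i, (tb$m - i) %/% 2L)
  }

  visits <- numeric(nch)
  burn <- floor(n_steps * 0.1)
  n_batches <- 50L
  keep <- n_steps - burn
  batch_len <- max(1L, floor(keep / n_batches))
  batch_counts <- matrix(0, n_batches, nch)
  accepted <- 0L
  step_w <- 8L   # local-walk half-width for the sharing coordinates

  with_seed(seed, {
    cur <- parent_idx
    ij <- mid_share(cur)
    lw_cur <- logw(cur, ij[1], ij[2])
    for (step in seq_len(n_steps)) {
      u <- stats::runif(1)
      if (u < p_shuffle) {
        # local symmetric random walk on the sharing coordinates
        prop <- ij + sample.int(2L * step_w + 1L, 2L) - step_w - 1L
        if (!tabs[[cur]]$has_trans) prop[1] <- 0L
        lw_new <- logw(cur, prop[1], prop[2])
        if (is.finite(lw_new) &&
            log(stats::runif(1)) < lw_new - lw_cur) {
          ij <- prop; lw_cur <- lw_new; accepted <- accepted + 1L
        }
      } else {
        kind <- if (u < p_shuffle + p_split) "split"
                else if (u < p_shuffle + p_split + p_merge) "merge"
                else "transfer"
        nb <- switch(kind, split = adj$split[[cur]],
                     merge = adj$merge[[cur]], adj$transfer[[cur]])
        if (length(nb) > 0) {
          cand <- nb[sample.int(length(nb), 1)]
          if (tabs[[cand]]$m >= 0) {
            rev_nb <- switch(kind, split = adj$merge[[cand]],
                             merge = adj$split[[cand]],
                             adj$transfer[[cand]])
            p_fwd <- switch(kind, split = p_split, merge = p_merge,
                            p_transfer)
            p_rev <- switch(kind, split = p_merge, merge = p_split,
                            p_transfer)
            # collapsed move: accept on the marginal channel density
            lhast <- tabs[[cand]]$lomega - tabs[[cur]]$lomega +
              log(p_rev) - log(p_fwd) +
              log(length(nb)) - log(length(rev_nb))
            if (log(stats::runif(1)) < lhast) {
              cur <- cand
              ij <- mid_share(cur)
              lw_cur <- logw(cur, ij[1], ij[2])
              accepted <- accepted + 1L
            }
          }
        }
      }
      if (step > burn) {
        visits[cur] <- visits[cur] + 1
        b <- min(n_batches, 1L + (step - burn - 1L) %/% batch_len)
        batch_counts[b, cur] <- batch_counts[b, cur] + 1
      }
    }
  })

  prob <- visits / sum(visits)
  bp <- batch_counts / rowSums(batch_counts)
  se <- apply(bp, 2, stats::sd) / sqrt(n_batches)
  names(prob) <- names(se) <- adj$keys
  frag_names <- vapply(cp$channels, `[[`, character(1), "charged_product")
  fprob <- tapply(prob, frag_names, sum)
  structure(list(parent = parent, e_total = e_total, n_steps = n_steps,
                 seed = seed, probabilities = prob, se = se,
                 fragment_probabilities = fprob,
                 acceptance_rate = accepted / n_steps,
                 channels = cp$channels, grid = grid, volume = volume),
            class = "metropolis_breakdown")
}

#' @export
print.metropolis_breakdown <- function(x, ...) {
  cat(sprintf(
    "<metropolis_breakdown> parent %s at E = %.2f eV (%g steps, seed %d)\n",
    x$parent, x$e_total, x$n_steps, x$seed))
  cat(sprintf("  acceptance rate %.2f\n", x$acceptance_rate))
  top <- sort(x$probabilities, decreasing = TRUE)
  top <- top[top > 0]
  for (nm in names(utils::head(top, 8))) {
    cat(sprintf("  %-40s %.4f +- %.4f\n", nm, x$probabilities[nm], x$se[nm]))
  }
  invisible(x)
}
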