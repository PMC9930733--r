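# Inverse analyses: appearance energies from ion-yield curves, and
# recovery of the internal-energy deposition distribution from observed
# fragmentation patterns.

#' Appearance energy from an ion-yield curve
#'
#' Fits a horizontal baseline and a straight line through the rising part
#' of a fragment's yield curve; the appearance energy is the intersection
#' of the two, with its uncertainty propagated from the fit covariance and
#' the baseline variance by the delta method.
#'
#' @param energies collision energies, eV.
#' @param intensities fragment intensities at `energies`.
#' @param baseline_window `c(lo, hi)` energy range of the flat baseline
#'   (>= 4 points).
#' @param rise_window `c(lo, hi)` energy range of the linear rise
#'   (>= 4 points).
#' @return Object of class `threshold_fit` with fields
#'   `appearance_energy`, `uncertainty`, `slope`, `intercept`, `baseline`
#'   and the fit windows.
#' @export
extract_appearance_energy <- function(energies, intensities,
                                      baseline_window, rise_window) {
  stopifnot(length(energies) == length(intensities))
  in_b <- energies >= baseline_window[1] & energies <= baseline_window[2]
  in_r <- energies >= rise_window[1] & energies <= rise_window[2]
  if (sum(in_b) < 4) stop("baseline window holds fewer than 4 points")
  if (sum(in_r) < 4) stop("rise window holds fewer than 4 points")
  base <- mean(intensities[in_b])
  var_base <- stats::var(intensities[in_b]) / sum(in_b)
  fit <- stats::lm(y ~ x, data = data.frame(x = energies[in_r],
                                            y = intensities[in_r]))
  a <- stats::coef(fit)[1]; m <- stats::coef(fit)[2]
  # noise-free inputs give an exactly singular residual; the perfect-fit
  # warning from summary.lm is expected there
  V <- suppressWarnings(stats::vcov(fit))
  if (!is.finite(m) || m <= 1e-8 * max(abs(intensities))) {
    stop("no onset detected (non-positive rise slope)")
  }
  ae <- (base - a) / m
  # delta method: AE = (b - a)/m
  g <- c(-1 / m, -(base - a) / m^2)      # d/d(a), d/d(m)
  var_ae <- as.numeric(t(g) %*% V %*% g) + var_base / m^2
  structure(list(appearance_energy = as.numeric(ae),
                 uncertainty = sqrt(max(var_ae, 0)),
                 slope = as.numeric(m), intercept = as.numeric(a),
                 baseline = base, baseline_window = baseline_window,
                 rise_window = rise_window),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf(
    "<threshold_fit> appearance energy %.3f +- %.3f eV (slope %.3g, baseline %.3g)\n",
    x$appearance_energy, x$uncertainty, x$slope, x$baseline))
  invisible(x)
}

# fast pattern-evaluation context: precomputed non-parent marginals plus
# O(1) interpolation, shared by all fitting internals (the public
# predict_pattern() is the reference implementation)
.pattern_ctx <- function(curve) {
  fp <- curve$fragment_probabilities
  keep <- setdiff(colnames(fp), curve$parent)
  list(e = curve$grid$energies, de = curve$grid$bin_width,
       fpk = fp[, keep, drop = FALSE], frag = keep)
}

# breakdown marginals at one energy (linear interpolation)
.ctx_ne <- function(ctx, ene) {
  i <- min(max(findInterval(ene, ctx$e), 1L), nrow(ctx$fpk) - 1L)
  t <- (ene - ctx$e[i]) / ctx$de
  (1 - t) * ctx$fpk[i, ] + t * ctx$fpk[i + 1, ]
}

# renormalized non-parent pattern of the two-component deposition model
.ctx_pattern <- function(ctx, w_ne, mu, sigma, ne_pat) {
  # the Gaussian weight is negligible outside mu +/- 6 sigma: evaluate on
  # that window only
  n <- length(ctx$e)
  i1 <- max(1L, 1L + as.integer(floor((mu - 6 * sigma) / ctx$de)))
  i2 <- min(n, 2L + as.integer(ceiling((mu + 6 * sigma) / ctx$de)))
  wts <- stats::dnorm(ctx$e[i1:i2], mu, sigma)
  tot <- sum(wts)
  erg <- if (tot > 0) {
    as.numeric(crossprod(ctx$fpk[i1:i2, , drop = FALSE], wts)) / tot
  } else numeric(length(ctx$frag))
  pat <- w_ne * ne_pat + (1 - w_ne) * erg
  s <- sum(pat)
  if (s > 0) pat / s else pat
}

# weighted residual sum of squares between an observed pattern and the
# model prediction for parameter vector th = (w_ne, mu, sigma[, e_ne]);
# `idx` maps the observation's fragments into the context's columns
.dep_objective <- function(th, observed, ctx, weights, e_ne_fixed,
                           idx = seq_along(ctx$frag)) {
  e_ne <- if (length(th) == 4) th[4] else e_ne_fixed
  pred <- .ctx_pattern(ctx, th[1], th[2], th[3], .ctx_ne(ctx, e_ne))
  r <- observed - pred[idx]
  sum(weights * r^2)
}

#' Fit the internal-energy deposition distribution to a pattern
#'
#' Weighted least squares recovering the two-component deposition model
#' (discrete non-ergodic point plus ergodic Gaussian) from an observed
#' fragmentation pattern at one collision energy, using the microcanonical
#' breakdown curve as the forward map. A bounded quasi-Newton optimizer is
#' run from a multi-start grid (the discrete component creates local
#' minima); the best converged solution is returned with an approximate
#' covariance from the Gauss-Newton normal equations. Weights are the
#' inverse Poisson variances when raw counts are supplied, else uniform.
#'
#' A model-comparison record (Gaussian-only versus Gaussian + discrete
#' point, by corrected AIC) is attached so that the need for the discrete
#' non-ergodic component is a reproducible statement rather than an
#' assumption.
#'
#' @param observed named relative intensities of the non-parent charged
#'   fragments (at least 3 nonzero entries); renormalized internally.
#' @param curve a [breakdown_exact()] result.
#' @param counts optional named raw counts behind `observed` (Poisson
#'   weights).
#' @param fit_ene also fit the discrete-point energy E_ne (default: keep it
#'   fixed at `e_ne`).
#' @param e_ne fixed (or starting) discrete-point energy, eV.
#' @param e_cm optional centre-of-mass collision energy, eV; used to place
#'   the multi-start grid for `mu` at `{0.25, 0.5, 0.75} * e_cm`.
#' @return Object of class `deposition_fit`: `coefficients`, `vcov`,
#'   `model` (a [deposition_model()]), `fitted`, `residuals`, `rss`,
#'   `aicc` (named: gaussian, two_component), `convergence`.
#' @export
fit_deposition <- function(observed, curve, counts = NULL, fit_ene = FALSE,
                           e_ne = 1.25, e_cm = NULL) {
  observed <- observed[setdiff(names(observed), curve$parent)]
  if (sum(observed > 0) < 3) {
    stop("need at least 3 non-parent fragments with nonzero intensity")
  }
  observed <- observed / sum(observed)
  fp <- curve$fragment_probabilities
  open <- setdiff(colnames(fp)[apply(fp, 2, max) > 1e-9], curve$parent)
  if (length(open) <= 1) {
    warning("only ", length(open), " fragmentation channel open on this ",
            "breakdown curve: deposition parameters are not identifiable")
  }
  weights <- if (is.null(counts)) {
    rep(1, length(observed))
  } else {
    n_tot <- sum(counts[names(observed)])
    n_tot / pmax(observed, 0.5 / n_tot)
  }

  mu_starts <- if (is.null(e_cm)) c(1, 2, 3) else c(0.25, 0.5, 0.75) * e_cm
  starts <- expand.grid(w_ne = c(0.1, 0.5), mu = mu_starts,
                        sigma = c(0.1, 0.3))
  lower <- c(0, 0.05, 0.02); upper <- c(1, curve$grid$e_max - 6, 1.5)
  if (fit_ene) {
    thr_min <- min(curve$thresholds[curve$thresholds > 0])
    lower <- c(lower, max(0.5 * thr_min, 0.1))
    upper <- c(upper, min(3, curve$grid$e_max))
  }
  ctx <- .pattern_ctx(curve)
  idx <- match(names(observed), ctx$frag)
  if (anyNA(idx)) stop("observed fragments not on the breakdown curve: ",
                       paste(names(observed)[is.na(idx)], collapse = ", "))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- as.numeric(starts[i, c("w_ne", "mu", "sigma")])
    if (fit_ene) th0 <- c(th0, e_ne)
    th0 <- pmin(pmax(th0, lower), upper)
    fit <- tryCatch(
      stats::optim(th0, .dep_objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   observed = observed, ctx = ctx, weights = weights,
                   e_ne_fixed = e_ne, idx = idx,
                   control = list(maxit = 500, factr = 1e5)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("deposition fit failed to converge from any start")
  .dep_fit_result(best, observed, ctx, weights, counts, fit_ene, e_ne)
}

# assemble the S3 result object (shared with the series fitter)
.dep_fit_result <- function(best, observed, ctx, weights, counts,
                            fit_ene, e_ne_fixed, aicc_compare = TRUE) {
  th <- best$par
  e_ne <- if (fit_ene) th[4] else e_ne_fixed
  model <- deposition_model(th[1], e_ne, th[2], th[3])
  idx <- match(names(observed), ctx$frag)
  pred_at <- function(tt) {
    en <- if (fit_ene) tt[4] else e_ne_fixed
    .ctx_pattern(ctx, tt[1], tt[2], tt[3], .ctx_ne(ctx, en))[idx]
  }
  pred <- setNames(pred_at(th), names(observed))
  resid <- observed - pred
  npar <- length(th)
  # Gauss-Newton covariance from a finite-difference Jacobian
  jac <- matrix(0, length(observed), npar)
  h <- pmax(abs(th) * 1e-4, 1e-6)
  for (k in seq_len(npar)) {
    tp <- th; tp[k] <- tp[k] + h[k]
    tp[1] <- min(tp[1], 1)
    jac[, k] <- (pred_at(tp) - pred) / h[k]
  }
  jtj <- crossprod(jac * sqrt(weights))
  vcov <- tryCatch(solve(jtj), error = function(e) {
    matrix(NA_real_, npar, npar)
  })
  if (is.null(counts)) {
    dfree <- max(length(observed) - npar, 1)
    vcov <- vcov * best$value / dfree
  }
  nm <- c("w_ne", "mu", "sigma", if (fit_ene) "e_ne")
  dimnames(vcov) <- list(nm, nm)
  coefs <- setNames(if (fit_ene) th else c(th, e_ne_fixed),
                    c("w_ne", "mu", "sigma", if (fit_ene) "e_ne"))

  aicc <- function(rss, k, n) {
    n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) /
      max(n - k - 1, 0.5)
  }
  n_obs <- length(observed)
  aic <- c(gaussian = NA_real_, two_component = aicc(best$value, npar, n_obs))
  if (aicc_compare) {
    g_only <- stats::optim(c(th[2], th[3]), function(p) {
      .dep_objective(c(0, p), observed, ctx, weights, e_ne_fixed, idx)
    }, method = "L-BFGS-B", lower = c(0.05, 0.02),
       upper = c(max(ctx$e) - 6, 1.5),
       control = list(maxit = 200, factr = 1e9))
    aic["gaussian"] <- aicc(g_only$value, 2, n_obs)
  }

  structure(list(coefficients = coefs, vcov = vcov, model = model,
                 fitted = pred, residuals = resid, observed = observed,
                 rss = best$value, weights = weights, aicc = aic,
                 convergence = best$convergence, fit_ene = fit_ene),
            class = "deposition_fit")
}

#' @export
print.deposition_fit <- function(x, ...) {
  cat("<deposition_fit>\n")
  print(x$model)
  cat(sprintf("  weighted RSS %.3g over %d fragments\n", x$rss,
              length(x$observed)))
  invisible(x)
}

#' @export
coef.deposition_fit <- function(object, ...) object$coefficients

#' @export
vcov.deposition_fit <- function(object, ...) object$vcov

#' @export
residuals.deposition_fit <- function(object, ...) object$residuals

#' @export
predict.deposition_fit <- function(object, ...) object$fitted

#' @export
summary.deposition_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  co <- object$coefficients[seq_along(se)]
  tab <- cbind(estimate = co, std_error = se)
  cat("Deposition-distribution fit\n\n")
  print(round(tab, 4))
  cat(sprintf("\nweighted RSS: %.4g   convergence code: %d\n",
              object$rss, object$convergence))
  d <- object$aicc["gaussian"] - object$aicc["two_component"]
  cat(sprintf(
    "model comparison (AICc): Gaussian-only %.2f, +discrete point %.2f (delta %.2f%s)\n",
    object$aicc["gaussian"], object$aicc["two_component"], d,
    if (d > 0) ", discrete component favoured" else ""))
  invisible(object)
}

#' Fit deposition distributions across collision energies
#'
#' Fits one deposition model per collision energy while sharing the
#' discrete-point energy E_ne and (by default) the Gaussian width sigma
#' across all of them: the discrete point sits at the same internal energy
#' in every panel, and the collision-energy spread is a property of the
#' beam, not of one panel. Sharing also keeps each per-energy fit
#' overdetermined (two free parameters, w_ne and mu, against a whole
#' fragment pattern), which the fully per-energy parameterization is not.
#' The shared parameters are found by a bounded search over the summed
#' weighted residuals; per-energy parameters are refit at each candidate
#' with warm starts.
#'
#' @param patterns list (one per collision energy) of named intensity
#'   vectors, or a matrix with fragments in columns.
#' @param curve a [breakdown_exact()] result.
#' @param energies centre-of-mass collision energies, eV.
#' @param counts optional list/matrix of raw counts (Poisson weights).
#' @param share_ene fit one E_ne shared across energies (default) or keep
#'   `e_ne` fixed.
#' @param share_sigma fit one Gaussian width shared across energies
#'   (default) instead of one width per energy.
#' @param e_ne fixed value / search start for the discrete energy.
#' @param sigma search start for the shared width, eV.
#' @param ene_bounds search interval for the shared E_ne.
#' @return Object of class `deposition_series`: per-energy fits, the shared
#'   `e_ne` (and `sigma`), and the collision energies.
#' @export
fit_deposition_series <- function(patterns, curve, energies, counts = NULL,
                                  share_ene = TRUE, share_sigma = TRUE,
                                  e_ne = 1.25, sigma = 0.3,
                                  ene_bounds = NULL) {
  if (is.matrix(patterns)) {
    patterns <- lapply(seq_len(nrow(patterns)), function(i) patterns[i, ])
  }
  if (is.matrix(counts)) {
    counts <- lapply(seq_len(nrow(counts)), function(i) counts[i, ])
  }
  stopifnot(length(patterns) == length(energies))
  if (is.null(ene_bounds)) {
    thr_min <- min(curve$thresholds[curve$thresholds > 0])
    ene_bounds <- c(max(0.5 * thr_min, 0.1), min(3, curve$grid$e_max))
  }
  obs_list <- lapply(patterns, function(obs) {
    obs <- obs[setdiff(names(obs), curve$parent)]
    obs / sum(obs)
  })
  wts_list <- lapply(seq_along(obs_list), function(i) {
    obs <- obs_list[[i]]
    if (is.null(counts)) rep(1, length(obs)) else {
      n_tot <- sum(counts[[i]][names(obs)])
      n_tot / pmax(obs, 0.5 / n_tot)
    }
  })
  ctx <- .pattern_ctx(curve)
  idx_list <- lapply(obs_list, function(obs) match(names(obs), ctx$frag))
  warm <- new.env(parent = emptyenv())
  mu_upper <- curve$grid$e_max - 6

  # per-energy refit at candidate shared parameters; free = (w_ne, mu) when
  # sigma is shared, else (w_ne, mu, sigma)
  fit_all <- function(ene, sig, final = FALSE) {
    fits <- vector("list", length(energies))
    total <- 0
    for (i in seq_along(energies)) {
      obs <- obs_list[[i]]; wts <- wts_list[[i]]; idx <- idx_list[[i]]
      ne_pat <- .ctx_ne(ctx, ene)
      objective <- if (share_sigma) {
        function(p) {
          pred <- .ctx_pattern(ctx, p[1], p[2], sig, ne_pat)
          sum(wts * (obs - pred[idx])^2)
        }
      } else {
        function(p) {
          pred <- .ctx_pattern(ctx, p[1], p[2], p[3], ne_pat)
          sum(wts * (obs - pred[idx])^2)
        }
      }
      key <- paste0("e", i)
      th0s <- if (!is.null(warm[[key]])) list(warm[[key]]) else {
        st <- expand.grid(w_ne = c(0.1, 0.5),
                          mu = c(0.25, 0.5, 0.75) * energies[i],
                          sigma = if (share_sigma) NA else c(0.1, 0.3))
        lapply(seq_len(nrow(st)), function(r) {
          v <- as.numeric(st[r, ])
          if (share_sigma) v[1:2] else v
        })
      }
      # mu may not exceed the collision energy: the ergodic component is
      # deposited collision energy
      mu_cap <- min(mu_upper, energies[i])
      lower <- if (share_sigma) c(0, 0.05) else c(0, 0.05, 0.02)
      upper <- if (share_sigma) c(1, mu_cap) else c(1, mu_cap, 1.5)
      best <- NULL
      for (th0 in th0s) {
        th0 <- pmin(pmax(th0, lower), upper)
        f <- tryCatch(
          stats::optim(th0, objective, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(maxit = 300, factr = 1e9)),
          error = function(e) NULL)
        if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
      }
      if (is.null(best)) stop("series fit failed at energy ", energies[i])
      warm[[key]] <- best$par
      total <- total + best$value
      if (final) {
        if (share_sigma) best$par <- c(best$par, sig)
        fits[[i]] <- .dep_fit_result(best, obs, ctx, wts,
                                     if (is.null(counts)) NULL else counts[[i]],
                                     fit_ene = FALSE, e_ne_fixed = ene,
                                     aicc_compare = FALSE)
      }
    }
    list(total = total, fits = fits)
  }

  ene_hat <- e_ne; sigma_hat <- sigma
  if (share_ene && share_sigma) {
    # Nelder-Mead on the clamped 2-d profile objective (robust to the
    # warm-start path dependence of the inner refits)
    clamp <- function(p) c(min(max(p[1], ene_bounds[1]), ene_bounds[2]),
                           min(max(p[2], 0.05), 1.0))
    opt <- stats::optim(c(e_ne, sigma), function(p) {
      p <- clamp(p)
      fit_all(p[1], p[2])$total
    }, method = "Nelder-Mead",
       control = list(maxit = 60, reltol = 1e-3))
    p <- clamp(opt$par)
    ene_hat <- p[1]; sigma_hat <- p[2]
  } else if (share_ene) {
    opt <- stats::optimize(function(x) fit_all(x, sigma)$total,
                           interval = ene_bounds, tol = 5e-3)
    ene_hat <- opt$minimum
  } else if (share_sigma) {
    opt <- stats::optimize(function(x) fit_all(ene_hat, x)$total,
                           interval = c(0.05, 1.0), tol = 5e-3)
    sigma_hat <- opt$minimum
  }
  final <- fit_all(ene_hat, sigma_hat, final = TRUE)
  structure(list(fits = final$fits, e_ne = ene_hat, sigma = sigma_hat,
                 energies = energies, rss = final$total,
                 share_ene = share_ene, share_sigma = share_sigma),
            class = "deposition_series")
}

#' @export
print.deposition_series <- function(x, ...) {
  cat(sprintf(
    "<deposition_series> %d collision energies, shared E_ne = %.3f eV%s, total RSS %.3g\n",
    length(x$energies), x$e_ne,
    if (isTRUE(x$share_sigma)) sprintf(", shared sigma = %.3f eV", x$sigma)
    else "", x$rss))
  for (i in seq_along(x$energies)) {
    m <- x$fits[[i]]$model
    cat(sprintf("  E_cm %.2f eV: w_ne %.3f, mu %.3f, sigma %.3f\n",
                x$energies[i], m$w_ne, m$mu, m$sigma))
  }
  invisible(x)
}

#' Ergodic-fraction summary across collision energies
#'
#' Summarizes fitted deposition models against the centre-of-mass collision
#' energy: the ordinary least-squares slope of the ergodic Gaussian mean mu
#' versus E_cm, the mean ergodic fraction mu/E_cm, and the trajectory of
#' the non-ergodic weight.
#'
#' @param fits a `deposition_series`, a list of `deposition_fit` /
#'   `deposition_model` objects, or a numeric vector of fitted means.
#' @param energies centre-of-mass collision energies, eV (taken from a
#'   `deposition_series` automatically); at least 3, not all equal.
#' @return Object of class `ergodic_summary` with `slope`, `intercept`,
#'   `mean_fraction`, `mu`, `w_ne`, `energies` and the slope's standard
#'   error.
#' @export
ergodic_summary <- function(fits, energies = NULL) {
  w_ne <- NULL
  if (inherits(fits, "deposition_series")) {
    energies <- fits$energies
    mu <- vapply(fits$fits, function(f) f$model$mu, numeric(1))
    w_ne <- vapply(fits$fits, function(f) f$model$w_ne, numeric(1))
  } else if (is.list(fits)) {
    mu <- vapply(fits, function(f) {
      if (inherits(f, "deposition_fit")) f$model$mu else f$mu
    }, numeric(1))
    w_ne <- vapply(fits, function(f) {
      if (inherits(f, "deposition_fit")) f$model$w_ne else f$w_ne
    }, numeric(1))
  } else {
    mu <- as.numeric(fits)
  }
  if (length(energies) < 3) stop("need at least 3 collision energies")
  if (stats::sd(energies) == 0) stop("degenerate (constant) energies")
  fit <- stats::lm(mu ~ energies)
  slope_se <- sqrt(suppressWarnings(stats::vcov(fit))[2, 2])
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = slope_se,
                 mean_fraction = mean(mu / energies),
                 mu = mu, w_ne = w_ne, energies = energies),
            class = "ergodic_summary")
}

#' @export
print.ergodic_summary <- function(x, ...) {
  cat(sprintf(
    "<ergodic_summary> slope d(mu)/d(E_cm) = %.3f +- %.3f; mean mu/E_cm = %.3f\n",
    x$slope, x$slope_se, x$mean_fraction))
  if (!is.null(x$w_ne)) {
    cat("  non-ergodic weights:",
        paste(sprintf("%.2f", x$w_ne), collapse = " "), "\n")
  }
  invisible(x)
}
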