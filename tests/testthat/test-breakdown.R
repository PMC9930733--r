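test_that("channel probabilities are normalized and open monotonically", {
  bc <- hex_curve()
  expect_lt(max(abs(rowSums(bc$probabilities) - 1)), 1e-9)
  # parent survival below the lowest threshold, non-increasing above
  surv <- bc$fragment_probabilities[, "Cys(H2O)6+"]
  thr_min <- min(bc$thresholds[bc$thresholds > 0])
  expect_true(all(surv[bc$grid$energies < thr_min] == 1))
  expect_true(all(diff(surv) <= 1e-9))
})

test_that("the fixture reproduces the low-energy fragmentation pattern", {
  bc <- hex_curve()
  # no fragmentation at 0.5 eV of internal energy
  p05 <- fragment_probs_at(bc, 0.5)
  expect_equal(unname(p05[1, "Cys(H2O)6+"]), 1)
  # at 1.5 eV the pattern is dominated by the loss of two waters, with
  # minor one- and three-water contributions
  p15 <- fragment_probs_at(bc, 1.5)[1, ]
  frag <- p15[names(p15) != "Cys(H2O)6+"]
  expect_equal(names(which.max(frag)), "Cys(H2O)4+")
  expect_gt(frag[["Cys(H2O)5+"]], 0.01)
  expect_gt(frag[["Cys(H2O)3+"]], 0.01)
  # the single-water channel dominates where the discrete deposition
  # component sits
  p125 <- fragment_probs_at(bc, 1.25)[1, ]
  frag125 <- p125[names(p125) != "Cys(H2O)6+"]
  expect_equal(names(which.max(frag125)), "Cys(H2O)5+")
})

test_that("branching ratios match a two-channel quadrature oracle", {
  # toy with two competing two-fragment channels: P -> A + B2 / AB + B
  a <- species("A", c(C = 1, O = 1), 1L, 0.2, 2100, 1.9, 1)
  b2 <- species("B2", c(N = 4), 0L, 0.15,
                c(700, 900, 1300, 1800, 2100, 2300), c(1.0, 0.8, 0.6), 1)
  ab <- species("AB", c(C = 1, O = 1, N = 2), 1L, 0.05,
                c(700, 1100, 1600, 1900, 2200, 2500), c(0.5, 0.4, 0.3), 1)
  b <- species("B", c(N = 2), 0L, 0.1, 2350, 2.0, 2)
  p <- species("P", c(C = 1, O = 1, N = 4), 1L, 0,
               c(300, 500, 650, 800, 950, 1100, 1400, 1700, 2000,
                 2300, 2600, 2900), c(0.2, 0.15, 0.1), 1)
  db <- species_db(list(a, b2, ab, b, p), reference = "P")
  g <- energy_grid(e_max = 2, bin_width = 1e-3)
  bc <- breakdown_exact(db, "P", grid = g, volume = default_volume(10),
                        max_fragments = 2)
  keys <- vapply(bc$channels, function(c) paste(c$products, collapse = "+"),
                 character(1))
  i <- which.min(abs(g$energies - 1.5))
  ratio <- bc$probabilities[i, which(keys == "A+B2")] /
    bc$probabilities[i, which(keys == "AB+B")]
  om1 <- channel_dos(db, bc$channels[[which(keys == "A+B2")]], g,
                     volume = default_volume(10))
  om2 <- channel_dos(db, bc$channels[[which(keys == "AB+B")]], g,
                     volume = default_volume(10))
  expect_equal(ratio, om1$values[i] / om2$values[i], tolerance = 1e-9)
})

test_that("energy components are conserved and behave like the model", {
  db <- hex_db()
  ep <- energy_partition(db, "Cys(H2O)6+", grid = energy_grid(6, 5e-3),
                         volume = default_volume(10))
  e <- ep$grid$energies
  comp <- ep$components
  expect_true(all(comp >= -1e-12))
  # components close the energy balance within one bin everywhere
  expect_lt(max(abs(rowSums(comp) - e)), ep$grid$bin_width + 1e-9)
  # below the lowest threshold: no intermolecular or translational energy,
  # vibration plus rotation carry everything
  thr_min <- 0.80
  below <- e < thr_min
  expect_true(all(comp[below, "intermolecular"] == 0))
  expect_true(all(comp[below, "translational"] == 0))
  expect_lt(max(abs(comp[below, "vibrational"] + comp[below, "rotational"] -
                    e[below])), ep$grid$bin_width)
  # intermolecular energy switches on at the first channel opening
  expect_gt(comp[which.min(abs(e - 0.95)), "intermolecular"], 0)
  # translational share stays low while vibration grows over 1-5 eV
  sel <- e >= 1 & e <= 5
  expect_lt(max(comp[sel, "translational"] / e[sel]), 0.15)
  expect_true(all(diff(comp[sel, "vibrational"]) > -1e-9))
})

test_that("the mean translational energy matches the beta-function integral", {
  # single open channel of two rigid diatomics: with the vibrational combs
  # frozen below their first quantum, <e_t> = Int t^(3/2) (E-t) dt /
  # Int t^(1/2) (E-t) dt = (3/7) E
  a <- species("A", c(C = 1, O = 1), 1L, 0.02, 3000, 1.9, 1)
  b <- species("B", c(N = 2), 0L, 0, 3000, 2.0, 2)
  p <- species("P", c(C = 1, O = 1, N = 2), 1L, 0,
               c(2600, 2800, 3000, 3200, 3400, 3600), c(0.5, 0.4, 0.3), 1)
  db <- species_db(list(a, b, p), reference = "P")
  g <- energy_grid(e_max = 0.35, bin_width = 5e-4)
  ep <- energy_partition(db, "P", grid = g, volume = default_volume(10))
  e_tot <- 0.3
  i <- which.min(abs(g$energies - e_tot))
  excess <- e_tot - 0.02
  # the parent channel still carries weight; condition on the open channel
  bc <- breakdown_exact(db, "P", grid = g, volume = default_volume(10))
  keys <- vapply(bc$channels, function(c) paste(c$products, collapse = "+"),
                 character(1))
  p_frag <- bc$probabilities[i, which(keys == "A+B")]
  et_cond <- unname(ep$components[i, "translational"]) / p_frag
  expect_equal(et_cond, 3 / 7 * excess, tolerance = 0.02)
})

test_that("Metropolis sampling reproduces exact branching ratios", {
  db <- tri_db()
  vol <- default_volume(10)
  g <- energy_grid(bin_width = 5e-3)
  bc <- breakdown_exact(db, "Cys(H2O)3+", grid = g, volume = vol,
                        e_max_prune = 1.6)
  i <- which.min(abs(g$energies - 1.6))
  exact <- bc$probabilities[i, ]
  names(exact) <- vapply(bc$channels, function(ch) {
    paste(ch$products, collapse = "+")
  }, character(1))
  mb <- breakdown_metropolis(db, "Cys(H2O)3+", e_total = 1.6,
                             n_steps = 1e5, seed = 42, volume = vol)
  # estimates within 3 standard errors (batch means) of the exact values
  for (nm in names(mb$probabilities)) {
    if (exact[nm] < 0.01) next
    expect_lt(abs(mb$probabilities[nm] - exact[nm]),
              3 * mb$se[nm] + 0.01)
  }
  tv <- 0.5 * sum(abs(mb$probabilities - exact[names(mb$probabilities)]))
  expect_lt(tv, 0.05)
})

test_that("Metropolis runs are seed-reproducible and respect thresholds", {
  db <- tri_db()
  m1 <- breakdown_metropolis(db, "Cys(H2O)3+", e_total = 1.4,
                             n_steps = 1e4, seed = 7)
  m2 <- breakdown_metropolis(db, "Cys(H2O)3+", e_total = 1.4,
                             n_steps = 1e4, seed = 7)
  expect_identical(m1$probabilities, m2$probabilities)
  # below the lowest threshold only the parent is ever visited
  m0 <- breakdown_metropolis(db, "Cys(H2O)3+", e_total = 0.5,
                             n_steps = 1e4, seed = 7)
  expect_equal(unname(m0$probabilities[["Cys(H2O)3+"]]), 1)
})
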