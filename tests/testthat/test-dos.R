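test_that("Beyer-Swinehart count matches closed forms and enumeration", {
  g <- energy_grid(e_max = 0.5, bin_width = 1e-3)
  # one oscillator of 0.1 eV: levels 0, 0.1, ..., 0.4 below 0.45
  one <- vib_states(0.1 / 1.239841984e-4, g)
  s <- sum_of_states(one)
  i <- which.min(abs(g$energies - 0.45))
  expect_equal(s$values[i], 5)
  # no oscillators: a single state everywhere
  none <- sum_of_states(vib_states(numeric(0), g))
  expect_true(all(none$values == 1))
  # exhaustive-enumeration oracle, three and four oscillators
  g2 <- energy_grid(e_max = 1, bin_width = 1e-3)
  for (freqs_ev in list(c(0.05, 0.07, 0.11), c(0.03, 0.05, 0.08, 0.12))) {
    freqs_cm <- freqs_ev / 1.239841984e-4
    s2 <- sum_of_states(vib_states(freqs_cm, g2))
    for (e in c(0.3, 0.61, 1.0)) {
      i <- which.min(abs(g2$energies - e))
      expect_equal(s2$values[i],
                   vib_enum_oracle(freqs_cm, e + 1e-9, g2$bin_width))
    }
  }
  expect_warning(vib_states(2, g), "grid too coarse")
})

test_that("classical rotor densities match their closed forms", {
  g <- energy_grid(e_max = 1, bin_width = 1e-3)
  cm <- 1.239841984e-4
  # linear rotor, B = 1e-3 eV, sigma 1: rho = 1000 per eV everywhere
  lin <- rot_dos(1e-3 / cm, 1, g)
  expect_true(all(abs(lin$values - 1000) < 1e-6))
  # nonlinear rotor, A = B = C = 1e-3 eV: rho(1e-3) = 2000 per eV
  nl <- rot_dos(rep(1e-3 / cm, 3), 1, g)
  i <- which.min(abs(g$energies - 1e-3))
  expect_equal(nl$values[i], 2 * sqrt(1e-3 / 1e-9), tolerance = 1e-9)
  # integrated density matches the closed-form sum of states within 1%
  for (sigma in c(1, 2)) {
    r <- rot_dos(rep(1e-3 / cm, 3), sigma, g)
    ssum <- sum_of_states(r)
    i1 <- which.min(abs(g$energies - 1))
    analytic <- (4 / (3 * sigma)) * 1^1.5 / sqrt(1e-9)
    expect_equal(ssum$values[i1], analytic, tolerance = 0.01)
  }
  expect_error(rot_dos(c(-1, 2, 3), 1, g), "positive")
  # an atom is the delta identity
  at <- rot_dos(numeric(0), 1, g)
  expect_equal(at$values[1], 1 / g$bin_width)
  expect_true(all(at$values[-1] == 0))
})

test_that("translational density carries the 3(n-1)/2 - 1 power law", {
  g <- energy_grid(e_max = 2, bin_width = 1e-3)
  v <- default_volume(10)
  # one fragment: the convolution identity
  one <- trans_dos(18, v, g)
  expect_equal(one$values[1], 1 / g$bin_width)
  # two fragments: exponent 1/2 by log-log regression
  two <- trans_dos(c(18, 211), v, g)
  sel <- g$energies >= 0.1
  slope2 <- coef(lm(log(two$values[sel]) ~ log(g$energies[sel])))[[2]]
  expect_equal(slope2, 0.5, tolerance = 1e-6)
  # three equal masses: exponent 2
  three <- trans_dos(c(50, 50, 50), v, g)
  slope3 <- coef(lm(log(three$values[sel]) ~ log(g$energies[sel])))[[2]]
  expect_equal(slope3, 2, tolerance = 1e-6)
  expect_error(trans_dos(c(-1, 5), v, g))
})

test_that("state-function convolution has identity, ramp and associativity", {
  g <- energy_grid(e_max = 1, bin_width = 1e-3)
  delta <- cidfrag:::delta_dos(g)
  f <- rot_dos(rep(8, 3), 1, g)
  expect_equal(dos_convolve(delta, f)$values, f$values)
  # constant (*) constant: a linear ramp c^2 * E within one bin
  const <- rot_dos(1e-3 / 1.239841984e-4, 1, g)   # rho = 1000
  ramp <- dos_convolve(const, const)
  i <- which.min(abs(g$energies - 0.5))
  expect_equal(ramp$values[i], 1000^2 * 0.5, tolerance = 1000^2 * g$bin_width)
  # associativity to numerical tolerance
  a <- vib_states(c(400, 900), g)
  b <- rot_dos(c(5, 3, 2), 1, g)
  ab_c <- dos_convolve(dos_convolve(a, b), const)
  a_bc <- dos_convolve(a, dos_convolve(b, const))
  sel <- ab_c$values > 0
  expect_lt(max(abs(ab_c$values[sel] - a_bc$values[sel]) / ab_c$values[sel]),
            1e-9)
  g2 <- energy_grid(e_max = 0.5, bin_width = 1e-3)
  expect_error(dos_convolve(a, rot_dos(c(5, 3, 2), 1, g2)), "grid mismatch")
})

test_that("channel DOS vanishes below threshold and reduces correctly", {
  db <- hex_db()
  g <- energy_grid(e_max = 3, bin_width = 2e-3)
  ch <- enumerate_channels(db, "Cys(H2O)6+")
  keys <- vapply(ch, function(c) paste(c$products, collapse = "+"),
                 character(1))
  dimer_ch <- ch[[which(keys == "(H2O)2+Cys(H2O)4+")]]
  om <- channel_dos(db, dimer_ch, g, volume = default_volume(10))
  below <- g$energies < dimer_ch$threshold
  expect_true(all(om$values[below] == 0))
  expect_true(any(om$values[!below] > 0))
  # single-product channel equals the species' rovibrational density (a
  # small toy keeps the FFT reference inside its accurate dynamic range)
  toy <- species("T", c(H = 2, O = 1), 1L, 0, c(800, 1500, 3600),
                 c(10, 8, 6), 1)
  tdb <- species_db(list(toy), reference = "T")
  tch <- enumerate_channels(tdb, "T")
  om_p <- channel_dos(tdb, tch[[1]], g, volume = default_volume(10))
  ref <- dos_convolve(vib_states(toy$frequencies, g),
                      rot_dos(toy$rot_constants, toy$symmetry_number, g))
  sel <- g$energies >= 0.2
  expect_lt(max(abs(om_p$values[sel] - ref$values[sel]) / ref$values[sel]),
            1e-6)
})

test_that("two-fragment channel DOS matches a direct quadrature oracle", {
  # toy: two rigid diatomics with one stiff oscillator each
  a <- species("A", c(C = 1, O = 1), 1L, 0, 2100, 1.9, 1)
  b <- species("B", c(N = 2), 0L, 0.4, 2300, 2.0, 2)
  p <- species("P", c(C = 1, O = 1, N = 2), 1L, 0,
               c(500, 700, 800, 1200, 1600, 2000), c(0.5, 0.4, 0.3), 1)
  db <- species_db(list(a, b, p), reference = "P")
  g <- energy_grid(e_max = 1.5, bin_width = 1e-3)
  ch <- enumerate_channels(db, "P")
  keys <- vapply(ch, function(c) paste(c$products, collapse = "+"),
                 character(1))
  om <- channel_dos(db, ch[[which(keys == "A+B")]], g,
                    volume = default_volume(10))
  # oracle: explicit Riemann convolution of the three factor densities
  de <- g$bin_width
  vib <- cidfrag:::bs_pass(c(2100, 2300), g) / de
  rot <- sapply(list(a, b), function(s) {
    rep(1 / (s$symmetry_number * s$rot_constants * 1.239841984e-4),
        g$n_bins)
  })
  trans <- trans_dos(c(a$mass, b$mass), default_volume(10), g)$values
  conv2 <- function(x, y) {
    n <- length(x)
    out <- numeric(n)
    for (k in seq_len(n)) {
      out[k] <- de * sum(x[seq_len(k)] * y[k:1])
    }
    out
  }
  oracle <- conv2(conv2(conv2(vib, rot[, 1]), rot[, 2]), trans)
  oracle <- cidfrag:::shift_by_threshold(oracle, g, 0.4)
  # the left-Riemann oracle carries an O(bin/excess) bias near threshold:
  # compare from 0.2 eV of excess upward
  sel <- g$energies > 0.6
  expect_lt(max(abs(om$values[sel] - oracle[sel]) /
                pmax(oracle[sel], 1e-300)), 0.02)
})

test_that("channel DOS is grid-converged at the default resolution", {
  db <- hex_db()
  ch <- enumerate_channels(db, "Cys(H2O)6+")
  keys <- vapply(ch, function(c) paste(c$products, collapse = "+"),
                 character(1))
  target <- ch[[which(keys == "(H2O)2+Cys(H2O)4+")]]
  g1 <- energy_grid(e_max = 3, bin_width = 1e-3)
  g2 <- energy_grid(e_max = 3, bin_width = 5e-4)
  o1 <- channel_dos(db, target, g1, volume = default_volume(10))
  o2 <- channel_dos(db, target, g2, volume = default_volume(10))
  for (e in c(0.5, 1.5, 2, 2.5)) {
    v1 <- o1$values[which.min(abs(g1$energies - e))]
    v2 <- o2$values[which.min(abs(g2$energies - e))]
    expect_equal(v1, v2, tolerance = 0.01)
  }
})

test_that("cumulative sums of states are non-decreasing", {
  g <- energy_grid(e_max = 2, bin_width = 2e-3)
  sp <- hex_db()$species[["Cys(H2O)4+"]]
  for (sf in list(vib_states(sp$frequencies, g),
                  rot_dos(sp$rot_constants, sp$symmetry_number, g),
                  trans_dos(c(18, 200), default_volume(10), g))) {
    expect_true(all(diff(sum_of_states(sf)$values) >= -1e-12))
  }
})
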