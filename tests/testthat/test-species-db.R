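test_that("species records enforce their invariants", {
  expect_error(
    species("bad", c(H = 2, O = 1), 0L, 0, c(-100, 1600, 3700),
            c(27.9, 14.5, 9.3), 2L),
    "positive")
  expect_error(
    species("bad", c(H = 2, O = 1), 0L, 0, c(1600, 3700),
            c(27.9, 14.5, 9.3), 2L),
    "expected 3 frequencies")
  expect_error(
    species("bad", c(H = 2, O = 1), 0L, 0, rep(1600, 3),
            c(27.9, 14.5), 2L),
    "length 0, 1 or 3")
  w <- species("H2O", c(H = 2, O = 1), 0L, 0, c(1595, 3657, 3756),
               c(27.88, 14.51, 9.28), 2L, 12.6223)
  expect_equal(w$mass, 18.015, tolerance = 1e-3)
})

test_that("mass derivation matches summed standard atomic weights", {
  expect_equal(composition_mass(c(H = 2, O = 1)), 18.015, tolerance = 5e-4)
  expect_equal(composition_mass(c(C = 3, H = 7, N = 1, O = 2, S = 1)),
               3 * 12.011 + 7 * 1.008 + 14.007 + 2 * 15.999 + 32.06)
  expect_error(composition_mass(c(Xx = 1)), "unknown element")
})

test_that("database I/O round-trips through JSON and YAML with validation", {
  db <- hex_db()
  expect_length(db$species, 14)   # Cys(H2O)0..6+, (H2O)1..6, neutral Cys
  for (ext in c("json", "yaml")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_species_db(db, f)
    db2 <- load_species_db(f)
    expect_length(db2$species, 14)
    expect_equal(db2$reference, "Cys(H2O)6+")
    expect_equal(db2$species[["(H2O)2"]]$energy,
                 db$species[["(H2O)2"]]$energy, tolerance = 1e-9)
    expect_equal(db2$species[["Cys+"]]$frequencies,
                 db$species[["Cys+"]]$frequencies, tolerance = 1e-7)
  }
})

test_that("malformed databases are rejected with informative errors", {
  db <- hex_db()
  dup <- c(unname(db$species), db$species["H2O"])
  expect_error(species_db(dup), "duplicate")
  f <- tempfile(fileext = ".json")
  write_species_db(db, f)
  raw <- jsonlite::fromJSON(f, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  raw$species[[2]]$frequencies_cm1[[1]] <- -50
  jsonlite::write_json(raw, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_species_db(f), "positive")
  raw$species[[2]]$energy_eV <- NULL
  jsonlite::write_json(raw, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_species_db(f), "missing field")
  expect_error(load_species_db("no/such/file.json"), "no such file")
})

test_that("channel enumeration covers exactly the integer partitions", {
  db <- hex_db()
  ch <- enumerate_channels(db, "Cys(H2O)6+")
  to_cys <- Filter(function(c) c$charged_product == "Cys+", ch)
  expect_length(to_cys, count_partitions_oracle(6))   # p(6) = 11
  # p(k) channels for every intermediate hydrate
  for (k in 1:5) {
    prod <- paste0("Cys(H2O)", 6 - k, "+")
    n_k <- length(Filter(function(c) c$charged_product == prod, ch))
    expect_equal(n_k, count_partitions_oracle(k))
  }
  # identity channel with max_fragments = 1
  ch1 <- enumerate_channels(db, "Cys(H2O)6+", max_fragments = 1)
  expect_length(ch1, 1)
  expect_equal(ch1[[1]]$products, "Cys(H2O)6+")
  expect_equal(ch1[[1]]$threshold, 0)
})

test_that("every enumerated channel conserves atoms and charge", {
  db <- hex_db()
  parent <- db$species[["Cys(H2O)6+"]]
  for (ch in enumerate_channels(db, "Cys(H2O)6+")) {
    comp <- Reduce(`+`, lapply(ch$products, function(nm) {
      v <- setNames(numeric(5), c("C", "H", "N", "O", "S"))
      cc <- db$species[[nm]]$composition
      v[names(cc)] <- cc
      v
    }))
    target <- setNames(numeric(5), c("C", "H", "N", "O", "S"))
    target[names(parent$composition)] <- parent$composition
    expect_equal(comp, target)
    q <- sum(vapply(ch$products, function(nm) db$species[[nm]]$charge,
                    integer(1)))
    expect_equal(q, parent$charge)
    expect_equal(sum(vapply(ch$products, function(nm) {
      db$species[[nm]]$charge != 0
    }, logical(1))), 1L)
  }
})

test_that("channels come in canonical ascending-threshold order", {
  ch <- enumerate_channels(hex_db(), "Cys(H2O)6+")
  thr <- vapply(ch, `[[`, numeric(1), "threshold")
  expect_true(all(diff(thr) >= -1e-12))
})

test_that("thresholds are state-function differences and additive", {
  db <- hex_db()
  # calculated two-water-loss value on the fixture
  expect_equal(compute_threshold(db, c("Cys(H2O)4+", "(H2O)2"), "Cys(H2O)6+"),
               0.94, tolerance = 1e-12)
  expect_equal(compute_threshold(db, "Cys(H2O)6+", "Cys(H2O)6+"), 0)
  # fully sequential loss costs the ladder top plus all cluster bindings
  b <- hex_spec()$binding_energies
  expect_equal(compute_threshold(db, c("Cys+", rep("H2O", 6)), "Cys(H2O)6+"),
               1.8 + sum(b), tolerance = 1e-12)
  # additivity under refinement: A -> B + C equals A -> B' where B' refines B
  thr_coarse <- compute_threshold(db, c("Cys(H2O)3+", "(H2O)3"), "Cys(H2O)6+")
  refine <- compute_threshold(db, c("(H2O)2", "H2O"), "(H2O)3") # uses (H2O)3 as parent
  thr_fine <- compute_threshold(db, c("Cys(H2O)3+", "(H2O)2", "H2O"),
                                "Cys(H2O)6+")
  expect_equal(thr_fine, thr_coarse + refine, tolerance = 1e-12)
  expect_error(compute_threshold(db, c("nope"), "Cys(H2O)6+"), "not in database")
})

test_that("the minimum-threshold channel ships lost waters as one cluster", {
  db <- hex_db()
  ladder <- hex_spec()$thresholds
  ch <- enumerate_channels(db, "Cys(H2O)6+")
  for (k in 2:6) {
    prod <- if (k == 6) "Cys+" else paste0("Cys(H2O)", 6 - k, "+")
    sub <- Filter(function(c) c$charged_product == prod, ch)
    thr <- vapply(sub, `[[`, numeric(1), "threshold")
    best <- sub[[which.min(thr)]]
    expect_equal(min(thr), ladder[k], tolerance = 1e-12)
    expect_equal(best$n_fragments, 2L)   # ion + one (H2O)k cluster
    expect_true(paste0("(H2O)", k) %in% best$products)
  }
})

test_that("the charge settles on the fragment with the lowest IE", {
  db <- hex_db()
  expect_equal(assign_charge(db, c("Cys", "H2O")), "Cys")
  expect_equal(assign_charge(db, c("Cys", "(H2O)2")), "Cys")
  expect_equal(assign_charge(db, "H2O"), "H2O")
  expect_error(assign_charge(db, c("Cys", "Cys+")), "missing ionization")
})
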