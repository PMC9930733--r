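# Shared fixtures (built once per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

hex_spec <- function() cached("hex_spec", fixture_spec(6, FALSE))
hex_db <- function() cached("hex_db", synthetic_cluster_db(hex_spec()))
hex_curve <- function() cached("hex_curve", {
  breakdown_exact(hex_db(), "Cys(H2O)6+", grid = energy_grid(15, 5e-3),
                  volume = default_volume(10))
})
tri_db <- function() cached("tri_db", synthetic_cluster_db(fixture_spec(3, FALSE)))

cys_parent_comp <- c(C = 3, H = 13, N = 1, O = 5, S = 1)  # Cys + 3 H2O

# --- independent oracles --------------------------------------------------

# number of integer partitions of n by direct recursive counting
count_partitions_oracle <- function(n, max_part = n) {
  if (n == 0) return(1L)
  total <- 0L
  for (p in seq_len(min(n, max_part))) {
    total <- total + count_partitions_oracle(n - p, p)
  }
  total
}

# brute-force harmonic-oscillator state count: number of quantum-number
# tuples with sum(n_i * quantum_i) <= e_max, quanta rounded to the grid as
# the direct count does
vib_enum_oracle <- function(freqs_cm, e_max, bin_width) {
  cm1_ev <- 1.239841984e-4
  quanta <- round(freqs_cm * cm1_ev / bin_width) * bin_width
  count <- 0L
  recurse <- function(i, remaining) {
    if (i > length(quanta)) { count <<- count + 1L; return(invisible()) }
    n_max <- floor(remaining / quanta[i] + 1e-9)
    for (n in 0:n_max) recurse(i + 1L, remaining - n * quanta[i])
    invisible()
  }
  recurse(1L, e_max)
  count
}

# O(n^2) union-find connected components under a distance cutoff
union_find_oracle <- function(coords, cutoff) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- parent[ri]
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# random cluster frame for oracle comparisons
random_frame <- function(n_atoms, seed, spread = 6) {
  set.seed(seed)
  list(symbols = sample(c("C", "H", "O", "N", "S"), n_atoms, replace = TRUE),
       coords = matrix(runif(3 * n_atoms, 0, spread), ncol = 3),
       charges = NULL, time = NA_real_)
}
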