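# Shared fixture builders; everything is generated in code at test time.

rand_layer <- function(nr = 8, nc = 8, origin = c(0, nr * 20), cs = 20,
                       name = "r", na_frac = 0, lo = 0, hi = 1) {
  v <- matrix(runif(nr * nc, lo, hi), nr, nc)
  if (na_frac > 0)
    v[sample.int(nr * nc, ceiling(na_frac * nr * nc))] <- NA_real_
  grid_layer(v, origin = origin, cell_size = cs, name = name)
}

# Small, fast scenario for integration-style unit tests (the package
# defaults stay at the full study scale).
tiny_config <- function(seed = 1, ...) {
  scenario_config(grid_shape = c(60L, 60L), population_size = 3000L,
                  seed = seed, ...)
}

# Random reciprocal pairwise matrix on the 1-9 scale.
rand_pairwise <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- sample(c(1 / (9:2), 1:9), 1)
    a[i, j] <- v
    a[j, i] <- 1 / v
  }
  pairwise_matrix(a)
}
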