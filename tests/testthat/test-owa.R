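# Direct transcription of the quantifier-guided OWA definition, kept as a
# slow independent oracle: explicit sort, cumulative-importance quantifier
# differences, scalar loop.
owa_oracle <- function(z, w, x) {
  ord <- order(z, decreasing = TRUE)
  zs <- z[ord]; u <- w[ord]
  total <- sum(u)
  acc <- 0
  prev <- 0
  for (j in seq_along(zs)) {
    Uj <- sum(u[seq_len(j)]) / total
    vj <- Uj^x - prev^x
    acc <- acc + vj * zs[j]
    prev <- Uj
  }
  acc
}

test_that("x = 1 collapses the OWA to the importance-weighted mean", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:9, 1)
    z <- runif(n)
    w <- weight_vector(setNames(runif(n, 0.1, 1), paste0("c", seq_len(n))))
    expect_equal(owa_cell(z, unname(w), x = 1), sum(w * z),
                 tolerance = 1e-14)
  }
})

test_that("x near 0 approaches the optimistic max operator", {
  v <- owa_cell(c(0.9, 0.4), c(0.5, 0.5), x = 1e-6)
  expect_equal(v, 0.9, tolerance = 1e-5)
})

test_that("owa_cell matches the direct two-term telescoping oracle", {
  z <- c(0.2, 0.5, 0.8)
  w <- c(0.5, 0.3, 0.2)
  expect_equal(owa_cell(z, w, x = 2), owa_oracle(z, w, 2), tolerance = 1e-14)
  # hand evaluation: sorted z (0.8, 0.5, 0.2) carries u = (0.2, 0.3, 0.5);
  # V = (0.2^2, 0.5^2 - 0.2^2, 1 - 0.5^2)
  expect_equal(owa_cell(z, w, x = 2),
               0.04 * 0.8 + 0.21 * 0.5 + 0.75 * 0.2, tolerance = 1e-14)
  set.seed(32)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    z <- runif(n); w <- runif(n, 0.05, 1)
    x <- runif(1, 0.1, 5)
    expect_equal(owa_cell(z, w, x), owa_oracle(z, w, x), tolerance = 1e-12)
  }
})

test_that("order weights sum to one and inputs are validated", {
  set.seed(33)
  for (rep in 1:10) {
    v <- owa_order_weights(runif(6, 0.01, 1), x = runif(1, 0.05, 6))
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_true(all(v >= -1e-15))
  }
  expect_error(owa_cell(c(0.2, 1.4), c(0.5, 0.5)), "\\[0, 1\\]")
  expect_error(owa_cell(c(0.2, 0.4, 0.1), c(0.5, 0.5)), "length")
  expect_error(owa_order_weights(c(0.5, 0.5), x = 0), "positive")
})

test_that("OWA is bounded, monotone in x, and monotone in memberships", {
  set.seed(34)
  xs <- c(0.1, 0.5, 1, 2, 5)
  for (rep in 1:15) {
    n <- sample(3:7, 1)
    z <- runif(n); w <- runif(n, 0.05, 1)
    vals <- vapply(xs, function(x) owa_cell(z, w, x), numeric(1))
    expect_true(all(vals >= min(z) - 1e-12 & vals <= max(z) + 1e-12))
    expect_true(all(diff(vals) <= 1e-12))   # non-increasing in x
    # raising one membership never lowers the output
    i <- sample(n, 1)
    z2 <- z; z2[i] <- min(1, z2[i] + runif(1, 0, 1 - z2[i]))
    for (x in xs)
      expect_gte(owa_cell(z2, w, x) - owa_cell(z, w, x), -1e-12)
  }
})

test_that("aggregating identical constant layers returns the constant", {
  w <- weight_vector(c(a = 0.2, b = 0.5, c = 0.3))
  layers <- lapply(c("a", "b", "c"), function(nm)
    grid_layer(matrix(0.42, 4, 4), name = nm))
  names(layers) <- c("a", "b", "c")
  for (x in c(0.3, 1, 4)) {
    out <- owa_aggregate(layers, w, x = x)
    expect_true(all(abs(out$values - 0.42) < 1e-12))
  }
})

test_that("owa_aggregate at x = 1 equals the weighted-linear-combination
           raster and any x matches the per-cell oracle", {
  set.seed(35)
  nms <- paste0("c", 1:5)
  layers <- lapply(nms, function(nm) rand_layer(5, 5, name = nm))
  names(layers) <- nms
  w <- weight_vector(setNames(runif(5, 0.1, 1), nms))
  wlc <- Reduce(`+`, Map(function(l, wi) l$values * wi, layers, w))
  out1 <- owa_aggregate(layers, w, x = 1)
  expect_equal(out1$values, wlc, tolerance = 1e-12)
  out2 <- owa_aggregate(layers, w, x = 2)
  for (r in 1:5) for (c in 1:5) {
    z <- vapply(layers, function(l) l$values[r, c], numeric(1))
    expect_equal(out2$values[r, c], unname(owa_oracle(z, as.vector(w), 2)),
                 tolerance = 1e-12)
  }
})

test_that("a cell masked in any input is masked in the aggregate", {
  nms <- c("a", "b")
  layers <- list(a = rand_layer(4, 4, name = "a"),
                 b = rand_layer(4, 4, name = "b"))
  layers$a$values[2, 3] <- NA
  layers$b$values[4, 1] <- NA
  out <- owa_aggregate(layers, weight_vector(c(a = 0.5, b = 0.5)))
  expect_true(is.na(out$values[2, 3]) && is.na(out$values[4, 1]))
  expect_equal(sum(is.na(out$values)), 2L)
})

test_that("misaligned or unstandardized layers are rejected", {
  a <- rand_layer(4, 4, name = "a")
  b <- rand_layer(5, 5, name = "b")
  w <- weight_vector(c(a = 0.5, b = 0.5))
  expect_error(owa_aggregate(list(a = a, b = b), w), "aligned")
  b2 <- rand_layer(4, 4, name = "b", lo = 0, hi = 3)
  expect_error(owa_aggregate(list(a = a, b = b2), w), "standardized")
  expect_error(owa_aggregate(list(a = a), w), "no layer")
})

test_that("equal-interval classification puts 0.55 in class 3 of 5", {
  g <- grid_layer(matrix(c(0.05, 0.25, 0.55, 0.95), 2, 2), name = "r")
  rm5 <- classify_risk(g, "equal", 5)
  expect_equal(rm5$classes$values, matrix(c(1, 2, 3, 5), 2, 2))
  expect_equal(rm5$breaks, c(0.2, 0.4, 0.6, 0.8))
  expect_identical(rm5$labels[3], "moderate")
})

test_that("quantile classes of a monotone ramp are equal-sized (+/- 1)", {
  g <- grid_layer(matrix(seq(0, 1, length.out = 100), 10, 10), name = "r")
  rmq <- classify_risk(g, "quantile", 4)
  expect_true(max(rmq$counts) - min(rmq$counts) <= 1)
})

test_that("quantile breaks reproduce a sort-based quantile computation", {
  set.seed(36)
  g <- rand_layer(8, 8, name = "r")
  rmq <- classify_risk(g, "quantile", 5)
  v <- sort(as.vector(g$values))
  # type-7 quantile, computed from the sorted vector by hand
  manual <- vapply(1:4 / 5, function(p) {
    h <- (length(v) - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[lo + 1] - v[lo])
  }, numeric(1))
  expect_equal(rmq$breaks, manual, tolerance = 1e-12)
})

test_that("a constant surface under the quantile scheme is a clear error", {
  g <- grid_layer(matrix(0.5, 4, 4), name = "r")
  expect_error(classify_risk(g, "quantile", 5), "equal")
  expect_s3_class(classify_risk(g, "equal", 5), "risk_map")
})
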