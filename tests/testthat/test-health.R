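# Dense-matrix transcription of the autocorrelation statistic, used as an
# independent oracle on small grids.
moran_oracle <- function(values, W) {
  W <- as.matrix(W)
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

rook_W <- function(nr, nc, row_standardize = TRUE) {
  n <- nr * nc
  W <- matrix(0, n, n)
  id <- function(r, c) (c - 1) * nr + r
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (r < nr) W[id(r, c), id(r + 1, c)] <- W[id(r + 1, c), id(r, c)] <- 1
    if (c < nc) W[id(r, c), id(r, c + 1)] <- W[id(r, c + 1), id(r, c)] <- 1
  }
  if (row_standardize) W <- W / pmax(rowSums(W), 1)
  W
}

test_that("panel built from records matches direct tabulation", {
  set.seed(51)
  n <- 400
  rec <- data.frame(year = sample(2012:2014, n, replace = TRUE),
                    sex = sample(c("female", "male"), n, replace = TRUE),
                    hypertensive = runif(n) < 0.3)
  pan <- build_panel(rec, cohort_size = 1000)
  expect_equal(sum(pan$total), sum(rec$hypertensive))   # conservation
  for (k in seq_len(nrow(pan))) {
    expect_equal(pan$female[k], sum(rec$hypertensive & rec$sex == "female" &
                                      rec$year == pan$year[k]))
    expect_equal(pan$total[k], pan$female[k] + pan$male[k])
  }
  expect_equal(pan$prevalence_pct, 100 * pan$total / 1000)
})

test_that("empty record sets and year violations are handled", {
  empty <- data.frame(year = integer(0), sex = character(0),
                      hypertensive = logical(0))
  pan <- build_panel(empty, cohort_size = 100, years = 2012:2013)
  expect_equal(pan$total, c(0L, 0L))
  expect_equal(pan$prevalence_pct, c(0, 0))
  rec <- data.frame(year = 2025, sex = "male", hypertensive = TRUE)
  expect_error(build_panel(rec, years = 2012:2020), "2025")
})

test_that("the packaged panel reproduces the printed case arithmetic", {
  pan <- salt_panel()
  expect_equal(pan$total[pan$year == 2019], 2340)   # 1225 + 1115
  expect_equal(pan$prevalence_pct[pan$year == 2019], 19.5)
  expect_equal(attr(pan, "cohort_size"), 12000L)
  expect_true(all(pan$total == pan$female + pan$male))
})

test_that("KDE of a single record peaks at the containing cell", {
  tpl <- rand_layer(15, 15, cs = 10, origin = c(0, 150))
  surf <- kde_surface(data.frame(x = 72, y = 88), tpl, bandwidth = 15)
  peak <- which(surf$values == max(surf$values), arr.ind = TRUE)[1, ]
  # (72, 88) falls in column 8, row 7 (cell centers at 75, 85)
  expect_equal(unname(peak), c(7, 8))
})

test_that("KDE integrates to the record count within 1%", {
  set.seed(52)
  tpl <- rand_layer(40, 40, cs = 10, origin = c(0, 400))
  pts <- data.frame(x = runif(200, 100, 300), y = runif(200, 100, 300))
  surf <- kde_surface(pts, tpl, bandwidth = 12)
  mass <- sum(surf$values) * tpl$cell_size^2
  expect_equal(mass, 200, tolerance = 0.01)
})

test_that("KDE matches a per-cell kernel-sum oracle and finds two modes", {
  set.seed(53)
  tpl <- rand_layer(30, 30, cs = 10, origin = c(0, 300))
  pts <- data.frame(x = c(rnorm(40, 80, 8), rnorm(40, 220, 8)),
                    y = c(rnorm(40, 220, 8), rnorm(40, 80, 8)))
  h <- 15
  surf <- kde_surface(pts, tpl, bandwidth = h)
  cx <- (seq_len(30) - 0.5) * 10
  cy <- 300 - (seq_len(30) - 0.5) * 10
  oracle <- matrix(0, 30, 30)
  for (r in 1:30) for (c in 1:30)
    oracle[r, c] <- sum(dnorm(cx[c] - pts$x, sd = h) *
                          dnorm(cy[r] - pts$y, sd = h))
  expect_equal(surf$values, oracle, tolerance = 1e-12)
  # the two cluster neighborhoods dominate the surface
  top <- which(surf$values >= sort(surf$values, decreasing = TRUE)[20],
               arr.ind = TRUE)
  expect_true(any(top[, "row"] < 15 & top[, "col"] < 15))
  expect_true(any(top[, "row"] > 15 & top[, "col"] > 15))
})

test_that("the 2x2 rook checkerboard gives Moran's I of -1", {
  g <- grid_layer(matrix(c(1, 0, 0, 1), 2, 2), name = "cb")
  res <- morans_i(g, weights = "rook", n_perm = 0)
  expect_equal(unname(res$statistic), -1, tolerance = 1e-12)
  expect_equal(unname(res$estimate), -1 / 3)
})

test_that("Moran's I matches the dense brute-force oracle on small grids", {
  set.seed(54)
  for (dims in list(c(2, 2), c(3, 4), c(5, 5), c(7, 6), c(10, 10))) {
    g <- rand_layer(dims[1], dims[2], name = "g")
    res <- morans_i(g, weights = "rook", n_perm = 0)
    oracle <- moran_oracle(as.vector(g$values), rook_W(dims[1], dims[2]))
    expect_equal(unname(res$statistic), oracle, tolerance = 1e-12)
  }
  # two-block surface: strong positive autocorrelation, oracle-checked
  v <- matrix(0, 6, 6); v[, 1:3] <- 1
  g2 <- grid_layer(v, name = "blocks")
  res2 <- morans_i(g2, weights = "rook", n_perm = 0)
  expect_equal(unname(res2$statistic),
               moran_oracle(as.vector(v), rook_W(6, 6)), tolerance = 1e-12)
  expect_gt(unname(res2$statistic), 0.5)
})

test_that("permutation inference behaves like a proper Monte-Carlo test", {
  set.seed(55)
  v <- matrix(0, 8, 8); v[, 1:4] <- 1
  g <- grid_layer(v + matrix(rnorm(64, 0, 0.01), 8, 8), name = "b")
  res <- morans_i(g, n_perm = 199)
  expect_gte(res$p.value, 1 / 200)
  expect_lte(res$p.value, 0.05)          # strong clustering is detected
  shuffled <- grid_layer(matrix(rnorm(400), 20, 20), name = "noise")
  res2 <- morans_i(shuffled, n_perm = 99)
  expect_gt(res2$p.value, 0.01)
  expect_error(morans_i(grid_layer(matrix(1, 3, 3)), n_perm = 0),
               "variance")
})

test_that("explicit weights matrices are accepted for plain vectors", {
  set.seed(56)
  vals <- rnorm(12)
  W <- rook_W(3, 4, row_standardize = FALSE)
  res <- morans_i(vals, weights = W, n_perm = 0)
  expect_equal(unname(res$statistic),
               moran_oracle(vals, W / pmax(rowSums(W), 1)),
               tolerance = 1e-12)
})

test_that("layer correlation anchors at +/-1 and rejects degenerate input", {
  set.seed(57)
  g <- rand_layer(10, 10, name = "a")
  expect_equal(correlate_layers(g, g)$r, 1)
  inv <- grid_layer(1 - g$values, origin = g$origin, name = "b")
  expect_equal(correlate_layers(g, inv)$r, -1)
  const <- grid_layer(matrix(0.5, 10, 10), origin = g$origin, name = "c")
  expect_error(correlate_layers(g, const), "variance")
  small <- grid_layer(matrix(c(1, NA, NA, NA), 2, 2), name = "s")
  expect_error(correlate_layers(small, small), "3 shared")
  bins <- correlate_layers(g, inv, n_bins = 5)$bins
  expect_equal(nrow(bins), 5L)
  expect_equal(sum(bins$n), 100L)
})

test_that("exposure proximity correlates with smoothed case density", {
  rs <- vapply(1:3, function(seed) {
    s <- generate_scenario(tiny_config(seed = seed))
    yr <- s$records[s$records$year == 2017, ]
    tpl <- s$layers$salt_center_distance
    dens_cases <- kde_surface(yr[yr$hypertensive, ], tpl, bandwidth = 150)
    dens_all <- kde_surface(yr, tpl, bandwidth = 150)
    rate <- grid_layer(dens_cases$values / pmax(dens_all$values, 1e-12),
                       origin = tpl$origin, cell_size = tpl$cell_size,
                       name = "rate")
    prox <- fuzzify(tpl, criterion_spec("salt_center_distance", "cost",
                                        "continuous", lo = 0, hi = 80000))
    correlate_layers(rate, prox)$r
  }, numeric(1))
  expect_true(all(rs > 0))
})

test_that("trend association recovers sign and matches a manual oracle", {
  pan <- salt_panel()
  ht <- trend_association(
    data.frame(year = pan$year, value = pan$salt_land_km2), pan)
  xs <- pan$salt_land_km2; ys <- pan$prevalence_pct
  manual <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  expect_equal(unname(ht$estimate), manual, tolerance = 1e-12)
  expect_gt(manual, 0)                    # drier years, more cases
  hs <- trend_association(
    data.frame(year = pan$year, value = pan$salt_land_km2), pan,
    method = "spearman")
  expect_equal(unname(hs$estimate),
               cor(rank(xs), rank(ys)), tolerance = 1e-12)
  ident <- setNames(ys, pan$year)
  expect_equal(unname(trend_association(ident, pan)$estimate), 1)
  expect_error(trend_association(setNames(rep(1, 9), pan$year), pan),
               "constant")
  expect_error(trend_association(setNames(1:2, 2012:2013), pan), "3 shared")
})
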