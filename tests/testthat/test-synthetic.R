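test_that("the same seed reproduces the scenario exactly", {
  s1 <- generate_scenario(tiny_config(seed = 5))
  s2 <- generate_scenario(tiny_config(seed = 5))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$layers$salt_center_distance$values,
                   s2$layers$salt_center_distance$values)
  expect_identical(s1$driver_series, s2$driver_series)
  s3 <- generate_scenario(tiny_config(seed = 6))
  expect_false(identical(s1$records, s3$records))
})

test_that("the scenario carries the eleven canonical criterion layers", {
  s <- generate_scenario(tiny_config())
  expect_length(s$layers, 11L)
  expect_setequal(names(s$layers), fanp_reference_weights()$criterion)
  cfg <- s$config
  expect_equal(nrow(s$records),
               cfg$population_size * length(cfg$years))
  expect_true(all(s$records$age >= 15 & s$records$age <= 64))
})

test_that("distance to a lone source is 0 there and grows along rays", {
  cfg <- scenario_config(grid_shape = c(40L, 40L), n_salt_sources = 1L,
                         population_size = 500L, years = 2012L, seed = 2)
  s <- generate_scenario(cfg)
  d <- s$layers$salt_center_distance$values
  src_cell <- which(d == min(d), arr.ind = TRUE)[1, ]
  expect_lt(min(d), cfg$cell_size)      # source cell distance ~ 0
  # walking away from the source along each grid direction is monotone
  r0 <- src_cell[1]; c0 <- src_cell[2]
  expect_true(all(diff(d[r0, c0:40]) > 0))
  expect_true(all(diff(d[r0, c0:1]) > 0))
  expect_true(all(diff(d[r0:40, c0]) > 0))
  expect_true(all(diff(d[r0:1, c0]) > 0))
})

test_that("a zero exposure coefficient flattens the spatial gradient", {
  cfg <- scenario_config(grid_shape = c(80L, 80L), population_size = 10000L,
                         beta = c(intercept = qlogis(0.1), exposure = 0,
                                  age = 0, sex = 0),
                         years = 2012L, seed = 3)
  s <- generate_scenario(cfg)
  dec <- prevalence_by_distance_decile(s)
  q_near <- mean(dec$prevalence_pct[dec$decile <= 3])
  q_far <- mean(dec$prevalence_pct[dec$decile >= 8])
  expect_lt(abs(q_near - q_far), 3)     # percentage points
})

test_that("an intercept-only model reproduces its Bernoulli mean", {
  cfg <- scenario_config(grid_shape = c(60L, 60L), population_size = 12000L,
                         beta = c(intercept = qlogis(0.02), exposure = 0,
                                  age = 0, sex = 0),
                         years = 2012L, seed = 4)
  s <- generate_scenario(cfg)
  pan <- build_panel(s$records, cohort_size = 12000L)
  expect_equal(pan$prevalence_pct[1], 2, tolerance = 0.25)  # +/- 0.5 pp
})

test_that("positive exposure effects create the near-source excess", {
  s <- generate_scenario(tiny_config(seed = 7))
  dec <- prevalence_by_distance_decile(s)
  expect_gt(dec$prevalence_pct[1], dec$prevalence_pct[10])
})

test_that("fitting the generating logistic model recovers the exposure
           coefficient within two standard errors", {
  cfg <- scenario_config(grid_shape = c(80L, 80L), population_size = 12000L,
                         years = 2017L, seed = 8)   # peak driver year
  s <- generate_scenario(cfg)
  dat <- merge(s$records, s$cohort[, c("id", "exposure")], by = "id")
  dat$female <- as.integer(dat$sex == "female")
  fit <- glm(hypertensive ~ exposure + I(age - 40) + female,
             family = binomial(), data = dat)
  est <- coef(summary(fit))["exposure", ]
  b1_true <- cfg$beta[["exposure"]] *
    (s$driver_series[["2017"]] / max(s$driver_series))
  expect_gt(est[["Estimate"]], 0)
  expect_lt(abs(est[["Estimate"]] - b1_true), 2 * est[["Std. Error"]])
})

test_that("downwind cells get amplified exposure relative to upwind twins", {
  cfg <- scenario_config(grid_shape = c(60L, 60L), n_salt_sources = 1L,
                         population_size = 100L, years = 2012L, seed = 9)
  s <- generate_scenario(cfg)
  wc <- s$layers$wind_direction$values
  e <- s$exposure$values
  d <- s$layers$salt_center_distance$values
  near <- d > 200 & d < 800
  if (any(near & wc == 1) && any(near & wc == 3)) {
    # compare decay-corrected exposure: downwind carries the amplification
    ratio_down <- mean((e / exp(-d / cfg$lambda))[near & wc == 1])
    ratio_up <- mean((e / exp(-d / cfg$lambda))[near & wc == 3])
    expect_equal(ratio_down, cfg$cone_amplification, tolerance = 1e-9)
    expect_equal(ratio_up, 1, tolerance = 1e-9)
  }
  expect_true(all(e >= 0))
})

test_that("scenario files round-trip and the manifest is complete", {
  s <- generate_scenario(scenario_config(grid_shape = c(25L, 25L),
                                         population_size = 400L,
                                         years = c(2012L, 2013L), seed = 10))
  dir <- withr::local_tempdir()
  manifest <- scenario_to_files(s, dir)
  expect_length(manifest$layers, 11L)
  for (nm in names(s$layers)) {
    back <- read_asc(file.path(dir, manifest$layers[[nm]]))
    expect_equal(back$values, s$layers[[nm]]$values, tolerance = 0,
                 info = nm)
  }
  recs <- read.csv(file.path(dir, "records.csv"))
  expect_equal(nrow(recs), nrow(s$records))
  expect_equal(sum(recs$hypertensive == "TRUE" | recs$hypertensive == TRUE),
               sum(s$records$hypertensive))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  drv <- read.csv(file.path(dir, "drivers.csv"))
  expect_equal(drv$salt_land_km2, unname(s$driver_series))
})
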