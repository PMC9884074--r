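#' Configuration for the synthetic salt-dust scenario
#'
#' Bundles and validates every knob of the synthetic study region: grid
#' geometry, salt-source count, prevailing wind, cohort size and age range,
#' the logistic outcome coefficients, the panel years, and the exposure
#' model (distance-decay length and downwind-cone amplification). Defaults
#' describe a desk-scale stand-in for a lakeside county survey: a 200 x 200
#' grid of 20 m cells (4 x 4 km), three salt-emission centers, a fixed
#' 12,000-adult cohort aged 15-64 followed 2012-2020, and an annual driver
#' series (exposed salt-land area, km^2) that rises and then falls over the
#' panel.
#'
#' The individual outcome model is
#' `P(hypertensive) = plogis(b0 + b1 * s_year * exposure +
#' b2 * (age - 40) + b3 * female)`, where `s_year` scales the exposure
#' coefficient proportionally to the annual driver (normalized by its
#' maximum) and `exposure = exp(-d / lambda) * amp` with `d` the distance to
#' the nearest salt source and `amp = cone_amplification` within
#' `+/- cone_half_angle` of the prevailing wind bearing (1 elsewhere).
#'
#' @param grid_shape integer (rows, cols) of the common grid.
#' @param cell_size cell size in meters.
#' @param n_salt_sources number of salt-emission centers.
#' @param wind_bearing prevailing wind bearing, degrees clockwise from
#'   north (direction the wind blows *toward*).
#' @param population_size cohort size (one record per participant per year).
#' @param age_range inclusive age bounds in years.
#' @param beta named logistic coefficients `intercept`, `exposure`
#'   (must be >= 0), `age` (per year, centered at 40), `sex` (female = 1).
#' @param years panel years.
#' @param lambda exposure distance-decay length, meters.
#' @param cone_half_angle downwind cone half-angle, degrees.
#' @param cone_amplification exposure multiplier inside the downwind cone
#'   (>= 1).
#' @param seed integer seed; the whole scenario is deterministic given it.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(grid_shape = c(200L, 200L), cell_size = 20,
                            n_salt_sources = 3L, wind_bearing = 135,
                            population_size = 12000L,
                            age_range = c(15L, 64L),
                            beta = c(intercept = stats::qlogis(0.012),
                                     exposure = 4.2, age = 0.035, sex = 0.25),
                            years = 2012:2020, lambda = 1500,
                            cone_half_angle = 45, cone_amplification = 1.5,
                            seed = 1L) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 8L), cell_size > 0,
            n_salt_sources >= 1L, population_size > 0L,
            length(age_range) == 2L, age_range[1] < age_range[2],
            length(years) >= 1L, lambda > 0,
            cone_half_angle > 0, cone_half_angle <= 180,
            cone_amplification >= 1)
  need <- c("intercept", "exposure", "age", "sex")
  if (!all(need %in% names(beta)))
    stop("'beta' must name: ", paste(need, collapse = ", "), call. = FALSE)
  if (beta[["exposure"]] < 0)
    stop("the exposure coefficient must be >= 0", call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape), cell_size = cell_size,
                 n_salt_sources = as.integer(n_salt_sources),
                 wind_bearing = wind_bearing %% 360,
                 population_size = as.integer(population_size),
                 age_range = as.integer(age_range), beta = beta[need],
                 years = as.integer(years), lambda = lambda,
                 cone_half_angle = cone_half_angle,
                 cone_amplification = cone_amplification,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Smooth Gaussian random field via separable kernel smoothing of white
# noise, rescaled to zero mean / unit sd.
smooth_field <- function(nr, nc, sigma_cells) {
  X <- matrix(stats::rnorm(nr * nc), nr, nc)
  gy <- stats::dnorm(outer(seq_len(nr), seq_len(nr), "-"), sd = sigma_cells)
  gx <- stats::dnorm(outer(seq_len(nc), seq_len(nc), "-"), sd = sigma_cells)
  f <- gy %*% X %*% gx
  (f - mean(f)) / stats::sd(f)
}

cut_classes <- function(f, k) {
  q <- stats::quantile(f, probs = seq_len(k - 1L) / k)
  matrix(findInterval(f, q) + 1, nrow = nrow(f))
}

#' Generate the synthetic scenario
#'
#' Builds the full synthetic study region from a [scenario_config()]: the
#' eleven criterion rasters the vulnerability analysis expects (age-group
#' class, population density, baseline hypertension probability, land
#' use/cover class, vegetation fraction, aspect class, slope,
#' distance-to-salt-center, soil moisture, wind-direction class, wind
#' speed), the true exposure field, the located cohort, the per-year health
#' records (Bernoulli draws from the logistic outcome model), and the annual
#' driver series. Distance to the salt centers is exact Euclidean distance
#' from each cell center to the nearest source; everything is deterministic
#' given `config$seed`.
#'
#' @param config a [scenario_config()].
#' @return object of class `salt_scenario`: `layers` (named list of 11
#'   [grid_layer]s), `exposure` (true exposure [grid_layer]), `sources`
#'   (data frame of source coordinates), `cohort` (one row per participant),
#'   `records` (one row per participant-year: `id, x, y, year, age, sex,
#'   hypertensive`), `driver_series` (named by year, km^2) and the config.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  cs <- config$cell_size
  template <- grid_layer(matrix(0, nr, nc), origin = c(0, nr * cs),
                         cell_size = cs, name = "template")
  cc <- cell_centers(template)
  gx <- matrix(cc$x, nr, nc, byrow = TRUE)
  gy <- matrix(cc$y, nr, nc, byrow = FALSE)

  # salt-emission centers, kept off the grid edge
  sx <- stats::runif(config$n_salt_sources, 0.15 * nc * cs, 0.85 * nc * cs)
  sy <- stats::runif(config$n_salt_sources, 0.15 * nr * cs, 0.85 * nr * cs)
  sources <- data.frame(x = sx, y = sy)

  dists <- vapply(seq_len(nrow(sources)), function(i)
    sqrt((gx - sx[i])^2 + (gy - sy[i])^2), matrix(0, nr, nc))
  dim(dists) <- c(nr * nc, nrow(sources))
  nearest <- max.col(-dists, ties.method = "first")
  dmin <- matrix(dists[cbind(seq_len(nr * nc), nearest)], nr, nc)

  # bearing (deg cw from north) from the nearest source toward each cell;
  # a cell is downwind when that bearing is within the wind cone
  dx <- gx - matrix(sx[nearest], nr, nc)
  dy <- gy - matrix(sy[nearest], nr, nc)
  bearing <- (atan2(dx, dy) * 180 / pi) %% 360
  ang <- abs((bearing - config$wind_bearing + 180) %% 360 - 180)
  wind_class <- matrix(3, nr, nc)                    # upwind
  wind_class[ang <= 90] <- 2                         # crosswind
  wind_class[ang <= config$cone_half_angle] <- 1     # downwind
  amp <- ifelse(wind_class == 1, config$cone_amplification, 1)
  exposure <- exp(-dmin / config$lambda) * amp
  exposure[dmin == 0] <- config$cone_amplification   # on-source cells

  mk <- function(values, name)
    grid_layer(values, origin = template$origin, cell_size = cs, name = name)

  dnorm01 <- dmin / max(dmin)
  veg <- pmin(pmax(0.45 + 0.25 * smooth_field(nr, nc, 6) +
                     0.35 * (dnorm01 - 0.5), 0), 1)
  moist <- pmin(pmax(0.4 + 0.22 * smooth_field(nr, nc, 8) +
                       0.4 * (dnorm01 - 0.5), 0), 1)
  popd <- 2000 * stats::plogis(1.2 * smooth_field(nr, nc, 10) - 0.8)
  baseline_scale <- mean(drivers_for(config$years) /
                           max(drivers_for(config$years)))
  b <- config$beta
  hyp_p <- stats::plogis(b[["intercept"]] +
                           b[["exposure"]] * baseline_scale * exposure +
                           b[["sex"]] * 0.5)
  layers <- list(
    age_group = mk(cut_classes(smooth_field(nr, nc, 12), 5), "age_group"),
    population_density = mk(popd, "population_density"),
    hypertension = mk(hyp_p, "hypertension"),
    land_use = mk(cut_classes(smooth_field(nr, nc, 9), 4), "land_use"),
    vegetation = mk(veg, "vegetation"),
    aspect = mk(cut_classes(smooth_field(nr, nc, 5), 3), "aspect"),
    slope = mk(pmin(abs(smooth_field(nr, nc, 7)) * 9, 30), "slope"),
    salt_center_distance = mk(dmin, "salt_center_distance"),
    moisture = mk(moist, "moisture"),
    wind_direction = mk(wind_class, "wind_direction"),
    wind_speed = mk(pmin(pmax(6 + 2.5 * smooth_field(nr, nc, 10), 0), 15),
                    "wind_speed"))

  # cohort located proportionally to population density, fixed across years
  n <- config$population_size
  pcell <- as.vector(popd); pcell <- pcell / sum(pcell)
  cell <- sample.int(nr * nc, n, replace = TRUE, prob = pcell)
  crow <- (cell - 1L) %% nr + 1L
  ccol <- (cell - 1L) %/% nr + 1L
  px <- cc$x[ccol] + stats::runif(n, -cs / 2, cs / 2)
  py <- cc$y[crow] + stats::runif(n, -cs / 2, cs / 2)
  age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                replace = TRUE)
  female <- stats::rbinom(n, 1L, 0.5)
  expo_i <- exposure[cbind(crow, ccol)]
  cohort <- data.frame(id = seq_len(n), x = px, y = py, age = age,
                       sex = ifelse(female == 1, "female", "male"),
                       exposure = expo_i)

  drv <- drivers_for(config$years)
  scale_y <- drv / max(drv)
  recs <- vector("list", length(config$years))
  for (k in seq_along(config$years)) {
    p <- stats::plogis(b[["intercept"]] +
                         b[["exposure"]] * scale_y[k] * expo_i +
                         b[["age"]] * (age - 40) + b[["sex"]] * female)
    recs[[k]] <- data.frame(id = cohort$id, x = px, y = py,
                            year = config$years[k], age = age,
                            sex = cohort$sex,
                            hypertensive = stats::rbinom(n, 1L, p) == 1L)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL

  structure(list(layers = layers, exposure = mk(exposure, "exposure"),
                 sources = sources, cohort = cohort, records = records,
                 driver_series = drv, config = config),
            class = "salt_scenario")
}

# Annual driver (salt-land area, km^2). For the canonical 2012-2020 panel
# the packaged observed series is used; other panels get a rise-and-fall
# bump with the same overall magnitude.
drivers_for <- function(years) {
  canonical <- c(`2012` = 103.24, `2013` = 135.14, `2014` = 185,
                 `2015` = 178, `2016` = 229, `2017` = 345, `2018` = 343.6,
                 `2019` = 189.70, `2020` = 111.51)
  if (all(as.character(years) %in% names(canonical))) {
    out <- canonical[as.character(years)]
  } else {
    t <- seq(0, 1, length.out = length(years))
    out <- 100 + 245 * exp(-((t - 0.62) / 0.3)^2)
    names(out) <- years
  }
  out
}

#' @method print salt_scenario
#' @export
print.salt_scenario <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<salt_scenario> %d x %d cells @ %g m, %d salt source%s\n",
              cfg$grid_shape[1], cfg$grid_shape[2], cfg$cell_size,
              cfg$n_salt_sources, if (cfg$n_salt_sources == 1) "" else "s"))
  cat(sprintf("  cohort %d (ages %d-%d), years %d-%d, seed %d\n",
              cfg$population_size, cfg$age_range[1], cfg$age_range[2],
              min(cfg$years), max(cfg$years), cfg$seed))
  pan <- build_panel(x$records, cohort_size = cfg$population_size)
  cat(sprintf("  prevalence: %.2f%% (first year) .. %.2f%% (peak year)\n",
              pan$prevalence_pct[1], max(pan$prevalence_pct)))
  invisible(x)
}

#' Write a scenario to disk
#'
#' Writes every criterion layer (plus the true exposure field) as an ESRI
#' ASCII grid, the per-year records and the driver series as CSV, and a JSON
#' manifest listing all artifacts.
#'
#' @param s a `salt_scenario`.
#' @param dir output directory (created if missing).
#' @return the manifest (named list of relative paths), invisibly; also
#'   written to `manifest.json`.
#' @export
scenario_to_files <- function(s, dir) {
  stopifnot(inherits(s, "salt_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layer_paths <- character(0)
  for (nm in names(s$layers)) {
    p <- paste0(nm, ".asc")
    write_asc(s$layers[[nm]], file.path(dir, p))
    layer_paths[nm] <- p
  }
  write_asc(s$exposure, file.path(dir, "exposure.asc"))
  utils::write.csv(s$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(year = as.integer(names(s$driver_series)),
                              salt_land_km2 = unname(s$driver_series)),
                   file.path(dir, "drivers.csv"), row.names = FALSE)
  manifest <- list(layers = as.list(layer_paths),
                   exposure = "exposure.asc",
                   records = "records.csv", drivers = "drivers.csv",
                   grid_shape = s$config$grid_shape,
                   cell_size = s$config$cell_size, seed = s$config$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Prevalence by distance-to-source decile
#'
#' Tabulates cohort prevalence (pooled over years, or for one year) across
#' deciles of individual distance to the nearest salt source — the direct
#' check that exposure translates into outcome gradient.
#'
#' @param s a `salt_scenario`.
#' @param year optional single panel year; default pools all years.
#' @return data frame `decile` (1 = nearest), `n`, `prevalence_pct`.
#' @export
prevalence_by_distance_decile <- function(s, year = NULL) {
  stopifnot(inherits(s, "salt_scenario"))
  rec <- s$records
  if (!is.null(year)) rec <- rec[rec$year == year, ]
  d <- sqrt(outer(rec$x, s$sources$x, "-")^2 +
              outer(rec$y, s$sources$y, "-")^2)
  dmin <- do.call(pmin, as.data.frame(d))
  qs <- stats::quantile(dmin, probs = seq(0.1, 0.9, by = 0.1))
  dec <- findInterval(dmin, qs) + 1L
  data.frame(
    decile = 1:10,
    n = tabulate(dec, 10L),
    prevalence_pct = vapply(1:10, function(k)
      100 * mean(rec$hypertensive[dec == k]), numeric(1)))
}
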