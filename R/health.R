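#' Build a sex-stratified prevalence panel from point health records
#'
#' Tabulates hypertensive cases per year and sex from individual records and
#' computes annual prevalence against a fixed survey cohort size. Prevalence
#' is reported exactly (percent, printed to 2 decimals), not re-rounded to
#' match any external tabulation.
#'
#' @param records data frame with at least columns `year`, `sex`
#'   (`"female"`/`"male"` or 0/1 with 1 = female) and logical
#'   `hypertensive`.
#' @param cohort_size survey cohort size used as the prevalence denominator
#'   (default 12000).
#' @param years optional vector of panel years; records outside it are an
#'   error, and years with no cases appear with zero counts.
#' @return a `health_panel`: data frame with columns `year`, `female`,
#'   `male`, `total`, `prevalence_pct`, and attribute `cohort_size`.
#' @export
build_panel <- function(records, cohort_size = 12000L, years = NULL) {
  if (cohort_size <= 0) stop("'cohort_size' must be positive", call. = FALSE)
  need <- c("year", "sex", "hypertensive")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  yr <- as.integer(records$year)
  if (is.null(years)) years <- sort(unique(yr))
  if (length(years) == 0L) years <- integer(0)
  if (nrow(records) && any(!(yr %in% years)))
    stop("record year(s) outside the panel: ",
         paste(sort(unique(yr[!(yr %in% years)])), collapse = ", "),
         call. = FALSE)
  sex <- records$sex
  if (is.numeric(sex)) sex <- ifelse(sex == 1, "female", "male")
  sex <- tolower(as.character(sex))
  if (nrow(records) && !all(sex %in% c("female", "male")))
    stop("sex must be 'female'/'male' (or 1/0)", call. = FALSE)
  hyp <- as.logical(records$hypertensive)
  fem <- mal <- integer(length(years))
  for (i in seq_along(years)) {
    sel <- yr == years[i] & hyp
    fem[i] <- sum(sel & sex == "female")
    mal[i] <- sum(sel & sex == "male")
  }
  health_panel(years, fem, mal, cohort_size = cohort_size)
}

#' @rdname build_panel
#' @param year,female,male per-year panel columns (integer counts of
#'   hypertensive cases by sex), for building a panel directly from printed
#'   tabulations rather than records.
#' @export
health_panel <- function(year, female, male, cohort_size = 12000L) {
  if (length(year) != length(female) || length(year) != length(male))
    stop("panel columns must have equal length", call. = FALSE)
  total <- as.integer(female) + as.integer(male)
  if (any(total > cohort_size))
    stop("annual case count exceeds the cohort size", call. = FALSE)
  out <- data.frame(year = as.integer(year), female = as.integer(female),
                    male = as.integer(male), total = total,
                    prevalence_pct = 100 * total / cohort_size)
  attr(out, "cohort_size") <- as.integer(cohort_size)
  class(out) <- c("health_panel", "data.frame")
  out
}

#' @method print health_panel
#' @export
print.health_panel <- function(x, ...) {
  cat(sprintf("<health_panel> cohort %d, %d year%s\n",
              attr(x, "cohort_size"), nrow(x), if (nrow(x) == 1) "" else "s"))
  df <- as.data.frame(x)
  df$prevalence_pct <- sprintf("%.2f", df$prevalence_pct)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Published environmental-driver and case panel
#'
#' The packaged 2012-2020 panel of annual salt-land area (km^2), lake
#' water-body area (km^2) and sex-stratified hypertensive case counts for
#' the 12,000-participant survey cohort, with exact prevalence computed on
#' load.
#'
#' @return a [health_panel()] with additional columns `salt_land_km2`,
#'   `water_body_km2`.
#' @export
salt_panel <- function() {
  path <- system.file("extdata", "salt_panel.csv", package = "saltrisk",
                      mustWork = TRUE)
  tab <- utils::read.csv(path)
  out <- health_panel(tab$year, tab$female, tab$male, cohort_size = 12000L)
  out$salt_land_km2 <- tab$salt_land_km2
  out$water_body_km2 <- tab$water_body_km2
  out
}

#' Kernel-density hotspot surface from point records
#'
#' Smooths point events (e.g. patient residences) into a continuous
#' intensity surface with an isotropic Gaussian kernel. The surface has
#' units of events per square meter, so summing it times the cell area
#' recovers the event count (up to edge loss when points sit within a few
#' bandwidths of the grid boundary). The default bandwidth is Silverman's
#' rule-of-thumb averaged over the two axes.
#'
#' @param records data frame with `x`, `y` (projected meters), or any object
#'   with those columns.
#' @param template [grid_layer] defining the output grid (its nodata mask is
#'   inherited).
#' @param bandwidth Gaussian kernel standard deviation in meters; `NULL` for
#'   Silverman's rule.
#' @return [grid_layer] named `"kde"`.
#' @export
kde_surface <- function(records, template, bandwidth = NULL) {
  stopifnot(is_grid_layer(template))
  x <- records$x; y <- records$y
  n <- length(x)
  if (n < 1L) stop("at least one record is required", call. = FALSE)
  if (is.null(bandwidth)) {
    bandwidth <- mean(c(stats::bw.nrd0(x), stats::bw.nrd0(y)))
    if (!is.finite(bandwidth) || bandwidth <= 0)
      bandwidth <- template$cell_size      # degenerate point clouds
  }
  if (bandwidth <= 0) stop("'bandwidth' must be positive", call. = FALSE)
  cc <- cell_centers(template)
  # separable Gaussian: D[r, c] = sum_i phi(cy[r] - y_i) phi(cx[c] - x_i)
  By <- stats::dnorm(outer(cc$y, y, "-"), sd = bandwidth)
  Ax <- stats::dnorm(outer(cc$x, x, "-"), sd = bandwidth)
  D <- By %*% t(Ax)
  D[is.na(template$values)] <- NA_real_
  g <- grid_layer(D, origin = template$origin, cell_size = template$cell_size,
                  name = "kde", crs = template$crs)
  attr(g, "bandwidth") <- bandwidth
  g
}

# Sparse contiguity weights among the unmasked cells of a grid.
grid_contiguity <- function(layer, type = c("queen", "rook"),
                            row_standardize = TRUE) {
  type <- match.arg(type)
  v <- layer$values
  nr <- nrow(v); nc <- ncol(v)
  keep <- !is.na(v)
  id <- matrix(NA_integer_, nr, nc)
  id[keep] <- seq_len(sum(keep))
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (type == "queen") offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  ii <- jj <- integer(0)
  for (o in offs) {
    r1 <- seq_len(nr - abs(o[1])) + max(0L, o[1])
    r0 <- r1 - o[1]
    c1 <- seq_len(nc - abs(o[2])) + max(0L, o[2])
    c0 <- c1 - o[2]
    a <- id[r0, c0, drop = FALSE]; b <- id[r1, c1, drop = FALSE]
    okp <- !is.na(a) & !is.na(b)
    ii <- c(ii, a[okp], b[okp])
    jj <- c(jj, b[okp], a[okp])
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = rep(sum(keep), 2L))
  if (row_standardize) {
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1
    W <- Matrix::Diagonal(x = 1 / rs) %*% W
  }
  W
}

#' Global Moran's I with permutation inference
#'
#' Computes the global spatial autocorrelation statistic
#' `I = n * sum_ij w_ij z_i z_j / (W * sum_i z_i^2)` with `z` the centered
#' attribute and `W` the total weight, and a permutation p-value from random
#' relabeling of the values over the spatial units (two-sided on the
#' distance from the null expectation `-1/(n-1)`). For a [grid_layer] the
#' spatial weights are queen (default) or rook contiguity among unmasked
#' cells, row-standardized; a plain numeric vector requires an explicit
#' weights matrix.
#'
#' @param x [grid_layer] or numeric vector of attribute values.
#' @param weights for a layer, `"queen"` or `"rook"`; for a vector, an
#'   `n x n` (dense or sparse) spatial weights matrix.
#' @param n_perm number of permutations (default 999); 0 skips inference.
#' @param row_standardize row-standardize the weights (default `TRUE`).
#' @return an object of classes `moran_test`/`htest` with the observed
#'   statistic, the null expectation `-1/(n-1)` and the permutation p-value.
#' @export
morans_i <- function(x, weights = "queen", n_perm = 999L,
                     row_standardize = TRUE) {
  dn <- deparse(substitute(x))
  if (is_grid_layer(x)) {
    W <- grid_contiguity(x, match.arg(weights, c("queen", "rook")),
                         row_standardize)
    vals <- x$values[!is.na(x$values)]
  } else {
    vals <- as.numeric(x)
    if (!is.matrix(weights) && !inherits(weights, "Matrix"))
      stop("a numeric attribute needs an explicit weights matrix",
           call. = FALSE)
    W <- Matrix::Matrix(weights, sparse = TRUE)
    if (nrow(W) != length(vals) || ncol(W) != length(vals))
      stop("weights matrix must be n x n", call. = FALSE)
    W <- W - Matrix::Diagonal(x = Matrix::diag(W))
    if (row_standardize) {
      rs <- Matrix::rowSums(W)
      rs[rs == 0] <- 1
      W <- Matrix::Diagonal(x = 1 / rs) %*% W
    }
  }
  n <- length(vals)
  if (n < 2L) stop("need at least two spatial units", call. = FALSE)
  z <- vals - mean(vals)
  ss <- sum(z^2)
  if (ss == 0)
    stop("attribute has zero variance; Moran's I is undefined",
         call. = FALSE)
  Wsum <- sum(W)
  I_of <- function(zv) (n / Wsum) * sum(zv * as.vector(W %*% zv)) / sum(zv^2)
  I <- I_of(z)
  expected <- -1 / (n - 1)
  p <- NA_real_
  if (n_perm > 0L) {
    dev <- abs(I - expected)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      zp <- z[sample.int(n)]
      if (abs(I_of(zp) - expected) >= dev - 1e-15) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
  }
  structure(list(statistic = c("Moran's I" = I),
                 parameter = c(n = n, permutations = n_perm),
                 p.value = p,
                 estimate = c(expectation = expected),
                 alternative = "two.sided (permutation)",
                 method = "Global Moran's I (permutation inference)",
                 data.name = dn),
            class = c("moran_test", "htest"))
}

#' Spatial correlation between an outcome surface and a criterion
#'
#' Pearson correlation over the cells unmasked in both layers, plus the
#' criterion-binned mean outcome (the data behind a correlation scatter
#' summary): the criterion range is cut into `n_bins` equal-width bins and
#' the mean outcome per bin is reported.
#'
#' @param outcome,criterion aligned [grid_layer]s.
#' @param n_bins number of criterion bins (default 10).
#' @return list with `r` (Pearson correlation) and `bins` (data frame
#'   `bin_mid`, `mean_outcome`, `n`).
#' @export
correlate_layers <- function(outcome, criterion, n_bins = 10L) {
  stopifnot(is_grid_layer(outcome), is_grid_layer(criterion))
  if (!same_grid(outcome, criterion))
    stop("layers are not aligned", call. = FALSE)
  ok <- !is.na(outcome$values) & !is.na(criterion$values)
  if (sum(ok) < 3L)
    stop("fewer than 3 shared unmasked cells", call. = FALSE)
  yo <- outcome$values[ok]; xc <- criterion$values[ok]
  if (stats::sd(yo) == 0 || stats::sd(xc) == 0)
    stop("zero variance in one of the layers", call. = FALSE)
  r <- stats::cor(xc, yo)
  br <- seq(min(xc), max(xc), length.out = n_bins + 1L)
  bin <- findInterval(xc, br, rightmost.closed = TRUE, left.open = TRUE)
  bin[bin == 0L] <- 1L
  bins <- data.frame(
    bin_mid = (br[-1] + br[-length(br)]) / 2,
    mean_outcome = vapply(seq_len(n_bins),
                          function(b) if (any(bin == b))
                            mean(yo[bin == b]) else NA_real_, numeric(1)),
    n = tabulate(bin, n_bins))
  list(r = r, bins = bins)
}

#' Association between an annual environmental driver and prevalence
#'
#' Correlates an annual driver series (e.g. exposed salt-land area) with
#' annual prevalence over the shared years, via [stats::cor.test()].
#'
#' @param driver data frame with columns `year`, `value`, or a numeric
#'   vector named by year.
#' @param panel a [health_panel()] (its `prevalence_pct` is used) or a
#'   numeric outcome vector named by year.
#' @param method `"pearson"` or `"spearman"`.
#' @return the `htest` from [stats::cor.test()], with the shared years in
#'   attribute `years`.
#' @export
trend_association <- function(driver, panel, method = c("pearson",
                                                        "spearman")) {
  method <- match.arg(method)
  if (is.data.frame(driver)) {
    dv <- driver$value; names(dv) <- driver$year
  } else dv <- driver
  if (inherits(panel, "health_panel")) {
    ov <- panel$prevalence_pct; names(ov) <- panel$year
  } else ov <- panel
  yrs <- intersect(names(dv), names(ov))
  if (length(yrs) < 3L)
    stop("need at least 3 shared years", call. = FALSE)
  dvv <- as.numeric(dv[yrs]); ovv <- as.numeric(ov[yrs])
  if (stats::sd(dvv) == 0 || stats::sd(ovv) == 0)
    stop("constant series; association is undefined", call. = FALSE)
  ht <- stats::cor.test(dvv, ovv, method = method, exact = FALSE)
  ht$data.name <- sprintf("driver vs prevalence over %d years",
                          length(yrs))
  attr(ht, "years") <- as.integer(yrs)
  ht
}
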