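#' Gridded raster layer
#'
#' Lightweight in-memory model of a single-band georeferenced raster: a
#' numeric matrix with an upper-left origin (projected meters), a square cell
#' size, and an implicit nodata mask (`NA` cells). All layers entering a
#' pixel-wise operation must share shape, origin and cell size
#' (see [same_grid()]); no reprojection is performed, so the optional `crs`
#' string is carried as opaque metadata and merely compared for equality.
#'
#' The coordinate convention is the usual raster one: cell `[1, 1]` sits at
#' the upper-left corner, row index increases southwards, and all
#' point-in-grid arithmetic uses cell centers. The center of cell
#' `[r, c]` is at `(origin[1] + (c - 0.5) * cell_size,
#' origin[2] - (r - 0.5) * cell_size)`.
#'
#' @param values numeric matrix; `NA` marks nodata.
#' @param origin numeric length-2, (x, y) of the grid's upper-left corner in
#'   projected meters.
#' @param cell_size positive scalar, meters per cell (the analyses here are
#'   designed around 20 m cells, but any positive size works).
#' @param name identifier used to match layers with criterion specs and
#'   weights.
#' @param crs optional free-text CRS tag; `NA` means unspecified.
#' @return An object of class `grid_layer`.
#' @examples
#' g <- grid_layer(matrix(runif(25), 5, 5), origin = c(0, 100),
#'                 cell_size = 20, name = "demo")
#' g
#' @export
grid_layer <- function(values, origin = c(0, 0), cell_size = 20,
                       name = "layer", crs = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("'origin' must be two finite coordinates (x, y)", call. = FALSE)
  cell_size <- as.numeric(cell_size)
  if (length(cell_size) != 1L || !is.finite(cell_size) || cell_size <= 0)
    stop("'cell_size' must be a positive scalar", call. = FALSE)
  structure(
    list(values = values, origin = origin, cell_size = cell_size,
         name = as.character(name)[1L], crs = as.character(crs)[1L]),
    class = "grid_layer")
}

#' @rdname grid_layer
#' @param x object to test or print.
#' @export
is_grid_layer <- function(x) inherits(x, "grid_layer")

#' @method print grid_layer
#' @export
print.grid_layer <- function(x, ...) {
  v <- x$values
  n_na <- sum(is.na(v))
  cat(sprintf("<grid_layer '%s'>  %d x %d cells @ %g m\n",
              x$name, nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  origin (UL): (%g, %g)%s\n", x$origin[1], x$origin[2],
              if (is.na(x$crs)) "" else paste0("  crs: ", x$crs)))
  if (n_na < length(v)) {
    rng <- range(v, na.rm = TRUE)
    cat(sprintf("  values: [%g, %g], %d nodata cell%s\n",
                rng[1], rng[2], n_na, if (n_na == 1) "" else "s"))
  } else cat("  values: all nodata\n")
  invisible(x)
}

#' @rdname grid_layer
#' @param layer a `grid_layer`.
#' @return `nodata_mask()`: logical matrix, `TRUE` where the cell is nodata.
#' @export
nodata_mask <- function(layer) {
  stopifnot(is_grid_layer(layer))
  is.na(layer$values)
}

#' Test whether two layers share a grid
#'
#' Shape, origin and cell size must agree (to a 1e-6 cell-size-relative
#' tolerance on the origin); CRS tags must not conflict when both are set.
#'
#' @param a,b `grid_layer` objects.
#' @return logical scalar.
#' @export
same_grid <- function(a, b) {
  stopifnot(is_grid_layer(a), is_grid_layer(b))
  tol <- 1e-6 * a$cell_size
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol) &&
    !(!is.na(a$crs) && !is.na(b$crs) && a$crs != b$crs)
}

# Cell-center coordinates: x along columns, y along rows (y decreases with row).
cell_centers <- function(layer) {
  d <- dim(layer$values)
  cs <- layer$cell_size
  list(x = layer$origin[1] + (seq_len(d[2]) - 0.5) * cs,
       y = layer$origin[2] - (seq_len(d[1]) - 0.5) * cs)
}

#' Read and write ESRI ASCII grid rasters
#'
#' Single-band georeferenced rasters are exchanged as ESRI ASCII grids
#' (`.asc`): a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by one row of cell values per line,
#' north to south. Cells equal to the declared nodata value are masked on
#' read; `write_asc()` prints values with 17 significant digits so a
#' read/write round trip reproduces values exactly.
#'
#' @param path file path.
#' @param name layer name to attach (defaults to the file stem).
#' @param crs optional CRS tag to attach (the format itself carries none).
#' @return `read_asc()`: a [grid_layer].
#' @export
read_asc <- function(path, name = NULL, crs = NA_character_) {
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L)
    stop("not an ESRI ASCII grid (truncated header): ", path, call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed ASCII grid header line: ", lines[i], call. = FALSE)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing geotransform fields in ", path,
         call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  body <- paste(lines[-(1:6)], collapse = " ")
  vals <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid body has %d values, expected %d",
                 length(vals), nr * nc), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  grid_layer(m, origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
             cell_size = hdr$cellsize, name = name, crs = crs)
}

#' @rdname read_asc
#' @param layer a [grid_layer] to write.
#' @param nodata numeric value standing for masked cells in the file; must not
#'   collide with a real data value.
#' @return `write_asc()`: `path`, invisibly.
#' @export
write_asc <- function(layer, path, nodata = -9999) {
  stopifnot(is_grid_layer(layer))
  v <- layer$values
  if (any(v == nodata, na.rm = TRUE))
    stop("nodata sentinel ", nodata, " collides with a data value",
         call. = FALSE)
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", sprintf("%.10g", layer$origin[1])),
    paste("yllcorner", sprintf("%.10g", layer$origin[2] - nr * layer$cell_size)),
    paste("cellsize", sprintf("%.10g", layer$cell_size)),
    paste("NODATA_value", sprintf("%.10g", nodata)))
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Align layers onto a common grid
#'
#' Resamples each layer onto the grid of `target` so that pixel-wise
#' aggregation is well defined. Continuous layers are resampled bilinearly,
#' categorical layers by nearest neighbor (so no new class values are
#' invented); the choice is declared per layer through `methods`. A layer
#' already on the target grid is returned unchanged, which makes the
#' operation idempotent. Nodata propagates: a target cell touching any masked
#' or out-of-extent source support becomes nodata.
#'
#' @param layers a `grid_layer` or list of them.
#' @param target `grid_layer` defining the output shape/origin/cell size.
#' @param methods character vector, `"bilinear"` or `"nearest"`, recycled
#'   across layers.
#' @return list of aligned `grid_layer` objects (a bare layer in gives a bare
#'   layer out).
#' @export
align <- function(layers, target, methods = "bilinear") {
  single <- is_grid_layer(layers)
  if (single) layers <- list(layers)
  stopifnot(is_grid_layer(target), length(layers) > 0L)
  methods <- rep_len(match.arg(methods, c("bilinear", "nearest"),
                               several.ok = TRUE), length(layers))
  out <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    out[[i]] <- resample_one(layers[[i]], target, methods[i])
  }
  names(out) <- vapply(out, function(l) l$name, character(1))
  if (single) out[[1]] else out
}

resample_one <- function(layer, target, method) {
  stopifnot(is_grid_layer(layer))
  if (!is.na(layer$crs) && !is.na(target$crs) && layer$crs != target$crs)
    stop("CRS mismatch: '", layer$crs, "' vs '", target$crs,
         "' (reprojection is out of scope)", call. = FALSE)
  if (same_grid(layer, target)) return(layer)
  tc <- cell_centers(target)
  # fractional (row, col) position of each target cell center in source space
  col_f <- (tc$x - layer$origin[1]) / layer$cell_size + 0.5
  row_f <- (layer$origin[2] - tc$y) / layer$cell_size + 0.5
  src <- layer$values
  nr <- nrow(src); nc <- ncol(src)
  if (all(col_f < 0.5) || all(col_f > nc + 0.5) ||
      all(row_f < 0.5) || all(row_f > nr + 0.5))
    stop("layer '", layer$name, "' does not overlap the target grid",
         call. = FALSE)
  R <- matrix(row_f, nrow = nrow(target$values), ncol = ncol(target$values),
              byrow = FALSE)
  C <- matrix(col_f, nrow = nrow(target$values), ncol = ncol(target$values),
              byrow = TRUE)
  if (method == "nearest") {
    ri <- pmin(pmax(round(R), 1L), nr)
    ci <- pmin(pmax(round(C), 1L), nc)
    vals <- src[cbind(as.vector(ri), as.vector(ci))]
    outside <- R < 0.5 | R > nr + 0.5 | C < 0.5 | C > nc + 0.5
    vals[as.vector(outside)] <- NA_real_
  } else {
    r0 <- floor(R - 0.5) + 1L; c0 <- floor(C - 0.5) + 1L
    fr <- (R - 0.5) - (r0 - 1L); fc <- (C - 0.5) - (c0 - 1L)
    # clamp support to the edge cells; cells beyond half a cell outside -> NA
    outside <- R < 0.5 | R > nr + 0.5 | C < 0.5 | C > nc + 0.5
    r0c <- pmin(pmax(r0, 1L), nr); r1c <- pmin(pmax(r0 + 1L, 1L), nr)
    c0c <- pmin(pmax(c0, 1L), nc); c1c <- pmin(pmax(c0 + 1L, 1L), nc)
    i00 <- cbind(as.vector(r0c), as.vector(c0c))
    i01 <- cbind(as.vector(r0c), as.vector(c1c))
    i10 <- cbind(as.vector(r1c), as.vector(c0c))
    i11 <- cbind(as.vector(r1c), as.vector(c1c))
    fr <- as.vector(fr); fc <- as.vector(fc)
    vals <- (1 - fr) * (1 - fc) * src[i00] + (1 - fr) * fc * src[i01] +
      fr * (1 - fc) * src[i10] + fr * fc * src[i11]
    vals[as.vector(outside)] <- NA_real_
  }
  grid_layer(matrix(vals, nrow = nrow(target$values)),
             origin = target$origin, cell_size = target$cell_size,
             name = layer$name,
             crs = if (!is.na(layer$crs)) layer$crs else target$crs)
}

#' Inverse-distance-weighted interpolation onto a grid
#'
#' Completes a surface from scattered point samples: each cell takes the
#' weighted mean of its `max_neighbors` nearest samples with weights
#' `d^(-power)`. A cell whose center coincides with a sample takes that
#' sample's value exactly. The result is a convex combination of sample
#' values, so it is bounded by their range everywhere.
#'
#' @param samples data frame with numeric columns `x`, `y`, `value`
#'   (projected meters).
#' @param template `grid_layer` defining the output grid; its nodata mask is
#'   inherited.
#' @param power positive IDW exponent (default 2).
#' @param max_neighbors number of nearest samples used per cell (default 12).
#' @return `grid_layer` on the template grid.
#' @export
idw_interpolate <- function(samples, template, power = 2, max_neighbors = 12) {
  stopifnot(is_grid_layer(template))
  if (is.null(samples$x) || is.null(samples$y) || is.null(samples$value))
    stop("'samples' needs columns x, y, value", call. = FALSE)
  n <- length(samples$x)
  if (n < 1L) stop("at least one sample is required", call. = FALSE)
  if (!all(is.finite(samples$x), is.finite(samples$y),
           is.finite(samples$value)))
    stop("sample coordinates and values must be finite", call. = FALSE)
  if (!is.finite(power) || power <= 0)
    stop("'power' must be positive", call. = FALSE)
  k <- min(as.integer(max_neighbors), n)
  cc <- cell_centers(template)
  d <- dim(template$values)
  gx <- rep(cc$x, each = d[1])
  gy <- rep(cc$y, times = d[2])
  ncell <- length(gx)
  out <- numeric(ncell)
  chunk <- max(1L, floor(4e6 / n))     # cap the distance matrix at ~4e6 cells
  for (s in seq(1L, ncell, by = chunk)) {
    idx <- s:min(s + chunk - 1L, ncell)
    d2 <- outer(gx[idx], samples$x, "-")^2 + outer(gy[idx], samples$y, "-")^2
    out[idx] <- apply_idw_rows(d2, samples$value, power, k)
  }
  res <- matrix(out, nrow = d[1])
  res[is.na(template$values)] <- NA_real_
  grid_layer(res, origin = template$origin, cell_size = template$cell_size,
             name = "idw", crs = template$crs)
}

apply_idw_rows <- function(d2, values, power, k) {
  n <- ncol(d2)
  apply(d2, 1L, function(row) {
    if (k < n) {
      keep <- order(row)[seq_len(k)]
      row <- row[keep]; v <- values[keep]
    } else v <- values
    hit <- row == 0
    if (any(hit)) return(mean(v[hit]))
    w <- row^(-power / 2)               # d^2 -> d^(-power)
    sum(w * v) / sum(w)
  })
}
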