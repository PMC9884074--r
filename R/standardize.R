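#' Criterion specification for fuzzy standardization
#'
#' Describes how one raw criterion layer maps to a [0, 1] fuzzy membership
#' under benefit/cost semantics. A *benefit* criterion is riskier the higher
#' its value (e.g. wind speed); a *cost* criterion is riskier the lower its
#' value (e.g. distance to a salt-emission center). Continuous criteria use a
#' linear ramp between two anchor values and are clamped outside the ramp;
#' classed criteria use an explicit class-to-membership lookup.
#'
#' @param name criterion identifier; must match the layer name and the weight
#'   vector entry.
#' @param direction `"benefit"` or `"cost"`.
#' @param kind `"continuous"` or `"classed"`.
#' @param lo,hi ramp anchors for continuous criteria (`lo < hi`, in the
#'   layer's native units).
#' @param classes named numeric vector for classed criteria: names are class
#'   codes (coerced to character), values are memberships in [0, 1].
#' @param weight optional reference importance weight carried for convenience.
#' @return An object of class `criterion_spec`.
#' @export
criterion_spec <- function(name, direction = c("benefit", "cost"),
                           kind = c("continuous", "classed"),
                           lo = NULL, hi = NULL, classes = NULL,
                           weight = NA_real_) {
  direction <- match.arg(direction)
  kind <- match.arg(kind)
  if (kind == "continuous") {
    if (is.null(lo) || is.null(hi) || !is.finite(lo) || !is.finite(hi) ||
        lo >= hi)
      stop("continuous criterion '", name, "' needs anchors lo < hi",
           call. = FALSE)
    classes <- NULL
  } else {
    if (is.null(classes) || length(classes) == 0L)
      stop("classed criterion '", name, "' needs a class->membership map",
           call. = FALSE)
    if (any(classes < 0 | classes > 1 | !is.finite(classes)))
      stop("class memberships must lie in [0, 1]", call. = FALSE)
    if (is.null(names(classes)))
      stop("'classes' must be a named vector (class code -> membership)",
           call. = FALSE)
    lo <- hi <- NULL
  }
  structure(list(name = as.character(name)[1], direction = direction,
                 kind = kind, lo = lo, hi = hi, classes = classes,
                 weight = as.numeric(weight)[1]),
            class = "criterion_spec")
}

#' @method print criterion_spec
#' @export
print.criterion_spec <- function(x, ...) {
  if (x$kind == "continuous") {
    cat(sprintf("<criterion_spec '%s'> %s, linear ramp [%g, %g]\n",
                x$name, x$direction, x$lo, x$hi))
  } else {
    cat(sprintf("<criterion_spec '%s'> %s, %d classes\n",
                x$name, x$direction, length(x$classes)))
  }
  invisible(x)
}

#' Fuzzy standardization of a criterion layer
#'
#' Converts a raw criterion layer to a [0, 1] membership surface. For a
#' continuous benefit criterion the membership is
#' `clamp((v - lo) / (hi - lo), 0, 1)`; for a cost criterion it is
#' `clamp((hi - v) / (hi - lo), 0, 1)`, so that low raw values (e.g. short
#' distance to a salt source) receive high risk membership. Classed layers
#' are mapped by pure table lookup (the membership map itself encodes the
#' risk direction). Nodata cells stay nodata; values outside a
#' continuous ramp are clamped rather than rejected, which keeps the
#' operation total on extreme synthetic inputs.
#'
#' @param layer a [grid_layer] in the criterion's native units.
#' @param spec a [criterion_spec].
#' @return [grid_layer] with values in [0, 1], named after the spec.
#' @export
fuzzify <- function(layer, spec) {
  stopifnot(is_grid_layer(layer), inherits(spec, "criterion_spec"))
  v <- layer$values
  if (spec$kind == "continuous") {
    m <- (v - spec$lo) / (spec$hi - spec$lo)
    if (spec$direction == "cost") m <- 1 - m
    m <- pmin(pmax(m, 0), 1)
  } else {
    key <- as.character(v)
    unknown <- !is.na(v) & !(key %in% names(spec$classes))
    if (any(unknown)) {
      bad <- unique(key[unknown])
      stop("criterion '", spec$name, "': no membership defined for class(es) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    # class maps already encode the risk direction; no flip is applied
    m <- matrix(unname(spec$classes[key]), nrow = nrow(v))
    m[is.na(v)] <- NA_real_
  }
  grid_layer(m, origin = layer$origin, cell_size = layer$cell_size,
             name = spec$name, crs = layer$crs)
}

#' Default criterion specifications for the salt-dust scenario
#'
#' One `criterion_spec` per criterion in the vulnerability analysis, matching
#' the layers produced by [generate_scenario()]. Anchors are stated in the
#' layers' native units. Distance to the nearest salt-emission center is a
#' cost criterion with an 80 km ramp (beyond which exposure membership is 0);
#' the remaining continuous criteria ramp over their natural or generated
#' ranges. Aspect and wind direction are classed by downwind alignment.
#'
#' @return named list of [criterion_spec] objects, in the canonical criterion
#'   order used by [fanp_reference_weights()].
#' @export
default_criterion_specs <- function() {
  specs <- list(
    criterion_spec("age_group", "benefit", "classed",
                   classes = c(`1` = 0.15, `2` = 0.35, `3` = 0.55,
                               `4` = 0.8, `5` = 1.0)),
    criterion_spec("population_density", "benefit", "continuous",
                   lo = 0, hi = 2000),                  # persons / km^2
    criterion_spec("hypertension", "benefit", "continuous", lo = 0, hi = 0.3),
    criterion_spec("land_use", "benefit", "classed",
                   classes = c(`1` = 0.1, `2` = 0.3, `3` = 0.6, `4` = 0.9)),
    criterion_spec("vegetation", "cost", "continuous", lo = 0, hi = 1),
    # 1 = facing downwind of the salt sources, 2 = crosswind, 3 = upwind
    criterion_spec("aspect", "benefit", "classed",
                   classes = c(`1` = 1.0, `2` = 0.5, `3` = 0.1)),
    criterion_spec("slope", "cost", "continuous", lo = 0, hi = 30),  # degrees
    criterion_spec("salt_center_distance", "cost", "continuous",
                   lo = 0, hi = 80000),                 # meters, 80 km ramp
    criterion_spec("moisture", "cost", "continuous", lo = 0, hi = 1),
    # 1 = downwind of a source (salt dust carried toward the cell),
    # 2 = crosswind, 3 = upwind
    criterion_spec("wind_direction", "benefit", "classed",
                   classes = c(`1` = 1.0, `2` = 0.5, `3` = 0.1)),
    criterion_spec("wind_speed", "benefit", "continuous", lo = 0, hi = 15))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}
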