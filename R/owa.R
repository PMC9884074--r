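#' Quantifier-guided order weights
#'
#' Given criterion importances reordered to follow the descending sort of the
#' memberships at one location (`u`), and a regular-increasing-monotone
#' quantifier `Q(p) = p^x`, the order weight of sort position `j` is
#' `V_j = (U_j / U_n)^x - (U_{j-1} / U_n)^x` with `U_j` the cumulative
#' importance through position `j`. The `V_j` telescope to sum exactly 1.
#' With `x = 1` they reduce to the (normalized) importances themselves, so
#' the OWA collapses to a weighted linear combination; `x < 1` shifts mass to
#' the largest memberships (optimistic, OR-like) and `x > 1` to the smallest
#' (conservative, AND-like).
#'
#' @param u positive importances in sorted-membership order.
#' @param x quantifier exponent, `x > 0`.
#' @return numeric vector of order weights summing to 1.
#' @export
owa_order_weights <- function(u, x = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("quantifier exponent 'x' must be a positive scalar", call. = FALSE)
  if (any(!is.finite(u)) || any(u < 0) || sum(u) <= 0)
    stop("importances must be non-negative with positive sum", call. = FALSE)
  p <- cumsum(u) / sum(u)
  v <- p^x - c(0, p[-length(p)])^x
  v
}

#' Ordered weighted average at a single location
#'
#' Sorts the criterion memberships at one location in descending order
#' (ties broken by the original criterion order), carries each membership's
#' importance weight along with it, derives quantifier-guided order weights
#' with [owa_order_weights()], and returns their inner product with the
#' sorted memberships. The result always lies between the smallest and
#' largest membership.
#'
#' @param z numeric vector of memberships in [0, 1], one per criterion.
#' @param w importance weights, same length as `z` (matched by name when both
#'   are named).
#' @param x quantifier exponent (> 0); default 1 gives the plain
#'   importance-weighted mean.
#' @return numeric scalar in [min(z), max(z)].
#' @examples
#' owa_cell(c(0.2, 0.5, 0.8), c(0.5, 0.3, 0.2), x = 2)
#' @export
owa_cell <- function(z, w, x = 1) {
  if (length(z) != length(w))
    stop("'z' and 'w' must have the same length", call. = FALSE)
  if (!is.null(names(z)) && !is.null(names(w))) {
    if (!setequal(names(z), names(w)))
      stop("criterion names of 'z' and 'w' differ", call. = FALSE)
    w <- w[names(z)]
  }
  if (any(!is.finite(z)) || any(z < 0 - 1e-12) || any(z > 1 + 1e-12))
    stop("memberships must lie in [0, 1]", call. = FALSE)
  ord <- order(-z, method = "radix")     # stable: ties keep criterion order
  zs <- z[ord]
  v <- owa_order_weights(w[ord], x)
  sum(v * zs)
}

# Vectorized OWA over a membership matrix (rows = locations, cols =
# criteria in the order of w). Rows containing NA return NA.
owa_apply <- function(Z, w, x = 1) {
  m <- nrow(Z); k <- ncol(Z)
  stopifnot(length(w) == k)
  ok <- rowSums(is.na(Z)) == 0L
  out <- rep(NA_real_, m)
  if (!any(ok)) return(out)
  Zc <- Z[ok, , drop = FALSE]
  mm <- nrow(Zc)
  o <- order(row(Zc), -Zc, method = "radix")   # stable within-row sort
  zs <- matrix(Zc[o], nrow = mm, byrow = TRUE)
  ci <- matrix((o - 1L) %/% mm + 1L, nrow = mm, byrow = TRUE)
  U <- matrix(w[ci], nrow = mm)
  cum <- U %*% upper.tri(diag(k), diag = TRUE)
  P <- cum / cum[, k]
  V <- P^x - cbind(0, P[, -k, drop = FALSE])^x
  out[ok] <- rowSums(V * zs)
  out
}

#' Ordered weighted averaging of standardized criterion layers
#'
#' Pixel-wise OWA aggregation of aligned, standardized ([0, 1]) criterion
#' layers under importance weights and the quantifier exponent `x`. Layers
#' are matched to weights by name; a cell masked in any input is masked in
#' the output.
#'
#' @param layers named list of standardized [grid_layer]s on a common grid.
#' @param w named importance [weight_vector()] covering every layer.
#' @param x quantifier exponent (> 0); 1 reproduces the weighted linear
#'   combination.
#' @return [grid_layer] named `"risk"` with values in [0, 1].
#' @export
owa_aggregate <- function(layers, w, x = 1) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  w <- weight_vector(w)
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- vapply(layers, function(l) l$name, character(1))
  missing <- setdiff(names(w), names(layers))
  if (length(missing))
    stop("no layer supplied for criterion: ",
         paste(missing, collapse = ", "), call. = FALSE)
  layers <- layers[names(w)]
  ref <- layers[[1]]
  for (l in layers) {
    if (!same_grid(l, ref))
      stop("layer '", l$name, "' is not aligned with '", ref$name,
           "' (run align() first)", call. = FALSE)
    rng <- suppressWarnings(range(l$values, na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
      stop("layer '", l$name, "' is not standardized to [0, 1]",
           call. = FALSE)
  }
  Z <- vapply(layers, function(l) as.vector(l$values),
              numeric(length(ref$values)))
  vals <- owa_apply(Z, unname(w), x)
  grid_layer(matrix(vals, nrow = nrow(ref$values)), origin = ref$origin,
             cell_size = ref$cell_size, name = "risk", crs = ref$crs)
}

#' Classify a risk surface into ordered classes
#'
#' Cuts an aggregated [0, 1] risk surface into `n_classes` ordered classes,
#' either at fixed equal intervals (`k / n_classes`) or at empirical
#' quantiles of the unmasked cells. A constant surface cannot be cut by
#' quantiles; the error suggests the equal-interval scheme instead.
#'
#' @param surface [grid_layer] with values in [0, 1].
#' @param scheme `"equal"` (equal interval) or `"quantile"`.
#' @param n_classes number of classes (default 5).
#' @param labels optional class labels, lowest risk first; defaults to
#'   very-low .. very-high for 5 classes, `class i` otherwise.
#' @return object of class `risk_map`: the surface, an integer class layer,
#'   the interior breaks, labels and per-class cell counts.
#' @export
classify_risk <- function(surface, scheme = c("equal", "quantile"),
                          n_classes = 5L, labels = NULL) {
  stopifnot(is_grid_layer(surface))
  scheme <- match.arg(scheme)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  v <- surface$values
  vv <- v[!is.na(v)]
  if (!length(vv)) stop("surface is entirely nodata", call. = FALSE)
  if (min(vv) < -1e-9 || max(vv) > 1 + 1e-9)
    stop("risk surface must lie in [0, 1]", call. = FALSE)
  if (scheme == "equal") {
    breaks <- seq_len(n_classes - 1L) / n_classes
  } else {
    breaks <- unname(stats::quantile(vv, probs = seq_len(n_classes - 1L) /
                                       n_classes))
    if (any(diff(breaks) <= 0))
      stop("degenerate quantile breaks (surface nearly constant); ",
           "use scheme = \"equal\"", call. = FALSE)
  }
  cls <- matrix(findInterval(v, breaks, left.open = TRUE) + 1L,
                nrow = nrow(v))
  cls[is.na(v)] <- NA_integer_
  if (is.null(labels)) {
    labels <- if (n_classes == 5L)
      c("very-low", "low", "moderate", "high", "very-high")
    else paste0("class ", seq_len(n_classes))
  }
  if (length(labels) != n_classes)
    stop("need one label per class", call. = FALSE)
  counts <- tabulate(cls[!is.na(cls)], nbins = n_classes)
  names(counts) <- labels
  structure(list(surface = surface,
                 classes = grid_layer(cls + 0, origin = surface$origin,
                                      cell_size = surface$cell_size,
                                      name = "risk_class",
                                      crs = surface$crs),
                 breaks = breaks, labels = labels, scheme = scheme,
                 n_classes = n_classes, counts = counts),
            class = "risk_map")
}

#' @method print risk_map
#' @export
print.risk_map <- function(x, ...) {
  cat(sprintf("<risk_map> %d classes (%s breaks)\n", x$n_classes,
              if (x$scheme == "equal") "equal-interval" else "quantile"))
  cat("  breaks:", paste(sprintf("%.4g", x$breaks), collapse = ", "), "\n")
  tot <- sum(x$counts)
  for (i in seq_along(x$counts))
    cat(sprintf("  %-10s %7d cells (%5.1f%%)\n", x$labels[i], x$counts[i],
                100 * x$counts[i] / tot))
  invisible(x)
}

#' @method plot risk_map
#' @export
plot.risk_map <- function(x, ...) {
  v <- x$classes$values
  image(t(v[nrow(v):1, , drop = FALSE]), axes = FALSE,
        col = grDevices::hcl.colors(x$n_classes, "YlOrRd", rev = TRUE),
        main = "risk classes", ...)
  invisible(x)
}
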