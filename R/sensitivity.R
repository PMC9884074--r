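#' Sample perturbed weight vectors
#'
#' Draws each criterion weight independently from
#' `U(w (1 - p), w (1 + p))` around the reference. The raw draws are
#' returned un-normalized: the instability statistic [mcs_instability()] is
#' defined on raw deviations, while any model consuming the draws (OWA,
#' Sobol evaluators) renormalizes internally.
#'
#' @param reference named positive reference weights.
#' @param n number of draws.
#' @param perturbation relative half-width `p` in (0, 1].
#' @return `n` x `k` matrix of raw sampled weights, columns named.
#' @export
sample_weights <- function(reference, n, perturbation = 0.2) {
  reference <- weight_vector(reference)
  if (!is.numeric(perturbation) || perturbation <= 0 || perturbation > 1)
    stop("'perturbation' must lie in (0, 1]", call. = FALSE)
  k <- length(reference)
  eps <- matrix(stats::runif(n * k, -perturbation, perturbation), nrow = n)
  s <- sweep(1 + eps, 2L, reference, `*`)
  colnames(s) <- names(reference)
  s
}

#' Monte-Carlo weight-instability statistic
#'
#' `T = sqrt(mean((delta / w_ref)^2))` over all sampled components, where
#' `delta` is the deviation of a sampled weight from its reference. `T` is a
#' dimensionless coefficient: 0 when every draw equals the reference, 1 when
#' every draw doubles it, and `p / sqrt(3)` in expectation under uniform
#' `+/- p` relative perturbation.
#'
#' @param samples matrix of sampled weight vectors (rows = draws), as from
#'   [sample_weights()].
#' @param reference the reference weights the draws perturb.
#' @return numeric scalar `T >= 0`.
#' @export
mcs_instability <- function(samples, reference) {
  reference <- weight_vector(reference)
  samples <- as.matrix(samples)
  if (ncol(samples) != length(reference))
    stop("sample columns must match the reference weights", call. = FALSE)
  if (!is.null(colnames(samples)))
    samples <- samples[, names(reference), drop = FALSE]
  if (any(reference == 0))
    stop("reference weights must be nonzero", call. = FALSE)
  rel <- sweep(samples, 2L, reference, `-`)
  rel <- sweep(rel, 2L, reference, `/`)
  sqrt(mean(rel^2))
}

#' Variance-based (Sobol) sensitivity indices
#'
#' Estimates first-order (`S`) and total-effect (`ST`) indices of a scalar
#' model output with respect to independently perturbed input factors, using
#' the paired-matrix (Saltelli) design: with base samples `A`, `B` and the
#' hybrids `AB_i` (column `i` of `A` replaced from `B`),
#' `S_i = mean(f(B) (f(AB_i) - f(A))) / V` and, by Jansen's estimator,
#' `ST_i = mean((f(A) - f(AB_i))^2) / (2 V)`. `S_i` is the fraction of output
#' variance attributable to factor `i` alone; `ST_i` adds all interactions
#' involving it, so `ST_i >= S_i` up to estimator noise, with equality for an
#' additive model. The model receives the raw factor draws; if the factors
#' are weights that must sum to 1, the model is expected to renormalize
#' internally (this induces mild correlation between factors, a documented
#' departure from the independence the decomposition assumes).
#'
#' @param model function taking an `n x k` factor matrix and returning `n`
#'   scalars; must be deterministic given its input.
#' @param reference named reference factor values (centers of perturbation).
#' @param perturbation relative half-width of the uniform factor ranges.
#' @param n_base number of base samples per matrix (total model evaluations
#'   `n_base * (k + 2)`); default 1024.
#' @param seed optional integer seed applied before sampling.
#' @return list with named numeric vectors `S` and `ST`, the output variance
#'   `V`, and `n_base`. Raw (unclipped) estimates are returned; values
#'   marginally outside [0, 1] are estimator noise.
#' @export
sobol_indices <- function(model, reference, perturbation = 0.2,
                          n_base = 1024L, seed = NULL) {
  reference <- weight_vector(reference)
  n_base <- as.integer(n_base)
  if (n_base < 64L) stop("'n_base' must be at least 64", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  k <- length(reference)
  A <- sample_weights(reference, n_base, perturbation)
  B <- sample_weights(reference, n_base, perturbation)
  fA <- eval_model(model, A, n_base)
  fB <- eval_model(model, B, n_base)
  V <- stats::var(c(fA, fB))
  if (!is.finite(V) || V <= 0)
    stop("model output has zero variance; indices are undefined",
         call. = FALSE)
  S <- ST <- numeric(k)
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    fABi <- eval_model(model, ABi, n_base)
    S[i] <- mean(fB * (fABi - fA)) / V
    ST[i] <- mean((fA - fABi)^2) / (2 * V)
  }
  names(S) <- names(ST) <- names(reference)
  list(S = S, ST = ST, V = V, n_base = n_base)
}

eval_model <- function(model, W, n) {
  y <- model(W)
  if (length(y) != n || any(!is.finite(y)))
    stop("model must return one finite value per factor-matrix row",
         call. = FALSE)
  as.numeric(y)
}

#' Average shift in ranks
#'
#' Mean absolute difference between a reference ranking and a perturbed
#' ranking of the same options: `ASR = (1/n) sum |rank_ref - rank|`. 0 means
#' the ranking is unchanged; a full reversal of 4 options gives 2; a single
#' adjacent swap among `n` options gives `2/n`.
#'
#' @param ref_ranks,new_ranks integer permutations of `1..n`; when both are
#'   named they are matched by option name.
#' @return numeric scalar in `[0, n - 1]`.
#' @export
average_shift_in_ranks <- function(ref_ranks, new_ranks) {
  if (length(ref_ranks) != length(new_ranks))
    stop("rankings must cover the same options", call. = FALSE)
  if (!is.null(names(ref_ranks)) && !is.null(names(new_ranks))) {
    if (!setequal(names(ref_ranks), names(new_ranks)))
      stop("rankings name different option sets", call. = FALSE)
    new_ranks <- new_ranks[names(ref_ranks)]
  }
  n <- length(ref_ranks)
  for (r in list(ref_ranks, new_ranks))
    if (!setequal(as.integer(r), seq_len(n)))
      stop("each ranking must be a permutation of 1..n", call. = FALSE)
  mean(abs(as.integer(ref_ranks) - as.integer(new_ranks)))
}

#' Rank-stability surfaces from repeated risk evaluations
#'
#' Given risk values at a set of sampled locations across many simulation
#' runs, ranks the locations within each run (rank 1 = highest risk), takes
#' per-location minimum, maximum, mean and standard deviation of the rank
#' across runs, and completes each statistic to a full surface by
#' inverse-distance interpolation.
#'
#' @param values `runs x locations` matrix of risk values.
#' @param x,y coordinates of the sampled locations (projected meters).
#' @param template [grid_layer] defining the output surfaces.
#' @param power,max_neighbors IDW parameters passed to [idw_interpolate()].
#' @return named list of four [grid_layer]s: `min`, `max`, `mean`, `sd`.
#' @export
rank_stability_surfaces <- function(values, x, y, template, power = 2,
                                    max_neighbors = 12) {
  values <- as.matrix(values)
  if (nrow(values) < 2L)
    stop("rank stability needs at least two runs", call. = FALSE)
  if (ncol(values) != length(x) || length(x) != length(y))
    stop("one coordinate pair per sampled location is required",
         call. = FALSE)
  ranks <- t(apply(values, 1L, function(v) rank(-v, ties.method = "first")))
  stats_tab <- list(
    min = apply(ranks, 2L, min),
    max = apply(ranks, 2L, max),
    mean = colMeans(ranks),
    sd = apply(ranks, 2L, stats::sd))
  out <- lapply(names(stats_tab), function(nm) {
    g <- idw_interpolate(data.frame(x = x, y = y, value = stats_tab[[nm]]),
                         template, power = power,
                         max_neighbors = max_neighbors)
    g$name <- paste0("rank_", nm)
    g
  })
  names(out) <- names(stats_tab)
  attr(out, "ranks") <- ranks
  out
}

# OWA of a fixed membership matrix under many weight vectors. The sort of Z
# does not depend on the weights, so the ordering is computed once.
owa_apply_many <- function(Z, W, x = 1) {
  m <- nrow(Z); k <- ncol(Z)
  stopifnot(ncol(W) == k)
  o <- order(row(Z), -Z, method = "radix")
  zs <- matrix(Z[o], nrow = m, byrow = TRUE)
  ci <- matrix((o - 1L) %/% m + 1L, nrow = m, byrow = TRUE)
  tri <- upper.tri(diag(k), diag = TRUE)
  res <- matrix(NA_real_, nrow(W), m)
  for (r in seq_len(nrow(W))) {
    U <- matrix(W[r, ][ci], nrow = m)
    cum <- U %*% tri
    P <- cum / cum[, k]
    V <- P^x - cbind(0, P[, -k, drop = FALSE])^x
    res[r, ] <- rowSums(V * zs)
  }
  res
}

#' Monte-Carlo weight-uncertainty analysis of an OWA risk model
#'
#' Perturbs the criterion weights `n_runs` times with independent uniform
#' relative noise, re-evaluates the OWA risk surface at a random subset of
#' unmasked cells for every draw, and summarizes the consequences of weight
#' uncertainty three ways: the instability statistic `T`
#' ([mcs_instability()]), the distribution of the average shift in the
#' criterion ranking ([average_shift_in_ranks()] with criteria as options,
#' ranked by weight), and per-location rank-stability surfaces
#' ([rank_stability_surfaces()]).
#'
#' @param layers named list of standardized, aligned [grid_layer]s.
#' @param w reference [weight_vector()].
#' @param x OWA quantifier exponent.
#' @param n_runs number of Monte-Carlo draws (default 10000).
#' @param perturbation relative half-width of the weight perturbation
#'   (default 0.2, i.e. +/- 20 %).
#' @param n_points number of cells sampled for the rank-stability analysis.
#' @return object of class `weight_sensitivity` with elements `T`, `asr`
#'   (per-run ASR of the criterion ranking), `rank_layers`, `samples_summary`
#'   and the call parameters.
#' @export
weight_uncertainty <- function(layers, w, x = 1, n_runs = 10000L,
                               perturbation = 0.2, n_points = 150L) {
  w <- weight_vector(w)
  if (n_runs < 2L) stop("'n_runs' must be at least 2", call. = FALSE)
  layers <- layers[names(w)]
  ref <- layers[[1]]
  Zfull <- vapply(layers, function(l) as.vector(l$values),
                  numeric(length(ref$values)))
  ok <- which(rowSums(is.na(Zfull)) == 0L)
  n_points <- min(as.integer(n_points), length(ok))
  if (n_points < 2L) stop("not enough unmasked cells", call. = FALSE)
  pick <- sort(sample(ok, n_points))
  Z <- Zfull[pick, , drop = FALSE]
  cc <- cell_centers(ref)
  d <- dim(ref$values)
  rows <- (pick - 1L) %% d[1] + 1L
  cols <- (pick - 1L) %/% d[1] + 1L
  S <- sample_weights(w, n_runs, perturbation)
  Tstat <- mcs_instability(S, w)
  ref_rank <- rank(-w, ties.method = "first")
  asr <- apply(S, 1L, function(s)
    average_shift_in_ranks(ref_rank, rank(-s, ties.method = "first")))
  Snorm <- S / rowSums(S)
  vals <- owa_apply_many(Z, Snorm, x)
  rl <- rank_stability_surfaces(vals, x = cc$x[cols], y = cc$y[rows],
                                template = ref)
  structure(list(T = Tstat, asr = asr, rank_layers = rl,
                 points = data.frame(x = cc$x[cols], y = cc$y[rows]),
                 reference = w, x = x, n_runs = n_runs,
                 perturbation = perturbation, n_points = n_points),
            class = "weight_sensitivity")
}

#' @method print weight_sensitivity
#' @export
print.weight_sensitivity <- function(x, ...) {
  cat(sprintf("<weight_sensitivity> %d runs, +/-%.0f%% uniform perturbation\n",
              x$n_runs, 100 * x$perturbation))
  cat(sprintf("  instability T          : %.4f\n", x$T))
  cat(sprintf("  criterion-rank ASR     : mean %.3f (max %.3f)\n",
              mean(x$asr), max(x$asr)))
  cat(sprintf("  rank surfaces          : %d sampled locations\n",
              x$n_points))
  invisible(x)
}

#' Sobol sensitivity of the OWA risk surface to criterion weights
#'
#' Convenience wrapper around [sobol_indices()] whose model maps a raw
#' weight draw to the mean OWA risk over a random subset of unmasked cells
#' (weights renormalized inside the model).
#'
#' @inheritParams weight_uncertainty
#' @param n_base Sobol base sample size (default 512).
#' @param n_points number of cells the risk summary averages over.
#' @return as [sobol_indices()].
#' @export
sobol_owa_sensitivity <- function(layers, w, x = 1, perturbation = 0.2,
                                  n_base = 512L, n_points = 150L) {
  w <- weight_vector(w)
  layers <- layers[names(w)]
  ref <- layers[[1]]
  Zfull <- vapply(layers, function(l) as.vector(l$values),
                  numeric(length(ref$values)))
  ok <- which(rowSums(is.na(Zfull)) == 0L)
  n_points <- min(as.integer(n_points), length(ok))
  Z <- Zfull[sort(sample(ok, n_points)), , drop = FALSE]
  model <- function(W) rowMeans(owa_apply_many(Z, W / rowSums(W), x))
  sobol_indices(model, w, perturbation = perturbation, n_base = n_base)
}
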