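#' Pairwise comparison matrix on the 1-9 judgment scale
#'
#' Validates an expert judgment matrix: square, positive, unit diagonal,
#' reciprocal (`a[j, i] == 1 / a[i, j]`), entries within [1/9, 9]. Row and
#' column names, when present, carry the criterion identities.
#'
#' @param a numeric square matrix of judgments.
#' @param tol reciprocity tolerance.
#' @return the validated matrix with class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(a, tol = 1e-9) {
  a <- as.matrix(a)
  n <- nrow(a)
  if (n != ncol(a) || n < 2L)
    stop("a pairwise matrix must be square with n >= 2", call. = FALSE)
  if (any(!is.finite(a)) || any(a <= 0))
    stop("pairwise judgments must be positive and finite", call. = FALSE)
  if (any(abs(diag(a) - 1) > tol))
    stop("pairwise matrix diagonal must be 1", call. = FALSE)
  if (any(abs(a * t(a) - 1) > tol * pmax(a, t(a))^2))
    stop("pairwise matrix is not reciprocal (a[j,i] != 1/a[i,j])",
         call. = FALSE)
  if (any(a < 1 / 9 - tol | a > 9 + tol))
    stop("judgments must lie on the 1/9..9 scale", call. = FALSE)
  class(a) <- c("pairwise_matrix", class(a))
  a
}

#' Aggregate expert judgment matrices
#'
#' Combines several experts' pairwise comparison matrices into one group
#' matrix by the element-wise geometric mean — the standard aggregation that
#' preserves reciprocity by construction.
#'
#' @param matrices list of [pairwise_matrix] objects of identical dimension.
#' @return a single `pairwise_matrix`.
#' @export
aggregate_experts <- function(matrices) {
  if (inherits(matrices, "pairwise_matrix")) matrices <- list(matrices)
  if (length(matrices) == 0L)
    stop("no matrices to aggregate", call. = FALSE)
  matrices <- lapply(matrices, pairwise_matrix)
  n <- nrow(matrices[[1]])
  if (!all(vapply(matrices, nrow, integer(1)) == n))
    stop("all expert matrices must have the same dimension", call. = FALSE)
  logsum <- Reduce(`+`, lapply(matrices, log))
  g <- exp(logsum / length(matrices))
  dimnames(g) <- dimnames(matrices[[1]])
  diag(g) <- 1                      # exact, not exp(mean(log(1))) noise
  pairwise_matrix(g)
}

#' Principal-eigenvector criterion weights
#'
#' Computes importance weights as the normalized principal right eigenvector
#' of a pairwise comparison matrix, by power iteration to a relative
#' tolerance of 1e-10. For a perfectly consistent matrix
#' (`a[i, j] = w_i / w_j`) this recovers `w` exactly.
#'
#' @param m a [pairwise_matrix].
#' @param max_iter iteration cap before a non-convergence error.
#' @return named numeric weight vector summing to 1, with the principal
#'   eigenvalue attached as attribute `lambda_max`.
#' @export
eigen_weights <- function(m, max_iter = 1000L) {
  m <- pairwise_matrix(unclass(m))
  n <- nrow(m)
  w <- rep(1 / n, n)
  lambda <- NA_real_
  for (it in seq_len(max_iter)) {
    v <- as.vector(m %*% w)
    lambda_new <- sum(v) / sum(w)
    v <- v / sum(v)
    if (max(abs(v - w)) < 1e-10 * max(v)) {
      w <- v; lambda <- lambda_new
      attr(w, "lambda_max") <- lambda
      names(w) <- rownames(m)
      return(w)
    }
    w <- v; lambda <- lambda_new
  }
  stop("power iteration did not converge after ", max_iter, " iterations",
       call. = FALSE)
}

# Saaty random consistency indices for n = 1..15.
saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
              1.51, 1.48, 1.56, 1.57, 1.59)

#' Consistency ratio of a pairwise matrix
#'
#' `CR = ((lambda_max - n) / (n - 1)) / RI(n)` with Saaty's random-index
#' table. A perfectly consistent (transitive) matrix has CR = 0; CR below
#' roughly 0.1 is conventionally considered acceptable. For n < 3 every
#' reciprocal matrix is consistent, so the ratio is 0 and a warning is
#' attached.
#'
#' @param m a [pairwise_matrix].
#' @return numeric scalar; attribute `lambda_max` carries the eigenvalue.
#' @export
consistency_ratio <- function(m) {
  m <- pairwise_matrix(unclass(m))
  n <- nrow(m)
  w <- eigen_weights(m)
  lambda <- attr(w, "lambda_max")
  if (n < 3L) {
    warning("consistency ratio is undefined for n < 3; returning 0")
    cr <- 0
  } else {
    if (n > length(saaty_ri))
      stop("random-index table covers n <= ", length(saaty_ri), call. = FALSE)
    ci <- (lambda - n) / (n - 1)
    cr <- ci / saaty_ri[n]
    if (abs(cr) < 1e-12) cr <- 0    # clean up numerically-consistent cases
  }
  attr(cr, "lambda_max") <- lambda
  cr
}

#' Validate (and optionally renormalize) a criterion weight vector
#'
#' @param w named numeric vector of positive weights.
#' @param renormalize if `TRUE` (default), scale to sum exactly 1; if
#'   `FALSE`, a sum off by more than 1e-9 is an error.
#' @return named numeric vector summing to 1.
#' @export
weight_vector <- function(w, renormalize = TRUE) {
  w <- unlist(w)
  if (is.null(names(w)) || any(!nzchar(names(w))))
    stop("weights must be named by criterion", call. = FALSE)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  s <- sum(w)
  if (renormalize) w <- w / s
  else if (abs(s - 1) > 1e-9)
    stop("weights must sum to 1 (got ", format(s), ")", call. = FALSE)
  w
}

#' Published reference weights and sensitivity indices
#'
#' Loads the packaged table of expert-derived (fuzzy analytic network
#' process) criterion weights for the eleven salt-dust vulnerability
#' criteria, together with the first-order (`s_first`) and total-effect
#' (`s_total`) sensitivity indices reported for them. The printed weights sum
#' to about 0.99; they are renormalized to sum exactly 1 on load so that they
#' satisfy the weight-vector contract.
#'
#' @param renormalize renormalize the weight column to sum 1 (default TRUE).
#' @return data frame with columns `criterion`, `group`, `weight`,
#'   `s_first`, `s_total`; the weight column (named by criterion) is also
#'   attached as attribute `weights`.
#' @export
fanp_reference_weights <- function(renormalize = TRUE) {
  path <- system.file("extdata", "fanp_weights.csv", package = "saltrisk",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  w <- tab$weight
  names(w) <- tab$criterion
  if (renormalize) {
    w <- w / sum(w)
    tab$weight <- unname(w)
  }
  attr(tab, "weights") <- w
  tab
}
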