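## R-side wrapper of the compiled KL-NMF engine, plus the fixed-profile
## exposure refit used after consensus clustering.

#' KL non-negative matrix factorization
#'
#' Factorizes a non-negative channels x samples matrix `v` as `W %*% H`
#' by Lee-Seung multiplicative updates minimizing the generalized
#' Kullback-Leibler divergence `D(v || WH)`. The objective is monotone
#' non-increasing across iterations; iteration stops when the relative
#' objective change falls below `tol` or after `maxIter` iterations.
#' Profile columns of `W` are normalized to sum 1 with the compensating
#' rescaling applied to `H`, so `W %*% H` is unchanged.
#'
#' @param v non-negative matrix (96 channels x samples) or a
#'   [`MutationCatalog-class`].
#' @param k number of signatures, `1 <= k <= min(dim(v))`.
#' @param seed integer seed for the random uniform initialization of `W`.
#'   `H` is initialized deterministically from the column sums, which
#'   makes the iteration equivariant under sample (column) permutation.
#' @param maxIter,tol stopping rule (defaults 10000 and 1e-9 relative
#'   change).
#' @param w0,h0 optional explicit initializations (override `seed`).
#' @return List with `w` (96 x k, columns sum to 1), `h` (k x samples),
#'   `objective` (the per-iteration objective trace, first entry the
#'   initial value), `iterations`, `converged`.
#' @export
nmfKL <- function(v, k, seed = 1L, maxIter = 10000L, tol = 1e-9,
                  w0 = NULL, h0 = NULL) {
  if (is(v, "MutationCatalog")) v <- counts(v)
  v <- as.matrix(v)
  if (!all(is.finite(v))) stop("matrix must be finite", call. = FALSE)
  if (any(v < 0)) stop("matrix must be non-negative", call. = FALSE)
  if (k < 1L || k > min(dim(v)))
    stop("k must lie in 1..min(dim(v))", call. = FALSE)
  if (sum(v) == 0) stop("matrix must not be all zero", call. = FALSE)
  if (is.null(w0)) {
    set.seed(seed)
    w0 <- matrix(runif(nrow(v) * k, 0.1, 1), nrow(v), k)
    w0 <- sweep(w0, 2, colSums(w0), "/")
  }
  if (is.null(h0))
    h0 <- matrix(rep(colSums(v) / k, each = k), k, ncol(v))
  fit <- nmf_kl_engine(v, w0, h0, as.integer(maxIter), tol, TRUE)
  .normalizeWH(fit, colnames(v))
}

.normalizeWH <- function(fit, sample_names) {
  w <- fit$w; h <- fit$h
  s <- colSums(w)
  s[s == 0] <- 1
  w <- sweep(w, 2, s, "/")
  h <- h * s
  rownames(w) <- channelLabels()
  colnames(h) <- sample_names
  list(w = w, h = h, objective = fit$objective,
       iterations = fit$iterations, converged = fit$converged)
}

## Non-negative KL fit of exposures with fixed profiles (H update only).
.fitExposures <- function(v, w, maxIter = 10000L, tol = 1e-9) {
  k <- ncol(w)
  h0 <- matrix(rep(colSums(v) / k, each = k), k, ncol(v))
  fit <- nmf_kl_engine(v, w, h0, as.integer(maxIter), tol, FALSE)
  h <- fit$h
  colnames(h) <- colnames(v)
  list(h = h, error = fit$objective[length(fit$objective)])
}
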