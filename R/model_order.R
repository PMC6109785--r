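#' Laplace-approximated evidence of a probabilistic PCA model
#'
#' Computes, from an eigen-spectrum, the log Bayesian evidence of a
#' probabilistic principal component model with `k` retained components,
#' using the Laplace approximation (Stiefel-manifold prior on the
#' component subspace, residual variance profiled out).
#'
#' @param lambda eigenvalues of the sample covariance, decreasing.
#' @param n_obs number of observations the covariance was formed from.
#' @param k number of retained components (`1 <= k <= length(lambda) - 1`).
#' @return log evidence (up to k-independent constants).
#' @export
ppca_log_evidence <- function(lambda, n_obs, k) {
  d <- length(lambda)
  stopifnot(k >= 1, k <= d - 1)
  N <- n_obs
  sigma2 <- mean(lambda[(k + 1):d])
  # an exactly low-rank spectrum makes the evidence unbounded at the rank
  if (sigma2 <= max(lambda) * d * .Machine$double.eps) return(Inf)
  m <- d * k - k * (k + 1) / 2
  i <- seq_len(k)
  log_pU <- -k * log(2) +
    sum(lgamma((d - i + 1) / 2) - ((d - i + 1) / 2) * log(pi))
  lam_hat <- c(lambda[seq_len(k)], rep(sigma2, d - k))
  log_Az <- 0
  for (ii in seq_len(k)) {
    jj <- (ii + 1):d
    terms <- (1 / lam_hat[jj] - 1 / lam_hat[ii]) * (lambda[ii] - lambda[jj]) * N
    terms[terms <= 0] <- .Machine$double.eps
    log_Az <- log_Az + sum(log(terms))
  }
  log_pU -
    (N / 2) * sum(log(lambda[seq_len(k)])) -
    (N * (d - k) / 2) * log(sigma2) +
    ((m + k) / 2) * log(2 * pi) -
    log_Az / 2 -
    (k / 2) * log(N)
}

#' Automatic model-order selection for decomposition
#'
#' Selects the number of signal components in a samples-by-voxels data
#' matrix as the order maximizing the Laplace-approximated evidence of a
#' probabilistic PCA model, evaluated on the eigen-spectrum of the
#' sample-dimension covariance. Candidate orders run from 1 to
#' `min(samples - 2, max_order)`; rank-deficient spectra are truncated to
#' the numerical rank with a warning.
#'
#' @param concat_data samples x voxels matrix (voxels > samples).
#' @param max_order cap on the candidate order search.
#' @return the selected order (integer) with the evidence curve attached as
#'   attribute `"evidence"`.
#' @export
estimate_model_order <- function(concat_data, max_order = 40) {
  d <- nrow(concat_data); N <- ncol(concat_data)
  if (d < 10) stop("need at least 10 samples")
  if (N <= d) stop("need more voxels than samples")
  X <- concat_data - rowMeans(concat_data)
  lambda <- sort(eigen(tcrossprod(X) / N, symmetric = TRUE,
                       only.values = TRUE)$values, decreasing = TRUE)
  tol <- max(lambda) * d * .Machine$double.eps
  rank <- sum(lambda > tol)
  if (rank < d)
    warning(sprintf("rank-deficient input (numerical rank %d of %d); evidence computed up to the rank",
                    rank, d))
  ks <- seq_len(min(rank, d - 2, max_order))
  ev <- vapply(ks, function(k) ppca_log_evidence(lambda, N, k), numeric(1))
  out <- ks[which.max(ev)]
  attr(out, "evidence") <- stats::setNames(ev, ks)
  out
}
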