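#' Multivariate autoregressive (MVAR) model
#'
#' Container for an order-`p` MVAR process
#' \deqn{x(t) = \sum_{j=1}^{p} B_j x(t-j) + e(t)}
#' with K-channel coefficient matrices \eqn{B_j} and innovation covariance
#' \eqn{\Sigma_e}. Some texts write the recursion with a leading minus and
#' matrices \eqn{A_j}; this package standardizes on the plus convention
#' (\eqn{B_j = -A_j}) everywhere: generator, estimator and oracles share it.
#'
#' @param coefs list of K x K coefficient matrices `B_j`, one per lag
#'   (possibly empty for a pure-noise model)
#' @param noise_cov K x K symmetric positive semi-definite innovation
#'   covariance
#' @param sampling_rate sampling rate in Hz
#' @return object of class `mvar_model` with fields `order`, `coefs`,
#'   `noise_cov`, `sampling_rate`
#' @examples
#' m <- mvar_model(list(matrix(c(0.5, 0, 0.3, 0.4), 2, 2)), diag(2), 1250)
#' mvar_spectral_radius(m)
#' @export
mvar_model <- function(coefs, noise_cov, sampling_rate) {
  assert_that(is.list(coefs), "coefs must be a list of K x K matrices")
  K <- nrow(noise_cov)
  assert_that(is.matrix(noise_cov) && ncol(noise_cov) == K,
              "noise_cov must be a square matrix")
  for (B in coefs) {
    assert_that(is.matrix(B) && all(dim(B) == K) && all(is.finite(B)),
                "every coefficient matrix must be finite K x K")
  }
  assert_that(max(abs(noise_cov - t(noise_cov))) < 1e-8,
              "noise_cov must be symmetric")
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) > -1e-8 * max(abs(ev), 1),
              "noise_cov must be positive semi-definite")
  assert_that(is.numeric(sampling_rate) && sampling_rate > 0,
              "sampling_rate must be positive")
  structure(list(order = length(coefs), coefs = coefs,
                 noise_cov = (noise_cov + t(noise_cov)) / 2,
                 sampling_rate = sampling_rate),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("MVAR model: K = %d channels, order p = %d, fs = %g Hz\n",
              nrow(x$noise_cov), x$order, x$sampling_rate))
  cat(sprintf("  companion spectral radius: %.4f\n", mvar_spectral_radius(x)))
  invisible(x)
}

# companion (stacked) form of the coefficient matrices
companion_matrix <- function(model) {
  K <- nrow(model$noise_cov); p <- model$order
  if (p == 0) return(matrix(0, K, K))
  C <- matrix(0, K * p, K * p)
  for (j in seq_len(p)) C[1:K, ((j - 1) * K + 1):(j * K)] <- model$coefs[[j]]
  if (p > 1) C[(K + 1):(K * p), 1:(K * (p - 1))] <- diag(K * (p - 1))
  C
}

#' Companion-matrix spectral radius of an MVAR model
#'
#' The process is (asymptotically) stationary iff the spectral radius of the
#' companion matrix is strictly below one.
#'
#' @param model an [mvar_model()]
#' @return largest eigenvalue modulus of the companion matrix
#' @export
mvar_spectral_radius <- function(model) {
  if (model$order == 0) return(0)
  max(Mod(eigen(companion_matrix(model), only.values = TRUE)$values))
}

#' Check MVAR stability
#'
#' @param model an [mvar_model()]
#' @param tol stability margin; radius must be below `1 - tol`
#' @return `TRUE`/`FALSE`
#' @export
mvar_is_stable <- function(model, tol = 1e-8) {
  mvar_spectral_radius(model) < 1 - tol
}
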