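# Loss components shared by the three autoencoder variants: L1 and MSE
# reconstruction errors, the closed-form Gaussian KL divergence, the
# reparameterization trick, and the empirical sliced-Wasserstein distance.

#' L1 reconstruction loss
#'
#' Sum of absolute per-pixel differences between an image and its
#' reconstruction (the plain-autoencoder training objective). The
#' `"mean"` reduction divides by the pixel count, making values comparable
#' across image sizes; the sum is recovered by multiplying back.
#'
#' @param x,xhat images (or arbitrary equal-shape numeric arrays).
#' @param reduction `"sum"` (default) or `"mean"`.
#' @return Non-negative scalar.
#' @examples
#' l1_loss(c(0, 0.5), c(0.25, 0.25))  # 0.5
#' @export
l1_loss <- function(x, xhat, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  check_same_shape(x, xhat, "x", "xhat")
  s <- sum(abs(x - xhat))
  if (reduction == "mean") s / length(x) else s
}

#' Mean-squared-error reconstruction loss
#'
#' `(1/n) * sum((x - xhat)^2)`, the per-pixel MSE used as the
#' sliced-Wasserstein autoencoder's reconstruction term.
#'
#' @inheritParams l1_loss
#' @return Non-negative scalar.
#' @export
mse_loss <- function(x, xhat) {
  check_same_shape(x, xhat, "x", "xhat")
  mean((x - xhat)^2)
}

#' Closed-form KL divergence of a diagonal Gaussian from the standard normal
#'
#' `KL(N(mu, diag(sigma^2)) || N(0, I)) =
#'  -1/2 * sum(1 + log(sigma^2) - mu^2 - sigma^2)`,
#' the regularization term of the variational autoencoder. Non-negative,
#' and zero exactly when `mu = 0`, `sigma = 1`.
#'
#' @param mu mean vector.
#' @param sigma standard-deviation vector, strictly positive.
#' @return Non-negative scalar.
#' @examples
#' kld_gaussian(0, 1)   # 0
#' kld_gaussian(1, 1)   # 0.5
#' @export
kld_gaussian <- function(mu, sigma) {
  if (length(mu) != length(sigma))
    stop_invalid("mu and sigma must have equal length")
  if (any(!is.finite(mu)) || any(!is.finite(sigma)) || any(sigma <= 0))
    stop_invalid("sigma must be strictly positive and finite")
  -0.5 * sum(1 + 2 * log(sigma) - mu^2 - sigma^2)
}

#' Reparameterization trick
#'
#' Draws `z = mu + eps * sigma` with `eps ~ N(0, I)`, the differentiable
#' sampling used by the variational autoencoder.
#'
#' @param mu mean vector.
#' @param sigma standard-deviation vector, strictly positive.
#' @param seed optional integer seed for a reproducible draw; `NULL` uses
#'   the current RNG stream.
#' @return Numeric vector of the same length as `mu`.
#' @export
reparameterize <- function(mu, sigma, seed = NULL) {
  if (length(mu) != length(sigma))
    stop_invalid("mu and sigma must have equal length")
  if (any(sigma <= 0)) stop_invalid("sigma must be strictly positive")
  eps <- if (is.null(seed)) rnorm(length(mu))
         else with_seed(seed, rnorm(length(mu)))
  mu + eps * sigma
}

#' Empirical sliced-Wasserstein distance (squared W2, sort-based)
#'
#' Monte-Carlo estimate of the squared sliced 2-Wasserstein distance
#' between two equal-size point sets: both sets are projected onto
#' `n_projections` uniformly random unit directions and, per direction, the
#' exact 1-D squared W2 between the projected empirical distributions is
#' computed by sorting and matching order statistics; the result is the
#' average over directions. Sorting solves the 1-D optimal transport
#' problem exactly, so no explicit transport plan is needed. Restricted to
#' equal sample counts, the setting in which a latent batch is matched to a
#' same-size draw from the prior.
#'
#' @param A,B numeric matrices with one point per row (vectors are taken as
#'   one-dimensional samples); `nrow(A) == nrow(B)` required.
#' @param n_projections number of random directions (>= 1).
#' @param seed integer seed for the directions.
#' @param power transport cost exponent; only 2 is implemented.
#' @return Non-negative scalar; exactly 0 when `A` and `B` coincide as
#'   multisets.
#' @examples
#' sliced_wasserstein(c(0, 2), c(1, 3))  # 1
#' @export
sliced_wasserstein <- function(A, B, n_projections = 50, seed = 1, power = 2) {
  if (power != 2) stop_invalid("only power = 2 is implemented")
  if (is.vector(A)) A <- matrix(A, ncol = 1)
  if (is.vector(B)) B <- matrix(B, ncol = 1)
  if (nrow(A) != nrow(B))
    stop_invalid("A and B must contain the same number of points")
  if (ncol(A) != ncol(B))
    stop_invalid("A and B must have the same dimension")
  if (n_projections < 1) stop_invalid("n_projections must be >= 1")
  theta <- with_seed(seed, random_directions(ncol(A), n_projections))
  pa <- A %*% theta
  pb <- B %*% theta
  sa <- apply(pa, 2, sort)
  sb <- apply(pb, 2, sort)
  mean((sa - sb)^2)
}

# d x L matrix of uniform unit directions (draws from the current stream)
random_directions <- function(d, L) {
  th <- matrix(rnorm(d * L), d, L)
  nrm <- sqrt(colSums(th^2))
  nrm[nrm == 0] <- 1
  sweep(th, 2, nrm, "/")
}

#' Variational-autoencoder loss
#'
#' L1 reconstruction error (sum form) plus `beta` times the closed-form
#' Gaussian KL divergence of the posterior from the standard-normal prior.
#'
#' @param x,xhat input image and reconstruction.
#' @param mu,sigma posterior mean and standard deviation.
#' @param beta KL weight (>= 0).
#' @return Scalar loss.
#' @export
vae_loss <- function(x, xhat, mu, sigma, beta = 1) {
  if (beta < 0) stop_invalid("beta must be >= 0")
  l1_loss(x, xhat) + beta * kld_gaussian(mu, sigma)
}

#' Sliced-Wasserstein-autoencoder loss
#'
#' Per-pixel MSE over the batch plus `lambda` times the sliced-Wasserstein
#' distance between the encoded latent batch and an equal-size draw from
#' the standard-normal prior.
#'
#' @param x_batch,xhat_batch equal-shape arrays holding the batch and its
#'   reconstructions.
#' @param z_batch latent codes, one row per batch element.
#' @param lambda prior-matching weight (>= 0).
#' @param n_projections,seed passed to [sliced_wasserstein()]; `seed` also
#'   seeds the prior draw.
#' @param prior_sample optional explicit prior sample (same shape as
#'   `z_batch`) replacing the internal standard-normal draw.
#' @return Scalar loss.
#' @export
swae_loss <- function(x_batch, xhat_batch, z_batch, lambda = 10,
                      n_projections = 50, seed = 1, prior_sample = NULL) {
  if (lambda < 0) stop_invalid("lambda must be >= 0")
  check_same_shape(x_batch, xhat_batch, "x_batch", "xhat_batch")
  if (is.vector(z_batch)) z_batch <- matrix(z_batch, ncol = 1)
  if (is.null(prior_sample))
    prior_sample <- with_seed(derive_seed(seed, "prior"),
                              matrix(rnorm(length(z_batch)), nrow(z_batch)))
  check_same_shape(z_batch, prior_sample, "z_batch", "prior_sample")
  mse_loss(x_batch, xhat_batch) +
    lambda * sliced_wasserstein(z_batch, prior_sample,
                                n_projections = n_projections, seed = seed)
}
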