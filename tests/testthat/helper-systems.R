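# Shared generators for random test systems.  Everything is built in code
# under explicit seeds; no stored fixtures.

random_spd <- function(d, jitter = 1) {
  A <- matrix(rnorm(d * d), d, d)
  crossprod(A) / d + jitter * diag(d)
}

random_antisym <- function(d, scale = 0.5) {
  A <- matrix(rnorm(d * d, sd = scale), d, d)
  A - t(A)
}

# SPD matrix with H[mu, eta] = 0 so that internal and external states are
# conditionally independent given the blanket (exact for Gaussians).
random_blanket_spd <- function(part, scale = 0.4) {
  d <- part$dim
  A <- matrix(rnorm(d * d, sd = scale), d, d)
  S <- (A + t(A)) / 2
  S[part$mu, part$eta] <- 0
  S[part$eta, part$mu] <- 0
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  S + diag(abs(ev) + 1, d)
}

# Quick 4-state partition (1 state per role).
part4 <- function() state_partition(eta = 1L, s = 2L, a = 3L, mu = 4L, dim = 4L)

# Partial correlation of variables i and j given the set k, from a sample
# covariance matrix (Schur-complement / precision route).
sample_partial_cor <- function(X, i, j, k) {
  S <- stats::cov(X[, c(i, j, k), drop = FALSE])
  P <- solve(S)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Adaptive-quadrature evaluation of the three free-energy routes for a
# 1-D external state; an oracle wholly independent of the closed forms.
quadrature_free_energy <- function(system, part, pi_value, q) {
  stopifnot(length(part$eta) == 1L)
  b_pos <- match(part$b, part$pi)
  qp <- q$params_of(pi_value[b_pos])
  mq <- qp$mean; vq <- as.numeric(qp$cov)
  dens_q <- function(e) dnorm(e, mq, sqrt(vq))
  joint_surprisal <- function(e) {
    vapply(e, function(ei) {
      x <- numeric(system$dim)
      x[part$eta] <- ei; x[part$pi] <- pi_value
      surprisal(system, x)
    }, numeric(1))
  }
  lim <- c(mq - 12 * sqrt(vq), mq + 12 * sqrt(vq))
  energy <- integrate(function(e) dens_q(e) * joint_surprisal(e),
                      lim[1], lim[2], rel.tol = 1e-10)$value
  entropy <- integrate(function(e) -dens_q(e) * log(dens_q(e)),
                       lim[1], lim[2], rel.tol = 1e-10)$value
  post <- exact_posterior(system, part, pi_value[b_pos])
  bound <- integrate(function(e) dens_q(e) *
                       (log(dens_q(e)) -
                          dnorm(e, post$mean, sqrt(post$cov), log = TRUE)),
                     lim[1], lim[2], rel.tol = 1e-10)$value
  list(energy = energy, entropy = entropy, bound = bound,
       F = energy - entropy)
}
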