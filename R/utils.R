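# Internal numerical helpers shared across modules.

max_abs <- function(x) if (length(x) == 0L) 0 else max(abs(x))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator with `seed`,
#' evaluates `code`, and restores the previous RNG state on exit.  All
#' randomness in the package flows through this helper so that no function
#' mutates global RNG state as a side effect.
#'
#' @param seed Integer seed (must be below 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Antisymmetry defect of a square matrix.
antisymmetry_defect <- function(Q) max_abs(Q + t(Q))

assert_antisymmetric <- function(Q, tol = 1e-10, name = "Q") {
  d <- antisymmetry_defect(Q)
  if (d > tol)
    stopf("%s is not antisymmetric: max|%s + t(%s)| = %.3g exceeds tol %.3g",
          name, name, name, d, tol)
  invisible(TRUE)
}

# Check symmetric positive definiteness; on failure name the offending
# eigenvalue (the smallest one).
assert_spd <- function(H, name = "H", tol = 1e-10) {
  if (!is.matrix(H) || nrow(H) != ncol(H))
    stopf("%s must be a square matrix", name)
  if (max_abs(H - t(H)) > tol)
    stopf("%s is not symmetric: max|%s - t(%s)| = %.3g", name, name, name,
          max_abs(H - t(H)))
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stopf("%s is not positive definite: smallest eigenvalue = %.6g",
          name, min(ev))
  invisible(ev)
}

# Coerce a diffusion specification (scalar, vector, or diagonal matrix) to
# the vector of diagonal entries, validating diagonality and sign.
as_gamma_diag <- function(Gamma, dim, allow_zero = FALSE) {
  if (is.matrix(Gamma)) {
    if (nrow(Gamma) != dim || ncol(Gamma) != dim)
      stopf("Gamma must be %d x %d", dim, dim)
    if (max_abs(Gamma - diag(diag(Gamma), dim)) > 0)
      stopf("Gamma must be diagonal (random fluctuations are independent)")
    g <- diag(Gamma)
  } else {
    g <- rep_len(as.numeric(Gamma), dim)
  }
  if (allow_zero) {
    if (any(g < 0)) stopf("Gamma diagonal entries must be >= 0")
  } else if (any(g <= 0)) {
    stopf("Gamma diagonal entries must be > 0 (got min %.3g); pass allow_deterministic = TRUE for the noiseless testing limit",
          min(g))
  }
  g
}

# Central finite-difference gradient.
num_grad <- function(f, x, h = 1e-5) {
  n <- length(x)
  g <- numeric(n)
  for (i in seq_len(n)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    g[i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  g
}

# Central finite-difference Hessian (symmetrised).
num_hess <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    hi <- h * max(1, abs(x[i])); hj <- h * max(1, abs(x[j]))
    pp <- x; pp[i] <- pp[i] + hi; pp[j] <- pp[j] + hj
    pm <- x; pm[i] <- pm[i] + hi; pm[j] <- pm[j] - hj
    mp <- x; mp[i] <- mp[i] - hi; mp[j] <- mp[j] + hj
    mm <- x; mm[i] <- mm[i] - hi; mm[j] <- mm[j] - hj
    H[i, j] <- H[j, i] <- (f(pp) - f(pm) - f(mp) + f(mm)) / (4 * hi * hj)
  }
  H
}

# Draw n samples from N(mean, Sigma) via the Cholesky factor.
rmvnorm_chol <- function(n, mean, Sigma) {
  d <- length(mean)
  L <- chol(Sigma)
  Z <- matrix(stats::rnorm(n * d), n, d)
  sweep(Z %*% L, 2, mean, `+`)
}

# log-determinant of an SPD matrix via Cholesky.
logdet_spd <- function(S) 2 * sum(log(diag(chol(S))))

# KL divergence between Gaussians N(m0, V0) || N(m1, V1), in nats.
gaussian_kl <- function(m0, V0, m1, V1) {
  k <- length(m0)
  V0 <- as.matrix(V0); V1 <- as.matrix(V1)
  P1 <- solve(V1)
  dm <- m1 - m0
  0.5 * (sum(diag(P1 %*% V0)) + sum(dm * (P1 %*% dm)) - k +
           logdet_spd(V1) - logdet_spd(V0))
}

# Derive a per-stream 31-bit seed from a base seed; keeps values positive
# and below 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 7919 + 17) %%
               2147483629)
}
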