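# Euler--Maruyama integration of NESS systems.

#' Integrate a NESS system by Euler--Maruyama
#'
#' Simulates `dx = f(x) dt + dW` with `f` the Helmholtz flow of the system
#' and Gaussian increments `dW ~ N(0, 2 * Gamma * dt)` (the package's fixed
#' noise convention).  The trajectory is exactly reproducible for a given
#' seed; the caller's RNG state is left untouched.
#'
#' @param system A `ness_system`.
#' @param x0 Initial state.
#' @param dt Step size (> 0), in model time units.
#' @param n_steps Number of steps (>= 1).
#' @param seed Integer seed for the noise stream.
#' @param guard Divergence guard: if any coordinate exceeds `guard` in
#'   absolute value the trajectory is truncated with a warning.
#' @param deterministic If `TRUE`, suppress the noise increments while
#'   keeping the full drift `(Q - Gamma) grad I` -- the zero-fluctuation
#'   limit, useful for validating the integrator against closed-form
#'   ODE solutions.
#' @return A `ness_trajectory`: list with `times` (length `n_steps + 1`),
#'   `states` (`(n_steps + 1) x dim` matrix, first row `x0`), `seed`,
#'   `dt`, `integrator_id`, and `diverged` flag.
#' @export
integrate_sde <- function(system, x0, dt, n_steps, seed = 1L, guard = 1e6,
                          deterministic = FALSE) {
  check_state(system, x0)
  if (dt <= 0) stopf("dt must be > 0")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stopf("n_steps must be >= 1")
  d <- system$dim
  sd_noise <- if (deterministic) rep(0, d) else sqrt(2 * system$gamma * dt)

  states <- matrix(NA_real_, n_steps + 1L, d)
  states[1L, ] <- x0
  diverged <- FALSE
  last <- n_steps + 1L

  with_seed(seed, {
    noise <- matrix(stats::rnorm((n_steps) * d), n_steps, d)
    x <- as.numeric(x0)
    if (inherits(system, "gaussian_ness")) {
      # linear drift: J (x - mean)
      J <- system$J; m <- system$mean
      for (k in seq_len(n_steps)) {
        x <- x + as.numeric(J %*% (x - m)) * dt + sd_noise * noise[k, ]
        if (any(abs(x) > guard) || any(!is.finite(x))) {
          diverged <- TRUE; last <- k; break
        }
        states[k + 1L, ] <- x
      }
    } else {
      for (k in seq_len(n_steps)) {
        x <- x + helmholtz_flow(system, x) * dt + sd_noise * noise[k, ]
        if (any(abs(x) > guard) || any(!is.finite(x))) {
          diverged <- TRUE; last <- k; break
        }
        states[k + 1L, ] <- x
      }
    }
  })

  if (diverged) {
    warnf("trajectory exceeded divergence guard %.3g at step %d; truncated",
          guard, last)
    states <- states[seq_len(last), , drop = FALSE]
  }
  structure(
    list(times = dt * (seq_len(nrow(states)) - 1L),
         states = states, seed = as.integer(seed), dt = dt,
         integrator_id = "euler-maruyama", diverged = diverged),
    class = "ness_trajectory")
}

#' @export
print.ness_trajectory <- function(x, ...) {
  cat(sprintf("<ness_trajectory> %d samples x %d states, dt = %g, seed = %d (%s)%s\n",
              nrow(x$states), ncol(x$states), x$dt, x$seed, x$integrator_id,
              if (isTRUE(x$diverged)) " [TRUNCATED: divergence guard]" else ""))
  invisible(x)
}

#' Stationary moments of a trajectory
#'
#' Discards an initial burn-in fraction and returns the empirical mean and
#' covariance of the remaining samples, together with batch-means standard
#' errors of the covariance entries.  Batch means are the honest way to
#' quantify Monte-Carlo error here because Euler--Maruyama samples are
#' serially correlated.
#'
#' @param traj A `ness_trajectory`.
#' @param burn_in Fraction of initial samples to discard (default 0.2).
#' @param n_batches Number of batches for the standard errors.
#' @return List with `mean`, `cov`, `cov_se` (matrix of batch-means
#'   standard errors), and `n` (samples retained).
#' @export
stationary_moments <- function(traj, burn_in = 0.2, n_batches = 50L) {
  X <- traj$states
  n0 <- floor(nrow(X) * burn_in)
  X <- X[(n0 + 1L):nrow(X), , drop = FALSE]
  n <- nrow(X); d <- ncol(X)
  mu <- colMeans(X)
  V <- stats::cov(X)
  # batch-means SE of each covariance entry
  bsize <- floor(n / n_batches)
  covs <- array(NA_real_, c(n_batches, d, d))
  for (b in seq_len(n_batches)) {
    idx <- ((b - 1L) * bsize + 1L):(b * bsize)
    covs[b, , ] <- stats::cov(X[idx, , drop = FALSE])
  }
  se <- apply(covs, c(2, 3), stats::sd) / sqrt(n_batches)
  list(mean = mu, cov = V, cov_se = se, n = n)
}

#' Mean circulation of a 2-D trajectory about the origin
#'
#' Average angular momentum-like statistic
#' `mean(x1 * dx2 - x2 * dx1) / dt`; nonzero circulation is the signature
#' of broken detailed balance (a nonzero stationary probability current),
#' with sign set by the sign of `Q[2,1]`.
#'
#' @param traj A 2-D `ness_trajectory`.
#' @return Scalar mean circulation.
#' @export
mean_circulation <- function(traj) {
  X <- traj$states
  if (ncol(X) != 2L) stopf("mean_circulation expects a 2-D trajectory")
  dX <- diff(X)
  mean(X[-nrow(X), 1] * dX[, 2] - X[-nrow(X), 2] * dX[, 1]) / traj$dt
}
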