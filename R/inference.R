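# The free-energy lemma for Gaussian NESS systems.
#
# Particular states pi = (mu, b) are the complement of the external states
# eta, so the joint density factors over (eta, pi).  A variational density
# q over eta -- parameterised by the conditional expectation of internal
# states, itself a function of the blanket value -- defines the
# variational free energy
#
#   F(pi) = E_q[I(eta, pi)] - H[q]                  (energy - entropy)
#         = I(pi) + KL[q || p(eta | b)]             (surprisal + bound)
#         = E_q[I(pi | eta)] + KL[q || p(eta)]      (inaccuracy + complexity)
#
# All three closed forms are computed independently; they agree exactly
# for Gaussian systems whose internal and external states are
# conditionally independent given the blanket (H[mu, eta] = 0, so that
# p(eta | pi) = p(eta | b)).

#' Conditional expectation of internal states given the blanket
#'
#' The internal statistical manifold is the set of conditional
#' expectations `E[mu | b]`; each point parameterises a posterior belief
#' over external states.  For a Gaussian system the map is linear:
#' `E[mu | b] = m_mu + Sigma[mu,b] Sigma[b,b]^-1 (b - m_b)`.
#'
#' @param system A `gaussian_ness`.
#' @param part A [state_partition()].
#' @param b_value Blanket state vector (length `length(part$b)`, ordered
#'   by increasing state index).
#' @return Numeric vector `E[mu | b]`.
#' @export
conditional_expectation <- function(system, part, b_value) {
  gc <- gaussian_condition(system, part$mu, part$b, b_value)
  gc$mean
}

#' Exact posterior over external states given the blanket
#'
#' Gaussian conditional `p(eta | b)` obtained from the stationary
#' covariance by Schur complement; this is the exact-inference reference
#' against which variational densities are scored.
#'
#' @inheritParams conditional_expectation
#' @return List with `mean` and `cov` of the conditional Gaussian.
#' @export
exact_posterior <- function(system, part, b_value) {
  gaussian_condition(system, part$eta, part$b, b_value)
}

# Gaussian conditioning p(x_target | x_given = value) from the stationary
# covariance of the system.
gaussian_condition <- function(system, target, given, value) {
  if (!inherits(system, "gaussian_ness"))
    stopf("Gaussian conditioning requires a gaussian_ness system")
  if (length(value) != length(given))
    stopf("conditioning value has length %d, expected %d",
          length(value), length(given))
  S <- system$Sigma; m <- system$mean
  Sgg <- S[given, given, drop = FALSE]
  cS <- tryCatch(chol(Sgg), error = function(e)
    stopf("conditioning covariance block is singular: %s", conditionMessage(e)))
  Stg <- S[target, given, drop = FALSE]
  W <- Stg %*% chol2inv(cS)
  list(mean = as.numeric(m[target] + W %*% (value - m[given])),
       cov = S[target, target, drop = FALSE] - W %*% t(Stg))
}

#' Gaussian variational density families
#'
#' A variational density assigns to every blanket value a Gaussian over
#' the external states.  `q_exact()` returns the family whose member at
#' `b` is the exact posterior `p(eta | b)` (the evidence bound then
#' collapses to zero).  `q_gaussian()` builds a family from user-supplied
#' mean and covariance maps; constants are accepted and treated as
#' blanket-independent.
#'
#' @param system A `gaussian_ness`.
#' @param part A [state_partition()].
#' @return An object of class `variational_density` whose `params_of(b)`
#'   returns `list(mean, cov)`.
#' @export
q_exact <- function(system, part) {
  structure(
    list(family = "gaussian", exact = TRUE,
         params_of = function(b_value) exact_posterior(system, part, b_value)),
    class = "variational_density")
}

#' @rdname q_exact
#' @param mean_fn Mean over external states: a function of the blanket
#'   value, or a constant vector.
#' @param cov_fn Covariance over external states: a function of the
#'   blanket value, or a constant SPD matrix.
#' @export
q_gaussian <- function(mean_fn, cov_fn) {
  mf <- if (is.function(mean_fn)) mean_fn else function(b) mean_fn
  cf <- if (is.function(cov_fn)) cov_fn else function(b) as.matrix(cov_fn)
  structure(
    list(family = "gaussian", exact = FALSE,
         params_of = function(b_value) list(mean = as.numeric(mf(b_value)),
                                            cov = as.matrix(cf(b_value)))),
    class = "variational_density")
}

#' Variational free energy and its three decompositions
#'
#' Evaluates the free energy of particular states `pi_value` under the
#' variational density `q`, returning every term of the three equivalent
#' decompositions: `energy - entropy`, `surprisal + bound`, and
#' `inaccuracy + complexity`.  Each decomposition is computed by an
#' independent closed-form route; their agreement (to ~1e-10) is a strong
#' internal consistency check, enforced by the object's `print` method and
#' by the test-suite invariants.  The evidence bound
#' `KL[q || p(eta | b)]` is nonnegative, so `F >= I(pi)` always.
#'
#' @param system A `gaussian_ness` whose `H[mu, eta]` block vanishes (the
#'   blanket condition under which the surprisal + bound split is exact).
#' @param part A [state_partition()].
#' @param pi_value Values of the particular states, ordered by increasing
#'   state index (`part$pi`).
#' @param q A `variational_density`.
#' @param heuristic_raw_internal If `TRUE`, parameterise `q` by the raw
#'   internal coordinates of `pi_value` instead of the blanket value.
#'   This is a heuristic: the statistical manifold is defined by
#'   conditional expectations of internal states, not raw internal states.
#' @return A `free_energy_decomposition` with fields `energy`, `entropy`,
#'   `surprisal`, `bound`, `inaccuracy`, `complexity`, `F`.
#' @export
free_energy <- function(system, part, pi_value, q,
                        heuristic_raw_internal = FALSE) {
  if (!inherits(q, "variational_density")) stopf("q must be a variational_density")
  if (length(pi_value) != length(part$pi))
    stopf("pi_value has length %d, expected %d", length(pi_value),
          length(part$pi))
  b_pos <- match(part$b, part$pi)
  mu_pos <- match(part$mu, part$pi)
  b_value <- pi_value[b_pos]
  coord <- if (heuristic_raw_internal) pi_value[mu_pos] else b_value
  qp <- q$params_of(coord)
  mq <- qp$mean; Vq <- as.matrix(qp$cov)
  ne <- length(part$eta)
  if (length(mq) != ne || nrow(Vq) != ne)
    stopf("q has dimension %d, expected %d external states", length(mq), ne)
  evq <- eigen((Vq + t(Vq)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(evq) <= 0)
    stopf("q covariance is not positive definite (smallest eigenvalue %.3g)",
          min(evq))

  H <- system$H; S <- system$Sigma; m <- system$mean
  eta <- part$eta; pp <- part$pi; d <- system$dim

  # --- route 1: energy - entropy -------------------------------------
  xbar <- numeric(d)
  xbar[eta] <- mq; xbar[pp] <- pi_value
  Dv <- xbar - m
  joint_const <- 0.5 * (d * log(2 * pi) - logdet_spd(H))
  energy <- 0.5 * sum(Dv * (H %*% Dv)) +
    0.5 * sum(diag(H[eta, eta, drop = FALSE] %*% Vq)) + joint_const
  entropy <- 0.5 * (ne * log(2 * pi * exp(1)) + logdet_spd(Vq))

  # --- route 2: surprisal + evidence bound ---------------------------
  Spp <- S[pp, pp, drop = FALSE]
  dpi <- pi_value - m[pp]
  surpr <- 0.5 * sum(dpi * solve(Spp, dpi)) +
    0.5 * (length(pp) * log(2 * pi) + logdet_spd(Spp))
  post <- exact_posterior(system, part, b_value)
  bound <- gaussian_kl(mq, Vq, post$mean, post$cov)

  # --- route 3: inaccuracy + complexity ------------------------------
  See <- S[eta, eta, drop = FALSE]
  A <- S[pp, eta, drop = FALSE] %*% chol2inv(chol(See))
  Cc <- Spp - A %*% S[eta, pp, drop = FALSE]
  P <- chol2inv(chol((Cc + t(Cc)) / 2))
  dbar <- dpi - as.numeric(A %*% (mq - m[eta]))
  inaccuracy <- 0.5 * sum(dbar * (P %*% dbar)) +
    0.5 * sum(diag(t(A) %*% P %*% A %*% Vq)) +
    0.5 * (length(pp) * log(2 * pi) + logdet_spd((Cc + t(Cc)) / 2))
  complexity <- gaussian_kl(mq, Vq, m[eta], See)

  structure(
    list(energy = energy, entropy = entropy, surprisal = surpr,
         bound = bound, inaccuracy = inaccuracy, complexity = complexity,
         F = energy - entropy),
    class = "free_energy_decomposition")
}

#' @export
print.free_energy_decomposition <- function(x, ...) {
  cat("<free_energy_decomposition> (nats)\n")
  cat(sprintf("  F = %.6f\n", x$F))
  cat(sprintf("  energy - entropy        = %.6f - %.6f = %.6f\n",
              x$energy, x$entropy, x$energy - x$entropy))
  cat(sprintf("  surprisal + bound       = %.6f + %.6f = %.6f\n",
              x$surprisal, x$bound, x$surprisal + x$bound))
  cat(sprintf("  inaccuracy + complexity = %.6f + %.6f = %.6f\n",
              x$inaccuracy, x$complexity, x$inaccuracy + x$complexity))
  invisible(x)
}

#' Evidence bound over a grid of blanket values
#'
#' Evaluates the bound `c(b) = KL[q_b || p(eta | b)]` over a grid and
#' reports its constancy defect `max(c) - min(c)`.  The gradient-flow
#' reading of the free energy only needs the bound to be (approximately)
#' constant over the manifold, not zero; the defect quantifies how far a
#' given family is from that regime and is reported, not thresholded.
#'
#' @param system A `gaussian_ness`.
#' @param part A [state_partition()].
#' @param q A `variational_density`.
#' @param b_grid Matrix of blanket values (rows = grid points) or a
#'   vector for a 1-D blanket.
#' @return List with `bounds` (vector `c(b)` per row), `max`, `min`, and
#'   `constancy_defect = max - min`.
#' @export
evidence_bound_profile <- function(system, part, q, b_grid) {
  if (is.null(dim(b_grid))) b_grid <- matrix(b_grid, ncol = length(part$b))
  n <- nrow(b_grid)
  bounds <- numeric(n)
  for (i in seq_len(n)) {
    b <- as.numeric(b_grid[i, ])
    qp <- q$params_of(b)
    post <- exact_posterior(system, part, b)
    bounds[i] <- gaussian_kl(qp$mean, as.matrix(qp$cov), post$mean, post$cov)
  }
  list(bounds = bounds, max = max(bounds), min = min(bounds),
       constancy_defect = max(bounds) - min(bounds))
}

#' Gradient equivalence of surprisal and free energy
#'
#' Compares the autonomous gradient of the particular-state surprisal,
#' `grad_alpha I(pi)` (closed form), with the autonomous gradient of the
#' variational free energy, `grad_alpha F(pi)` (central finite
#' differences), and returns their difference -- the gradient of the
#' evidence bound.  When the bound is constant over the manifold the two
#' gradient flows coincide even though the bound itself may be large.
#'
#' @param system A `gaussian_ness`.
#' @param part A [state_partition()].
#' @param q A `variational_density`.
#' @param pi_value Particular-state vector (ordered by `part$pi`).
#' @param fd_step Base finite-difference step (scaled by coordinate
#'   magnitude), default `1e-5`.
#' @return List with `grad_surprisal`, `grad_F`, `grad_bound`
#'   (= difference), `max_abs_diff`, and `alpha_idx` (the state indices
#'   the gradients refer to).
#' @export
gradient_equivalence <- function(system, part, q, pi_value, fd_step = 1e-5) {
  if (fd_step <= 0) stopf("fd_step must be > 0")
  pp <- part$pi
  alpha_pos <- match(part$alpha, pp)
  S <- system$Sigma; m <- system$mean
  Spp <- S[pp, pp, drop = FALSE]
  grad_pi <- as.numeric(solve(Spp, pi_value - m[pp]))
  grad_surpr <- grad_pi[alpha_pos]

  F_of <- function(pv) free_energy(system, part, pv, q)$F
  grad_F <- numeric(length(alpha_pos))
  for (k in seq_along(alpha_pos)) {
    i <- alpha_pos[k]
    h <- fd_step * max(1, abs(pi_value[i]))
    up <- pi_value; up[i] <- up[i] + h
    dn <- pi_value; dn[i] <- dn[i] - h
    grad_F[k] <- (F_of(up) - F_of(dn)) / (2 * h)
  }
  diff <- grad_F - grad_surpr
  list(grad_surprisal = grad_surpr, grad_F = grad_F, grad_bound = diff,
       max_abs_diff = max_abs(diff), alpha_idx = part$alpha)
}

#' Autonomous flow toward a desired steady state
#'
#' Engineering reading of the free-energy gradient flow: given a
#' generative model (a Gaussian NESS density), the autonomous flow
#' `f_alpha = (Q[alpha,alpha] - Gamma[alpha,alpha]) grad_alpha F(mu, b)`
#' drives particular states toward the generative model's marginal
#' steady state.  With `q` the exact posterior, `F = I(pi)` and this
#' reduces to the sparse-form autonomous flow.
#'
#' @param system A `gaussian_ness` encoding the generative model.
#' @param part A [state_partition()].
#' @param pi_value Particular-state vector.
#' @param q A `variational_density`.
#' @param Q_alpha,Gamma_alpha Optional overrides for the autonomous
#'   blocks of `Q` and `Gamma` (defaults: the system's own blocks).
#' @param fd_step Finite-difference step for `grad_alpha F`.
#' @return Numeric autonomous flow vector (ordered by `part$alpha`).
#' @export
desired_steady_state_flow <- function(system, part, pi_value, q,
                                      Q_alpha = NULL, Gamma_alpha = NULL,
                                      fd_step = 1e-5) {
  al <- part$alpha
  if (is.null(Q_alpha)) Q_alpha <- system$Q[al, al, drop = FALSE]
  if (is.null(Gamma_alpha)) Gamma_alpha <- system$Gamma[al, al, drop = FALSE]
  ge <- gradient_equivalence(system, part, q, pi_value, fd_step = fd_step)
  as.numeric((Q_alpha - Gamma_alpha) %*% ge$grad_F)
}

#' Simulate self-organisation to a desired steady state
#'
#' Integrates the particular states under the free-energy gradient flow
#' of [desired_steady_state_flow()] with matched noise
#' (`cov = 2 * Gamma[alpha,alpha] * dt`).  Supported when the sensory set
#' is empty, so that the autonomous states are exactly the particular
#' states and the flow closes over them.
#'
#' @inheritParams desired_steady_state_flow
#' @param pi0 Initial particular-state vector.
#' @param dt,n_steps,seed Integration parameters as in [integrate_sde()].
#' @return A `ness_trajectory` over the particular states.
#' @export
simulate_desired_steady_state <- function(system, part, q, pi0, dt, n_steps,
                                          seed = 1L, fd_step = 1e-5) {
  if (length(part$s) > 0L)
    stopf("simulation requires an empty sensory set (alpha must equal pi)")
  al <- part$alpha
  gamma_al <- system$gamma[al]
  sd_noise <- sqrt(2 * gamma_al * dt)
  n_steps <- as.integer(n_steps)
  states <- matrix(NA_real_, n_steps + 1L, length(al))
  states[1L, ] <- pi0
  with_seed(seed, {
    noise <- matrix(stats::rnorm(n_steps * length(al)), n_steps, length(al))
    x <- as.numeric(pi0)
    for (k in seq_len(n_steps)) {
      f <- desired_steady_state_flow(system, part, x, q, fd_step = fd_step)
      x <- x + f * dt + sd_noise * noise[k, ]
      states[k + 1L, ] <- x
    }
  })
  structure(
    list(times = dt * (0:n_steps), states = states, seed = as.integer(seed),
         dt = dt, integrator_id = "euler-maruyama-free-energy",
         diverged = FALSE),
    class = "ness_trajectory")
}
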