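# Nonequilibrium steady-state (NESS) systems defined by a Helmholtz
# decomposition of the stationary flow,
#
#     dx = f(x) dt + dW,   f(x) = (Q - Gamma) grad I(x),
#
# where I(x) = -log p(x) is the surprisal of the prescribed steady-state
# density p, Q is an antisymmetric ("solenoidal") matrix, and Gamma is a
# diagonal positive diffusion matrix.  Random-fluctuation increments have
# covariance 2 * Gamma * dt (the unique convention under which a Gaussian
# density with precision H is stationary for the constant Jacobian
# J = (Q - Gamma) H; see the methods vignette).

#' Construct a NESS system from a surprisal function
#'
#' Defines a stochastic system whose drift is the Helmholtz decomposition
#' `(Q - Gamma) grad I(x)` of a prescribed steady-state surprisal
#' `I(x) = -log p(x)`.  `Q` mediates divergence-free solenoidal flow on the
#' iso-probability contours of `p`; `-Gamma grad I` is the dissipative
#' gradient flow that counteracts the random fluctuations.  Both `Q` and
#' `Gamma` are treated as constant in `x`.
#'
#' @param surprisal Function of a length-`dim` numeric vector returning the
#'   scalar surprisal in nats (an additive constant is irrelevant to the
#'   flow).
#' @param dim State-space dimension.
#' @param Q `dim` x `dim` antisymmetric matrix (default zero: purely
#'   dissipative flow, detailed balance).
#' @param Gamma Diffusion amplitudes: scalar, length-`dim` vector, or
#'   diagonal matrix; all entries must be positive unless
#'   `allow_deterministic = TRUE`.
#' @param grad,hess Optional analytic gradient / Hessian of the surprisal;
#'   central finite differences are used when omitted.
#' @param allow_deterministic Permit zero diffusion entries (noiseless
#'   limit, intended for testing integrators against closed-form ODEs).
#' @return An object of class `ness_system`.
#' @seealso [gaussian_ness()] for the quadratic-surprisal special case,
#'   [helmholtz_flow()], [integrate_sde()].
#' @export
ness_system <- function(surprisal, dim, Q = NULL, Gamma = 1,
                        grad = NULL, hess = NULL,
                        allow_deterministic = FALSE) {
  stopifnot(is.function(surprisal), dim >= 1)
  dim <- as.integer(dim)
  if (is.null(Q)) Q <- matrix(0, dim, dim)
  Q <- as.matrix(Q)
  if (nrow(Q) != dim || ncol(Q) != dim) stopf("Q must be %d x %d", dim, dim)
  assert_antisymmetric(Q)
  gamma <- as_gamma_diag(Gamma, dim, allow_zero = allow_deterministic)
  if (is.null(grad)) {
    srp <- surprisal
    grad <- function(x) num_grad(srp, x)
  }
  if (is.null(hess)) {
    srp2 <- surprisal
    hess <- function(x) num_hess(srp2, x)
  }
  structure(
    list(dim = dim, surprisal = surprisal, grad = grad, hess = hess,
         Q = Q, gamma = gamma, Gamma = diag(gamma, dim),
         noise_convention = "cov(dW) = 2 * Gamma * dt"),
    class = "ness_system")
}

#' Construct a Gaussian NESS system from a precision matrix
#'
#' The steady-state density is `N(mean, H^-1)` with surprisal
#' `I(x) = (x - mean)' H (x - mean) / 2 + log((2*pi)^dim / det H) / 2`.
#' The flow is linear with constant Jacobian `J = (Q - Gamma) H`, and the
#' stationary covariance `Sigma = H^-1` satisfies the continuous Lyapunov
#' identity `J Sigma + Sigma J' + 2 Gamma = 0` for every admissible
#' `(H, Q, Gamma)` -- the algebraic statement that solenoidal flow leaves
#' the steady-state density untouched.
#'
#' @param H Symmetric positive-definite precision matrix of the
#'   steady-state density.
#' @param Q Antisymmetric solenoidal matrix (default zero).
#' @param Gamma Diffusion amplitudes as in [ness_system()] (default
#'   identity).
#' @param mean Stationary mean (default zero).
#' @inheritParams ness_system
#' @return An object of class `c("gaussian_ness", "ness_system")` with
#'   components `H`, `Sigma = H^-1`, `J = (Q - Gamma) H`, `mean`.
#' @examples
#' sys <- gaussian_ness(H = diag(2), Q = matrix(c(0, -0.5, 0.5, 0), 2))
#' sys$J
#' @export
gaussian_ness <- function(H, Q = NULL, Gamma = 1, mean = NULL,
                          allow_deterministic = FALSE) {
  H <- as.matrix(H)
  assert_spd(H, "H")
  dim <- nrow(H)
  if (is.null(mean)) mean <- numeric(dim)
  if (length(mean) != dim) stopf("mean must have length %d", dim)
  if (is.null(Q)) Q <- matrix(0, dim, dim)
  Q <- as.matrix(Q)
  if (nrow(Q) != dim || ncol(Q) != dim) stopf("Q must be %d x %d", dim, dim)
  assert_antisymmetric(Q)
  gamma <- as_gamma_diag(Gamma, dim, allow_zero = allow_deterministic)
  Gm <- diag(gamma, dim)
  Sigma <- chol2inv(chol(H))
  ld <- logdet_spd(H)
  const <- 0.5 * (dim * log(2 * pi) - ld)
  mean <- as.numeric(mean)

  sys <- structure(
    list(dim = dim, H = H, mean = mean, Sigma = Sigma,
         J = (Q - Gm) %*% H,
         surprisal = function(x) {
           d <- x - mean
           0.5 * sum(d * (H %*% d)) + const
         },
         grad = function(x) as.numeric(H %*% (x - mean)),
         hess = function(x) H,
         Q = Q, gamma = gamma, Gamma = Gm,
         noise_convention = "cov(dW) = 2 * Gamma * dt"),
    class = c("gaussian_ness", "ness_system"))
  sys
}

#' @export
print.ness_system <- function(x, ...) {
  cat(sprintf("<%s> dim = %d\n", class(x)[1], x$dim))
  cat(sprintf("  solenoidal Q: max|Q| = %.3g, Gamma diag in [%.3g, %.3g]\n",
              max_abs(x$Q), min(x$gamma), max(x$gamma)))
  cat("  noise convention:", x$noise_convention, "\n")
  invisible(x)
}

#' Evaluate the surprisal of a system at a state
#'
#' @param system A `ness_system`.
#' @param x State vector of length `system$dim`.
#' @return Scalar surprisal in nats.
#' @export
surprisal <- function(system, x) {
  check_state(system, x)
  system$surprisal(x)
}

#' @rdname surprisal
#' @export
surprisal_grad <- function(system, x) {
  check_state(system, x)
  system$grad(x)
}

#' @rdname surprisal
#' @export
surprisal_hess <- function(system, x) {
  check_state(system, x)
  system$hess(x)
}

check_state <- function(system, x) {
  if (length(x) != system$dim)
    stopf("state has length %d but system dimension is %d",
          length(x), system$dim)
  if (!all(is.finite(x)))
    stopf("state has non-finite entries at positions %s",
          paste(which(!is.finite(x)), collapse = ", "))
  invisible(TRUE)
}

#' Helmholtz-decomposed flow at a state
#'
#' Evaluates the drift `f(x) = (Q - Gamma) grad I(x)`, optionally split
#' into its dissipative part `-Gamma grad I(x)` (the gradient descent on
#' surprisal) and its solenoidal part `Q grad I(x)` (divergence-free
#' circulation on iso-probability contours, the ingredient that breaks
#' detailed balance).
#'
#' @param system A `ness_system`.
#' @param x State vector.
#' @param decompose If `TRUE` return a list with components `flow`,
#'   `dissipative`, `solenoidal`; otherwise the flow vector.
#' @return Flow vector, or decomposition list.
#' @export
helmholtz_flow <- function(system, x, decompose = FALSE) {
  check_state(system, x)
  g <- surprisal_grad(system, x)
  if (!all(is.finite(g)))
    stopf("surprisal gradient is non-finite at positions %s (x = %s)",
          paste(which(!is.finite(g)), collapse = ", "),
          paste(signif(x, 4), collapse = ", "))
  diss <- -system$gamma * g
  sol <- as.numeric(system$Q %*% g)
  if (decompose) list(flow = diss + sol, dissipative = diss, solenoidal = sol)
  else diss + sol
}

#' Vector potential of the solenoidal flow (3-D systems)
#'
#' For a 3-dimensional system the solenoidal component `Q grad I(x)` is the
#' curl of the vector potential
#' `A(x) = c(-Q[3,2], Q[3,1], -Q[2,1]) * I(x)`,
#' which rewrites the Helmholtz decomposition in the familiar
#' scalar-plus-vector-potential form of vector calculus.  The identity
#' `curl A(x) = Q grad I(x)` holds at every `x` because `Q` is constant and
#' antisymmetric.
#'
#' @param system A 3-dimensional `ness_system`.
#' @param x State vector of length 3.
#' @return The 3-vector `A(x)`.
#' @export
vector_potential <- function(system, x) {
  if (system$dim != 3L)
    stopf("vector_potential is defined for 3-dimensional systems only (dim = %d)",
          system$dim)
  check_state(system, x)
  Q <- system$Q
  c(-Q[3, 2], Q[3, 1], -Q[2, 1]) * surprisal(system, x)
}
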