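# Markov blanket verification for Gaussian NESS systems.
#
# Two separate conditions are in play:
#   condition 1 (flow):    autonomous states are uncoupled from external
#                          states -- J[mu, eta] = 0 and J[a, eta] = 0 for
#                          the constant Jacobian J = (Q - Gamma) H;
#   condition 2 (blanket): internal and external states are conditionally
#                          independent given the blanket -- for a Gaussian
#                          density exactly H[mu, eta] = 0.
# Neither implies the other; the admissible sparse form requires, on top
# of the blanket condition, the additional Hessian zeros H[eta, a] = 0 and
# H[s, mu] = 0 together with the precluded solenoidal couplings
# Q[eta, a] = Q[eta, mu] = Q[s, a] = Q[s, mu] = 0, which jointly force the
# Jacobian zero blocks J[eta, mu], J[s, mu], J[a, eta], J[mu, eta].

#' Conditional independence of internal and external states
#'
#' For a Gaussian steady-state density with precision `H`, internal and
#' external states are conditionally independent given the blanket exactly
#' when the `H[mu, eta]` block vanishes.  The check is
#' `max|H[mu, eta]| < tol`.
#'
#' @param H Symmetric precision matrix.
#' @param part A [state_partition()].
#' @param tol Tolerance (> 0), default `1e-8`.
#' @return List with `pass` (logical), `max_abs`, and `worst` (row/col
#'   indices in the full matrix of the largest-magnitude entry).
#' @export
check_conditional_independence <- function(H, part, tol = 1e-8) {
  H <- as.matrix(H)
  if (part$dim != nrow(H)) stopf("partition dim %d != nrow(H) %d", part$dim, nrow(H))
  if (tol <= 0) stopf("tol must be > 0")
  B <- part_block(H, part, "mu", "eta")
  m <- max_abs(B)
  worst <- if (length(B)) {
    w <- which(abs(B) == m, arr.ind = TRUE)[1, ]
    c(row = part$mu[w[1]], col = part$eta[w[2]])
  } else c(row = NA_integer_, col = NA_integer_)
  list(pass = m < tol, max_abs = m, worst = worst, tol = tol)
}

#' Flow constraint: autonomous states uncoupled from external states
#'
#' Checks that the Jacobian blocks `J[mu, eta]` and `J[a, eta]` of
#' `J = (Q - Gamma) H` vanish, i.e. the flow of autonomous states is a
#' function of, and only of, particular states.
#'
#' @param system A `gaussian_ness` (constant Jacobian).
#' @inheritParams check_conditional_independence
#' @return List with `pass`, `max_abs`, and per-block maxima.
#' @export
check_flow_constraint <- function(system, part, tol = 1e-8) {
  if (!inherits(system, "gaussian_ness"))
    stopf("check_flow_constraint requires a constant-Jacobian (gaussian_ness) system")
  if (tol <= 0) stopf("tol must be > 0")
  J <- system$J
  m_mu <- max_abs(part_block(J, part, "mu", "eta"))
  m_a <- max_abs(part_block(J, part, "a", "eta"))
  list(pass = max(m_mu, m_a) < tol, max_abs = max(m_mu, m_a),
       blocks = c(J_mu_eta = m_mu, J_a_eta = m_a), tol = tol)
}

#' Full sparse-form blanket report
#'
#' Measures every block that the admissible sparse coupling structure
#' requires to vanish: the Hessian blocks `H[eta, a]`, `H[eta, mu]`,
#' `H[s, mu]`; the solenoidal blocks `Q[eta, a]`, `Q[eta, mu]`,
#' `Q[s, a]`, `Q[s, mu]`; and the implied Jacobian zero blocks
#' `J[eta, mu]`, `J[s, mu]`, `J[a, eta]`, `J[mu, eta]` of
#' `J = (Q - Gamma) H`.  Violations are reported, never raised.
#'
#' @param H Symmetric precision (Hessian) matrix.
#' @param Q Antisymmetric solenoidal matrix.
#' @param part A [state_partition()].
#' @param tol Tolerance for "zero", default `1e-8`.
#' @param Gamma Diffusion amplitudes used for the Jacobian (default
#'   identity; the zero pattern of `J` is what matters, and diagonal
#'   `Gamma` cannot create coupling across blocks).
#' @return A `blanket_report` with elements `hessian_blocks`, `q_blocks`,
#'   `jacobian_blocks` (named max-abs values), `tol`, and `passes`, a list
#'   of logicals: `condition1_flow` (Jacobian blocks `J[mu,eta]`,
#'   `J[a,eta]` vanish), `condition2_blanket` (`H[mu,eta]` vanishes),
#'   `sparse_form_eq7` (all Hessian and solenoidal blocks vanish) and
#'   `condition3` (additionally no solenoidal coupling between any two
#'   different kinds of states, i.e. `Q[eta,s]` and `Q[a,mu]` also
#'   vanish).
#' @export
check_sparse_form <- function(H, Q, part, tol = 1e-8, Gamma = 1) {
  H <- as.matrix(H); Q <- as.matrix(Q)
  d <- part$dim
  if (nrow(H) != d || nrow(Q) != d) stopf("H and Q must be %d x %d", d, d)
  if (max_abs(H - t(H)) > tol) stopf("H must be symmetric")
  assert_antisymmetric(Q, tol)
  if (tol <= 0) stopf("tol must be > 0")
  gamma <- as_gamma_diag(Gamma, d, allow_zero = TRUE)
  J <- (Q - diag(gamma, d)) %*% H

  hb <- c(H_eta_a = max_abs(part_block(H, part, "eta", "a")),
          H_eta_mu = max_abs(part_block(H, part, "eta", "mu")),
          H_s_mu = max_abs(part_block(H, part, "s", "mu")))
  qb <- c(Q_eta_a = max_abs(part_block(Q, part, "eta", "a")),
          Q_eta_mu = max_abs(part_block(Q, part, "eta", "mu")),
          Q_s_a = max_abs(part_block(Q, part, "s", "a")),
          Q_s_mu = max_abs(part_block(Q, part, "s", "mu")))
  jb <- c(J_eta_mu = max_abs(part_block(J, part, "eta", "mu")),
          J_s_mu = max_abs(part_block(J, part, "s", "mu")),
          J_a_eta = max_abs(part_block(J, part, "a", "eta")),
          J_mu_eta = max_abs(part_block(J, part, "mu", "eta")))
  extra_q <- c(Q_eta_s = max_abs(part_block(Q, part, "eta", "s")),
               Q_a_mu = max_abs(part_block(Q, part, "a", "mu")))

  passes <- list(
    condition1_flow = unname(jb["J_mu_eta"] < tol && jb["J_a_eta"] < tol),
    condition2_blanket = unname(hb["H_eta_mu"] < tol),
    sparse_form_eq7 = all(hb < tol) && all(qb < tol),
    condition3 = all(hb < tol) && all(qb < tol) && all(extra_q < tol))

  structure(
    list(hessian_blocks = hb, q_blocks = qb, jacobian_blocks = jb,
         q_within_blanket_blocks = extra_q, tol = tol, passes = passes,
         partition = part),
    class = "blanket_report")
}

#' @export
print.blanket_report <- function(x, ...) {
  cat(sprintf("<blanket_report> tol = %.3g\n", x$tol))
  show <- function(lab, v)
    cat(sprintf("  %s: %s\n", lab,
                paste(sprintf("%s=%.3g", names(v), v), collapse = "  ")))
  show("Hessian ", x$hessian_blocks)
  show("Q       ", x$q_blocks)
  show("Jacobian", x$jacobian_blocks)
  p <- x$passes
  cat(sprintf("  condition1 (flow): %s   condition2 (blanket): %s\n",
              p$condition1_flow, p$condition2_blanket))
  cat(sprintf("  sparse form: %s   condition3 (block-diagonal Q): %s\n",
              p$sparse_form_eq7, p$condition3))
  invisible(x)
}

#' Serialise a blanket report to JSON
#'
#' @param report A `blanket_report`.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
blanket_report_json <- function(report, path = NULL) {
  obj <- list(
    tol = report$tol,
    hessian_blocks = as.list(report$hessian_blocks),
    q_blocks = as.list(report$q_blocks),
    jacobian_blocks = as.list(report$jacobian_blocks),
    passes = report$passes,
    partition = report$partition[c("eta", "s", "a", "mu")])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Blockwise flow of a sparse-form system
#'
#' For a system passing [check_sparse_form()], the flow splits into the
#' blocks `f_eta(eta, b)`, `f_s(eta, b)` and -- crucially --
#' `f_alpha(mu, b) = (Q[alpha,alpha] - Gamma[alpha,alpha]) grad_alpha I`,
#' where the autonomous gradient is computed from particular states only.
#' The returned `f_alpha` is assembled without ever reading the external
#' coordinates of `x`, so it agrees exactly (to machine precision) with
#' the corresponding rows of the full flow `f(x) = (Q - Gamma) grad I(x)`.
#'
#' @param system A `gaussian_ness` passing the sparse-form check at `tol`.
#' @param part A [state_partition()].
#' @param x Full state vector.
#' @param tol Tolerance for the precondition check.
#' @return List with `f_eta`, `f_s`, `f_alpha` (named by state index) and
#'   `full` (the flow vector in state order, assembled from the blocks).
#' @export
autonomous_flow <- function(system, part, x, tol = 1e-8) {
  if (!inherits(system, "gaussian_ness"))
    stopf("autonomous_flow requires a gaussian_ness system")
  check_state(system, x)
  rep <- check_sparse_form(system$H, system$Q, part, tol = tol,
                           Gamma = system$gamma)
  if (!rep$passes$sparse_form_eq7) {
    bad <- c(rep$hessian_blocks, rep$q_blocks)
    bad <- bad[bad >= tol]
    stopf("system does not satisfy the sparse blanket form: %s",
          paste(sprintf("%s = %.3g", names(bad), bad), collapse = ", "))
  }
  H <- system$H; Q <- system$Q; Gm <- system$Gamma; m <- system$mean
  eta <- part$eta; s <- part$s; al <- part$alpha; pp <- part$pi
  eb <- c(eta, part$b)  # eta and blanket indices

  # gradients restricted to the blocks each flow may legally read
  g_eta <- as.numeric(H[eta, eb, drop = FALSE] %*% (x[eb] - m[eb]))
  g_s <- if (length(s))
    as.numeric(H[s, eb, drop = FALSE] %*% (x[eb] - m[eb])) else numeric(0)
  g_alpha <- as.numeric(H[al, pp, drop = FALSE] %*% (x[pp] - m[pp]))

  QG <- Q - Gm
  f_eta <- as.numeric(QG[eta, eta, drop = FALSE] %*% g_eta) +
    (if (length(s)) as.numeric(Q[eta, s, drop = FALSE] %*% g_s) else 0)
  f_s <- if (length(s))
    as.numeric(Q[s, eta, drop = FALSE] %*% g_eta) +
      as.numeric(QG[s, s, drop = FALSE] %*% g_s) else numeric(0)
  f_alpha <- as.numeric(QG[al, al, drop = FALSE] %*% g_alpha)

  full <- numeric(system$dim)
  full[eta] <- f_eta; full[s] <- f_s; full[al] <- f_alpha
  list(f_eta = stats::setNames(f_eta, eta),
       f_s = stats::setNames(f_s, s),
       f_alpha = stats::setNames(f_alpha, al),
       full = full)
}

#' Exhaustive search for admissible blanket partitions
#'
#' Enumerates labelings of the states as external / sensory / active /
#' internal and returns every partition under which `(H, Q)` satisfies the
#' sparse blanket form.  The search is a depth-first backtracking over
#' states with pairwise pruning: an entry `|H[i,j]| >= tol` forbids the
#' label pairs (eta,a), (eta,mu), (s,mu); an entry `|Q[i,j]| >= tol`
#' additionally forbids (s,a).  Results are in deterministic lexicographic
#' order of the label vector (eta < s < a < mu).
#'
#' @param H Symmetric matrix.
#' @param Q Antisymmetric matrix.
#' @param tol Tolerance for treating couplings as zero.
#' @param max_dim Refuse exhaustive search above this dimension
#'   (default 12).
#' @return List of results, each with elements `partition` and `report`.
#' @export
find_admissible_partitions <- function(H, Q, tol = 1e-8, max_dim = 12L) {
  H <- as.matrix(H); Q <- as.matrix(Q)
  d <- nrow(H)
  if (d > max_dim)
    stopf("exhaustive search supports dim <= %d (got %d); no heuristic search is implemented",
          max_dim, d)
  assert_antisymmetric(Q, tol)

  # forbidden unordered label pairs per coupled state pair
  # labels: 1 = eta, 2 = s, 3 = a, 4 = mu
  forbid_h <- matrix(FALSE, 4, 4)
  forbid_h[1, 3] <- forbid_h[3, 1] <- TRUE  # eta-a
  forbid_h[1, 4] <- forbid_h[4, 1] <- TRUE  # eta-mu
  forbid_h[2, 4] <- forbid_h[4, 2] <- TRUE  # s-mu
  forbid_q <- forbid_h
  forbid_q[2, 3] <- forbid_q[3, 2] <- TRUE  # s-a

  h_coupled <- abs(H) >= tol
  q_coupled <- abs(Q) >= tol

  results <- list()
  labels <- integer(d)
  recurse <- function(k) {
    if (k > d) {
      eta <- which(labels == 1L); s <- which(labels == 2L)
      a <- which(labels == 3L); mu <- which(labels == 4L)
      if (length(eta) && length(mu) && (length(s) + length(a))) {
        part <- state_partition(eta, s, a, mu, dim = d)
        rep <- check_sparse_form(H, Q, part, tol = tol)
        if (rep$passes$sparse_form_eq7)
          results[[length(results) + 1L]] <<- list(partition = part,
                                                   report = rep)
      }
      return(invisible(NULL))
    }
    for (lab in 1:4) {
      ok <- TRUE
      for (j in seq_len(k - 1L)) {
        if (h_coupled[j, k] && forbid_h[labels[j], lab]) { ok <- FALSE; break }
        if (q_coupled[j, k] && forbid_q[labels[j], lab]) { ok <- FALSE; break }
      }
      if (ok) {
        labels[k] <<- lab
        recurse(k + 1L)
      }
    }
    invisible(NULL)
  }
  recurse(1L)
  results
}
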