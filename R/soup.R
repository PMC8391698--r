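# A "primordial soup" of macromolecules: each molecule carries a 3-D
# electrochemical state evolving as a stochastic Lorenz attractor,
# diffusively coupled to the other molecules with a strength that decays
# with inter-molecule distance; positions and velocities follow stochastic
# Newtonian motion driven by electrochemical differences between
# neighbours, with damping, a weak containing potential, and short-range
# repulsion to keep the ensemble cohesive but extended.

#' Soup simulation configuration
#'
#' Defaults describe a rod-like ensemble of nine molecules, initialised on
#' a line with spacing `coupling_length`, at a coupling strength for which
#' adjacent Lorenz attractors partially synchronise (the regime in which
#' generalised synchronisation across the blanket is visible).  The
#' analysis window is the final `window` time units of the run.
#'
#' @param n_molecules Number of molecules (>= 4).
#' @param lorenz Lorenz parameters `c(sigma, rho, beta)` shared by all
#'   molecules; classical values by default.
#' @param coupling_scale Peak electrochemical coupling rate (1/time).
#' @param coupling_length Length scale of the Gaussian coupling kernel
#'   `k(d) = coupling_scale * exp(-d^2 / (2 * coupling_length^2))`.
#' @param force_gain Scale of the Newtonian force produced by the
#'   mixed electrochemical difference between neighbours.
#' @param mixing Fixed 3-vector projecting an electrochemical difference
#'   to the scalar that drives the pairwise force.
#' @param damping Velocity damping rate (bounds kinetic energy).
#' @param container Harmonic containment rates toward the origin, one
#'   per spatial axis (recycled from a scalar).  The default is an
#'   elongated trap, weak along the rod axis and stiff across it, which
#'   preserves the rod-like geometry of the ensemble.
#' @param repulsion_scale,repulsion_length Short-range pairwise repulsion
#'   (keeps molecules from collapsing onto each other).
#' @param chem_noise,motion_noise Diffusion amplitudes Gamma for the
#'   electrochemical and motion equations (increment covariance
#'   `2 * Gamma * dt`).
#' @param dt Integration step (time units).
#' @param t_total Total simulated time; must be >= `window`.
#' @param window Length of the final analysis window (default 512 time
#'   units for full-scale runs).
#' @param record_every Keep every `record_every`-th step (thinning).
#' @param seed Integer seed.
#' @return A `soup_config`.
#' @export
soup_config <- function(n_molecules = 9L,
                        lorenz = c(sigma = 10, rho = 28, beta = 8 / 3),
                        coupling_scale = 6, coupling_length = 1.5,
                        force_gain = 0.01, mixing = c(1, 0, 0),
                        damping = 1, container = c(0.02, 0.5),
                        repulsion_scale = 1, repulsion_length = 0.8,
                        chem_noise = 0.5, motion_noise = 0.005,
                        dt = 0.005, t_total = 640, window = 512,
                        record_every = 10L, seed = 1L) {
  cfg <- list(n_molecules = as.integer(n_molecules),
              lorenz = lorenz, coupling_scale = coupling_scale,
              coupling_length = coupling_length, force_gain = force_gain,
              mixing = mixing, damping = damping,
              container = rep_len(container, 2L),
              repulsion_scale = repulsion_scale,
              repulsion_length = repulsion_length,
              chem_noise = chem_noise, motion_noise = motion_noise,
              dt = dt, t_total = t_total, window = window,
              record_every = as.integer(record_every),
              seed = as.integer(seed))
  if (cfg$n_molecules < 4L) stopf("need at least 4 molecules")
  pos_scales <- c("coupling_length", "damping", "dt", "t_total", "window",
                  "repulsion_length")
  for (nm in pos_scales) if (cfg[[nm]] <= 0) stopf("%s must be > 0", nm)
  for (nm in c("coupling_scale", "force_gain", "repulsion_scale",
               "chem_noise", "motion_noise"))
    if (cfg[[nm]] < 0) stopf("%s must be >= 0", nm)
  if (any(cfg$container < 0)) stopf("container rates must be >= 0")
  if (cfg$t_total < cfg$window)
    stopf("t_total (%g) must cover the analysis window (%g)",
          cfg$t_total, cfg$window)
  structure(cfg, class = "soup_config")
}

#' @export
print.soup_config <- function(x, ...) {
  cat(sprintf("<soup_config> %d molecules, t_total = %g (window %g), dt = %g, seed = %d\n",
              x$n_molecules, x$t_total, x$window, x$dt, x$seed))
  cat(sprintf("  lorenz = (%g, %g, %g), coupling = %g @ length %g, force_gain = %g\n",
              x$lorenz[1], x$lorenz[2], x$lorenz[3],
              x$coupling_scale, x$coupling_length, x$force_gain))
  invisible(x)
}

# Lorenz drift for an n x 3 matrix of electrochemical states.
lorenz_drift <- function(C, p) {
  cbind(p[[1]] * (C[, 2] - C[, 1]),
        C[, 1] * (p[[2]] - C[, 3]) - C[, 2],
        C[, 1] * C[, 2] - p[[3]] * C[, 3])
}

# Deterministic initial layout: molecules on a line through the origin
# with spacing coupling_length (a small rod), plus a tiny fixed lateral
# offset so the geometry is genuinely 2-D.
soup_initial_positions <- function(cfg) {
  n <- cfg$n_molecules
  offs <- (seq_len(n) - (n + 1) / 2) * cfg$coupling_length
  cbind(offs, 0.05 * cfg$coupling_length * (-1)^(seq_len(n)))
}

#' Simulate the macromolecular soup
#'
#' Euler--Maruyama integration of the coupled electrochemical (Lorenz) and
#' Newtonian equations.  Each molecule consumes its own seeded noise
#' stream (derived from `config$seed`), so the decoupled limit
#' (`coupling_scale = 0`, `force_gain = 0`) reproduces isolated
#' single-molecule runs exactly.
#'
#' @param config A [soup_config()].
#' @return A `soup_state`: `times` (recorded), `positions`, `velocities`
#'   (`T x n x 2` arrays), `chem` (`T x n x 3`), `config`, `diverged`.
#' @export
simulate_soup <- function(config) {
  cfg <- config
  n <- cfg$n_molecules
  n_steps <- round(cfg$t_total / cfg$dt)
  rec_idx <- seq(0L, n_steps, by = cfg$record_every)
  n_rec <- length(rec_idx)

  # per-molecule noise streams (chem 3 + velocity 2 per step)
  noise <- vector("list", n)
  for (i in seq_len(n))
    noise[[i]] <- with_seed(derive_seed(cfg$seed, i),
                            matrix(stats::rnorm(n_steps * 5L), n_steps, 5L))

  # initial chem states near the attractor, jittered per molecule
  C <- matrix(0, n, 3)
  for (i in seq_len(n))
    C[i, ] <- c(1, 1, 25) + with_seed(derive_seed(cfg$seed, 100000L + i),
                                      stats::rnorm(3, sd = 2))
  X <- soup_initial_positions(cfg)
  V <- matrix(0, n, 2)

  sd_chem <- sqrt(2 * cfg$chem_noise * cfg$dt)
  sd_mot <- sqrt(2 * cfg$motion_noise * cfg$dt)
  w <- cfg$mixing
  two_cl2 <- 2 * cfg$coupling_length^2
  two_rl2 <- 2 * cfg$repulsion_length^2

  positions <- array(NA_real_, c(n_rec, n, 2))
  velocities <- array(NA_real_, c(n_rec, n, 2))
  chem <- array(NA_real_, c(n_rec, n, 3))
  rec <- 1L
  positions[1L, , ] <- X; velocities[1L, , ] <- V; chem[1L, , ] <- C
  diverged <- FALSE

  for (k in seq_len(n_steps)) {
    dx <- outer(X[, 1], X[, 1], `-`)   # dx[i,j] = x_i - x_j
    dy <- outer(X[, 2], X[, 2], `-`)
    D2 <- dx^2 + dy^2
    Dinv <- 1 / sqrt(D2 + 1e-12)
    K <- cfg$coupling_scale * exp(-D2 / two_cl2); diag(K) <- 0

    # electrochemical: Lorenz + diffusive distance-weighted coupling
    dC <- lorenz_drift(C, cfg$lorenz) + (K %*% C - rowSums(K) * C)

    # Newtonian forces: mixed chem differences through the coupling
    # kernel, along the inter-molecule axis; plus repulsion, damping,
    # containment
    p <- as.numeric(C %*% w)
    Smix <- outer(p, p, `-`)           # p_i - p_j
    Wf <- cfg$force_gain * K * Smix
    R <- cfg$repulsion_scale * exp(-D2 / two_rl2); diag(R) <- 0
    ux <- dx * Dinv; uy <- dy * Dinv
    Fx <- rowSums((Wf + R) * ux) - cfg$damping * V[, 1] -
      cfg$container[1] * X[, 1]
    Fy <- rowSums((Wf + R) * uy) - cfg$damping * V[, 2] -
      cfg$container[2] * X[, 2]

    nz <- matrix(NA_real_, n, 5L)
    for (i in seq_len(n)) nz[i, ] <- noise[[i]][k, ]

    C <- C + dC * cfg$dt + sd_chem * nz[, 1:3]
    V <- V + cbind(Fx, Fy) * cfg$dt + sd_mot * nz[, 4:5]
    X <- X + V * cfg$dt

    if (!all(is.finite(C)) || !all(is.finite(X)) ||
        max(abs(C)) > 1e6 || max(abs(X)) > 1e6) {
      diverged <- TRUE
      warnf("soup simulation diverged at step %d (t = %.3f); truncated",
            k, k * cfg$dt)
      break
    }
    if (rec < n_rec && k == rec_idx[rec + 1L]) {
      rec <- rec + 1L
      positions[rec, , ] <- X; velocities[rec, , ] <- V; chem[rec, , ] <- C
    }
  }
  keep <- seq_len(rec)
  structure(
    list(times = rec_idx[keep] * cfg$dt,
         positions = positions[keep, , , drop = FALSE],
         velocities = velocities[keep, , , drop = FALSE],
         chem = chem[keep, , , drop = FALSE],
         config = cfg, diverged = diverged),
    class = "soup_state")
}

#' @export
print.soup_state <- function(x, ...) {
  cat(sprintf("<soup_state> %d molecules, %d recorded samples over t = [0, %g]%s\n",
              dim(x$chem)[2], length(x$times), max(x$times),
              if (isTRUE(x$diverged)) " [TRUNCATED]" else ""))
  invisible(x)
}

# Indices of recorded samples inside the analysis window (final `window`
# time units, or the whole record if shorter).
analysis_window_idx <- function(state, window = NULL) {
  if (is.null(window)) window <- state$config$window
  tmax <- max(state$times)
  which(state$times >= tmax - window)
}

#' Partition soup molecules into blanket roles
#'
#' Deterministic rule based on time-averaged geometry: molecules are
#' ranked by the norm of their time-averaged position ("radial
#' position"); the `n_internal` innermost form the internal set; their
#' neighbours in the coupling graph (time-averaged distance below
#' `adjacency_radius`) are active; the active set's outward neighbours
#' are sensory; everything else is external.
#'
#' @param state A `soup_state`.
#' @param n_internal Number of internal molecules (default
#'   `max(1, floor(n / 4))`).
#' @param adjacency_radius Optional coupling-graph radius (edge when the
#'   time-averaged distance is below it).  By default the graph is
#'   instead the symmetrized 2-nearest-neighbour graph, which adapts to
#'   how far the ensemble has expanded or compressed.
#' @param window Analysis window for the time averages.
#' @return A `soup_partition`: `labels` (factor per molecule with levels
#'   internal/active/sensory/external), index vectors per role, and the
#'   derivation parameters.
#' @export
partition_soup <- function(state, n_internal = NULL, adjacency_radius = NULL,
                           window = NULL) {
  n <- dim(state$chem)[2]
  if (n < 4L) stopf("need at least 4 molecules to partition")
  if (is.null(n_internal)) n_internal <- max(1L, floor(n / 4))
  idx <- analysis_window_idx(state, window)
  P <- apply(state$positions[idx, , , drop = FALSE], c(2, 3), mean)
  D <- as.matrix(stats::dist(P))
  if (max(D) < 1e-9) stopf("degenerate geometry: all molecules coincide")
  radial <- sqrt(rowSums(P^2))
  ord <- order(radial, seq_len(n))  # deterministic tie-break by index
  internal <- sort(ord[seq_len(n_internal)])
  if (is.null(adjacency_radius)) {
    # symmetrized k-nearest-neighbour graph, k = 2
    Dna <- D; diag(Dna) <- Inf
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      nb <- order(Dna[i, ])[seq_len(min(2L, n - 1L))]
      adj[i, nb] <- TRUE
    }
    adj <- adj | t(adj)
    rule_id <- "radial-knn2"
  } else {
    adj <- D <= adjacency_radius & D > 0
    rule_id <- "radial-radius"
  }
  neigh <- function(set) sort(unique(which(rowSums(adj[, set, drop = FALSE]) > 0)))
  active <- setdiff(neigh(internal), internal)
  sensory <- setdiff(neigh(active), c(internal, active))
  external <- setdiff(seq_len(n), c(internal, active, sensory))
  if (length(external) == 0L)
    warnf("partition has no external molecules; increase n or reduce adjacency_radius")
  labels <- factor(rep("external", n),
                   levels = c("internal", "active", "sensory", "external"))
  labels[internal] <- "internal"; labels[active] <- "active"
  labels[sensory] <- "sensory"
  structure(
    list(labels = labels, internal = internal, active = active,
         sensory = sensory, external = external,
         derivation = list(rule = rule_id,
                           n_internal = n_internal,
                           adjacency_radius = adjacency_radius)),
    class = "soup_partition")
}

#' @export
print.soup_partition <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ",") else "-"
  cat(sprintf("<soup_partition> internal = {%s} active = {%s} sensory = {%s} external = {%s}\n",
              fmt(x$internal), fmt(x$active), fmt(x$sensory), fmt(x$external)))
  invisible(x)
}

#' Map a soup partition to a flat state partition over chem channels
#'
#' Flattens molecule-level labels onto the `3 * n` electrochemical state
#' vector (molecule `i` occupies channels `3i - 2 .. 3i`), giving a
#' [state_partition()] usable with the blanket-checking functions.
#'
#' @param spart A `soup_partition`.
#' @return A `state_partition` over `3 * n` channels.
#' @export
as_state_partition <- function(spart) {
  chan <- function(mols) as.integer(outer(1:3, (mols - 1L) * 3L, `+`))
  state_partition(eta = chan(spart$external), s = chan(spart$sensory),
                  a = chan(spart$active), mu = chan(spart$internal),
                  dim = 3L * length(spart$labels))
}

# Flattened channel matrices over the analysis window.
soup_channels <- function(state, molecules, what = c("chem", "velocity",
                                                     "position"),
                          window = NULL) {
  what <- match.arg(what)
  idx <- analysis_window_idx(state, window)
  arr <- switch(what, chem = state$chem, velocity = state$velocities,
                position = state$positions)
  ns <- dim(arr)[3]
  out <- matrix(NA_real_, length(idx), length(molecules) * ns)
  for (j in seq_along(molecules))
    out[, (j - 1L) * ns + seq_len(ns)] <- arr[idx, molecules[j], ]
  out
}

# Core CCA via SVD of the whitened cross-covariance.  Rank-deficient
# sides are reduced to their informative subspace with a warning.
cca_core <- function(X, Y, rank_tol = 1e-10) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  n <- nrow(Xc)
  Sxx <- crossprod(Xc) / (n - 1); Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  whiten <- function(S, side) {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    keep <- e$values > rank_tol * max(e$values)
    if (!all(keep))
      warnf("%s side is rank deficient; reduced from %d to %d dimensions",
            side, length(keep), sum(keep))
    e$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(e$values[keep]), sum(keep))
  }
  Wx <- whiten(Sxx, "internal"); Wy <- whiten(Syy, "external")
  Km <- t(Wx) %*% Sxy %*% Wy
  sv <- svd(Km)
  a <- Wx %*% sv$u; b <- Wy %*% sv$v
  # sign convention: first nonzero loading of each internal vector positive
  for (j in seq_len(ncol(a))) {
    nz <- which(abs(a[, j]) > 1e-12)[1]
    if (!is.na(nz) && a[nz, j] < 0) { a[, j] <- -a[, j]; b[, j] <- -b[, j] }
  }
  list(cor = pmin(pmax(sv$d, 0), 1), xcoef = a, ycoef = b,
       xcenter = attr(Xc, "scaled:center"), ycenter = attr(Yc, "scaled:center"))
}

#' Canonical correlation between internal chemistry and external motion
#'
#' Computes the canonical correlation analysis (CCA) between the internal
#' molecules' electrochemical channels and the external molecules' motion
#' channels over the analysis window.  The first canonical pair is the
#' maximally covarying linear combination on each side -- the raw
#' material of the synchronisation-manifold analysis.
#'
#' @param state A `soup_state`.
#' @param partition A `soup_partition`.
#' @param targets External-side signal: `"velocity"` (default) or
#'   `"position+velocity"`.
#' @param window Analysis window (time units).
#' @return A `sync_manifold` with `canonical_correlations` (descending,
#'   in `[0, 1]`), `internal_loadings`, `external_loadings`, the canonical
#'   variate time series `internal_variate`, `external_variate`, and
#'   `times`.
#' @export
cca_internal_external <- function(state, partition,
                                  targets = c("velocity",
                                              "position+velocity"),
                                  window = NULL) {
  targets <- match.arg(targets)
  if (length(partition$internal) < 2L || length(partition$external) < 2L)
    stopf("need at least 2 molecules on each side (internal %d, external %d)",
          length(partition$internal), length(partition$external))
  X <- soup_channels(state, partition$internal, "chem", window)
  Y <- soup_channels(state, partition$external, "velocity", window)
  if (targets == "position+velocity")
    Y <- cbind(Y, soup_channels(state, partition$external, "position", window))
  cc <- cca_core(X, Y)
  idx <- analysis_window_idx(state, window)
  structure(
    list(canonical_correlations = cc$cor,
         internal_loadings = cc$xcoef, external_loadings = cc$ycoef,
         internal_variate = as.numeric(scale(X, scale = FALSE) %*% cc$xcoef[, 1]),
         external_variate = as.numeric(scale(Y, scale = FALSE) %*% cc$ycoef[, 1]),
         times = state$times[idx], targets = targets,
         poly_order = NULL, ci_level = NULL),
    class = "sync_manifold")
}

#' @export
print.sync_manifold <- function(x, ...) {
  cat(sprintf("<sync_manifold> canonical correlations: %s\n",
              paste(sprintf("%.3f", utils::head(x$canonical_correlations, 5)),
                    collapse = ", ")))
  if (!is.null(x$poly_order))
    cat(sprintf("  polynomial order %d fit, residual sd %.3g (%.0f%% interval)\n",
                x$poly_order, x$residual_sd, 100 * x$ci_level))
  invisible(x)
}

#' Permutation null for the first canonical correlation
#'
#' Re-runs the CCA with the rows of one side randomly permuted,
#' destroying the temporal alignment while preserving each side's
#' marginal structure, and returns the null distribution of the first
#' canonical correlation.
#'
#' @param X,Y Centered data matrices (rows = time).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Numeric vector of `n_perm` null first correlations.
#' @export
cca_permutation_null <- function(X, Y, n_perm = 1000L, seed = 1L) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  n <- nrow(Xc)
  # whitening matrices are permutation-invariant; only Sxy changes
  Sxx <- crossprod(Xc) / (n - 1); Syy <- crossprod(Yc) / (n - 1)
  wh <- function(S) {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    keep <- e$values > 1e-10 * max(e$values)
    e$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(e$values[keep]), sum(keep))
  }
  Wx <- wh(Sxx); Wy <- wh(Syy)
  Xw <- Xc %*% Wx; Yw <- Yc %*% Wy
  with_seed(seed, {
    vapply(seq_len(n_perm), function(j) {
      p <- sample.int(n)
      max(svd(crossprod(Xw[p, , drop = FALSE], Yw) / (n - 1))$d)
    }, numeric(1))
  })
}

#' Fit the synchronisation manifold by polynomial regression
#'
#' Least-squares polynomial (default fifth order) predicting the external
#' canonical variate from the internal canonical variate, with pointwise
#' prediction intervals at level `ci`.  The fitted curve is the estimated
#' synchronisation manifold: the conditional expectation of external
#' motion given the internal electrochemical coordinate.
#'
#' @param manifold A `sync_manifold` from [cca_internal_external()], or
#'   `NULL` when supplying variates directly.
#' @param internal_variates,external_variates Optional explicit variates
#'   (default: taken from `manifold`).
#' @param order Polynomial order (default 5).
#' @param ci Prediction-interval level (default 0.90).
#' @return The manifold updated with `poly_order`, `poly_coefficients`,
#'   `fitted`, `pi_lower`, `pi_upper`, `residual_sd`, `ci_level`.
#' @export
fit_sync_manifold <- function(manifold = NULL, internal_variates = NULL,
                              external_variates = NULL, order = 5L,
                              ci = 0.90) {
  x <- internal_variates %||% manifold$internal_variate
  y <- external_variates %||% manifold$external_variate
  order <- as.integer(order)
  if (length(x) < order + 2L)
    stopf("need at least order + 2 = %d samples (got %d)", order + 2L,
          length(x))
  if (stats::sd(x) < 1e-12)
    stopf("internal variate is constant; synchronisation manifold undefined")
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    stats::lm(y ~ poly(x, degree = order), data = df),
    error = function(e) {
      warnf("ill-conditioned polynomial design (%s); falling back to raw powers with jitter",
            conditionMessage(e))
      df$x <- df$x + 1e-10 * stats::sd(y) * seq_along(df$x)
      stats::lm(y ~ poly(x, degree = order, raw = TRUE), data = df)
    })
  # predicting at the training abscissae is intentional here (pointwise
  # intervals along the manifold), so silence the "future responses" note
  pr <- suppressWarnings(
    stats::predict(fit, interval = "prediction", level = ci))
  out <- manifold %||% structure(list(internal_variate = x,
                                      external_variate = y),
                                 class = "sync_manifold")
  out$poly_order <- order
  out$poly_coefficients <- stats::coef(fit)
  out$fit <- fit
  out$fitted <- as.numeric(pr[, "fit"])
  out$pi_lower <- as.numeric(pr[, "lwr"])
  out$pi_upper <- as.numeric(pr[, "upr"])
  out$residual_sd <- stats::sigma(fit)
  out$ci_level <- ci
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Event-related averaging time-locked to canonical-variate peaks
#'
#' Selects the `n_events` largest local maxima of the internal canonical
#' variate (greedily, with an exclusion radius equal to the epoch length),
#' extracts epochs of the internal electrochemical channels and of the
#' external canonical variate around each event, and averages across
#' epochs -- the simulated analogue of an event-related potential.
#'
#' @param state A `soup_state`.
#' @param partition A `soup_partition`.
#' @param manifold A `sync_manifold` (provides the canonical variates and
#'   their time axis).
#' @param n_events Number of events (default 6).
#' @param window `c(pre, post)` epoch extent in time units around each
#'   event (default `c(1, 1)`).
#' @return An `erp_result`: `event_times`, `window`, `epoch_times`
#'   (relative), `epochs_internal` (`events x time x channels`),
#'   `epochs_external` (`events x time`), `average_internal`,
#'   `average_external`.  Fewer than `n_events` separable peaks yields a
#'   warning and a shorter result.
#' @export
erp_timelock <- function(state, partition, manifold, n_events = 6L,
                         window = c(1, 1)) {
  u <- manifold$internal_variate
  tt <- manifold$times
  dt_rec <- stats::median(diff(tt))
  pre_n <- round(window[1] / dt_rec); post_n <- round(window[2] / dt_rec)
  excl_n <- pre_n + post_n
  if (excl_n < 1L) stopf("epoch window is shorter than the recording step")

  # local maxima, excluding edges that cannot host a full epoch
  nmax <- length(u)
  cand <- which(diff(sign(diff(u))) == -2) + 1L
  cand <- cand[cand > pre_n & cand <= nmax - post_n]
  cand <- cand[order(u[cand], decreasing = TRUE)]
  events <- integer(0)
  for (i in cand) {
    if (length(events) == n_events) break
    if (all(abs(i - events) >= excl_n)) events <- c(events, i)
  }
  if (length(events) < n_events)
    warnf("only %d separable events found (requested %d)", length(events),
          n_events)
  if (length(events) == 0L) stopf("no separable canonical-variate peaks found")
  events <- sort(events)

  # internal chem rows aligned with the manifold's analysis window
  rows <- match(round(tt, 9), round(state$times, 9))
  if (anyNA(rows)) stopf("manifold time axis does not match the soup state")
  arr <- state$chem
  Xint <- matrix(NA_real_, length(rows), 3L * length(partition$internal))
  for (j in seq_along(partition$internal))
    Xint[, (j - 1L) * 3L + 1:3] <- arr[rows, partition$internal[j], ]
  len <- pre_n + post_n + 1L
  epochs_int <- array(NA_real_, c(length(events), len, ncol(Xint)))
  epochs_ext <- matrix(NA_real_, length(events), len)
  for (e in seq_along(events)) {
    span <- (events[e] - pre_n):(events[e] + post_n)
    epochs_int[e, , ] <- Xint[span, ]
    epochs_ext[e, ] <- manifold$external_variate[span]
  }
  structure(
    list(event_times = tt[events], window = window,
         epoch_times = dt_rec * ((-pre_n):post_n),
         epochs_internal = epochs_int, epochs_external = epochs_ext,
         average_internal = apply(epochs_int, c(2, 3), mean),
         average_external = colMeans(epochs_ext)),
    class = "erp_result")
}

#' @export
print.erp_result <- function(x, ...) {
  cat(sprintf("<erp_result> %d events at t = %s; epoch [-%g, +%g]\n",
              length(x$event_times),
              paste(sprintf("%.2f", x$event_times), collapse = ", "),
              x$window[1], x$window[2]))
  invisible(x)
}

#' Pointwise average of a stack of epochs
#'
#' @param epochs `events x time` matrix or `events x time x channels`
#'   array.
#' @return Average trace (vector or `time x channels` matrix).
#' @export
erp_average <- function(epochs) {
  if (length(dim(epochs)) == 3L) apply(epochs, c(2, 3), mean)
  else colMeans(epochs)
}
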