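# Coupled stochastic-Lorenz soup and its analysis pipeline.

mini_cfg <- function(seed = 1, ...) {
  args <- list(n_molecules = 9L, t_total = 30, window = 20, dt = 0.005,
               record_every = 10L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(soup_config, args)
}

test_that("soup config validates scales and window", {
  expect_error(soup_config(n_molecules = 3), "4 molecules")
  expect_error(soup_config(dt = 0), "dt")
  expect_error(soup_config(t_total = 100, window = 512), "window")
  expect_error(soup_config(coupling_scale = -1), "coupling_scale")
})

test_that("soup simulation is deterministic under its seed", {
  cfg <- mini_cfg(seed = 4, t_total = 5, window = 5)
  s1 <- simulate_soup(cfg)
  s2 <- simulate_soup(cfg)
  expect_identical(s1$chem, s2$chem)
  expect_identical(s1$positions, s2$positions)
  s3 <- simulate_soup(mini_cfg(seed = 5, t_total = 5, window = 5))
  expect_false(identical(s1$chem, s3$chem))
})

test_that("decoupled limit reproduces isolated per-molecule Lorenz runs", {
  cfg <- mini_cfg(seed = 6, t_total = 5, window = 5,
                  coupling_scale = 0, force_gain = 0)
  st <- simulate_soup(cfg)
  n_steps <- round(cfg$t_total / cfg$dt)

  # independent oracle: single-molecule Euler-Maruyama with the same
  # derived noise stream
  isolated_chem <- function(i) {
    nz <- with_seed(bayesmech:::derive_seed(cfg$seed, i),
                    matrix(rnorm(n_steps * 5L), n_steps, 5L))
    C <- c(1, 1, 25) + with_seed(bayesmech:::derive_seed(cfg$seed, 100000L + i),
                                 rnorm(3, sd = 2))
    sdc <- sqrt(2 * cfg$chem_noise * cfg$dt)
    out <- matrix(NA_real_, n_steps + 1L, 3); out[1, ] <- C
    for (k in seq_len(n_steps)) {
      dC <- c(10 * (C[2] - C[1]), C[1] * (28 - C[3]) - C[2],
              C[1] * C[2] - (8 / 3) * C[3])
      C <- C + dC * cfg$dt + sdc * nz[k, 1:3]
      out[k + 1L, ] <- C
    }
    out[seq(1L, n_steps + 1L, by = cfg$record_every), ]
  }
  for (i in c(1L, 5L, 9L))
    expect_equal(st$chem[, i, ], isolated_chem(i), tolerance = 1e-12)

  # cross-covariances between molecules are statistically zero
  x1 <- st$chem[, 1, 1]; x2 <- st$chem[, 7, 1]
  r <- cor(x1, x2)
  # crude effective sample size from lag-1 autocorrelation
  rho <- cor(x1[-1], x1[-length(x1)])
  neff <- length(x1) * (1 - rho) / (1 + rho)
  expect_lt(abs(r), 3 / sqrt(neff))
})

test_that("noiseless single-attractor dynamics match an RK4 oracle", {
  cfg <- soup_config(n_molecules = 4, coupling_scale = 0, force_gain = 0,
                     chem_noise = 0, motion_noise = 0, t_total = 0.5,
                     window = 0.5, dt = 0.001, record_every = 500L, seed = 7)
  st <- simulate_soup(cfg)
  lor <- function(u) c(10 * (u[2] - u[1]), u[1] * (28 - u[3]) - u[2],
                       u[1] * u[2] - 8 / 3 * u[3])
  u <- st$chem[1, 1, ]
  h <- 2e-4
  for (k in seq_len(0.5 / h)) {
    k1 <- lor(u); k2 <- lor(u + h / 2 * k1); k3 <- lor(u + h / 2 * k2)
    k4 <- lor(u + h * k3)
    u <- u + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_lt(max(abs(st$chem[nrow(st$chem), 1, ] - u)), 0.35)

  # first-order convergence: halving dt roughly halves the error
  errs <- vapply(c(0.002, 0.0005), function(dt) {
    cfg2 <- soup_config(n_molecules = 4, coupling_scale = 0, force_gain = 0,
                        chem_noise = 0, motion_noise = 0, t_total = 0.5,
                        window = 0.5, dt = dt,
                        record_every = round(0.5 / dt), seed = 7)
    st2 <- simulate_soup(cfg2)
    max(abs(st2$chem[nrow(st2$chem), 1, ] - u))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 2.5)
})

test_that("default mini run stays within the guard and keeps the window", {
  st <- simulate_soup(mini_cfg(seed = 1))
  expect_false(st$diverged)
  expect_lt(max(abs(st$chem)), 1e3)
  idx <- which(st$times >= max(st$times) - st$config$window)
  expect_gte(length(idx) * st$config$dt * st$config$record_every,
             st$config$window)
})

test_that("partition rule follows chain adjacency on a hand-placed rod", {
  # synthetic static state: 4 molecules on a line starting at the origin
  pos <- array(0, c(3, 4, 2))
  for (tt in 1:3) pos[tt, , 1] <- c(0, 1, 2, 3)
  fake <- structure(
    list(times = 0:2,
         positions = pos,
         velocities = array(0, c(3, 4, 2)),
         chem = array(rnorm(36), c(3, 4, 3)),
         config = soup_config(n_molecules = 4, t_total = 2, window = 2,
                              coupling_length = 1),
         diverged = FALSE),
    class = "soup_state")
  sp <- partition_soup(fake, n_internal = 1, adjacency_radius = 1.2)
  expect_equal(sp$internal, 1L)
  expect_equal(sp$active, 2L)
  expect_equal(sp$sensory, 3L)
  expect_equal(sp$external, 4L)

  # permutation equivariance: relabeling molecules permutes labels
  perm <- c(3L, 1L, 4L, 2L)   # old molecule k becomes new index perm[k]
  fake2 <- fake
  inv <- match(seq_len(4), perm)
  fake2$positions <- fake$positions[, inv, , drop = FALSE]
  fake2$chem <- fake$chem[, inv, , drop = FALSE]
  sp2 <- partition_soup(fake2, n_internal = 1, adjacency_radius = 1.2)
  expect_equal(as.character(sp2$labels[perm]), as.character(sp$labels))

  # degenerate geometry is rejected
  fake3 <- fake; fake3$positions[] <- 0
  expect_error(partition_soup(fake3), "degenerate")
})

test_that("soup partition passes a loose Gaussian blanket check on chem precision", {
  st <- simulate_soup(mini_cfg(seed = 2))
  sp <- partition_soup(st)
  part <- as_state_partition(sp)
  X <- bayesmech:::soup_channels(st, seq_len(9), "chem")
  P <- solve(cov(X) + diag(1e-8, 27))
  # normalise to partial correlations so blocks are comparable
  Dn <- diag(1 / sqrt(diag(P)))
  Pn <- Dn %*% P %*% Dn
  cross <- max(abs(Pn[part$mu, part$eta]))
  within <- max(abs(Pn[part$mu, part$b]), abs(Pn[part$eta, part$b]))
  # internal-external precision coupling is weak relative to the
  # couplings that flow through the blanket
  expect_lt(cross, within)
})

test_that("CCA recovers exact and noisy linear synchronisation", {
  set.seed(91)
  n <- 2000
  X <- matrix(rnorm(n * 4), n, 4)
  B <- matrix(rnorm(8), 4, 2)
  Y <- X %*% B                      # exact linear function
  cc <- bayesmech:::cca_core(X, Y)
  expect_gt(cc$cor[1], 1 - 1e-10)

  # known mixing plus noise at SNR 10: population first correlation
  b <- c(1, -1, 0.5, 0)
  sig2 <- as.numeric(crossprod(b))  # var of signal X b
  y <- X %*% b + rnorm(n, sd = sqrt(sig2 / 10))
  pop <- sqrt(sig2 / (sig2 + sig2 / 10))  # sqrt(SNR / (1 + SNR))
  cc2 <- bayesmech:::cca_core(X, as.matrix(y))
  expect_equal(cc2$cor[1], pop, tolerance = 0.02)

  # agreement with stats::cancor as an independent implementation
  Y2 <- cbind(y, rnorm(n))
  ref <- stats::cancor(X, Y2)
  cc3 <- bayesmech:::cca_core(X, Y2)
  expect_equal(cc3$cor[seq_along(ref$cor)], ref$cor, tolerance = 1e-6)
})

test_that("independent white-noise sides stay below the permutation null", {
  set.seed(92)
  X <- matrix(rnorm(3000 * 6), 3000, 6)
  Y <- matrix(rnorm(3000 * 6), 3000, 6)
  obs <- bayesmech:::cca_core(X, Y)$cor[1]
  null <- cca_permutation_null(X, Y, n_perm = 300, seed = 93)
  expect_lt(obs, quantile(null, 0.95))
})

test_that("synchronisation emerges across the blanket in default mini runs", {
  wins <- 0L
  for (sd in 1:3) {
    st <- simulate_soup(mini_cfg(seed = sd))
    sp <- partition_soup(st)
    sm <- cca_internal_external(st, sp)
    expect_true(all(diff(sm$canonical_correlations) <= 1e-12))
    expect_true(all(sm$canonical_correlations >= 0 &
                      sm$canonical_correlations <= 1))
    X <- bayesmech:::soup_channels(st, sp$internal, "chem")
    Y <- bayesmech:::soup_channels(st, sp$external, "velocity")
    null <- cca_permutation_null(X, Y, n_perm = 500, seed = sd)
    if (sm$canonical_correlations[1] > quantile(null, 0.95)) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("polynomial manifold fit recovers structure and intervals", {
  # exact linear relation at order 1: zero residual
  x <- seq(-1, 1, length.out = 100)
  m0 <- fit_sync_manifold(internal_variates = x, external_variates = 2 * x,
                          order = 1)
  expect_lt(m0$residual_sd, 1e-10)

  # cubic truth + noise, order 5: prediction-interval coverage near 0.90
  set.seed(94)
  cover <- replicate(30, {
    x <- runif(400, -2, 2)
    y <- x^3 - x + rnorm(400, sd = 0.1)
    mf <- fit_sync_manifold(internal_variates = x, external_variates = y,
                            order = 5, ci = 0.90)
    ynew <- x^3 - x + rnorm(400, sd = 0.1)
    mean(ynew >= mf$pi_lower & ynew <= mf$pi_upper)
  })
  expect_gt(mean(cover), 0.87)
  expect_lt(mean(cover), 0.93)

  expect_error(fit_sync_manifold(internal_variates = 1:4,
                                 external_variates = 1:4, order = 5),
               "samples")
  expect_error(fit_sync_manifold(internal_variates = rep(1, 50),
                                 external_variates = rnorm(50), order = 5),
               "constant")
})

test_that("manifold prediction is informative on a default mini run", {
  st <- simulate_soup(mini_cfg(seed = 3))
  sp <- partition_soup(st)
  sm <- fit_sync_manifold(cca_internal_external(st, sp))
  expect_equal(sm$poly_order, 5L)
  expect_lt(sm$residual_sd, sd(sm$external_variate))
})

test_that("event-related averaging is the exact pointwise mean of epochs", {
  # identical synthetic epochs: average equals any single epoch
  ep <- matrix(rep(sin(seq(0, 2 * pi, length.out = 50)), each = 6), 6, 50)
  expect_equal(erp_average(ep), ep[1, ])

  # template + noise across 6 epochs: averaging shrinks noise by 1/sqrt(6)
  set.seed(95)
  template <- 2 * sin(seq(0, 4 * pi, length.out = 400))
  epochs <- matrix(rep(template, each = 6), 6, 400) +
    matrix(rnorm(6 * 400), 6, 400)
  resid <- erp_average(epochs) - template
  se3 <- 3 * (1 / sqrt(6)) / sqrt(2 * 400)
  expect_lt(abs(sd(resid) - 1 / sqrt(6)), se3)
})

test_that("time-locked ERP extraction respects the exclusion radius", {
  st <- simulate_soup(mini_cfg(seed = 1))
  sp <- partition_soup(st)
  sm <- fit_sync_manifold(cca_internal_external(st, sp))
  erp <- erp_timelock(st, sp, sm, n_events = 6, window = c(1, 1))
  expect_lte(length(erp$event_times), 6L)
  if (length(erp$event_times) > 1)
    expect_true(all(diff(erp$event_times) >= 2 - 1e-9))
  expect_equal(erp$average_external, colMeans(erp$epochs_external))
  expect_equal(erp$average_internal,
               apply(erp$epochs_internal, c(2, 3), mean))

  # too-wide windows force fewer events, still separated
  expect_warning(
    erp2 <- erp_timelock(st, sp, sm, n_events = 6, window = c(5, 5)),
    "separable")
  expect_lt(length(erp2$event_times), 6L)
  if (length(erp2$event_times) > 1)
    expect_true(all(diff(erp2$event_times) >= 10 - 1e-9))
})

test_that("full pipeline is deterministic end-to-end under one seed", {
  run <- function() {
    st <- simulate_soup(mini_cfg(seed = 8, t_total = 25, window = 15))
    sp <- partition_soup(st)
    sm <- fit_sync_manifold(cca_internal_external(st, sp))
    # the short horizon hosts only 5 separable events; that is fine here
    erp <- suppressWarnings(erp_timelock(st, sp, sm))
    list(cc = sm$canonical_correlations, coef = sm$poly_coefficients,
         ev = erp$event_times, avg = erp$average_external)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1, r2)
})
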