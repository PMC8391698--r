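# Configuration and file I/O: JSON system specs, CSV trajectories, run
# manifests, deterministic test fixtures.
#
# Matrices are serialised row-major with an explicit `dim`; numbers are
# written at 17 significant digits so that doubles round-trip
# bit-identically through save/load.

mat_to_rows <- function(M) lapply(seq_len(nrow(M)), function(i) unname(M[i, ]))
rows_to_mat <- function(rows, dim) {
  M <- do.call(rbind, lapply(rows, as.numeric))
  if (!all(dim(M) == c(dim, dim))) stopf("matrix is not %d x %d", dim, dim)
  unname(M)
}

#' Save / load a Gaussian NESS system spec
#'
#' The spec is a JSON object with keys `dim`, `H` (row-major list of
#' rows), `Q`, `Gamma` (diagonal vector), `mean`.  Loading validates the
#' invariants and produces structured errors naming the failing one
#' (asymmetry magnitude of `Q`, offending eigenvalue of `H`).
#'
#' @param system A `gaussian_ness`.
#' @param path File path.
#' @return `save_system_spec` returns `path` invisibly;
#'   `load_system_spec` returns a `gaussian_ness`.
#' @export
save_system_spec <- function(system, path) {
  if (!inherits(system, "gaussian_ness"))
    stopf("only gaussian_ness systems are serialisable")
  obj <- list(dim = system$dim, H = mat_to_rows(system$H),
              Q = mat_to_rows(system$Q), Gamma = unname(system$gamma),
              mean = unname(system$mean))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_system_spec
#' @export
load_system_spec <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("dim", "H", "Q", "Gamma"))
    if (is.null(obj[[key]])) stopf("spec is missing required key '%s'", key)
  d <- as.integer(obj$dim)
  H <- rows_to_mat(obj$H, d)
  Q <- rows_to_mat(obj$Q, d)
  gamma <- as.numeric(unlist(obj$Gamma))
  mean <- if (is.null(obj$mean)) numeric(d) else as.numeric(unlist(obj$mean))
  gaussian_ness(H = H, Q = Q, Gamma = gamma, mean = mean)
}

#' Write / read a trajectory as CSV with a JSON manifest
#'
#' The CSV has a `time` column followed by `x1 .. xd`; the companion
#' `<path>.manifest.json` records seed, dt, integrator and package
#' version, so any output is reproducible from its manifest.
#'
#' @param traj A `ness_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory` returns `path` invisibly;
#'   `read_trajectory` returns a `ness_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states)
  names(df) <- c("time", paste0("x", seq_len(ncol(traj$states))))
  utils::write.csv(df, path, row.names = FALSE)
  manifest <- run_manifest(command = "integrate",
                           config = list(dt = traj$dt,
                                         integrator_id = traj$integrator_id),
                           seed = traj$seed, outputs = path)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  man_path <- paste0(path, ".manifest.json")
  man <- if (file.exists(man_path)) jsonlite::read_json(man_path) else list()
  structure(
    list(times = df$time,
         states = unname(as.matrix(df[, -1, drop = FALSE])),
         seed = man$seed %||% NA_integer_,
         dt = man$config$dt %||% stats::median(diff(df$time)),
         integrator_id = man$config$integrator_id %||% "unknown",
         diverged = FALSE),
    class = "ness_trajectory")
}

#' Run manifest
#'
#' A small provenance record written alongside every CLI output: the
#' command, a hash of its configuration, the seed, package version and
#' timestamp.
#'
#' @param command Command label.
#' @param config List of configuration values (hashed into the manifest).
#' @param seed Integer seed.
#' @param outputs Character vector of output paths.
#' @return A list suitable for JSON serialisation.
#' @export
run_manifest <- function(command, config, seed, outputs) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  list(command = command,
       config = config,
       config_hash = sprintf("sum%08x", sum(utf8ToInt(as.character(cfg_json)))),
       seed = seed,
       package_version = as.character(utils::packageVersion("bayesmech")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       outputs = outputs)
}

# ---- deterministic fixtures -------------------------------------------

# Random SPD matrix with a prescribed set of zero off-diagonal blocks
# (achieved by zeroing entries of a random symmetric matrix and bumping
# the diagonal, which cannot reintroduce cross-block coupling).
random_structured_spd <- function(d, zero_pairs = list(), scale = 0.5) {
  A <- matrix(stats::rnorm(d * d, sd = scale), d, d)
  S <- (A + t(A)) / 2
  for (pr in zero_pairs) { S[pr[[1]], pr[[2]]] <- 0; S[pr[[2]], pr[[1]]] <- 0 }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  S + diag(abs(min(ev)) + 1, d)
}

# Random antisymmetric matrix supported only on the allowed pairs.
structured_antisym <- function(d, allowed_pairs, scale = 0.5) {
  Q <- matrix(0, d, d)
  for (pr in allowed_pairs) for (i in pr[[1]]) for (j in pr[[2]]) {
    if (i < j) { v <- stats::rnorm(1, sd = scale); Q[i, j] <- v; Q[j, i] <- -v }
    if (i > j) { v <- stats::rnorm(1, sd = scale); Q[j, i] <- v; Q[i, j] <- -v }
  }
  Q
}

#' Build a deterministic test fixture
#'
#' Four kinds are available:
#' \describe{
#'   \item{`gaussian-blanket`}{A 6-state system (2 external, 1 sensory,
#'     1 active, 2 internal) satisfying the full sparse blanket form.}
#'   \item{`gaussian-counterexample-c1`}{A 4-state system whose flow
#'     constraint holds (autonomous states uncoupled from external
#'     states) while the blanket condition fails (`H[mu, eta] != 0`):
#'     solenoidal couplings are solved for so that the offending Jacobian
#'     blocks cancel exactly.}
#'   \item{`gaussian-counterexample-c2`}{A 4-state system whose blanket
#'     condition holds (`H[mu, eta] = 0`) while solenoidal coupling
#'     `Q[eta, mu] != 0` breaks the flow constraint.}
#'   \item{`soup-mini`}{A 9-molecule, short-horizon soup configuration
#'     that completes in well under a minute.}
#' }
#'
#' @param kind Fixture kind (see above).
#' @param seed Integer seed controlling the random draws.
#' @param dir Output directory (created if missing); if `NULL`, nothing
#'   is written and only the objects are returned.
#' @return List with `system` (or `config`), `partition`, and `path`
#'   (`NULL` when `dir` is `NULL`).
#' @export
make_fixture <- function(kind = c("gaussian-blanket",
                                  "gaussian-counterexample-c1",
                                  "gaussian-counterexample-c2",
                                  "soup-mini"),
                         seed = 1L, dir = NULL) {
  kind <- match.arg(kind)
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out_path <- if (is.null(dir)) NULL else file.path(dir, paste0(kind, ".json"))

  if (kind == "gaussian-blanket") {
    part <- state_partition(eta = 1:2, s = 3L, a = 4L, mu = 5:6, dim = 6L)
    res <- with_seed(seed, {
      H <- random_structured_spd(6L, zero_pairs = list(
        list(part$eta, part$a), list(part$eta, part$mu),
        list(part$s, part$mu)))
      Q <- structured_antisym(6L, allowed_pairs = list(
        list(part$eta, part$eta), list(part$eta, part$s),
        list(part$s, part$s), list(part$a, part$a),
        list(part$a, part$mu), list(part$mu, part$mu)))
      gamma <- stats::runif(6L, 0.5, 1.5)
      gaussian_ness(H, Q, gamma)
    })
    if (!is.null(out_path)) save_system_spec(res, out_path)
    return(list(system = res, partition = part, path = out_path))
  }

  if (kind %in% c("gaussian-counterexample-c1", "gaussian-counterexample-c2")) {
    part <- state_partition(eta = 1L, s = 2L, a = 3L, mu = 4L, dim = 4L)
    sys <- with_seed(seed, {
      gamma <- stats::runif(4L, 0.8, 1.2)
      if (kind == "gaussian-counterexample-c2") {
        H <- random_structured_spd(4L, zero_pairs = list(list(4L, 1L)))
        Q <- matrix(0, 4, 4)
        Q[1, 4] <- -0.7; Q[4, 1] <- 0.7   # Q[eta, mu] != 0
        Q[2, 3] <- 0.3; Q[3, 2] <- -0.3
      } else {
        # condition 1 without condition 2: start from a generic H with a
        # nonzero mu-eta block, then solve the solenoidal entries Q[4,1]
        # (mu-eta) and Q[3,1] (a-eta) so that J[mu,eta] = J[a,eta] = 0.
        H <- random_structured_spd(4L)
        if (abs(H[4, 1]) < 0.1) H[4, 1] <- H[1, 4] <- 0.3
        Q <- structured_antisym(4L, allowed_pairs = list(
          list(2L, 3L), list(2L, 4L), list(3L, 4L)))
        # J[4,1] = Q[4,1] H[1,1] + Q[4,2] H[2,1] + Q[4,3] H[3,1]
        #          + (Q[4,4] - gamma[4]) H[4,1]
        Q[4, 1] <- -(Q[4, 2] * H[2, 1] + Q[4, 3] * H[3, 1] -
                       gamma[4] * H[4, 1]) / H[1, 1]
        Q[1, 4] <- -Q[4, 1]
        # J[3,1] = Q[3,1] H[1,1] + Q[3,2] H[2,1] - gamma[3] H[3,1]
        #          + Q[3,4] H[4,1]
        Q[3, 1] <- -(Q[3, 2] * H[2, 1] - gamma[3] * H[3, 1] +
                       Q[3, 4] * H[4, 1]) / H[1, 1]
        Q[1, 3] <- -Q[3, 1]
      }
      gaussian_ness(H, Q, gamma)
    })
    if (!is.null(out_path)) save_system_spec(sys, out_path)
    return(list(system = sys, partition = part, path = out_path))
  }

  # soup-mini
  cfg <- soup_config(n_molecules = 9L, t_total = 30, window = 20,
                     dt = 0.005, record_every = 10L, seed = seed)
  if (!is.null(out_path)) {
    jsonlite::write_json(unclass(cfg), out_path, auto_unbox = TRUE,
                         digits = I(17))
  }
  list(config = cfg, path = out_path)
}

#' Load a soup configuration from JSON
#'
#' @param path JSON file written by [make_fixture()] or by hand.
#' @return A `soup_config`.
#' @export
load_soup_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(soup_config, obj[intersect(names(obj), names(formals(soup_config)))])
}
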