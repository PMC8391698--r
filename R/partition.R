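# Four-way state partitions: external (eta), sensory (s), active (a),
# internal (mu), with the derived groupings
#   blanket    b     = s + a
#   autonomous alpha = a + mu   (states not influenced by external states)
#   particular pi    = mu + b   (the states of the "particle")

#' Construct a four-way state partition
#'
#' Indices are 1-based positions in the state vector.  The four sets must
#' be pairwise disjoint and jointly cover `1:dim`; `eta` and `mu` must be
#' nonempty, and the blanket `b = union(s, a)` must be nonempty (either of
#' `s`, `a` individually may be empty).
#'
#' @param eta,s,a,mu Integer index vectors for external, sensory, active
#'   and internal states.
#' @param dim Total state dimension.
#' @return A `state_partition` with elements `eta`, `s`, `a`, `mu` and the
#'   derived `b`, `alpha`, `pi` (all sorted), plus `dim`.
#' @export
state_partition <- function(eta, s = integer(0), a = integer(0), mu, dim) {
  sets <- list(eta = as.integer(eta), s = as.integer(s),
               a = as.integer(a), mu = as.integer(mu))
  all_idx <- unlist(sets)
  if (anyDuplicated(all_idx))
    stopf("partition sets overlap at indices %s",
          paste(unique(all_idx[duplicated(all_idx)]), collapse = ", "))
  if (!setequal(all_idx, seq_len(dim)))
    stopf("partition must cover 1..%d exactly (got %d indices)",
          dim, length(all_idx))
  if (length(sets$eta) == 0L) stopf("external set eta must be nonempty")
  if (length(sets$mu) == 0L) stopf("internal set mu must be nonempty")
  b <- sort(c(sets$s, sets$a))
  if (length(b) == 0L)
    stopf("blanket b = union(s, a) must be nonempty")
  structure(
    list(eta = sort(sets$eta), s = sort(sets$s), a = sort(sets$a),
         mu = sort(sets$mu), b = b,
         alpha = sort(c(sets$a, sets$mu)),
         pi = sort(c(sets$mu, b)),
         dim = as.integer(dim)),
    class = "state_partition")
}

#' @export
print.state_partition <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ",") else "-"
  cat(sprintf("<state_partition> dim = %d\n", x$dim))
  cat(sprintf("  eta = {%s}  s = {%s}  a = {%s}  mu = {%s}\n",
              fmt(x$eta), fmt(x$s), fmt(x$a), fmt(x$mu)))
  cat(sprintf("  blanket b = {%s}  autonomous alpha = {%s}  particular pi = {%s}\n",
              fmt(x$b), fmt(x$alpha), fmt(x$pi)))
  invisible(x)
}

# Extract the (i, j) block of a matrix for two partition set names.
part_block <- function(M, part, i, j) {
  M[part[[i]], part[[j]], drop = FALSE]
}

# Apply a permutation perm (new index of old state k is perm[k]) to a
# partition; used by equivariance tests.
permute_partition <- function(part, perm) {
  state_partition(eta = sort(perm[part$eta]), s = sort(perm[part$s]),
                  a = sort(perm[part$a]), mu = sort(perm[part$mu]),
                  dim = part$dim)
}
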