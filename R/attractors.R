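# Attractors and attractor landscapes.
#
# An attractor is a periodic orbit of the synchronous dynamics, stored in
# canonical form: the cycle is rotated so that the lexicographically
# smallest state comes first. Two attractors are equal iff their canonical
# forms are identical. Restrictions of attractors to a gene prefix (used by
# the conservation criterion) may contain repeated states and are therefore
# "attractor-like" sequences: they share the canonical form and comparison
# machinery but are not guaranteed to be orbits of any network.

state_key <- function(bits) paste(bits, collapse = "")

#' Construct an attractor from a cycle of states
#'
#' @param states Integer 0/1 matrix, one row per state in temporal order.
#' @param canonicalize Rotate to canonical form (default). Canonicalization
#'   is idempotent and rotation-invariant.
#' @return An object of class `rbn_attractor` with fields `states`,
#'   `period`, and a cached comparison `key`.
#' @export
attractor <- function(states, canonicalize = TRUE) {
  states <- matrix(as.integer(states), nrow = nrow(states))
  if (canonicalize) states <- canonical_rotation(states)
  structure(list(states = states, period = nrow(states),
                 key = paste(apply(states, 1L, state_key), collapse = ";")),
            class = "rbn_attractor")
}

# Rotate the cycle so the full key sequence is lexicographically minimal.
# Robust to repeated rows (restricted sequences), where "smallest state
# first" alone would be ambiguous.
canonical_rotation <- function(states) {
  p <- nrow(states)
  if (p == 1L) return(states)
  keys <- apply(states, 1L, state_key)
  cand <- which(keys == min(keys))
  if (length(cand) > 1L) {
    full <- vapply(cand, function(r) {
      paste(keys[c(seq(r, p), seq_len(r - 1L))], collapse = ";")
    }, character(1))
    cand <- cand[which(full == min(full))[1L]]
  }
  r <- cand[1L]
  states[c(seq(r, p), seq_len(r - 1L)), , drop = FALSE]
}

#' @export
print.rbn_attractor <- function(x, ...) {
  cat("Attractor, period", x$period, "\n")
  for (t in seq_len(x$period)) cat(" ", state_key(x$states[t, ]), "\n")
  invisible(x)
}

#' Assemble an attractor landscape
#'
#' @param attractors List of [attractor()] objects (no shared states).
#' @param complete Whether the set was obtained by exhaustive enumeration
#'   (`TRUE`) or by sampling/search (`FALSE`).
#' @param basin_sizes Optional per-attractor basin sizes (complete
#'   landscapes only); they must partition the `2^N` states.
#' @return An object of class `rbn_landscape`.
#' @export
landscape <- function(attractors, complete = FALSE, basin_sizes = NULL) {
  structure(list(attractors = attractors, complete = complete,
                 basin_sizes = basin_sizes),
            class = "rbn_landscape")
}

#' @export
print.rbn_landscape <- function(x, ...) {
  cat("Attractor landscape:", length(x$attractors), "attractors",
      if (x$complete) "(complete)" else "(sampled)", "\n")
  invisible(x)
}

landscape_keys <- function(ls) vapply(ls$attractors, function(a) a$key, character(1))

#' Follow a trajectory to its attractor
#'
#' Iterates the synchronous dynamics from `s0`, recording visited states,
#' until a state repeats; the cycle between the two visits is the attractor.
#' Termination within `2^N` steps is guaranteed for deterministic dynamics,
#' so `max_steps` only matters when set below that bound.
#'
#' @param net An `rbn_network`.
#' @param s0 Initial 0/1 state vector.
#' @param max_steps Abort with a "transient-exceeded" error if no state
#'   repeats within this many steps (default `2^N`, capped at `1e6`).
#' @return List with `attractor` (canonical [attractor()]) and `transient`
#'   (number of steps before the cycle is entered).
#' @export
trajectory_to_attractor <- function(net, s0, max_steps = NULL) {
  n <- network_size(net)
  if (length(s0) != n)
    stop("state length ", length(s0), " does not match network size ", n)
  if (is.null(max_steps)) max_steps <- min(2^n, 1e6)
  if (max_steps < 1L) stop("max_steps must be at least 1")
  res <- rbn_traj_cpp(compile_network(net), as.integer(s0), as.integer(max_steps))
  if (!res$found)
    stop("transient-exceeded: no state revisited within ", max_steps, " steps")
  list(attractor = attractor(res$cycle), transient = res$transient)
}

#' Exhaustively enumerate the attractor landscape
#'
#' Visits all `2^N` states with a memoised state-to-attractor map and
#' returns the complete landscape with basin sizes. Only feasible for small
#' networks; larger ones must use [search_new_attractors()] or
#' [blind_search()].
#'
#' @param net An `rbn_network`.
#' @param exhaustive_limit Refuse networks with `N >=` this bound
#'   (default 25).
#' @return A complete `rbn_landscape` whose basin sizes sum to `2^N`.
#' @export
enumerate_attractors <- function(net, exhaustive_limit = 25L) {
  n <- network_size(net)
  if (n >= exhaustive_limit)
    stop("too-large-for-exhaustive: N = ", n, " >= ", exhaustive_limit,
         "; use search_new_attractors() or blind_search()")
  res <- rbn_enum_cpp(compile_network(net))
  atts <- lapply(res$cycles, attractor)
  ord <- order(vapply(atts, function(a) a$key, character(1)))
  landscape(atts[ord], complete = TRUE, basin_sizes = res$basin_sizes[ord])
}

#' Restrict an attractor to the first genes of the genome
#'
#' Projects every state of the cycle onto the `first_n` lowest-id gene
#' positions (e.g. the pre-duplication genome) and collapses the projected
#' sequence to its minimal repeating pattern. The result is an
#' attractor-like sequence used for conservation comparisons; it may repeat
#' states and need not be an orbit of any network.
#'
#' @param a An `rbn_attractor`.
#' @param first_n Number of leading gene positions to keep.
#' @return An `rbn_attractor` object over `first_n` genes (canonical form).
#' @export
restrict_attractor <- function(a, first_n) {
  if (first_n > ncol(a$states)) stop("first_n exceeds state length")
  proj <- a$states[, seq_len(first_n), drop = FALSE]
  attractor(minimal_period(proj))
}

# Reduce a periodic sequence of rows to one period of its minimal period.
minimal_period <- function(states) {
  p <- nrow(states)
  keys <- apply(states, 1L, state_key)
  for (q in seq_len(p)) {
    if (p %% q != 0L) next
    if (all(keys == keys[((seq_len(p) - 1L) %% q) + 1L]))
      return(states[seq_len(q), , drop = FALSE])
  }
  states
}
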