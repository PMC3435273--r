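# Perturbation-based attractor discovery for networks too large to
# enumerate, plus blind random-state audits.

#' Attractor-search configuration
#'
#' @param perturb_fraction Fraction of genes bit-flipped per trial (the
#'   perturbed subset is drawn without replacement; the count is
#'   `round(perturb_fraction * N)` rounded half-up, minimum 1).
#' @param relax_steps Relaxation window: a trial counts only if the
#'   trajectory closes a cycle entirely within this many steps.
#' @param trials_per_state Perturbation trials per attractor state.
#' @param D_max_new Stop after this many new attractors per network per
#'   search.
#' @param landscape_cap Maximum tracked attractors per network; previously
#'   tracked attractors are never evicted, only new additions are capped.
#' @param exhaustive_below Networks with `N` below this bound use exhaustive
#'   enumeration instead.
#' @return A list of class `rbn_search_config`.
#' @export
search_config <- function(perturb_fraction = 0.1, relax_steps = 60L,
                          trials_per_state = 20L, D_max_new = 10L,
                          landscape_cap = 500L, exhaustive_below = 25L) {
  structure(list(perturb_fraction = perturb_fraction,
                 relax_steps = as.integer(relax_steps),
                 trials_per_state = as.integer(trials_per_state),
                 D_max_new = as.integer(D_max_new),
                 landscape_cap = as.integer(landscape_cap),
                 exhaustive_below = as.integer(exhaustive_below)),
            class = "rbn_search_config")
}

#' Search for new attractors by perturbing tracked ones
#'
#' For each state of each tracked attractor, up to `trials_per_state`
#' trials: flip a random `perturb_fraction` subset of genes, relax for at
#' most `relax_steps` steps, and if a cycle closes within the window and is
#' not already tracked or found, record it. Every returned attractor is
#' step-closure-verified by construction (the cycle was observed). The
#' search stops after `D_max_new` finds.
#'
#' @param net An `rbn_network`.
#' @param tracked Non-empty `rbn_landscape` whose attractor states have the
#'   network's full width.
#' @param cfg A [search_config()].
#' @param compare_width Attractors are considered "new" iff their
#'   restriction to the first `compare_width` genes differs from every
#'   tracked/found one (default: full width).
#' @return List of new canonical `rbn_attractor`s (full width).
#' @export
search_new_attractors <- function(net, tracked, cfg = search_config(),
                                  compare_width = NULL) {
  if (length(tracked$attractors) == 0L) stop("tracked landscape is empty")
  n <- network_size(net)
  if (is.null(compare_width)) compare_width <- n
  enc <- compile_network(net)
  restrict_key <- function(a)
    if (compare_width == n) a$key else restrict_attractor(a, compare_width)$key
  known <- vapply(tracked$attractors, restrict_key, character(1))
  n_flip <- max(1L, as.integer(floor(cfg$perturb_fraction * n + 0.5)))
  found <- list()
  for (a in tracked$attractors) {
    for (t in seq_len(a$period)) {
      base <- a$states[t, ]
      for (trial in seq_len(cfg$trials_per_state)) {
        flip <- sample.int(n, n_flip)
        s <- base
        s[flip] <- 1L - s[flip]
        res <- rbn_relax_cpp(enc, as.integer(s), cfg$relax_steps)
        if (!res$found) next
        att <- attractor(res$cycle)
        k <- restrict_key(att)
        if (k %in% known) next
        known <- c(known, k)
        found <- c(found, list(att))
        if (length(found) >= cfg$D_max_new) return(found)
      }
    }
  }
  found
}

#' Blind attractor search from random initial states
#'
#' Follows full trajectories (no relaxation cap) from uniformly random
#' initial states, deduplicating the attractors reached.
#'
#' @param net An `rbn_network`.
#' @param n_samples Number of random initial states (at least 1).
#' @param max_steps Transient bound passed to the trajectory follower.
#' @return List with `count` (distinct attractors discovered), `curve`
#'   (non-decreasing integer vector: distinct attractors after each
#'   sample), and `attractors`.
#' @export
blind_search <- function(net, n_samples, max_steps = NULL) {
  if (n_samples < 1L) stop("n_samples must be at least 1")
  n <- network_size(net)
  if (is.null(max_steps)) max_steps <- min(2^n, 1e6)
  enc <- compile_network(net)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  atts <- list()
  curve <- integer(n_samples)
  for (i in seq_len(n_samples)) {
    s <- as.integer(runif(n) < 0.5)
    res <- rbn_traj_cpp(enc, s, as.integer(max_steps))
    if (res$found) {
      att <- attractor(res$cycle)
      if (is.null(seen[[att$key]])) {
        seen[[att$key]] <- TRUE
        atts[[length(atts) + 1L]] <- att
      }
    }
    curve[i] <- length(atts)
  }
  list(count = length(atts), curve = curve, attractors = atts)
}
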