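# Darwinian filters: attractor conservation (ACC), attractor innovation
# (AIC), and fitness-proportional replication.

#' Fitness specification for replication
#'
#' @param mode `"alpha"` (replication weight = horizontal gene-expression
#'   variability of the tracked landscape), `"S"` (weight
#'   `f = max(0, 1 - |S_annealed - 1|)`, so networks with sensitivity close
#'   to the critical value 1 replicate fastest and `f <= 0` networks do not
#'   replicate), or `"neutral"` (equal weights).
#' @param replication_threshold_fraction Replication happens only when the
#'   survivor count drops below this fraction of the nominal population size
#'   (default 1/2).
#' @return A list of class `rbn_fitness_spec`.
#' @export
fitness_spec <- function(mode = c("alpha", "S", "neutral"),
                         replication_threshold_fraction = 0.5) {
  structure(list(mode = match.arg(mode),
                 replication_threshold_fraction = replication_threshold_fraction),
            class = "rbn_fitness_spec")
}

# Core conservation machinery. `tracked` is the landscape of the network
# before the change; `net_after` may have grown. Returns ok plus, when the
# network grew, the conserved attractors re-expressed at full width (each
# tracked attractor's first state, padded with 0 for the new genes, is
# relaxed to its attractor, whose restriction must reproduce the tracked
# attractor bit-exactly and in the same cyclic order).
conserve_landscape <- function(tracked, net_after, max_steps = NULL) {
  n2 <- network_size(net_after)
  enc <- compile_network(net_after)
  atts <- tracked$attractors
  if (length(atts) == 0L) return(list(ok = TRUE, attractors = atts))
  w <- ncol(atts[[1L]]$states)
  if (n2 == w) {
    ok <- all(vapply(atts, function(a) rbn_closure_cpp(enc, a$states), logical(1)))
    return(list(ok = ok, attractors = if (ok) atts else NULL))
  }
  if (is.null(max_steps)) max_steps <- min(2^n2, 1e5)
  updated <- vector("list", length(atts))
  for (i in seq_along(atts)) {
    a <- atts[[i]]
    s0 <- c(a$states[1L, ], integer(n2 - w))
    res <- rbn_traj_cpp(enc, as.integer(s0), as.integer(max_steps))
    if (!res$found) return(list(ok = FALSE, attractors = NULL))
    full <- attractor(res$cycle)
    if (restrict_attractor(full, w)$key != a$key)
      return(list(ok = FALSE, attractors = NULL))
    updated[[i]] <- full
  }
  list(ok = TRUE, attractors = updated)
}

#' Attractor conservation criterion (ACC)
#'
#' `TRUE` iff every tracked attractor, restricted to the genes common to
#' before and after the change (all genes for point mutations, the first
#' `N` for duplications), is still an attractor of the new network with
#' identical states and cyclic order. Conservation is strict: a single-bit
#' discrepancy fails.
#'
#' @param tracked The network's tracked `rbn_landscape` before the change.
#' @param net_after The network after mutation or duplication.
#' @return Logical.
#' @export
acc_check <- function(tracked, net_after)
  conserve_landscape(tracked, net_after)$ok

#' Attractor innovation criterion (AIC)
#'
#' Applied at duplication events: `TRUE` iff the ACC passes and the
#' attractor search found at least one attractor not matching any tracked
#' attractor (comparison on the common gene prefix).
#'
#' @param tracked_before Tracked landscape before the duplication.
#' @param net_after The duplicated network.
#' @param search_result List of new attractors from
#'   [search_new_attractors()].
#' @return Logical.
#' @export
aic_check <- function(tracked_before, net_after, search_result)
  length(search_result) >= 1L && acc_check(tracked_before, net_after)

#' Fitness-proportional replication
#'
#' If the survivor count `M'` is at least
#' `replication_threshold_fraction * M0` the population passes through
#' unchanged. Otherwise survivor `i` contributes
#' `n_i = max(1, round(lambda * f_i))` total copies (the original included,
#' so no survivor is eliminated by rounding), with `lambda = M0 / sum(f)` so
#' the restored size is as close to `M0` as rounding allows. Daughters
#' inherit the mother's strain label.
#'
#' @param survivors List of networks that passed selection.
#' @param fitnesses Numeric vector of replication weights, one per survivor.
#' @param M0 Nominal population size.
#' @param spec A [fitness_spec()].
#' @param warn_env Internal: environment used to emit the all-zero-fitness
#'   warning at most once per run.
#' @return List with `networks` (possibly replicated) and `copies` (integer
#'   copy counts per survivor).
#' @export
replicate_survivors <- function(survivors, fitnesses, M0,
                                spec = fitness_spec(), warn_env = NULL) {
  m <- length(survivors)
  if (m < 1L) stop("cannot replicate an empty survivor set")
  if (m >= spec$replication_threshold_fraction * M0)
    return(list(networks = survivors, copies = rep(1L, m)))
  f <- pmax(fitnesses, 0)
  if (all(f == 0)) {
    if (is.null(warn_env) || !isTRUE(warn_env$warned_zero_fitness)) {
      warning("all survivors have zero fitness; falling back to neutral replication",
              call. = FALSE)
      if (!is.null(warn_env)) warn_env$warned_zero_fitness <- TRUE
    }
    f <- rep(1, m)
  }
  lambda <- M0 / sum(f)
  copies <- pmax(1L, as.integer(floor(lambda * f + 0.5)))
  list(networks = rep(survivors, times = copies), copies = copies)
}

#' Extinction status of a survivor set
#'
#' @param survivors List (possibly empty) of surviving networks.
#' @return `"extinct"` when empty, `"alive"` otherwise.
#' @export
extinction_check <- function(survivors)
  if (length(survivors) == 0L) "extinct" else "alive"

# Replication weight of one network under a fitness spec.
network_fitness <- function(net, tracked, spec) {
  switch(spec$mode,
         alpha = {
           if (is.null(tracked) || length(tracked$attractors) == 0L)
             stop("alpha-fitness undefined: network has an empty tracked landscape")
           landscape_alpha_h(tracked)
         },
         S = max(0, 1 - abs(annealed_sensitivity(net) - 1)),
         neutral = 1)
}
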