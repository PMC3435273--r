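# Criticality and phenotype statistics.

#' Network sensitivity (order parameter of the order-chaos transition)
#'
#' Two estimates are returned. The annealed sensitivity is
#' `S = 2 * K * p * (1 - p)` where `K` is the mean number of distinct
#' regulators per gene and `p` is the fraction of 1-outputs pooled over all
#' truth-table entries of the network. The exact sensitivity averages, over
#' genes, the Boolean-function average sensitivity: the expected number of
#' input coordinates whose flip changes the output, inputs uniform.
#' `S < 1` is ordered, `S > 1` chaotic, `S = 1` critical.
#'
#' @param net An `rbn_network`.
#' @return List of class `rbn_sensitivity` with `S_annealed`, `S_exact`,
#'   `K_mean`, `p_mean`, and `p_pooling = "network"` (the pooling
#'   convention, recorded for reporting).
#' @export
sensitivity <- function(net) {
  k <- in_degrees(net)
  all_tt <- unlist(lapply(net$genes, function(g) g$tt))
  p_bar <- mean(all_tt)
  s_ex <- mean(vapply(net$genes, function(g) {
    kk <- length(unique(g$bs))
    acts <- vapply(seq_len(kk), function(pos) {
      bit <- bitwShiftL(1L, pos - 1L)
      idx <- seq_along(g$tt) - 1L
      mean(g$tt[idx + 1L] != g$tt[bitwXor(idx, bit) + 1L])
    }, numeric(1))
    sum(acts)
  }, numeric(1)))
  structure(list(S_annealed = 2 * mean(k) * p_bar * (1 - p_bar),
                 S_exact = s_ex, K_mean = mean(k), p_mean = p_bar,
                 p_pooling = "network"),
            class = "rbn_sensitivity")
}

# Annealed S only (census fast path; avoids the exact-sensitivity sweep).
annealed_sensitivity <- function(net) {
  k <- mean(vapply(net$genes, function(g) length(unique(g$bs)), numeric(1)))
  tt <- unlist(lapply(net$genes, function(g) g$tt))
  p <- mean(tt)
  2 * k * p * (1 - p)
}

#' @export
print.rbn_sensitivity <- function(x, ...) {
  cat(sprintf("S_annealed = %.4f  S_exact = %.4f  (K = %.3f, p = %.3f)\n",
              x$S_annealed, x$S_exact, x$K_mean, x$p_mean))
  invisible(x)
}

#' Derrida map of a network
#'
#' For each initial Hamming distance `d` in `1..N`, samples `n_pairs` state
#' pairs at that distance, advances each one synchronous step and records
#' the mean resulting normalised distance. The slope at the origin (least
#' squares through the smallest distances, intercept 0) estimates the
#' sensitivity: a curve tangent to the identity at the origin diagnoses
#' criticality.
#'
#' @param net An `rbn_network`.
#' @param n_pairs Sampled pairs per distance.
#' @param fit_frac Distances with `d/N <= fit_frac` enter the slope fit
#'   (at least the smallest distance is always used).
#' @return List of class `rbn_derrida` with `points` (data frame `d`,
#'   `d_next`, both normalised, including the fixed point (0,0)) and
#'   `slope_at_origin`.
#' @export
derrida_map <- function(net, n_pairs = 200L, fit_frac = 0.1) {
  if (n_pairs < 1L) stop("n_pairs must be at least 1")
  n <- network_size(net)
  d_next <- rbn_derrida_cpp(compile_network(net), as.integer(n_pairs))
  d <- seq_len(n) / n
  use <- which(d <= fit_frac)
  if (length(use) == 0L) use <- 1L
  slope <- sum(d[use] * d_next[use]) / sum(d[use]^2)
  structure(list(points = data.frame(d = c(0, d), d_next = c(0, d_next)),
                 slope_at_origin = slope, n_pairs = n_pairs),
            class = "rbn_derrida")
}

alpha_of <- function(n1, method = c("gini", "min")) {
  method <- match.arg(method)
  if (method == "gini") 2 * n1 * (1 - n1) else pmin(n1, 1 - n1)
}

#' Gene-expression variability of an attractor landscape
#'
#' The variability `alpha(n0, n1)` of a set of binary values with fractions
#' `n0` of 0s and `n1` of 1s is 0 when the set is frozen in one state and
#' maximal (0.5 under the default convention `alpha = 2 n0 n1`) when
#' balanced. Horizontal variability measures each attractor state across
#' genes, then averages over the states of the cycle and over attractors;
#' vertical variability measures each gene across the cycle, then averages
#' over genes and attractors. A cycle alternating between the all-ones and
#' all-zeros states has `alpha_h = 0` but `alpha_v = 0.5`: the two measures
#' capture different things.
#'
#' @param ls An `rbn_landscape` (non-empty).
#' @param method `"gini"` for `alpha = 2 n0 n1` (default) or `"min"` for
#'   `alpha = min(n0, n1)`.
#' @return List of class `rbn_variability` with `alpha_h`, `alpha_v`, `n0`,
#'   `n1` (average fractions of 0s and 1s over all attractor states).
#' @export
variability <- function(ls, method = c("gini", "min")) {
  method <- match.arg(method)
  if (length(ls$attractors) == 0L) stop("empty landscape: variability undefined")
  per_att <- vapply(ls$attractors, function(a) {
    st <- a$states
    ah <- mean(alpha_of(rowMeans(st), method))
    av <- mean(alpha_of(colMeans(st), method))
    c(ah, av, mean(st))
  }, numeric(3))
  structure(list(alpha_h = mean(per_att[1L, ]),
                 alpha_v = mean(per_att[2L, ]),
                 n1 = mean(per_att[3L, ]), n0 = 1 - mean(per_att[3L, ]),
                 method = method),
            class = "rbn_variability")
}

#' Per-attractor variability profile of a population
#'
#' Pools the horizontal and vertical variability of every tracked attractor
#' of every network, the unit on which variability histograms are drawn.
#'
#' @param population An `rbn_population`.
#' @param method Passed to [variability()].
#' @return Data frame with columns `network`, `alpha_h`, `alpha_v`.
#' @export
population_variability <- function(population, method = "gini") {
  rows <- lapply(seq_along(population$networks), function(i) {
    ls <- population$landscapes[[i]]
    if (is.null(ls) || length(ls$attractors) == 0L) return(NULL)
    vals <- vapply(ls$attractors, function(a) {
      v <- variability(landscape(list(a)), method)
      c(v$alpha_h, v$alpha_v)
    }, numeric(2))
    data.frame(network = i, alpha_h = vals[1L, ], alpha_v = vals[2L, ])
  })
  do.call(rbind, rows)
}

#' In/out degree statistics of a network
#'
#' Degrees count distinct regulators (in) and distinct targets (out); the
#' two sums are equal because each distinct regulatory edge contributes one
#' to each.
#'
#' @param net An `rbn_network`.
#' @return List with `in_degree`, `out_degree` (per-gene vectors in id
#'   order), `in_hist`, `out_hist` (tabulated counts named by degree), and
#'   `max_out_degree`.
#' @export
degree_stats <- function(net) {
  ind <- in_degrees(net)
  outd <- out_degrees(net)
  list(in_degree = ind, out_degree = outd,
       in_hist = table(ind), out_hist = table(outd),
       max_out_degree = max(outd))
}

#' Link persistence across a population
#'
#' For populations sharing an id space (a common lineage), returns the
#' matrix `F` whose entry `(i, j)` is the fraction of networks containing
#' the regulatory edge from gene `i` to gene `j`.
#'
#' @param population An `rbn_population` or a plain list of networks.
#' @return Numeric matrix with rownames/colnames the union of gene ids.
#' @export
link_persistence <- function(population) {
  nets <- if (inherits(population, "rbn_population")) population$networks
          else population
  all_ids <- sort(unique(unlist(lapply(nets, network_ids))))
  f <- matrix(0, length(all_ids), length(all_ids),
              dimnames = list(all_ids, all_ids))
  for (net in nets) {
    for (g in net$genes)
      for (r in unique(g$bs))
        f[as.character(r), as.character(g$id)] <-
          f[as.character(r), as.character(g$id)] + 1
  }
  f / length(nets)
}
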