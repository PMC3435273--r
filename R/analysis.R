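# Post-hoc analyses: de novo critical controls, gene-knockout robustness,
# and the seeded-hub experiment.

#' De novo critical ensemble
#'
#' Random networks built to sit exactly at the order-chaos phase boundary
#' (`K = 2`, `p = 0.5`, hence annealed sensitivity 1) with no evolutionary
#' history; the standard control against which evolved populations are
#' compared.
#'
#' @param M Number of networks.
#' @param N Genes per network.
#' @param exhaustive_below Landscapes are enumerated when
#'   `N < exhaustive_below`, otherwise discovered by [blind_search()].
#' @param blind_samples Samples per network for the blind search fallback.
#' @return An `rbn_population` with complete (or sampled) landscapes and
#'   strains `1..M`.
#' @export
de_novo_critical_ensemble <- function(M, N, exhaustive_below = 25L,
                                      blind_samples = 2000L) {
  nets <- vector("list", M)
  lands <- vector("list", M)
  for (i in seq_len(M)) {
    net <- random_network(N, 2L, 0.5)
    net$strain <- i
    nets[[i]] <- net
    lands[[i]] <- if (N < exhaustive_below) enumerate_attractors(net, exhaustive_below)
                  else landscape(blind_search(net, blind_samples)$attractors,
                                 complete = FALSE)
  }
  structure(list(networks = nets, landscapes = lands, strains = seq_len(M),
                 generation = 0L),
            class = "rbn_population")
}

#' Knock out one gene
#'
#' Structural removal: the gene is deleted and every target's truth table
#' collapses by the rule-4 convention (keeping only the entries where the
#' deleted regulator is 0). A knockout that would leave some target with no
#' regulators is inadmissible and returns a skip status instead of a
#' network. The alternative `method = "clamp"` keeps the gene but freezes
#' it at 0 (constant-0 truth table), preserving `N`.
#'
#' @param net An `rbn_network`.
#' @param gene_id Gene to remove.
#' @param method `"remove"` (default) or `"clamp"`.
#' @return List of class `rbn_knockout` with `status` (`"ok"` or
#'   `"inadmissible"`), `net` (the reduced network, or `NULL`), `gene_id`,
#'   and `blocked` (targets that would be orphaned).
#' @export
knockout <- function(net, gene_id, method = c("remove", "clamp")) {
  method <- match.arg(method)
  ids <- network_ids(net)
  if (!(gene_id %in% ids)) stop("no gene with id ", gene_id)
  if (method == "clamp") {
    g <- gene_by_id(net, gene_id)
    g$tt <- rep(0L, length(g$tt))
    return(structure(list(status = "ok", net = set_gene(net, g),
                          gene_id = gene_id, blocked = integer(0)),
                     class = "rbn_knockout"))
  }
  tgt <- setdiff(targets_of(net, gene_id), gene_id)
  blocked <- tgt[vapply(tgt, function(t)
    identical(unique(gene_by_id(net, t)$bs), as.integer(gene_id)), logical(1))]
  if (length(blocked) > 0L)
    return(structure(list(status = "inadmissible", net = NULL,
                          gene_id = gene_id, blocked = blocked),
                     class = "rbn_knockout"))
  genes <- list()
  for (g in net$genes) {
    if (g$id == gene_id) next
    if (gene_id %in% g$bs) {
      pos <- reg_pos(g, gene_id)
      g$tt <- tt_collapse(g$tt, pos)
      g$bs <- g$bs[g$bs != gene_id]
    }
    genes[[length(genes) + 1L]] <- g
  }
  structure(list(status = "ok",
                 net = boolean_network(genes, strain = net$strain,
                                       parent = net$parent),
                 gene_id = gene_id, blocked = integer(0)),
            class = "rbn_knockout")
}

# Is the restriction of attractor `a` (full width) to the genes remaining
# after deleting position `drop_pos` still an attractor of `net_ko`?
restricted_conserved <- function(a, drop_pos, enc_ko) {
  proj <- a$states[, -drop_pos, drop = FALSE]
  red <- minimal_period(proj)
  keys <- apply(red, 1L, state_key)
  if (anyDuplicated(keys)) return(FALSE)  # cannot be a deterministic orbit
  rbn_closure_cpp(enc_ko, red)
}

#' Knockout robustness profile P(q) of a population
#'
#' For every admissible (network, gene) pair, deletes the gene, tests each
#' tracked attractor (restricted to the remaining genes) for bit-exact
#' conservation, and records the percentage `q` of conserved attractors.
#' Returns the normalised histogram `P(q)` over the 101 integer percentage
#' bins `0..100`.
#'
#' @param population An `rbn_population` whose networks carry tracked
#'   landscapes.
#' @param method Knockout semantics, passed to [knockout()].
#' @return List of class `rbn_robustness` with `P` (named numeric vector,
#'   `sum(P) = 1`), `q_values` (raw percentages), `n_knockouts`,
#'   `n_skipped`.
#' @export
robustness_pq <- function(population, method = "remove") {
  qs <- numeric(0)
  skipped <- 0L
  for (i in seq_along(population$networks)) {
    net <- population$networks[[i]]
    tracked <- population$landscapes[[i]]
    if (length(tracked$attractors) == 0L) next
    ids <- network_ids(net)
    for (gid in ids) {
      ko <- knockout(net, gid, method = method)
      if (ko$status != "ok") {
        skipped <- skipped + 1L
        next
      }
      if (method == "remove") {
        drop_pos <- match(gid, ids)
        enc <- compile_network(ko$net)
        cons <- vapply(tracked$attractors, restricted_conserved,
                       logical(1), drop_pos = drop_pos, enc_ko = enc)
      } else {
        enc <- compile_network(ko$net)
        cons <- vapply(tracked$attractors, function(a)
          rbn_closure_cpp(enc, a$states), logical(1))
      }
      qs <- c(qs, 100 * sum(cons) / length(cons))
    }
  }
  bins <- tabulate(round(qs) + 1L, nbins = 101L)
  p <- bins / sum(bins)
  names(p) <- 0:100
  structure(list(P = p, q_values = qs, n_knockouts = length(qs),
                 n_skipped = skipped),
            class = "rbn_robustness")
}

#' Seeded-hub experiment
#'
#' Builds an initial population in which every network contains one
#' designated gene regulating `hub_out_fraction` of the other genes, runs
#' the evolutionary process, and reports what became of the initial hub:
#' its final out-degree rank per network and the link persistence of its
#' original out-edges compared with the most persistent links overall.
#'
#' @param cfg An [evolution_config()].
#' @param hub_out_fraction Fraction of the other genes the seeded hub
#'   regulates initially (0.8 at `N = 10` gives 8 targets).
#' @return List of class `rbn_hub_report` with `run`, `hub_id`,
#'   `hub_initial_out`, `hub_edges` (initial out-edges of the hub),
#'   `hub_edge_persistence`, `top_decile_persistence`, `final_hub_rank`
#'   (per final network: rank of the seeded hub's out-degree, 1 = largest),
#'   `argmax_out` (per final network: id of its highest-out-degree gene).
#' @export
seeded_hub_experiment <- function(cfg, hub_out_fraction = 0.8) {
  set.seed(cfg$seed)
  hub_id <- 1L
  n_targets <- as.integer(ceiling(hub_out_fraction * (cfg$N0 - 1L)))
  nets <- vector("list", cfg$M0)
  lands <- vector("list", cfg$M0)
  others <- setdiff(seq_len(cfg$N0), hub_id)
  tg <- sort(others[sample.int(length(others), n_targets)])  # shared hub wiring
  for (i in seq_len(cfg$M0)) {
    net <- random_network(cfg$N0, cfg$K0, cfg$p0,
                          k_max = cfg$mutation$k_max,
                          allow_self = cfg$mutation$allow_self)
    for (t in tg) {
      gt <- gene_by_id(net, t)
      if (hub_id %in% gt$bs) next
      res <- gene_add_bs(gt, hub_id, cfg$mutation$k_max)
      if (!is.null(res)) net <- set_gene(net, res$g)
    }
    net$strain <- i
    nets[[i]] <- net
    lands[[i]] <- cache_alpha(enumerate_attractors(net, cfg$search$exhaustive_below))
  }
  pop <- structure(list(networks = nets, landscapes = lands,
                        strains = seq_len(cfg$M0), generation = 0L),
                   class = "rbn_population")
  hub_edges <- cbind(from = hub_id, to = tg)
  run <- run_evolution(cfg, initial_population = pop)
  fin <- run$population
  pers <- link_persistence(fin)
  edge_p <- apply(hub_edges, 1L, function(e)
    pers[as.character(e[1L]), as.character(e[2L])])
  present <- pers[pers > 0]
  top_dec <- if (length(present) > 0)
    mean(present[present >= stats::quantile(present, 0.9)]) else NA_real_
  ranks <- vapply(fin$networks, function(net) {
    outs <- out_degrees(net)
    as.integer(rank(-outs, ties.method = "min")[as.character(hub_id)])
  }, integer(1))
  argmax <- vapply(fin$networks, function(net) {
    outs <- out_degrees(net)
    as.integer(names(outs)[which.max(outs)])
  }, integer(1))
  structure(list(run = run, hub_id = hub_id,
                 hub_initial_out = nrow(hub_edges), hub_edges = hub_edges,
                 hub_edge_persistence = edge_p,
                 top_decile_persistence = top_dec,
                 final_hub_rank = ranks, argmax_out = argmax),
            class = "rbn_hub_report")
}
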