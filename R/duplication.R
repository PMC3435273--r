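# Gene duplication followed by divergence: the network-growth mechanism.

#' Duplicate one gene and let the copy diverge
#'
#' A random parent gene is duplicated; the copy receives the next unused id
#' (ids are never reused, so the first `N` positions always identify the
#' pre-duplication genome). Two modes, equally likely by default:
#'
#' * mode A: the copy duplicates with its own regulatory region, inheriting
#'   the parent's binding sites, truth table and targets;
#' * mode B: the copy is inserted into the transcription unit of a random
#'   host gene `j`, inheriting `j`'s binding sites and truth table but the
#'   parent's targets (`j` itself is untouched).
#'
#' Every target of the new gene extends its truth table by the rule-2
#' convention (entries with the new gene = 0 keep the old outputs verbatim),
#' so clamping the new gene to 0 reproduces the old dynamics on the first
#' `N` genes exactly. Divergence then applies `divergence_events` mutations
#' to the copy (coding with probability `p_coding`, else regulatory).
#'
#' @param net An `rbn_network` with fewer than `n_max` genes.
#' @param cfg A [mutation_config()] (governs divergence and the rule-2
#'   ceiling).
#' @param n_max Growth cap; at `N = n_max` a condition of class
#'   `rbn_growth_cap` is signalled.
#' @param p_mode_a Probability of mode A.
#' @param divergence_events Number of divergence mutations applied to the
#'   copy (default 1).
#' @return List with `net` (grown network), `new_id`, and `record` (parent,
#'   mode, host, divergence record).
#' @export
duplicate_gene <- function(net, cfg = mutation_config(), n_max = 100L,
                           p_mode_a = 0.5, divergence_events = 1L) {
  n <- network_size(net)
  if (n >= n_max)
    stop(structure(class = c("rbn_growth_cap", "error", "condition"),
                   list(message = sprintf("growth-cap: network already at N_max = %d", n_max),
                        call = sys.call())))
  ids <- network_ids(net)
  parent_id <- ids[sample.int(n, 1L)]
  parent <- gene_by_id(net, parent_id)
  new_id <- max(ids) + 1L
  mode_a <- runif(1) < p_mode_a
  host_id <- NA_integer_
  if (mode_a) {
    template <- parent
  } else {
    host_id <- ids[sample.int(n, 1L)]     # parent may equal host
    template <- gene_by_id(net, host_id)
  }
  copy <- gene(new_id, template$bs, template$tt)
  net$genes <- c(net$genes, list(copy))   # new id is the largest: stays sorted

  # the copy inherits the parent's targets: each extends its table (rule 2)
  for (t in targets_of(net, parent_id)) {
    if (t == new_id) next
    gt <- gene_by_id(net, t)
    res <- gene_add_bs(gt, new_id, cfg$k_max)   # always rule 2 (new regulator)
    if (!is.null(res)) net <- set_gene(net, res$g)
  }

  div <- vector("list", divergence_events)
  for (i in seq_len(divergence_events)) {
    res <- if (runif(1) < cfg$p_coding) mutate_coding(net, new_id, cfg)
           else mutate_regulatory(net, new_id, cfg)
    net <- res$net
    div[[i]] <- res$record
  }
  list(net = net, new_id = new_id,
       record = list(parent = parent_id,
                     mode = if (mode_a) "A" else "B",
                     host = host_id, divergence = div))
}

#' Simultaneous duplication-divergence event for a population
#'
#' Applies [duplicate_gene()] to every network; networks already at the
#' growth cap are left unchanged (the event is a no-op for them). With the
#' default duplication period of 2000 generations and `N <= 100`, the
#' effective duplication rate is of order `1e-5` per gene per generation.
#'
#' @param population An `rbn_population`.
#' @param cfg A [mutation_config()].
#' @param n_max Growth cap.
#' @return List with `population` (networks grown; landscapes untouched) and
#'   `records` (per-network duplication records; `NULL` where capped).
#' @export
population_duplication_event <- function(population, cfg = mutation_config(),
                                         n_max = 100L) {
  records <- vector("list", length(population$networks))
  for (i in seq_along(population$networks)) {
    net <- population$networks[[i]]
    if (network_size(net) >= n_max) next
    res <- duplicate_gene(net, cfg, n_max = n_max)
    population$networks[[i]] <- res$net
    records[[i]] <- res$record
  }
  list(population = population, records = records)
}
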