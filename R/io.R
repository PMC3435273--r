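# Readers and writers. Network JSON schema:
#   {"genes": [{"id": int, "binding_sites": [int, ...],
#               "truth_table": [0/1, ...]}, ...],
#    "meta": {"strain": int|null, "parent": ..., "format": "rbn-network-v1",
#             "tt_convention": "ascending-regulator-ids-lsb-first"}}
# Round trips are byte-identical: keys are written in a fixed order with a
# fixed formatting.

network_to_list <- function(net) {
  list(genes = lapply(net$genes, function(g)
         list(id = g$id, binding_sites = as.list(g$bs),
              truth_table = as.list(g$tt))),
       meta = list(strain = if (is.na(net$strain)) NULL else net$strain,
                   parent = if (length(net$parent) == 1L && is.na(net$parent))
                     NULL else net$parent,
                   format = "rbn-network-v1",
                   tt_convention = "ascending-regulator-ids-lsb-first"))
}

network_from_list <- function(x) {
  if (is.null(x$genes)) stop("network JSON: missing required field 'genes'")
  genes <- lapply(x$genes, function(g) {
    for (f in c("id", "binding_sites", "truth_table"))
      if (is.null(g[[f]])) stop("network JSON: gene missing field '", f, "'")
    gene(g$id, unlist(g$binding_sites), unlist(g$truth_table))
  })
  boolean_network(genes,
                  strain = if (is.null(x$meta$strain)) NA_integer_ else x$meta$strain,
                  parent = if (is.null(x$meta$parent)) NA else x$meta$parent)
}

#' Write a network to JSON
#' @param net An `rbn_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  json <- jsonlite::toJSON(network_to_list(net), auto_unbox = TRUE,
                           pretty = FALSE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a network from JSON
#' @param path Input file written by [write_network_json()].
#' @return An `rbn_network` (bit-exact round trip, including truth tables
#'   and binding-site multiplicities).
#' @export
read_network_json <- function(path) {
  network_from_list(jsonlite::fromJSON(path, simplifyVector = FALSE))
}

#' Write an attractor landscape as TSV
#'
#' One row per state: `attractor_id`, `position_in_cycle`, `bitstring`.
#'
#' @param ls An `rbn_landscape`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_landscape_tsv <- function(ls, path) {
  rows <- list()
  for (i in seq_along(ls$attractors)) {
    a <- ls$attractors[[i]]
    rows[[i]] <- data.frame(attractor_id = i,
                            position_in_cycle = seq_len(a$period) - 1L,
                            bitstring = apply(a$states, 1L, state_key),
                            stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

landscape_to_list <- function(ls) {
  list(attractors = lapply(ls$attractors, function(a)
         as.list(apply(a$states, 1L, state_key))),
       complete = ls$complete,
       basin_sizes = if (is.null(ls$basin_sizes)) NULL else as.list(ls$basin_sizes))
}

landscape_from_list <- function(x) {
  atts <- lapply(x$attractors, function(states) {
    m <- do.call(rbind, lapply(states, function(s)
      as.integer(strsplit(s, "")[[1L]])))
    attractor(m)
  })
  landscape(atts, complete = isTRUE(x$complete),
            basin_sizes = if (is.null(x$basin_sizes)) NULL else unlist(x$basin_sizes))
}

#' Write a population checkpoint to JSON
#'
#' Serialises the networks, tracked landscapes, strain labels, generation
#' counter, lineage log, census so far, and the RNG state, so a run can be
#' resumed bit-identically.
#'
#' @param state List with `population`, and optionally `lineage`, `census`,
#'   `rng_state`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(state, path) {
  pop <- state$population
  census <- state$census
  if (is.list(census) && !is.data.frame(census))
    census <- do.call(rbind, census)
  x <- list(format = "rbn-checkpoint-v1",
            generation = pop$generation,
            strains = as.list(pop$strains),
            networks = lapply(pop$networks, network_to_list),
            landscapes = lapply(pop$landscapes, landscape_to_list),
            lineage = if (is.null(state$lineage)) NULL else
              list(birth = as.list(state$lineage$birth),
                   intervals = state$lineage$intervals,
                   fixations = as.list(state$lineage$fixations)),
            census = census,
            rng_state = state$rng_state)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", dataframe = "columns"),
             path)
  invisible(path)
}

#' Read a population checkpoint
#' @param path File written by [save_checkpoint()].
#' @return List with `population`, `lineage`, `census`, `rng_state`,
#'   suitable for `run_evolution(cfg, resume = ...)`.
#' @export
read_checkpoint <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(x$format, "rbn-checkpoint-v1"))
    stop("checkpoint JSON: unrecognised 'format' field")
  nets <- lapply(x$networks, network_from_list)
  lands <- lapply(x$landscapes, landscape_from_list)
  pop <- structure(list(networks = nets, landscapes = lands,
                        strains = as.integer(unlist(x$strains)),
                        generation = as.integer(x$generation),
                        S = vapply(nets, annealed_sensitivity, numeric(1))),
                   class = "rbn_population")
  lineage <- if (is.null(x$lineage)) NULL else {
    b <- unlist(x$lineage$birth)
    iv <- x$lineage$intervals
    list(birth = setNames(as.integer(b), names(b)),
         intervals = data.frame(strain = as.integer(unlist(iv$strain)),
                                birth = as.integer(unlist(iv$birth)),
                                death = as.integer(unlist(iv$death)),
                                nu = as.integer(unlist(iv$nu))),
         fixations = as.integer(unlist(x$lineage$fixations)))
  }
  census <- if (is.null(x$census)) NULL else
    as.data.frame(lapply(x$census, unlist), stringsAsFactors = FALSE)
  list(population = pop, lineage = lineage, census = census,
       rng_state = as.integer(unlist(x$rng_state)))
}

#' Export a network (or population) topology as GraphML
#'
#' Nodes carry the out-degree and a hub flag (out-degree at least three
#' times the network mean); edges carry the link persistence when a
#' population is given.
#'
#' @param x An `rbn_network` or `rbn_population`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(x, path) {
  if (inherits(x, "rbn_population")) {
    pers <- link_persistence(x)
    idx <- which(pers > 0, arr.ind = TRUE)
    edges <- data.frame(from = rownames(pers)[idx[, 1L]],
                        to = colnames(pers)[idx[, 2L]],
                        persistence = pers[idx])
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    outs <- igraph::degree(g, mode = "out")
  } else {
    net <- x
    el <- do.call(rbind, lapply(net$genes, function(g) {
      regs <- unique(g$bs)
      cbind(from = as.character(regs), to = as.character(rep(g$id, length(regs))))
    }))
    g <- igraph::graph_from_data_frame(as.data.frame(el), directed = TRUE,
                                       vertices = data.frame(name = as.character(network_ids(net))))
    outs <- igraph::degree(g, mode = "out")
  }
  igraph::V(g)$out_degree <- as.numeric(outs)
  igraph::V(g)$hub <- as.numeric(outs >= 3 * mean(outs))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a per-generation census to CSV
#' @param census Census data frame from an `rbn_run`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_census_csv <- function(census, path) {
  write.csv(census, path, row.names = FALSE)
  invisible(path)
}

#' Build an evolution config from a YAML file
#'
#' Flat keys mirror the [evolution_config()], [mutation_config()],
#' [search_config()] and [fitness_spec()] argument names; nested sections
#' `mutation`, `search`, `fitness` hold the sub-configs.
#'
#' @param path YAML file.
#' @return An `rbn_evolution_config`.
#' @export
evolution_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("mutation", "search", "fitness"))]
  if (!is.null(y$mutation)) args$mutation <- do.call(mutation_config, y$mutation)
  if (!is.null(y$search)) args$search <- do.call(search_config, y$search)
  if (!is.null(y$fitness)) args$fitness <- do.call(fitness_spec, y$fitness)
  do.call(evolution_config, args)
}
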