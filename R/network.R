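# Gene and network data model.
#
# A gene is a regulatory region (an ordered vector of binding sites, each
# occupied by the id of a regulator gene; several sites may be occupied by
# the same regulator) plus a truth table over its distinct regulators.
# Truth-table convention: distinct regulator ids sorted ascending; entry
# index (1-based) = 1 + binary number whose least significant bit is the
# activity of the lowest-id regulator.

#' Construct a gene
#'
#' @param id Stable non-negative integer identifier.
#' @param binding_sites Integer vector of regulator ids, one entry per
#'   binding site; repeats allowed. At least one site.
#' @param truth_table Integer vector of 0/1 outputs with `2^k` entries where
#'   `k` is the number of distinct regulator ids, ordered by the binary
#'   index convention (lowest-id regulator = least significant bit).
#' @return An object of class `rbn_gene`.
#' @export
gene <- function(id, binding_sites, truth_table) {
  g <- structure(list(id = as.integer(id),
                      bs = as.integer(binding_sites),
                      tt = as.integer(truth_table)),
                 class = "rbn_gene")
  validate_gene(g)
  g
}

#' Distinct regulators of a gene, ascending id order
#' @param g An `rbn_gene`.
#' @return Integer vector of distinct regulator ids.
#' @export
regulators <- function(g) sort(unique(g$bs))

validate_gene <- function(g, k_max = NULL) {
  if (g$id < 0L) stop("gene id must be non-negative")
  if (length(g$bs) < 1L) stop("gene ", g$id, " has no binding sites")
  k <- length(unique(g$bs))
  if (length(g$tt) != 2^k)
    stop("gene ", g$id, ": truth table has ", length(g$tt),
         " entries, expected ", 2^k)
  if (!all(g$tt %in% c(0L, 1L))) stop("gene ", g$id, ": non-binary truth table")
  if (!is.null(k_max) && k > k_max)
    stop("gene ", g$id, ": in-degree ", k, " exceeds K_max = ", k_max)
  invisible(g)
}

#' Construct a Boolean network
#'
#' @param genes List of [gene()] objects with unique ids. Stored sorted by
#'   id; state position `i` always refers to the gene with the i-th smallest
#'   id.
#' @param strain Integer lineage label (inherited by daughters on
#'   replication).
#' @param parent Optional id/label of the parent network.
#' @return An object of class `rbn_network`.
#' @export
boolean_network <- function(genes, strain = NA_integer_, parent = NA) {
  ids <- vapply(genes, function(g) g$id, integer(1))
  net <- structure(list(genes = genes[order(ids)],
                        strain = as.integer(strain),
                        parent = parent),
                   class = "rbn_network")
  validate_network(net)
  net
}

#' @export
print.rbn_network <- function(x, ...) {
  cat("Boolean network:", network_size(x), "genes, mean in-degree",
      round(mean(in_degrees(x)), 3), "\n")
  invisible(x)
}

#' Number of genes in a network
#' @param net An `rbn_network`.
#' @return Integer gene count.
#' @export
network_size <- function(net) length(net$genes)

network_ids <- function(net) vapply(net$genes, function(g) g$id, integer(1))

#' Validate all structural invariants of a network
#'
#' Checks unique ids, the truth-table size of every gene, the in-degree
#' ceiling, and that every referenced regulator is a gene of the network.
#'
#' @param net An `rbn_network`.
#' @param k_max Optional in-degree ceiling to enforce.
#' @param n_max Optional size ceiling to enforce.
#' @return The network, invisibly; errors on any violation.
#' @export
validate_network <- function(net, k_max = NULL, n_max = NULL) {
  ids <- network_ids(net)
  if (anyDuplicated(ids)) stop("duplicated gene ids")
  if (is.unsorted(ids)) stop("genes must be stored in ascending id order")
  if (!is.null(n_max) && length(ids) > n_max)
    stop("network size ", length(ids), " exceeds N_max = ", n_max)
  for (g in net$genes) {
    validate_gene(g, k_max = k_max)
    if (!all(g$bs %in% ids))
      stop("gene ", g$id, " references regulators absent from the network")
  }
  invisible(net)
}

gene_by_id <- function(net, id) {
  i <- match(id, network_ids(net))
  if (is.na(i)) stop("no gene with id ", id)
  net$genes[[i]]
}

set_gene <- function(net, g) {
  i <- match(g$id, network_ids(net))
  if (is.na(i)) stop("no gene with id ", g$id)
  net$genes[[i]] <- g
  net
}

#' In-degrees (distinct regulator counts) of all genes
#' @param net An `rbn_network`.
#' @return Integer vector, one entry per gene in id order.
#' @export
in_degrees <- function(net)
  vapply(net$genes, function(g) length(unique(g$bs)), integer(1))

#' Out-degrees (distinct target counts) of all genes
#' @param net An `rbn_network`.
#' @return Named integer vector, one entry per gene in id order.
#' @export
out_degrees <- function(net) {
  ids <- network_ids(net)
  out <- setNames(integer(length(ids)), ids)
  for (g in net$genes)
    for (r in unique(g$bs)) out[as.character(r)] <- out[as.character(r)] + 1L
  out
}

#' Ids of the genes regulated by a given gene
#' @param net An `rbn_network`.
#' @param id Regulator gene id.
#' @return Integer vector of target ids.
#' @export
targets_of <- function(net, id) {
  ids <- network_ids(net)
  ids[vapply(net$genes, function(g) id %in% g$bs, logical(1))]
}

#' Generate a random Boolean network
#'
#' Every gene receives `K_in` distinct regulators drawn without replacement
#' (one binding site each) and a random truth table whose outputs are 1
#' independently with probability `p` (the bias).
#'
#' @param N Number of genes.
#' @param K_in In-degree: a single integer, or an integer range
#'   `c(lo, hi)` from which each gene's in-degree is drawn uniformly.
#' @param p Truth-table bias in `[0, 1]`.
#' @param k_max In-degree ceiling (checked against `K_in`).
#' @param allow_self Whether a gene may regulate itself.
#' @return An `rbn_network` with ids `1..N`.
#' @export
random_network <- function(N, K_in, p, k_max = 8L, allow_self = TRUE) {
  if (p < 0 || p > 1) stop("bias p must lie in [0, 1]")
  K_in <- as.integer(K_in)
  k_hi <- max(K_in)
  if (min(K_in) < 1L) stop("in-degree must be at least 1")
  if (k_hi > k_max) stop("K_in exceeds K_max = ", k_max)
  pool_size <- if (allow_self) N else N - 1L
  if (k_hi > pool_size)
    stop("K_in = ", k_hi, " regulators cannot be drawn from ", pool_size,
         " candidates (self-loops ", if (allow_self) "allowed" else "disabled", ")")
  genes <- vector("list", N)
  for (i in seq_len(N)) {
    k <- if (length(K_in) > 1L)
      K_in[1L] + sample.int(K_in[2L] - K_in[1L] + 1L, 1L) - 1L else K_in
    pool <- if (allow_self) seq_len(N) else setdiff(seq_len(N), i)
    regs <- sort(pool[sample.int(length(pool), k)])
    genes[[i]] <- gene(i, regs, rbinom(2^k, 1L, p))
  }
  boolean_network(genes)
}

# Flatten a network into the representation the C++ core consumes.
compile_network <- function(net) {
  ids <- network_ids(net)
  n <- length(ids)
  reg_ptr <- integer(n + 1L)
  tt_ptr <- integer(n + 1L)
  reg_idx <- vector("list", n)
  tt_val <- vector("list", n)
  for (i in seq_len(n)) {
    g <- net$genes[[i]]
    regs <- sort(unique(g$bs))
    reg_idx[[i]] <- match(regs, ids) - 1L
    tt_val[[i]] <- g$tt
    reg_ptr[i + 1L] <- reg_ptr[i] + length(regs)
    tt_ptr[i + 1L] <- tt_ptr[i] + length(g$tt)
  }
  list(n = n, reg_ptr = reg_ptr, reg_idx = unlist(reg_idx),
       tt_ptr = tt_ptr, tt_val = unlist(tt_val))
}

#' One synchronous update of the network state
#'
#' All genes update simultaneously: the new value of each gene is its
#' truth-table output for its regulators' activities in `state`.
#'
#' @param net An `rbn_network`.
#' @param state Integer 0/1 vector of length `network_size(net)`; position
#'   `i` is the activity of the gene with the i-th smallest id.
#' @return The successor state (integer 0/1 vector).
#' @export
network_step <- function(net, state) {
  if (length(state) != network_size(net))
    stop("state length ", length(state), " does not match network size ",
         network_size(net))
  rbn_step_cpp(compile_network(net), as.integer(state))
}
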