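# Point mutations of the regulatory grammar.
#
# Six mutation rules operate on binding sites (BS):
#   1. new BS occupied by an existing regulator: rerandomize the truth-table
#      outputs only on configurations where that regulator is 1;
#   2. new BS occupied by a new regulator: the table doubles, configurations
#      with the new regulator = 0 keep the old outputs verbatim, = 1 are
#      random; rejected if the in-degree would exceed K_max;
#   3. removal of one BS of a regulator that keeps other BS: rerandomize
#      outputs where that regulator is 1;
#   4. removal of a regulator's last BS: the regulator is dropped and the
#      table halves, keeping only the regulator = 0 entries; rejected if the
#      gene would be left with no regulators;
#   5. coding-region gain: targets (drawn from the whole genome) gain one BS
#      for the mutated gene, via rule 1/3/4 choices for existing targets
#      (5.1) or a rule-2 connection for new targets (5.2);
#   6. coding-region loss: targets drawn among current outputs lose one BS
#      for the mutated gene, via rules 3/4.
# Rejected events consume the event (they are recorded as no-ops, never
# redrawn). All rerandomized outputs are 0/1 with probability 1/2.

#' Mutation configuration
#'
#' @param mu Per-gene per-network per-generation mutation probability.
#' @param p_add,p_rem Per-event binding-site gain/loss probabilities; must
#'   be equal, with `p_add + p_rem <= 1` (the remainder is the no-op
#'   probability per event).
#' @param p_coding Probability that a selected gene's mutation hits the
#'   coding region rather than the regulatory region.
#' @param k_max In-degree ceiling; rule-2 additions beyond it are rejected.
#' @param allow_self Whether drawn regulators/targets may be the gene itself.
#' @param events_per_regulatory Function of the current binding-site count
#'   giving the number of mutational events in one regulatory mutation
#'   (default `bs_count + 1`, so genes with more sites are bigger targets).
#' @return A list of class `rbn_mutation_config`.
#' @export
mutation_config <- function(mu = 0.01, p_add = 0.5, p_rem = 0.5,
                            p_coding = 0.5, k_max = 8L, allow_self = TRUE,
                            events_per_regulatory = function(bs) bs + 1L) {
  if (p_add != p_rem) stop("binding sites are gained and lost with the same probability: p_add must equal p_rem")
  if (p_add + p_rem > 1) stop("p_add + p_rem must not exceed 1")
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  structure(list(mu = mu, p_add = p_add, p_rem = p_rem, p_coding = p_coding,
                 k_max = as.integer(k_max), allow_self = allow_self,
                 events_per_regulatory = events_per_regulatory),
            class = "rbn_mutation_config")
}

# ---- truth-table surgery (shared by mutation, duplication, knockout) ----

# Bit position (1-based) of regulator r among the gene's distinct regulators.
reg_pos <- function(g, r) match(r, sort(unique(g$bs)))

# Rerandomize outputs on configurations where the regulator at bit `pos` is 1.
tt_rerand <- function(tt, pos) {
  hot <- bitwAnd(seq_along(tt) - 1L, bitwShiftL(1L, pos - 1L)) != 0L
  tt[hot] <- rbinom(sum(hot), 1L, 0.5)
  tt
}

# Double the table for a new regulator inserted at bit `pos`; entries with
# the new regulator = 0 keep the old outputs verbatim, = 1 are random.
tt_extend <- function(tt, pos) {
  idx <- seq_len(2L * length(tt)) - 1L
  low <- bitwAnd(idx, bitwShiftL(1L, pos - 1L) - 1L)
  high <- bitwShiftR(idx, pos)
  old <- bitwOr(low, bitwShiftL(high, pos - 1L)) + 1L
  newbit <- bitwAnd(bitwShiftR(idx, pos - 1L), 1L)
  out <- tt[old]
  out[newbit == 1L] <- rbinom(sum(newbit == 1L), 1L, 0.5)
  out
}

# Halve the table when the regulator at bit `pos` is dropped, keeping only
# the entries where it is 0.
tt_collapse <- function(tt, pos) {
  keep <- bitwAnd(seq_along(tt) - 1L, bitwShiftL(1L, pos - 1L)) == 0L
  tt[keep]
}

# ---- per-gene edits (each returns the updated gene or NULL if rejected) ----

# Add one binding site for regulator r (rules 1 and 2).
gene_add_bs <- function(g, r, k_max) {
  regs <- sort(unique(g$bs))
  if (r %in% regs) {                      # rule 1
    g$bs <- c(g$bs, r)
    g$tt <- tt_rerand(g$tt, match(r, regs))
    list(g = g, rule = 1L)
  } else {                                # rule 2
    if (length(regs) + 1L > k_max) return(NULL)
    pos <- sum(regs < r) + 1L
    g$tt <- tt_extend(g$tt, pos)
    g$bs <- c(g$bs, r)
    list(g = g, rule = 2L)
  }
}

# Remove the binding site at index `bs_i` (rules 3 and 4).
gene_remove_bs <- function(g, bs_i) {
  r <- g$bs[bs_i]
  regs <- sort(unique(g$bs))
  if (sum(g$bs == r) > 1L) {              # rule 3
    g$bs <- g$bs[-bs_i]
    g$tt <- tt_rerand(g$tt, match(r, regs))
    list(g = g, rule = 3L)
  } else {                                # rule 4
    if (length(regs) == 1L) return(NULL)  # never leave a gene regulator-free
    g$tt <- tt_collapse(g$tt, match(r, regs))
    g$bs <- g$bs[-bs_i]
    list(g = g, rule = 4L)
  }
}

# Remove one randomly chosen binding site occupied by regulator r.
gene_remove_bs_for <- function(g, r) {
  cand <- which(g$bs == r)
  gene_remove_bs(g, cand[sample.int(length(cand), 1L)])
}

mutation_record <- function(gene_id, region, events) {
  structure(list(gene_id = gene_id, region = region, events = events,
                 effective = any(vapply(events, function(e) e$accepted, logical(1)))),
            class = "rbn_mutation_record")
}

#' Mutate the regulatory region of one gene
#'
#' Performs `events_per_regulatory(bs_count)` independent mutational events
#' (default `bs_count + 1`). Each event adds a binding site with probability
#' `p_add` (rules 1/2), removes a randomly chosen one with probability
#' `p_rem` (rules 3/4), and otherwise does nothing. New regulators are drawn
#' uniformly from the genome. Rejected events (in-degree ceiling,
#' last-regulator protection) are recorded as no-ops.
#'
#' @param net An `rbn_network`.
#' @param gene_id Id of the gene to mutate.
#' @param cfg A [mutation_config()].
#' @return List with `net` (the mutated network) and `record`
#'   (`rbn_mutation_record` auditing every event).
#' @export
mutate_regulatory <- function(net, gene_id, cfg = mutation_config()) {
  g <- gene_by_id(net, gene_id)
  ids <- network_ids(net)
  n_events <- cfg$events_per_regulatory(length(g$bs))
  events <- vector("list", n_events)
  for (ev in seq_len(n_events)) {
    u <- runif(1)
    if (u < cfg$p_add) {
      pool <- if (cfg$allow_self) ids else setdiff(ids, gene_id)
      r <- pool[sample.int(length(pool), 1L)]
      res <- gene_add_bs(g, r, cfg$k_max)
      if (is.null(res)) {
        events[[ev]] <- list(type = "add", rule = 2L, regulator = r,
                             accepted = FALSE)
      } else {
        g <- res$g
        events[[ev]] <- list(type = "add", rule = res$rule, regulator = r,
                             accepted = TRUE)
      }
    } else if (u < cfg$p_add + cfg$p_rem) {
      bs_i <- sample.int(length(g$bs), 1L)
      r <- g$bs[bs_i]
      res <- gene_remove_bs(g, bs_i)
      if (is.null(res)) {
        events[[ev]] <- list(type = "remove", rule = 4L, regulator = r,
                             accepted = FALSE)
      } else {
        g <- res$g
        events[[ev]] <- list(type = "remove", rule = res$rule, regulator = r,
                             accepted = TRUE)
      }
    } else {
      events[[ev]] <- list(type = "none", rule = NA_integer_,
                           regulator = NA_integer_, accepted = FALSE)
    }
  }
  list(net = set_gene(net, g),
       record = mutation_record(gene_id, "regulatory", events))
}

#' Mutate the coding region of one gene
#'
#' Draws `beta ~ Uniform(0, 1)` and affects `n = round(beta * k_out)` target
#' genes, where `k_out` is the mutated gene's out-degree: with probability
#' 1/2 all `n` gain one binding site for the gene (targets drawn uniformly
#' from the whole genome; rules 5.1/5.2), otherwise all `n` lose one
#' (targets drawn among current outputs; rules 3/4). A gene with no targets
#' yields a no-op record.
#'
#' @inheritParams mutate_regulatory
#' @return List with `net` and `record`.
#' @export
mutate_coding <- function(net, gene_id, cfg = mutation_config()) {
  ids <- network_ids(net)
  outs <- targets_of(net, gene_id)
  k_out <- length(outs)
  if (k_out == 0L)
    return(list(net = net,
                record = mutation_record(gene_id, "coding", list())))
  beta <- runif(1)
  n_aff <- floor(beta * k_out + 0.5)
  if (n_aff == 0L)
    return(list(net = net,
                record = mutation_record(gene_id, "coding", list())))
  events <- list()
  if (runif(1) < 0.5) {                  # rule 5: targets gain a BS
    pool <- if (cfg$allow_self) ids else setdiff(ids, gene_id)
    tg <- pool[sample.int(length(pool), min(n_aff, length(pool)))]
    for (t in tg) {
      gt <- gene_by_id(net, t)
      if (gene_id %in% gt$bs && runif(1) < 0.5) {     # 5.1, removal branch
        res <- gene_remove_bs_for(gt, gene_id)
        type <- "target_remove"
      } else {                                        # 5.1 add / 5.2
        res <- gene_add_bs(gt, gene_id, cfg$k_max)
        type <- "target_add"
      }
      if (is.null(res)) {
        events <- c(events, list(list(type = type, rule = NA_integer_,
                                      target = t, accepted = FALSE)))
      } else {
        net <- set_gene(net, res$g)
        events <- c(events, list(list(type = type, rule = res$rule,
                                      target = t, accepted = TRUE)))
      }
    }
  } else {                               # rule 6: outputs lose a BS
    tg <- outs[sample.int(k_out, n_aff)]
    for (t in tg) {
      gt <- gene_by_id(net, t)
      res <- gene_remove_bs_for(gt, gene_id)
      if (is.null(res)) {
        events <- c(events, list(list(type = "target_remove",
                                      rule = 4L, target = t, accepted = FALSE)))
      } else {
        net <- set_gene(net, res$g)
        events <- c(events, list(list(type = "target_remove", rule = res$rule,
                                      target = t, accepted = TRUE)))
      }
    }
  }
  list(net = net, record = mutation_record(gene_id, "coding", events))
}

#' Mutate a whole network for one generation
#'
#' Each gene is independently selected with probability `mu`; each selected
#' gene undergoes a coding-region mutation with probability `p_coding`, else
#' a regulatory-region mutation.
#'
#' @inheritParams mutate_regulatory
#' @return List with `net` and `records` (one `rbn_mutation_record` per
#'   selected gene; empty when no gene was selected).
#' @export
mutate_network <- function(net, cfg = mutation_config()) {
  ids <- network_ids(net)
  hit <- ids[runif(length(ids)) < cfg$mu]
  records <- vector("list", length(hit))
  for (i in seq_along(hit)) {
    res <- if (runif(1) < cfg$p_coding) mutate_coding(net, hit[i], cfg)
           else mutate_regulatory(net, hit[i], cfg)
    net <- res$net
    records[[i]] <- res$record
  }
  list(net = net, records = records)
}

records_effective <- function(records)
  any(vapply(records, function(r) isTRUE(r$effective), logical(1)))
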