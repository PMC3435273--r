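# Hand-built fixture networks used across test files.

# Two genes that copy each other: (0,1) -> (1,0) -> (0,1).
swap_pair <- function() {
  boolean_network(list(gene(1, 2, c(0L, 1L)), gene(2, 1, c(0L, 1L))))
}

# Two genes that negate each other: (0,1) and (1,0) are fixed points,
# {(0,0),(1,1)} is the period-2 cycle.
negation_pair <- function() {
  boolean_network(list(gene(1, 2, c(1L, 0L)), gene(2, 1, c(1L, 0L))))
}

# N-gene ring in which every gene copies its predecessor.
copy_ring <- function(n) {
  boolean_network(lapply(seq_len(n), function(i) {
    pred <- if (i == 1L) n else i - 1L
    gene(i, pred, c(0L, 1L))
  }))
}

# All functions constant 0 (every gene keeps one self-input to satisfy the
# no-regulator-free-genes invariant).
constant_zero_net <- function(n) {
  boolean_network(lapply(seq_len(n), function(i) gene(i, i, c(0L, 0L))))
}

all_states <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  dimnames(m) <- NULL
  m
}

# Independent brute-force oracle: follow the trajectory from every state by
# plain R iteration (no shared code with enumerate_attractors' sweep).
naive_landscape_keys <- function(net) {
  n <- network_size(net)
  states <- all_states(n)
  keys <- character(0)
  for (r in seq_len(nrow(states))) {
    s <- as.integer(states[r, ])
    seen <- list()
    seen_keys <- character(0)
    repeat {
      k <- paste(s, collapse = "")
      hit <- match(k, seen_keys)
      if (!is.na(hit)) {
        cyc <- do.call(rbind, seen[hit:length(seen)])
        keys <- c(keys, attractor(cyc)$key)
        break
      }
      seen_keys <- c(seen_keys, k)
      seen[[length(seen) + 1L]] <- s
      s <- network_step(net, s)
    }
  }
  sort(unique(keys))
}
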