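# Independent oracles and small fixture builders shared across tests.

# Brute-force synchronous recurrence, written directly from its definition:
# next(v) = clamp(sum over incoming edges of w * current(source)), clamped
# nodes pinned, basal nodes initialised only. Pure R, no package internals.
oracle_propagate <- function(nodes, edges, weights, clamped, basal, steps) {
  a <- setNames(rep(0, length(nodes)), nodes)
  if (length(basal)) a[names(basal)] <- basal
  if (length(clamped)) a[names(clamped)] <- clamped
  for (s in seq_len(steps)) {
    nxt <- setNames(rep(0, length(nodes)), nodes)
    for (i in seq_len(nrow(edges))) {
      nxt[edges$to[i]] <- nxt[edges$to[i]] + weights[i] * a[edges$from[i]]
    }
    nxt <- pmin(pmax(nxt, -1), 1)  # nxt first: pmin/pmax keep its names
    if (length(clamped)) nxt[names(clamped)] <- clamped
    a <- nxt
  }
  a
}

# Exhaustive hypergeometric tail: enumerate every draw of size |query| from
# the universe and tally how often the overlap with the term reaches the
# observed one. Only feasible for small universes.
oracle_hypergeom <- function(query, term, universe) {
  obs <- length(intersect(query, term))
  draws <- combn(universe, length(query))
  hits <- apply(draws, 2, function(d) length(intersect(d, term)) >= obs)
  mean(hits)
}

# Random small directed network with signed weights, for property tests.
random_net <- function(n, p = 0.3) {
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  if (!nrow(pairs)) pairs <- data.frame(from = 1L, to = 2L)
  nodes <- paste0("N", seq_len(n))
  protein_network(
    data.frame(from = nodes[pairs$from], to = nodes[pairs$to]),
    nodes = nodes)
}

# Small planted fixture used by several training tests.
small_fixture <- function(seed = 11, n_nodes = 20L, ...) {
  generate_fixture(fixture_spec(
    n_nodes = n_nodes, m = 2L, n_motives = 2L, effectors_per_motive = 2L,
    n_drugs = 1L, targets_per_drug = 2L, n_bioflags = 1L, n_rules = 6L,
    n_terms = 5L, term_size_range = c(3L, 8L), seed = seed, ...))
}

# Three-node chain A -> B -> C with explicit weights.
chain_net <- function() {
  protein_network(data.frame(from = c("A", "B"), to = c("B", "C")))
}
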