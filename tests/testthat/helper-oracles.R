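# Fixture builders and independent brute-force oracles used across tests.

# Build a module object directly from weights and tree edges.
make_module <- function(weights, edges = NULL, regulator = "R", id = 1L) {
  n <- length(weights)
  if (is.null(edges)) {
    edges <- data.frame(a = integer(0), b = integer(0), weight = numeric(0))
  }
  list(id = id, regulator = regulator,
       links = data.frame(regulator = regulator,
                          target = sprintf("G%03d", seq_len(n)),
                          weight = weights, stringsAsFactors = FALSE),
       edges = edges)
}

# Independent energy: recomputed from first principles (spins +-1).
oracle_energy <- function(weights, edges, x, gamma, lambda) {
  s <- 2 * x - 1
  e <- -sum((weights - gamma) * s)
  if (nrow(edges)) {
    e <- e - lambda * sum(edges$weight * s[edges$a] * s[edges$b])
  }
  e
}

# Exhaustive-enumeration marginals, honoring clamped evidence.
oracle_marginals <- function(weights, edges, gamma, lambda, clamp = TRUE) {
  n <- length(weights)
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  if (clamp) {
    fixed <- weights > gamma
    if (any(fixed)) {
      states <- states[apply(states[, fixed, drop = FALSE] == 1, 1, all), ,
                       drop = FALSE]
    }
  }
  loge <- apply(states, 1, function(x) {
    -oracle_energy(weights, edges, x, gamma, lambda)
  })
  w <- exp(loge - max(loge))
  w <- w / sum(w)
  as.numeric(crossprod(states, w))
}

# Random tree over n nodes: each node attaches to a random predecessor.
random_tree_edges <- function(n, weight_fn = function(k) runif(k)) {
  if (n < 2) {
    return(data.frame(a = integer(0), b = integer(0), weight = numeric(0)))
  }
  a <- vapply(2:n, function(i) sample.int(i - 1, 1), 0L)
  data.frame(a = a, b = 2:n, weight = weight_fn(n - 1))
}

# Exhaustive maximum spanning tree weight for a small connected graph.
oracle_max_spanning_tree <- function(n_nodes, edges) {
  stopifnot(n_nodes <= 7)
  m <- nrow(edges)
  if (n_nodes == 1) return(0)
  best <- -Inf
  for (pick in utils::combn(m, n_nodes - 1, simplify = FALSE)) {
    sub <- edges[pick, , drop = FALSE]
    # spanning + acyclic <=> n-1 edges connecting all nodes
    parent <- seq_len(n_nodes)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (k in seq_len(nrow(sub))) {
      ra <- find(sub$a[k]); rb <- find(sub$b[k])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (ok && length(unique(vapply(seq_len(n_nodes), find, 0L))) == 1) {
      best <- max(best, sum(sub$weight))
    }
  }
  best
}

# One-sided hypergeometric tail P(X >= hits_pred) for the enrichment table.
oracle_fisher_p <- function(hits_pred, n_pred, hits_bg, n_bg) {
  ks <- hits_pred:min(n_pred, hits_bg)
  sum(vapply(ks, function(k) {
    choose(hits_bg, k) * choose(n_bg - hits_bg, n_pred - k)
  }, 0)) / choose(n_bg, n_pred)
}

# Directed link keys for set comparisons in tests.
link_id_test <- function(net) paste(net$regulator, net$target)

# Tiny deterministic gold-standard fixture.
toy_gold <- function() {
  list(
    regulatory = data.frame(regulator = c("A", "A", "B"),
                            target = c("g1", "g2", "g3"),
                            stringsAsFactors = FALSE),
    cofunction = data.frame(gene_a = c("g1", "g1"), gene_b = c("g2", "g3"),
                            stringsAsFactors = FALSE)
  )
}
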