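# Independent oracles and small fixture builders. These never call the
# simulation engine they are used to check.

# Brute-force fixed point of the threshold rule: repeatedly add any
# susceptible node whose infected-neighbor fraction strictly exceeds tau,
# until no node changes. Works directly on the igraph object.
bf_threshold_fixpoint <- function(g, tau, seeds) {
  n <- igraph::vcount(g)
  nbrs <- lapply(seq_len(n), function(u) as.integer(igraph::neighbors(g, u)))
  deg <- lengths(nbrs)
  infected <- rep(FALSE, n)
  infected[seeds] <- TRUE
  repeat {
    changed <- FALSE
    for (u in seq_len(n)) {
      if (infected[u] || deg[u] == 0) next
      if (sum(infected[nbrs[[u]]]) / deg[u] > tau) {
        infected[u] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  which(infected)
}

# Nodes within graph distance t of the seed set (BFS-layer oracle).
bfs_within <- function(g, seeds, t) {
  d <- igraph::distances(g, v = seeds)
  which(apply(d, 2, min) <= t)
}

# Small random test graph.
rand_gnp <- function(n, p, seed) {
  set.seed(seed)
  igraph::sample_gnp(n, p, directed = FALSE)
}

# Path graph 1-2-...-n.
path_graph <- function(n)
  igraph::make_graph(c(rbind(seq_len(n - 1), seq_len(n - 1) + 1L)),
                     directed = FALSE)

# A star whose center (id 1) has `leaves` neighbors.
star_graph <- function(leaves) {
  igraph::make_graph(rbind(1L, seq_len(leaves) + 1L), directed = FALSE)
}

edgeless_graph <- function(n) igraph::make_empty_graph(n, directed = FALSE)

run_final_fracs <- function(g, params, n_runs, iterations, seed_frac = 0.05,
                            root = 99L) {
  idx <- if (inherits(g, "adj_index")) g else adjacency_index(g)
  sets <- sample_seed_sets(idx, seed_frac, n_runs, derive_seed(root, 0))
  vapply(seq_len(n_runs), function(i) {
    r <- run_diffusion(idx, params, sets[[i]], iterations,
                       rng_seed = derive_seed(root, i))
    r$trend[length(r$trend)]
  }, numeric(1))
}
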