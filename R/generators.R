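# Synthetic substrate networks. All generators return a simple undirected
# igraph object with a `generator` graph attribute recording the exact
# specification (family, parameters, seed) needed to rebuild it.

set_generator_attr <- function(g, family, params, rng_seed) {
  igraph::graph_attr(g, "generator") <-
    c(list(family = family), params, list(rng_seed = rng_seed))
  g
}

#' Generate a Barabasi-Albert preferential-attachment graph
#'
#' Nodes are added one at a time; each new node attaches `m` edges to existing
#' nodes with probability proportional to their current degree, yielding the
#' heavy-tailed degree distribution typical of social graphs. The initial core
#' follows the `igraph::sample_pa()` convention: growth starts from a single
#' vertex, so the first few vertices attach to all nodes present at the time
#' (fewer than `m` edges); every later node contributes exactly `m`. The result
#' is connected.
#'
#' @param n number of nodes.
#' @param m edges created per new node (`1 <= m < n`).
#' @param rng_seed integer seed; the same spec reproduces the identical edge set.
#' @return An undirected simple `igraph` graph with `n` nodes.
#' @examples
#' g <- generate_ba(200, 3, rng_seed = 1)
#' graph_stats(g)
#' @export
generate_ba <- function(n, m, rng_seed = 1L) {
  if (!is_count(n) || n < 2) param_error("`n` must be an integer >= 2")
  if (!is_count(m) || m < 1 || m >= n)
    param_error(sprintf("`m` must satisfy 1 <= m < n, got m=%s n=%s", m, n))
  set.seed(rng_seed)
  g <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE,
                         algorithm = "psumtree")
  g <- igraph::simplify(g)
  set_generator_attr(g, "ba", list(n = n, m = m,
                                   core = "single-vertex start (igraph sample_pa)"),
                     rng_seed)
}

#' Generate an Erdos-Renyi G(n, p) random graph
#'
#' Each of the `choose(n, 2)` unordered node pairs is an edge independently
#' with probability `p_edge`.
#'
#' @param n number of nodes.
#' @param p_edge edge creation probability in `[0, 1]`.
#' @param rng_seed integer seed.
#' @return An undirected simple `igraph` graph with `n` nodes.
#' @export
generate_er <- function(n, p_edge, rng_seed = 1L) {
  if (!is_count(n) || n < 1) param_error("`n` must be a positive integer")
  check_prob(p_edge, "p_edge")
  set.seed(rng_seed)
  g <- igraph::sample_gnp(n, p_edge, directed = FALSE)
  set_generator_attr(g, "er", list(n = n, p_edge = p_edge), rng_seed)
}

#' Generate a Watts-Strogatz small-world graph
#'
#' A ring lattice in which every node is joined to its `floor(k/2)` nearest
#' neighbors on each side, after which each lattice edge is rewired with
#' probability `p_rewire` (self-loops and duplicate edges produced by rewiring
#' are dropped). For odd `k` the effective lattice degree is therefore
#' `k - 1`: a uniform ring cannot realize an odd degree, and joining
#' `floor(k/2)` neighbors per side is the standard convention.
#'
#' @param n number of nodes.
#' @param k nominal neighborhood size (`0 < k < n`); `floor(k/2)` neighbors
#'   are joined on each side of the ring.
#' @param p_rewire per-edge rewiring probability in `[0, 1]`.
#' @param rng_seed integer seed.
#' @return An undirected simple `igraph` graph with `n` nodes.
#' @examples
#' g <- generate_ws(100, 4, 0, rng_seed = 1)
#' all(igraph::degree(g) == 4)
#' @export
generate_ws <- function(n, k, p_rewire, rng_seed = 1L) {
  if (!is_count(n) || n < 3) param_error("`n` must be an integer >= 3")
  if (!is_count(k) || k <= 0 || k >= n)
    param_error(sprintf("`k` must satisfy 0 < k < n, got k=%s n=%s", k, n))
  check_prob(p_rewire, "p_rewire")
  nei <- k %/% 2
  if (nei < 1) param_error("`k` must be at least 2 to form a ring lattice")
  set.seed(rng_seed)
  # Ring lattice: node i (0-based) joined to i+1..i+nei (mod n). Rewiring
  # replaces the far endpoint of each lattice edge, keeping the near one, so
  # the edge count is conserved and every node keeps degree >= nei.
  u <- rep(0:(n - 1), nei)
  v <- (u + rep(seq_len(nei), each = n)) %% n
  if (p_rewire > 0) {
    key <- function(a, b) pmin(a, b) * n + pmax(a, b)  # exact for n < 2^26
    rew <- which(stats::runif(n * nei) < p_rewire)
    if (length(rew) > 0) {
      v[rew] <- sample.int(n, length(rew), replace = TRUE) - 1L
      # redraw any rewired endpoint that produced a self-loop or a duplicate
      # edge until the graph is simple again (a handful of passes at most)
      repeat {
        kk <- key(u, v)
        clash <- duplicated(kk) | duplicated(kk, fromLast = TRUE)
        bad <- rew[u[rew] == v[rew] | clash[rew]]
        if (length(bad) == 0) break
        v[bad] <- sample.int(n, length(bad), replace = TRUE) - 1L
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(u + 1L, v + 1L))
  set_generator_attr(g, "ws",
                     list(n = n, k = k, neighbors_per_side = nei,
                          p_rewire = p_rewire),
                     rng_seed)
}
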