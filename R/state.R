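# Simulation state: a per-node status ledger over a fixed substrate graph.
# Status codes: 0 = susceptible, 1 = infected (adopter), 2 = blocked.
# Infected and blocked are absorbing; the three sets partition V at all times.

STATUS_SUSCEPTIBLE <- 0L
STATUS_INFECTED <- 1L
STATUS_BLOCKED <- 2L

#' Precompute the adjacency index of a graph
#'
#' Builds the neighbor lists and degree vector used by the simulation engine.
#' Computing this once and passing it to [run_diffusion()] (or letting
#' [run_protocol()] do so) avoids rebuilding it for every seed set on large
#' graphs.
#'
#' @param g an `igraph` graph.
#' @return An object of class `adj_index`.
#' @export
adjacency_index <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  from <- as.integer(c(el[, 1], el[, 2]))
  to <- as.integer(c(el[, 2], el[, 1]))
  adj <- unname(split(to, factor(from, levels = seq_len(n))))
  structure(list(n = n, adj = adj, deg = lengths(adj)), class = "adj_index")
}

as_adj_index <- function(g) {
  if (inherits(g, "adj_index")) g else adjacency_index(g)
}

#' Initialize a simulation state
#'
#' Marks the seed nodes as infected, everyone else susceptible, at iteration 0.
#'
#' @param g an `igraph` graph or a prebuilt [adjacency_index()].
#' @param seeds integer vector of seed node ids in `1..n` (the initial adopter
#'   set). May be empty, which only makes sense with a positive spontaneous
#'   adoption rate; [run_diffusion()] warns otherwise.
#' @return An object of class `sim_state` holding the status ledger, the
#'   per-node infected-neighbor counts, and the iteration counter.
#' @export
initialize_state <- function(g, seeds) {
  idx <- as_adj_index(g)
  seeds <- as.integer(unique(seeds))
  if (length(seeds) > 0 && (min(seeds) < 1 || max(seeds) > idx$n))
    param_error(sprintf("seed ids must lie in 1..%d", idx$n))
  status <- rep(STATUS_SUSCEPTIBLE, idx$n)
  status[seeds] <- STATUS_INFECTED
  cnt <- tabulate(as.integer(unlist(idx$adj[seeds], use.names = FALSE)),
                  nbins = idx$n)
  structure(list(n = idx$n, adj = idx$adj, deg = idx$deg,
                 status = status, cnt = cnt, iteration = 0L,
                 spont_new = integer(0)),
            class = "sim_state")
}

#' Count nodes per status
#'
#' @param state a `sim_state`.
#' @return Named integer vector `c(susceptible=, infected=, blocked=)`.
#' @export
status_counts <- function(state) {
  c(susceptible = sum(state$status == STATUS_SUSCEPTIBLE),
    infected = sum(state$status == STATUS_INFECTED),
    blocked = sum(state$status == STATUS_BLOCKED))
}

#' @export
print.sim_state <- function(x, ...) {
  sc <- status_counts(x)
  cat(sprintf("<sim_state> n=%d t=%d | S=%d I=%d B=%d\n",
              x$n, x$iteration, sc[["susceptible"]], sc[["infected"]],
              sc[["blocked"]]))
  invisible(x)
}

# Mark `ids` infected and update neighbor counts incrementally.
mark_infected <- function(state, ids) {
  if (length(ids) == 0) return(state)
  state$status[ids] <- STATUS_INFECTED
  nb <- unlist(state$adj[ids], use.names = FALSE)
  if (length(nb) > 0)
    state$cnt <- state$cnt + tabulate(nb, nbins = state$n)
  state
}
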