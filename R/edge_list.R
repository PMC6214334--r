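# Plain-text edge lists (SNAP style): one edge per line, two labels separated
# by whitespace or a comma, '#' lines are comments.

#' Read a graph from a plain edge-list file
#'
#' Node labels are mapped to contiguous internal ids `1..N` (the order of first
#' appearance); the original labels are kept as the `name` vertex attribute.
#' Self-loops and duplicate edges are dropped and counted; the counts are
#' stored as graph attributes `dropped_self_loops` / `dropped_duplicates` and
#' reported with a message.
#'
#' @param path path to an edge-list file.
#' @return An undirected simple `igraph` graph; `igraph::V(g)$name` holds the
#'   file's labels.
#' @export
load_edge_list <- function(path) {
  if (!file.exists(path)) io_error(sprintf("edge-list file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) io_error(sprintf("edge-list file is empty: %s", path))
  toks <- strsplit(trimws(lines[rows]), "[,[:space:]]+")
  bad <- which(lengths(toks) != 2)
  if (length(bad) > 0)
    io_error(sprintf("malformed edge-list line %d in %s: '%s'",
                     rows[bad[1]], path, lines[rows[bad[1]]]))
  from <- vapply(toks, `[`, "", 1)
  to <- vapply(toks, `[`, "", 2)
  labels <- unique(c(rbind(from, to)))
  fi <- match(from, labels)
  ti <- match(to, labels)
  self <- fi == ti
  n_self <- sum(self)
  fi <- fi[!self]; ti <- ti[!self]
  key <- paste(pmin(fi, ti), pmax(fi, ti))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  g <- igraph::make_empty_graph(length(labels), directed = FALSE)
  g <- igraph::add_edges(g, rbind(fi[!dup], ti[!dup]))
  igraph::V(g)$name <- labels
  igraph::graph_attr(g, "dropped_self_loops") <- n_self
  igraph::graph_attr(g, "dropped_duplicates") <- n_dup
  if (n_self + n_dup > 0)
    message(sprintf("load_edge_list: dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_self, n_dup))
  g
}

#' Write a graph as a plain edge-list file
#'
#' One edge per line, endpoints separated by a single space. Labels come from
#' the `name` vertex attribute when present, otherwise internal ids are used.
#'
#' @param g an `igraph` graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = !is.null(igraph::V(g)$name))
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Basic statistics of a graph
#'
#' @param g an `igraph` graph.
#' @return A one-row data frame with columns `n_nodes`, `n_edges`,
#'   `avg_degree` (`2|E|/|V|`) and `n_components`.
#' @examples
#' tri <- igraph::make_ring(3)
#' graph_stats(tri)  # 3 nodes, 3 edges, mean degree 2, one component
#' @export
graph_stats <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  data.frame(n_nodes = n,
             n_edges = m,
             avg_degree = if (n > 0) 2 * m / n else 0,
             n_components = if (n > 0) igraph::count_components(g) else 0L)
}
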