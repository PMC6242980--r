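#' Construct an undirected simple graph for link prediction
#'
#' The basic container scored by every similarity index in this package: an
#' undirected simple graph (no self-loops, no multi-edges) over contiguous
#' 1-based internal node ids, with external labels preserved in a label map.
#'
#' @param edges two-column matrix (or data.frame) of node ids in `1..n_nodes`,
#'   one row per undirected edge. Duplicate rows, reversed duplicates and
#'   self-loops are dropped with a warning.
#' @param n_nodes number of nodes. Defaults to the largest id seen in `edges`.
#' @param labels character vector of external node labels, one per node.
#'   Defaults to `as.character(1:n_nodes)`.
#' @return An object of class `lp_graph` with elements `n_nodes` (integer),
#'   `edges` (m x 2 integer matrix, each row sorted, rows unique),
#'   `adj` (sparse symmetric 0/1 adjacency `Matrix`), and `labels`.
#' @examples
#' g <- lp_graph(cbind(c(1, 1, 2, 2, 3, 4), c(2, 3, 3, 4, 4, 5)))
#' g$n_nodes
#' node_neighbors(g, 4)
#' @export
lp_graph <- function(edges, n_nodes = NULL, labels = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  if (ncol(edges) < 2L) stop("'edges' must have two columns")
  edges <- matrix(as.integer(edges[, 1:2]), ncol = 2L)
  if (is.null(n_nodes)) {
    n_nodes <- if (nrow(edges)) max(edges) else 0L
  }
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1L) stop("graph must have at least one node")
  if (nrow(edges) && (min(edges) < 1L || max(edges) > n_nodes)) {
    stop("edge endpoints must lie in 1..n_nodes")
  }
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical orientation i < j, then dedupe
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (nrow(edges)) {
    key <- (edges[, 1] - 1) * n_nodes + edges[, 2]
    dup <- duplicated(key)
    if (any(dup)) {
      warning(sprintf("dropped %d duplicate edge(s)", sum(dup)))
      edges <- edges[!dup, , drop = FALSE]
    }
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  if (is.null(labels)) labels <- as.character(seq_len(n_nodes))
  if (length(labels) != n_nodes) stop("'labels' must have one entry per node")
  adj <- Matrix::sparseMatrix(
    i = c(edges[, 1], edges[, 2]), j = c(edges[, 2], edges[, 1]),
    x = 1, dims = c(n_nodes, n_nodes)
  )
  structure(
    list(n_nodes = n_nodes, edges = edges, adj = adj,
         labels = as.character(labels)),
    class = "lp_graph"
  )
}

#' @export
print.lp_graph <- function(x, ...) {
  cat(sprintf("lp_graph: %d nodes, %d edges\n", x$n_nodes, n_edges(x)))
  invisible(x)
}

#' Number of edges of a graph
#' @param g an [lp_graph].
#' @return Integer edge count |E|.
#' @export
n_edges <- function(g) nrow(g$edges)

#' Degree sequence of a graph
#' @param g an [lp_graph].
#' @return Integer vector of node degrees, in node-id order.
#' @export
degrees <- function(g) {
  tabulate(c(g$edges[, 1], g$edges[, 2]), nbins = g$n_nodes)
}

#' Neighbor set of a node
#'
#' @param g an [lp_graph].
#' @param x node id in `1..n_nodes`.
#' @return Sorted integer vector of the ids adjacent to `x`; never contains
#'   `x` itself.
#' @export
node_neighbors <- function(g, x) {
  x <- as.integer(x)
  if (length(x) != 1L || is.na(x) || x < 1L || x > g$n_nodes) {
    stop("node id out of range")
  }
  sort(c(g$edges[g$edges[, 1] == x, 2], g$edges[g$edges[, 2] == x, 1]))
}

#' All node pairs not connected by an edge
#'
#' Enumerates the nonexistent links U - E: every unordered node pair absent
#' from the edge set. These form the negative class when measuring AUC.
#'
#' @param g an [lp_graph].
#' @return Two-column integer matrix of pairs with column 1 < column 2;
#'   `choose(n, 2) - |E|` rows.
#' @export
nonexistent_pairs <- function(g) {
  n <- g$n_nodes
  ut <- upper.tri(matrix(0, n, n))
  a <- as.matrix(g$adj)
  idx <- which(ut & a == 0, arr.ind = TRUE)
  m <- cbind(idx[, 1], idx[, 2])
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Read a graph from an edge-list text file
#'
#' Accepts whitespace- or comma-delimited lines; the first two fields of each
#' line are the edge endpoints (arbitrary labels). Lines beginning with `#`
#' and blank lines are ignored. Labels are mapped to internal ids `1..|V|` in
#' order of first appearance. Duplicate edges and self-loops are dropped with
#' a warning.
#'
#' @param file path or connection.
#' @return An [lp_graph].
#' @export
read_edge_list <- function(file) {
  lines <- readLines(file, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty edge list: ", file)
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("line %d has fewer than 2 fields", lineno[bad[1]]))
  }
  from <- vapply(parts, `[`, "", 1L)
  to <- vapply(parts, `[`, "", 2L)
  labels <- unique(c(rbind(from, to)))  # first-appearance order
  ids <- stats::setNames(seq_along(labels), labels)
  lp_graph(cbind(ids[from], ids[to]), n_nodes = length(labels),
           labels = labels)
}

#' Write a graph as an edge-list text file
#'
#' One line per edge, two space-separated external labels. Round-trips
#' through [read_edge_list()] unchanged (up to label order of isolated
#' nodes, which an edge list cannot represent).
#'
#' @param g an [lp_graph].
#' @param file path or connection.
#' @export
write_edge_list <- function(g, file) {
  writeLines(paste(g$labels[g$edges[, 1]], g$labels[g$edges[, 2]]), file)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected")
}

#' Descriptive network statistics
#'
#' Computes the standard summary of an undirected network: node and link
#' counts, average shortest distance `<d>` (over reachable pairs; a warning
#' is issued if the graph is disconnected), average degree `<k> = 2|E|/|V|`,
#' degree heterogeneity `<H> = <k^2>/<k>^2`, average local clustering
#' coefficient `<C>` (nodes of degree < 2 contribute 0), and degree
#' assortativity `<r>` (Pearson correlation of endpoint degrees over edges).
#'
#' For an edgeless graph `avg_degree` is 0 and the distance, heterogeneity,
#' clustering and assortativity fields are `NA`.
#'
#' @param g an [lp_graph] with at least 2 nodes.
#' @return A one-row data.frame with columns `n_nodes`, `n_links`,
#'   `avg_shortest_distance`, `avg_degree`, `degree_heterogeneity`,
#'   `clustering_coefficient`, `assortativity`.
#' @export
network_stats <- function(g) {
  if (g$n_nodes < 2L) stop("network_stats requires at least 2 nodes")
  m <- n_edges(g)
  k <- degrees(g)
  avg_k <- 2 * m / g$n_nodes
  if (m == 0L) {
    return(data.frame(
      n_nodes = g$n_nodes, n_links = 0L, avg_shortest_distance = NA_real_,
      avg_degree = 0, degree_heterogeneity = NA_real_,
      clustering_coefficient = NA_real_, assortativity = NA_real_
    ))
  }
  ig <- as_igraph(g)
  if (!igraph::is_connected(ig)) {
    warning("graph is disconnected; <d> averages over reachable pairs only")
  }
  d_avg <- igraph::mean_distance(ig, unconnected = TRUE)
  cl <- igraph::transitivity(ig, type = "local", isolates = "zero")
  r <- if (stats::var(k[g$edges]) == 0) NA_real_ else {
    igraph::assortativity_degree(ig)
  }
  data.frame(
    n_nodes = g$n_nodes, n_links = m,
    avg_shortest_distance = d_avg,
    avg_degree = avg_k,
    degree_heterogeneity = mean(k^2) / mean(k)^2,
    clustering_coefficient = mean(cl),
    assortativity = r
  )
}
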