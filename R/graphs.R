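# Experiment transition graphs: modular, lattice, ring, custom.
# Node ids are 0-based integers; all built-ins have 15 nodes of degree 4 and
# uniform 0.25 transition probability per edge.

modular_edges <- function() {
  # Three communities of five nodes {5c..5c+4}. Within a community every pair
  # is connected except the two boundary nodes (5c and 5c+4); each boundary
  # node carries a single edge to the nearest boundary node of the adjacent
  # community, closing a ring of communities. This is the unique wiring that
  # is 4-regular with three dense 5-node communities and 3 bridge edges.
  e <- NULL
  for (cc in 0:2) {
    v <- (5L * cc):(5L * cc + 4L)
    pr <- t(combn(v, 2L))
    pr <- pr[!(pr[, 1] == 5L * cc & pr[, 2] == 5L * cc + 4L), , drop = FALSE]
    e <- rbind(e, pr)
  }
  rbind(e, c(4L, 5L), c(9L, 10L), c(14L, 0L))
}

lattice_edges <- function() {
  # 3 x 5 grid with periodic boundaries; node id = 5*row + col.
  e <- NULL
  for (r in 0:2) {
    for (cl in 0:4) {
      i <- 5L * r + cl
      e <- rbind(e, c(i, 5L * ((r + 1L) %% 3L) + cl),
                    c(i, 5L * r + (cl + 1L) %% 5L))
    }
  }
  e
}

ring_edges <- function() {
  # 15-ring, each node tied to nearest and next-nearest neighbors.
  e <- NULL
  for (i in 0:14) e <- rbind(e, c(i, (i + 1L) %% 15L), c(i, (i + 2L) %% 15L))
  e
}

canonical_edges <- function(e) {
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  storage.mode(e) <- "integer"
  colnames(e) <- c("from", "to")
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

as_igraph <- function(graph) {
  igraph::graph_from_edgelist(graph$edges + 1L, directed = FALSE)
}

#' Build a transition graph
#'
#' Constructs one of the three 15-node experiment topologies, or a custom
#' graph from an explicit edge list. Every graph carries a row-stochastic
#' transition matrix `A` with \eqn{A_{ij} = 1/\mathrm{degree}(i)} on edges.
#' The built-ins are 4-regular, so every edge has transition probability
#' 0.25: the modular graph has three communities of five densely connected
#' nodes, the lattice graph is a 3 x 5 grid with periodic boundaries, and
#' the ring graph connects each node to its nearest and next-nearest
#' neighbors.
#'
#' @param topology one of `"modular"`, `"lattice"`, `"ring"`, `"custom"`.
#' @param edge_list for `"custom"` only: a 2-column matrix (or data.frame) of
#'   0-based node-id pairs describing an undirected, connected graph.
#' @param name optional label; defaults to the topology.
#' @return an object of class `transition_graph`: a list with `name`,
#'   `n_nodes`, `edges` (2-column 0-based matrix), `A` (row-stochastic
#'   matrix) and `communities` (0-based labels, modular only).
#' @export
#' @examples
#' g <- build_graph("modular")
#' rowSums(g$A)
build_graph <- function(topology = c("modular", "lattice", "ring", "custom"),
                        edge_list = NULL, name = NULL) {
  topology <- match.arg(topology)
  if (topology != "custom" && !is.null(edge_list)) {
    stop("`edge_list` is only accepted for topology = 'custom'")
  }
  if (topology == "custom") {
    if (is.null(edge_list)) stop("a custom graph needs an `edge_list`")
    e <- as.matrix(edge_list)
    if (ncol(e) != 2L || nrow(e) < 1L) stop("`edge_list` must be a 2-column matrix")
    if (any(e < 0) || any(e != round(e))) stop("node ids must be non-negative integers")
    if (any(e[, 1] == e[, 2])) stop("self-loops are not allowed")
    e <- canonical_edges(e)
    n <- max(e) + 1L
  } else {
    e <- canonical_edges(switch(topology,
      modular = modular_edges(),
      lattice = lattice_edges(),
      ring    = ring_edges()))
    n <- 15L
  }
  deg <- tabulate(c(e[, 1], e[, 2]) + 1L, nbins = n)
  if (any(deg == 0L)) {
    stop("graph has degree-0 nodes: ", paste(which(deg == 0L) - 1L, collapse = ", "))
  }
  A <- matrix(0, n, n)
  A[cbind(e[, 1], e[, 2]) + 1L] <- 1
  A[cbind(e[, 2], e[, 1]) + 1L] <- 1
  A <- A / deg
  graph <- structure(
    list(name = name %||% topology, n_nodes = n, edges = e, A = A,
         communities = if (topology == "modular") rep(0:2, each = 5L) else NULL),
    class = "transition_graph")
  comp <- igraph::components(as_igraph(graph))
  if (comp$no != 1L) stop("graph is disconnected (", comp$no, " components)")
  graph
}

#' @export
print.transition_graph <- function(x, ...) {
  cat("<transition_graph> ", x$name, ": ", x$n_nodes, " nodes, ",
      nrow(x$edges), " edges", sep = "")
  if (!is.null(x$communities)) {
    cat(", ", length(unique(x$communities)), " communities", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' All-pairs topological distances
#'
#' Shortest-path (hop) distances between every pair of nodes. Violations of
#' the transition structure are classified by this distance.
#'
#' @param graph a [build_graph()] object.
#' @return symmetric integer matrix of BFS distances with zero diagonal;
#'   row/column names are 0-based node ids.
#' @export
topological_distances <- function(graph) {
  stopifnot(inherits(graph, "transition_graph"))
  D <- igraph::distances(as_igraph(graph))
  storage.mode(D) <- "integer"
  dimnames(D) <- list(0:(graph$n_nodes - 1L), 0:(graph$n_nodes - 1L))
  D
}

# adjacency list: element i+1 holds the 0-based neighbors of node i
neighbor_list <- function(graph) {
  n <- graph$n_nodes
  nb <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
    nb[[i + 1L]] <- c(nb[[i + 1L]], j)
    nb[[j + 1L]] <- c(nb[[j + 1L]], i)
  }
  lapply(nb, sort)
}
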