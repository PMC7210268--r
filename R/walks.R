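# Walk protocols: plain random walks, the Hamiltonian-interleaved session,
# and the ring session with topological-distance violations.

new_walk_sequence <- function(nodes, segment, violation_distance, graph, seed) {
  structure(
    list(nodes = as.integer(nodes),
         segment = segment,
         violation_distance = as.integer(violation_distance),
         graph = graph,
         seed = seed),
    class = "walk_sequence")
}

#' @export
print.walk_sequence <- function(x, ...) {
  tab <- table(x$segment)
  cat("<walk_sequence> ", length(x$nodes), " trials on '", x$graph$name, "' (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
length.walk_sequence <- function(x) length(x$nodes)

#' @export
as.data.frame.walk_sequence <- function(x, ...) {
  data.frame(trial = seq_along(x$nodes), node = x$nodes,
             segment = x$segment, violation_distance = x$violation_distance)
}

walk_nodes <- function(walk) {
  if (inherits(walk, "walk_sequence")) return(walk$nodes)
  if (is.numeric(walk)) return(as.integer(walk))
  stop("`walk` must be a walk_sequence or an integer vector of 0-based nodes")
}

#' Random walk on a transition graph
#'
#' The first node is uniform over all nodes; each subsequent node is drawn
#' uniformly from the current node's neighbors (probability 0.25 per edge on
#' the 4-regular built-ins).
#'
#' @param graph a [build_graph()] object.
#' @param n_trials walk length (>= 1).
#' @param seed optional RNG seed for reproducibility.
#' @return a `walk_sequence` with every trial labeled `"random"`.
#' @export
random_walk <- function(graph, n_trials, seed = NULL) {
  stopifnot(inherits(graph, "transition_graph"))
  if (length(n_trials) != 1L || n_trials < 1) stop("`n_trials` must be >= 1")
  n_trials <- as.integer(n_trials)
  nb <- neighbor_list(graph)
  nodes <- with_seed(seed, {
    x <- integer(n_trials)
    x[1] <- sample.int(graph$n_nodes, 1L) - 1L
    for (t in seq_len(n_trials - 1L)) {
      cand <- nb[[x[t] + 1L]]
      x[t + 1L] <- cand[sample.int(length(cand), 1L)]
    }
    x
  })
  new_walk_sequence(nodes, rep("random", n_trials),
                    c(NA_integer_, rep(1L, n_trials - 1L)), graph, seed)
}

# Randomized depth-first backtracking search for a Hamiltonian path starting
# at `start` (0-based). Neighbor order is shuffled with the session RNG.
# Returns the path or NULL if the search exhausts.
hamiltonian_path_from <- function(nb, n, start) {
  path <- integer(n)
  path[1] <- start
  visited <- logical(n)
  visited[start + 1L] <- TRUE
  # iterative DFS with explicit choice stacks
  choices <- vector("list", n)
  choices[[1]] <- sample(nb[[start + 1L]])
  depth <- 1L
  while (depth >= 1L) {
    if (depth == n) return(path)
    opts <- choices[[depth]]
    opts <- opts[!visited[opts + 1L]]
    if (length(opts) == 0L) {
      # backtrack
      if (depth > 1L) visited[path[depth] + 1L] <- FALSE
      depth <- depth - 1L
      if (depth >= 1L) {
        # drop the choice we just explored
        choices[[depth]] <- setdiff(choices[[depth]], path[depth + 1L])
      }
      next
    }
    nxt <- opts[1]
    choices[[depth]] <- setdiff(choices[[depth]], nxt)
    depth <- depth + 1L
    path[depth] <- nxt
    visited[nxt + 1L] <- TRUE
    choices[[depth]] <- sample(nb[[nxt + 1L]])
  }
  NULL
}

#' Hamiltonian-interleaved session
#'
#' Generates the 1500-trial session used to control for stimulus recency:
#' 700 random-walk trials, then eight repeats of 85 random-walk trials
#' followed by 15 Hamiltonian-walk trials. Each Hamiltonian segment visits
#' every node exactly once, starts at a neighbor of the preceding trial's
#' node, follows edges throughout, and the next random segment resumes from
#' a neighbor of its final node, so the whole session is a valid walk.
#'
#' @param graph a [build_graph()] object admitting Hamiltonian paths from
#'   any start node (true for the modular graph).
#' @param seed optional RNG seed.
#' @return a `walk_sequence` with segments labeled `"random"`/`"hamiltonian"`.
#' @export
hamiltonian_session <- function(graph, seed = NULL) {
  stopifnot(inherits(graph, "transition_graph"))
  n <- graph$n_nodes
  nb <- neighbor_list(graph)
  with_seed(seed, {
    nodes <- integer(0)
    segment <- character(0)
    step_from <- function(i) {
      cand <- nb[[i + 1L]]
      cand[sample.int(length(cand), 1L)]
    }
    rw <- function(len, from = NULL) {
      x <- integer(len)
      x[1] <- if (is.null(from)) sample.int(n, 1L) - 1L else step_from(from)
      for (t in seq_len(len - 1L)) x[t + 1L] <- step_from(x[t])
      x
    }
    nodes <- rw(700L)
    segment <- rep("random", 700L)
    for (rep_i in 1:8) {
      r <- rw(85L, from = nodes[length(nodes)])
      nodes <- c(nodes, r)
      segment <- c(segment, rep("random", 85L))
      start <- step_from(nodes[length(nodes)])
      ham <- hamiltonian_path_from(nb, n, start)
      if (is.null(ham)) {
        stop("Hamiltonian path search exhausted from start node ", start)
      }
      nodes <- c(nodes, ham)
      segment <- c(segment, rep("hamiltonian", n))
    }
    new_walk_sequence(nodes, segment,
                      c(NA_integer_, rep(1L, length(nodes) - 1L)), graph, seed)
  })
}

#' Random walk with topological-distance violations
#'
#' Generates the 1500-trial ring session probing reactions to novel
#' transitions. Trials 1-500 are a standard random walk; 50 violations are
#' placed at random non-adjacent positions within trials 501-1500: 20 of
#' topological distance two (short), 20 of distance three and 10 of distance
#' four (long). A violation jumps to a node drawn uniformly from those at
#' the required shortest-path distance from the current node, and the walk
#' continues from the violation target.
#'
#' @param graph a [build_graph()] object whose distance classes 2, 3 and 4
#'   are non-empty from every node (true for the ring graph).
#' @param seed optional RNG seed.
#' @return a `walk_sequence`; `violation_distance` records 1 for standard
#'   transitions and the BFS distance (2-4) for violations.
#' @export
violation_walk <- function(graph, seed = NULL) {
  stopifnot(inherits(graph, "transition_graph"))
  n_trials <- 1500L
  nb <- neighbor_list(graph)
  D <- topological_distances(graph)
  with_seed(seed, {
    # violation positions: uniform without replacement in 501..1500, no two
    # adjacent (avoids compounding two non-edge steps)
    pos <- NULL
    for (try in 1:10000) {
      cand <- sort(sample(501:1500, 50L))
      if (all(diff(cand) > 1L)) { pos <- cand; break }
    }
    if (is.null(pos)) stop("could not place non-adjacent violation positions")
    dist_req <- sample(c(rep(2L, 20L), rep(3L, 20L), rep(4L, 10L)))
    nodes <- integer(n_trials)
    vdist <- c(NA_integer_, rep(1L, n_trials - 1L))
    nodes[1] <- sample.int(graph$n_nodes, 1L) - 1L
    viol_at <- integer(graph$n_nodes)  # lookup: trial -> required distance
    viol_lookup <- integer(n_trials)
    viol_lookup[pos] <- dist_req
    for (t in 2:n_trials) {
      d_req <- viol_lookup[t]
      if (d_req > 0L) {
        cand <- which(D[nodes[t - 1L] + 1L, ] == d_req) - 1L
        if (length(cand) == 0L) {
          stop("no node at distance ", d_req, " from node ", nodes[t - 1L])
        }
        nodes[t] <- cand[sample.int(length(cand), 1L)]
        vdist[t] <- d_req
      } else {
        cand <- nb[[nodes[t - 1L] + 1L]]
        nodes[t] <- cand[sample.int(length(cand), 1L)]
      }
    }
    segment <- rep("random", n_trials)
    segment[pos] <- "violation"
    new_walk_sequence(nodes, segment, vdist, graph, seed)
  })
}
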