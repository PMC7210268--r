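# The memory-error learner: Boltzmann lag distribution, belief-weighted
# sequential counting, the asymptotic closed form, higher-order competing
# counts, and the model-predicted network-effect curves.

#' Boltzmann memory distribution over temporal lags
#'
#' Weights \eqn{w(\Delta t) \propto e^{-\beta \Delta t}} over lags
#' \eqn{\Delta t = 0, \dots, \mathrm{horizon}-1}, renormalized over the
#' finite horizon. `beta = Inf` is the error-free delta limit (all mass at
#' lag 0); `beta = 0` is the uniform limit.
#'
#' @param beta inverse temperature, `>= 0` or `Inf`.
#' @param horizon number of supported lags (>= 1).
#' @return a `memory_distribution`: list with `beta`, `horizon`, `weights`
#'   and the finite-horizon partition constant `z`.
#' @export
#' @examples
#' boltzmann_weights(log(2), 4)$weights
boltzmann_weights <- function(beta, horizon) {
  if (length(beta) != 1L || is.na(beta) || beta < 0) stop("`beta` must be >= 0 (Inf allowed)")
  if (length(horizon) != 1L || horizon < 1) stop("`horizon` must be >= 1")
  horizon <- as.integer(horizon)
  if (is.infinite(beta)) {
    w <- c(1, rep(0, horizon - 1L))
    z <- 1
  } else {
    u <- exp(-beta * (0:(horizon - 1L)))
    z <- sum(u)
    w <- u / z
  }
  structure(list(beta = beta, horizon = horizon, weights = w, z = z),
            class = "memory_distribution")
}

#' @export
print.memory_distribution <- function(x, ...) {
  cat("<memory_distribution> beta =", format(x$beta),
      "over", x$horizon, "lags\n")
  invisible(x)
}

#' Free energy of a lag distribution
#'
#' For a candidate distribution \eqn{Q} over lags, the mean recall error is
#' \eqn{E(Q) = \sum Q(\Delta t)\,\Delta t}, the complexity is the negative
#' entropy \eqn{-S(Q) = \sum Q \log Q} (natural log, \eqn{0 \log 0 = 0}),
#' and the total cost is \eqn{F(Q) = \beta E(Q) - S(Q)}. Among all
#' distributions on a fixed lag range the Boltzmann distribution minimizes
#' \eqn{F}.
#'
#' @param weights a `memory_distribution` or a non-negative numeric vector
#'   summing to 1, giving probabilities for lags `0, 1, ...`.
#' @param beta inverse temperature weighting error against complexity.
#' @return list with components `E`, `S`, and `F`.
#' @export
free_energy <- function(weights, beta) {
  if (inherits(weights, "memory_distribution")) weights <- weights$weights
  if (!is.numeric(weights) || any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (length(beta) != 1L || is.na(beta)) stop("`beta` must be a single number")
  lags <- seq_along(weights) - 1
  E <- sum(weights * lags)
  nz <- weights > 0
  S <- -sum(weights[nz] * log(weights[nz]))
  list(E = E, S = S, F = beta * E - S)
}

#' Sequentially learn transition counts under memory errors
#'
#' Runs the learner over a walk. At each trial the learner forms a belief
#' over which node occurred on the previous trial, weighting history
#' positions by the Boltzmann lag distribution renormalized over the
#' available history, and credits one unit of count mass, split according to
#' that belief, to the transitions into the observed node. With
#' `beta = Inf` the belief is a delta on the true previous node and the
#' counts reduce to the exact integer transition tally of maximum
#' likelihood estimation.
#'
#' The anticipation series `a(t)` records, for each trial `t >= 2`, the
#' learner's estimated probability of the transition actually observed at
#' `t`, computed from counts accumulated through trial `t - 1` (rows with no
#' mass yet fall back to the uniform `1/n`).
#'
#' @param walk a `walk_sequence` or an integer vector of 0-based node ids
#'   (length >= 2).
#' @param beta inverse temperature (`>= 0`, `Inf` allowed).
#' @param n_nodes number of nodes; inferred from the walk's graph when
#'   available.
#' @return a `learner_state`: list with `counts` (n x n real matrix whose
#'   total mass after `T` trials is `T - 1`), `anticipation` (length-`T`
#'   numeric, `NA` at trial 1), `beta`, `n_nodes`, `n_trials`.
#' @export
sequential_learn <- function(walk, beta, n_nodes = NULL) {
  nodes <- walk_nodes(walk)
  if (length(nodes) < 2L) stop("walk must have at least 2 trials")
  if (length(beta) != 1L || is.na(beta) || beta < 0) stop("`beta` must be >= 0 (Inf allowed)")
  n <- n_nodes %||%
    (if (inherits(walk, "walk_sequence")) walk$graph$n_nodes else max(nodes) + 1L)
  if (any(nodes < 0L | nodes >= n)) stop("node ids out of range 0..", n - 1L)
  d <- exp(-beta)  # Inf -> 0 (delta belief), 0 -> 1 (uniform belief)
  T_len <- length(nodes)
  counts <- matrix(0, n, n, dimnames = list(0:(n - 1L), 0:(n - 1L)))
  rowmass <- numeric(n)
  a <- rep(NA_real_, T_len)
  # unnormalized belief over nodes; recursion u_t = d * u_{t-1} + e_{x_t}
  u <- numeric(n)
  u[nodes[1] + 1L] <- 1
  usum <- 1
  for (t in 2:T_len) {
    i <- nodes[t - 1L] + 1L
    j <- nodes[t] + 1L
    a[t] <- if (rowmass[i] > 0) counts[i, j] / rowmass[i] else 1 / n
    B <- u / usum
    counts[, j] <- counts[, j] + B
    rowmass <- rowmass + B
    u <- d * u
    u[j] <- u[j] + 1
    usum <- d * usum + 1
  }
  structure(list(counts = counts, anticipation = a, beta = beta,
                 n_nodes = n, n_trials = T_len),
            class = "learner_state")
}

#' @export
print.learner_state <- function(x, ...) {
  cat("<learner_state> beta =", format(x$beta), "after", x$n_trials,
      "trials on", x$n_nodes, "nodes\n")
  invisible(x)
}

#' Transition estimate from accumulated counts
#'
#' Row-normalizes a count matrix into expected transition probabilities,
#' \eqn{\hat A_{ij} = \tilde n_{ij} / \sum_k \tilde n_{ik}}. Rows with zero
#' mass (never-visited nodes) fall back to the uniform `1/n`.
#'
#' @param x a `learner_state` or a non-negative count matrix.
#' @return row-stochastic matrix of the same dimension.
#' @export
estimate_from_counts <- function(x) {
  counts <- if (inherits(x, "learner_state")) x$counts else as.matrix(x)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- ncol(counts)
  rs <- rowSums(counts)
  Ahat <- counts / ifelse(rs > 0, rs, 1)
  Ahat[rs == 0, ] <- 1 / n
  Ahat
}

#' Asymptotic closed-form transition estimate
#'
#' In the long-sequence limit the learner's estimate converges to
#' \deqn{\hat A = (1 - e^{-\beta})\, A\, (I - e^{-\beta} A)^{-1},}
#' a discounted average over walks of all lengths,
#' \eqn{\sum_{\Delta t \ge 0} P(\Delta t) A^{\Delta t + 1}}. Computed with a
#' linear solve (never an explicit inverse); the system is well conditioned
#' since the spectral radius of \eqn{e^{-\beta} A} is \eqn{e^{-\beta} < 1}.
#'
#' @param A a `transition_graph` or a row-stochastic matrix.
#' @param beta finite inverse temperature, `> 0`.
#' @return row-stochastic matrix \eqn{\hat A}.
#' @export
#' @examples
#' g <- build_graph("modular")
#' round(asymptotic_estimate(g, 0.3), 3)[1:5, 1:5]
asymptotic_estimate <- function(A, beta) {
  if (inherits(A, "transition_graph")) A <- A$A
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("`A` must be square")
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-8)) {
    stop("`A` must be row-stochastic")
  }
  if (length(beta) != 1L || is.na(beta) || !is.finite(beta) || beta <= 0) {
    stop("`beta` must be a finite value > 0")
  }
  q <- exp(-beta)
  n <- nrow(A)
  # A %*% solve(I - qA) via one triangular-factor solve on the transpose
  Ahat <- (1 - q) * t(solve(t(diag(n) - q * A), t(A)))
  dimnames(Ahat) <- dimnames(A)
  Ahat
}

#' Online anticipations of the higher-order competing models
#'
#' The competing hierarchy assumes explicit learning of k-step transition
#' statistics: \eqn{n^{(k)}} tallies observed k-step transitions, and the
#' k-th anticipation at trial `t` is the row-normalized k-step estimate at
#' the observed one-step pair, using counts through trial `t - 1`. Rows with
#' zero mass fall back to the uniform `1/n`. The first-order series equals
#' the `beta = Inf` learner's anticipations.
#'
#' @param walk a `walk_sequence` or 0-based integer node vector.
#' @param order maximal step length `l >= 1`; walk must be longer than `l`.
#' @param n_nodes number of nodes; inferred when possible.
#' @return list with `anticipation` (`T x order` matrix, `NA` at trial 1)
#'   and `counts` (list of k-step integer count matrices).
#' @export
order_anticipation <- function(walk, order, n_nodes = NULL) {
  nodes <- walk_nodes(walk)
  if (length(order) != 1L || order < 1) stop("`order` must be >= 1")
  order <- as.integer(order)
  if (length(nodes) <= order) stop("walk must be longer than `order`")
  n <- n_nodes %||%
    (if (inherits(walk, "walk_sequence")) walk$graph$n_nodes else max(nodes) + 1L)
  T_len <- length(nodes)
  counts <- replicate(order, matrix(0L, n, n), simplify = FALSE)
  rowm <- replicate(order, numeric(n), simplify = FALSE)
  a <- matrix(NA_real_, T_len, order,
              dimnames = list(NULL, paste0("a", seq_len(order))))
  for (t in 2:T_len) {
    i <- nodes[t - 1L] + 1L
    j <- nodes[t] + 1L
    for (k in seq_len(order)) {
      a[t, k] <- if (rowm[[k]][i] > 0) counts[[k]][i, j] / rowm[[k]][i] else 1 / n
    }
    for (k in seq_len(min(order, t - 1L))) {
      src <- nodes[t - k] + 1L
      counts[[k]][src, j] <- counts[[k]][src, j] + 1L
      rowm[[k]][src] <- rowm[[k]][src] + 1
    }
  }
  list(anticipation = a, counts = counts)
}

modular_edge_index <- function(graph, which = c("all", "within", "between")) {
  which <- match.arg(which)
  e <- graph$edges
  if (which != "all") {
    comm <- graph$communities
    within <- comm[e[, 1] + 1L] == comm[e[, 2] + 1L]
    e <- e[if (which == "within") within else !within, , drop = FALSE]
  }
  # both directions of each undirected edge
  rbind(cbind(e[, 1], e[, 2]), cbind(e[, 2], e[, 1])) + 1L
}

#' Predicted network-effect curves over an inverse-temperature sweep
#'
#' For each `beta`, computes the asymptotic estimate on the modular and
#' lattice graphs and reports two ratios of mean estimated probabilities
#' over directed edges of the true graphs: within-community over
#' between-community edges of the modular graph (the cross-cluster
#' surprisal prediction), and modular edges over lattice edges (the
#' modular-lattice prediction). Both approach 1 as `beta` grows and the
#' estimates converge to the true uniform 0.25 structure.
#'
#' @param beta numeric vector of finite inverse temperatures `> 0`.
#' @return data.frame with columns `beta`, `ratio_within_between`,
#'   `ratio_modular_lattice`.
#' @export
#' @examples
#' effect_curves(c(0.1, 0.3, 1))
effect_curves <- function(beta) {
  if (length(beta) == 0L) stop("`beta` grid is empty")
  gm <- build_graph("modular")
  gl <- build_graph("lattice")
  iw <- modular_edge_index(gm, "within")
  ib <- modular_edge_index(gm, "between")
  im <- modular_edge_index(gm, "all")
  il <- modular_edge_index(gl, "all")
  res <- vapply(beta, function(b) {
    Am <- asymptotic_estimate(gm, b)
    Al <- asymptotic_estimate(gl, b)
    c(mean(Am[iw]) / mean(Am[ib]), mean(Am[im]) / mean(Al[il]))
  }, numeric(2))
  data.frame(beta = beta,
             ratio_within_between = res[1, ],
             ratio_modular_lattice = res[2, ])
}

#' Mean estimated transition probability by topological distance
#'
#' Averages the asymptotic estimate over all ordered node pairs at each
#' shortest-path distance `d >= 1`. The model predicts anticipations of
#' violations to decay with the topological distance of the jump.
#'
#' @param graph a [build_graph()] object.
#' @param beta finite inverse temperature `> 0`.
#' @return data.frame with columns `distance`, `mean_estimate`, `n_pairs`.
#' @export
distance_profile <- function(graph, beta) {
  stopifnot(inherits(graph, "transition_graph"))
  D <- topological_distances(graph)
  Ahat <- asymptotic_estimate(graph, beta)
  ds <- sort(unique(D[D >= 1L]))
  data.frame(
    distance = ds,
    mean_estimate = vapply(ds, function(d) mean(Ahat[D == d]), numeric(1)),
    n_pairs = vapply(ds, function(d) sum(D == d), numeric(1)))
}
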