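# Independent oracles used across tests; deliberately naive implementations
# that share no code with the package internals.

# all-pairs BFS distances from an edge list (0-based), frontier by frontier
bfs_distances <- function(edges, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1] + 1L; j <- edges[k, 2] + 1L
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  D <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    d <- 0L
    while (length(frontier)) {
      d <- d + 1L
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# truncated-series form of the asymptotic estimate: sum_{dt<=K} P(dt) A^(dt+1)
series_estimate <- function(A, beta, K = 500L) {
  q <- exp(-beta)
  S <- matrix(0, nrow(A), ncol(A))
  Ap <- A
  for (dt in 0:K) {
    S <- S + (1 - q) * q^dt * Ap
    Ap <- Ap %*% A
  }
  S
}

# integer one-step transition tally of a 0-based node sequence
mle_tally <- function(nodes, n) {
  tab <- table(factor(nodes[-length(nodes)], levels = 0:(n - 1L)),
               factor(nodes[-1], levels = 0:(n - 1L)))
  matrix(as.integer(tab), n, n)
}

# toy single-subject trial table with constant defaults, for filter tests
toy_trials <- function(n = 600L, rt = 500, correct = TRUE) {
  data.frame(subject_id = "t01", trial = seq_len(n), stage = 1L,
             node = rep(0:14, length.out = n),
             target_combo = sprintf("C%02d", rep(1:15, length.out = n)),
             rt_ms = rep(rt, length.out = n),
             correct = rep(correct, length.out = n),
             segment = "random",
             violation_distance = c(NA, rep(1L, n - 1L)),
             graph = "modular")
}

# noise-free subject whose RTs are an exact affine function of the
# anticipation series at beta_star (no nuisance effects)
exact_subject <- function(graph, beta_star = 0.3, r0 = 800, r1 = -700,
                          n_trials = 800L, seed = 11) {
  tr <- ground_truth(beta_true = beta_star, r0 = r0, r1 = r1, noise_sd = 0,
                     button_offsets = rep(0, 15), trial_slope = 0,
                     recency_slope = 0, error_rate = 0, outlier_rate = 0)
  sim <- simulate_subject_rt(graph, "random", tr, n_trials = n_trials, seed = seed)
  sim$data <- sim$data[sim$data$trial > 1L, ]
  sim
}
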