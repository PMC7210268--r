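test_that("Boltzmann weights cover the geometric, uniform and delta regimes", {
  w <- boltzmann_weights(log(2), 40)
  # long horizon approximates the infinite-horizon geometric 1/2, 1/4, 1/8
  expect_equal(w$weights[1:3], c(1 / 2, 1 / 4, 1 / 8), tolerance = 1e-9)
  # successive ratio is exactly e^-beta everywhere
  expect_equal(w$weights[-1] / w$weights[-40], rep(exp(-log(2)), 39))
  expect_equal(sum(w$weights), 1)
  expect_equal(boltzmann_weights(0, 3)$weights, rep(1 / 3, 3))
  expect_equal(boltzmann_weights(Inf, 5)$weights, c(1, 0, 0, 0, 0))
  expect_error(boltzmann_weights(-0.1, 5), ">= 0")
})

test_that("free energy has the closed-form values and rejects bad input", {
  d0 <- free_energy(c(1, 0, 0), beta = 3)
  expect_equal(d0, list(E = 0, S = 0, F = 0))
  du <- free_energy(c(0.5, 0.5), beta = 1)
  expect_equal(du$E, 0.5)
  expect_equal(du$S, log(2))
  expect_equal(du$F, 0.5 - log(2))
  expect_error(free_energy(c(0.7, 0.7), beta = 1), "sum to 1")
  expect_error(free_energy(c(1.2, -0.2), beta = 1), "non-negative")
})

test_that("the Boltzmann distribution minimizes free energy on the simplex", {
  # brute-force grid over distributions on lags {0, 1, 2}
  beta <- 0.7
  fb <- free_energy(boltzmann_weights(beta, 3), beta)$F
  step <- 0.01
  for (p0 in seq(step, 1 - 2 * step, by = step)) {
    for (p1 in seq(step, 1 - p0 - step, by = step)) {
      f <- free_energy(c(p0, p1, 1 - p0 - p1), beta)$F
      expect_gte(f, fb - 1e-12)
    }
  }
})

test_that("sequential learning applies the belief-weighted count update", {
  # single transition: all mass on the observed pair, regardless of beta
  for (b in c(0, 0.5, Inf)) {
    st <- sequential_learn(c(1, 2), b, n_nodes = 15)
    expect_equal(st$counts[2, 3], 1)
    expect_equal(sum(st$counts), 1)
  }
  # uniform belief over a 2-node history splits the unit mass in half
  st <- sequential_learn(c(1, 2, 3), 0, n_nodes = 15)
  expect_equal(st$counts[2, 4], 0.5)
  expect_equal(st$counts[3, 4], 0.5)
  # total count mass after T trials is exactly T - 1
  w <- random_walk(build_graph("modular"), 400, seed = 2)
  for (b in c(0, 0.3, Inf)) {
    expect_equal(sum(sequential_learn(w, b)$counts), 399, tolerance = 1e-10)
  }
})

test_that("the delta-belief limit reproduces the integer transition tally", {
  g <- build_graph("lattice")
  w <- random_walk(g, 1000, seed = 9)
  st <- sequential_learn(w, Inf)
  expect_identical(unname(st$counts), mle_tally(w$nodes, 15L) + 0)
})

test_that("count normalization handles zero-mass rows and rejects negatives", {
  counts <- matrix(0, 15, 15)
  counts[1, 2:3] <- c(2, 1)
  Ahat <- estimate_from_counts(counts)
  expect_equal(Ahat[1, 2:3], c(2 / 3, 1 / 3))
  expect_equal(Ahat[2, ], rep(1 / 15, 15), ignore_attr = TRUE)
  expect_equal(estimate_from_counts(matrix(0, 4, 4)),
               matrix(1 / 4, 4, 4))
  expect_error(estimate_from_counts(matrix(-1, 2, 2)), "non-negative")
})

test_that("the closed-form estimate matches hand algebra and the series oracle", {
  # 2-node swap graph at e^-beta = 1/2, invertible by hand
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(asymptotic_estimate(A2, log(2)),
               matrix(c(1 / 3, 2 / 3, 2 / 3, 1 / 3), 2, 2, byrow = TRUE),
               tolerance = 1e-12)
  for (topo in c("modular", "lattice", "ring")) {
    A <- build_graph(topo)$A
    expect_lt(max(abs(asymptotic_estimate(A, 0.3) - series_estimate(A, 0.3))),
              1e-8)
  }
  # high precision limit: estimates converge to the true structure
  Am <- build_graph("modular")$A
  expect_lt(max(abs(asymptotic_estimate(Am, 50) - Am)), 1e-20)
  expect_error(asymptotic_estimate(Am, 0), "> 0")
  expect_error(asymptotic_estimate(matrix(1, 2, 2), 0.3), "row-stochastic")
})

test_that("the closed form is row-stochastic for random stochastic matrices", {
  set.seed(41)
  for (rep in 1:5) {
    A <- matrix(runif(36), 6, 6)
    A <- A / rowSums(A)
    for (b in c(0.05, 0.5, 3)) {
      Ahat <- asymptotic_estimate(A, b)
      expect_equal(rowSums(Ahat), rep(1, 6), tolerance = 1e-12)
      expect_true(all(Ahat >= -1e-14 & Ahat <= 1 + 1e-14))
    }
  }
})

test_that("series truncation error stays below the geometric tail bound", {
  A <- build_graph("modular")$A
  for (b in c(0.2, 0.5)) {
    for (K in c(20L, 60L)) {
      bound <- exp(-b * (K + 1)) / (1 - exp(-b))
      expect_lt(max(abs(asymptotic_estimate(A, b) - series_estimate(A, b, K))),
                bound + 1e-15)
    }
  }
})

test_that("estimate error shrinks monotonically as memory precision grows", {
  for (topo in c("modular", "lattice", "ring")) {
    g <- build_graph(topo)
    errs <- vapply(c(0.1, 0.3, 1, 3, 10),
                   function(b) max(abs(asymptotic_estimate(g, b) - g$A)),
                   numeric(1))
    expect_true(all(diff(errs) < 0))
  }
})

test_that("higher-order counts tally k-step transitions online", {
  oa <- order_anticipation(c(1, 2, 3, 1, 2), 2, n_nodes = 15)
  n2 <- oa$counts[[2]]
  expect_equal(n2[2, 4], 1L)  # 1 -> 3 in two steps
  expect_equal(n2[3, 2], 1L)  # 2 -> 1
  expect_equal(n2[4, 3], 1L)  # 3 -> 2
  expect_equal(sum(n2), 3L)   # total mass after t trials is t - k
  expect_equal(sum(oa$counts[[1]]), 4L)
  # first-order anticipations coincide with the delta-belief learner
  w <- random_walk(build_graph("modular"), 300, seed = 21)
  a1 <- order_anticipation(w, 3)$anticipation[, 1]
  expect_equal(a1, sequential_learn(w, Inf)$anticipation)
  expect_error(order_anticipation(w, 0), ">= 1")
})

test_that("network-effect ratios collapse to 1 at high precision and exceed it at moderate", {
  ec <- effect_curves(c(0.3, 50))
  expect_equal(ec$ratio_within_between[2], 1, tolerance = 1e-6)
  expect_equal(ec$ratio_modular_lattice[2], 1, tolerance = 1e-6)
  expect_gt(ec$ratio_within_between[1], 1)
  expect_gt(ec$ratio_modular_lattice[1], 1)
  expect_error(effect_curves(numeric(0)), "empty")
})

test_that("distance profile decays on the ring and conserves row mass", {
  g <- build_graph("ring")
  dp <- distance_profile(g, 0.3)
  expect_equal(dp$distance, 1:4)
  expect_true(all(diff(dp$mean_estimate) < 0))
  # high precision: edges keep 0.25, non-edges vanish
  dp50 <- distance_profile(g, 50)
  expect_equal(dp50$mean_estimate[1], 0.25, tolerance = 1e-10)
  expect_lt(max(dp50$mean_estimate[-1]), 1e-10)
  # class means recombine with the diagonal to one unit of mass per node
  Ahat <- asymptotic_estimate(g, 0.3)
  total <- sum(dp$mean_estimate * dp$n_pairs) + sum(diag(Ahat))
  expect_equal(total, 15, tolerance = 1e-10)
})

test_that("sequential estimates converge toward the closed form on long walks", {
  g <- build_graph("modular")
  w <- random_walk(g, 2e4, seed = 33)
  st <- sequential_learn(w, 0.3)
  err <- max(abs(estimate_from_counts(st) - asymptotic_estimate(g, 0.3)))
  expect_lt(err, 0.03)
})
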