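test_that("trial filtering applies each exclusion rule in order", {
  # a 90 ms reaction after the warm-up is dropped by the 100 ms floor
  d <- toy_trials(600)
  d$rt_ms[550] <- 90
  f <- filter_trials(d)
  expect_false(550 %in% f$trial)
  expect_equal(attr(f, "exclusions")[["implausible"]], 1)

  # 2100 ms within 3 SD: dropped under the 2000 ms model-fitting cap,
  # kept under the 3500 ms network-effect cap
  d2 <- toy_trials(600)
  d2$rt_ms[501:600] <- seq(500, 1900, length.out = 100)  # wide spread
  d2$rt_ms[560] <- 2100
  f2000 <- filter_trials(d2, rt_cap = 2000)
  expect_false(560 %in% f2000$trial)
  f3500 <- filter_trials(d2, rt_cap = 3500)
  expect_true(560 %in% f3500$trial)

  # constant all-correct toy: nothing beyond the warm-up is excluded
  f0 <- filter_trials(toy_trials(600))
  expect_equal(nrow(f0), 100)
  expect_equal(sum(attr(f0, "exclusions")[-1]), 0)

  # incorrect trials are dropped before the SD rule
  d3 <- toy_trials(600)
  d3$correct[501:510] <- FALSE
  f3 <- filter_trials(d3)
  expect_equal(attr(f3, "exclusions")[["incorrect"]], 10)
})

test_that("exclusion accounting is exact: rows_in = rows_out + sum(exclusions)", {
  g <- build_graph("modular")
  sim <- simulate_subject_rt(g, "random", ground_truth(outlier_rate = 0.05),
                             seed = 71)
  for (cap in c(2000, 3500)) {
    f <- filter_trials(add_covariates(sim$data, g), rt_cap = cap)
    expect_equal(attr(f, "rows_in"), nrow(f) + sum(attr(f, "exclusions")))
  }
})

test_that("hamiltonian scope keeps only hamiltonian-segment trials", {
  g <- build_graph("modular")
  sim <- simulate_subject_rt(g, "hamiltonian", ground_truth(error_rate = 0),
                             seed = 23)
  f <- filter_trials(sim$data, scope = "hamiltonian_only")
  expect_true(all(f$segment == "hamiltonian"))
  expect_equal(attr(f, "exclusions")[["warmup_or_scope"]], 1380)
})

test_that("covariates follow the declared recency and transition-type conventions", {
  d <- data.frame(subject_id = "a", trial = 1:3, node = c(3L, 7L, 3L))
  dc <- add_covariates(d)
  expect_equal(dc$recency, c(1, 2, 2))   # first occurrences get recency = t
  d2 <- data.frame(subject_id = "a", trial = 1:12,
                   node = c(0L, 1L, 2L, 3L, 4L, 0L, 1L, 2L, 3L, 4L, 0L, 9L))
  dc2 <- add_covariates(d2)
  expect_equal(dc2$recency[12], 12)      # node 9 first seen at trial 12
  expect_equal(dc2$recency[6], 5)
  expect_equal(dc2$log_trial, log(1:12))
  # community crossings on the modular graph
  g <- build_graph("modular")
  d3 <- data.frame(subject_id = "a", trial = 1:4, node = c(1L, 4L, 5L, 6L))
  dc3 <- add_covariates(d3, g)
  expect_equal(dc3$transition_type, c(NA, "within", "between", "within"))
})

test_that("nuisance residualization recovers known button offsets", {
  g <- build_graph("modular")
  offs <- seq(-70, 70, length.out = 15)
  tr <- ground_truth(beta_true = 0.3, r1 = 0, noise_sd = 20,
                     button_offsets = offs, trial_slope = 0,
                     recency_slope = 0, error_rate = 0, outlier_rate = 0)
  sim <- simulate_subject_rt(g, "random", tr, seed = 21)
  r <- nuisance_residualize(add_covariates(sim$data, g)[-1, ])
  fit <- attr(r, "nuisance_fit")
  cf <- coef(fit)[grep("target_combo", names(coef(fit)))]
  # treatment contrasts against combination C01: offsets k minus offset 1
  expected <- offs[2:15] - offs[1]
  se <- 20 / sqrt(1500 / 15)  # ~ per-combination cell noise
  expect_lt(max(abs(cf - expected)), 3 * se)
  # residuals keep the ms scale: centered at the subject mean
  expect_equal(mean(r$rt_resid), mean(r$rt_ms))
})

test_that("a pure log-trial trend residualizes to a constant", {
  d <- toy_trials(600)
  d$rt_ms <- 800 - 40 * log(d$trial)
  d <- add_covariates(d)
  r <- nuisance_residualize(d)
  expect_lt(sd(r$rt_resid), 1e-8)
})

test_that("single-stage data gets no stage terms; two-stage data does", {
  d <- add_covariates(toy_trials(300))
  d$rt_ms <- d$rt_ms + rnorm(300)
  f1 <- attr(nuisance_residualize(d), "nuisance_fit")
  expect_false(any(grepl("stage", names(coef(f1)))))
  d2 <- rbind(d, transform(d, stage = 2L))
  f2 <- attr(nuisance_residualize(d2), "nuisance_fit")
  expect_true(any(grepl("stage", names(coef(f2)))))
})

test_that("noiseless maxent fits recover beta, r0 and r1 essentially exactly", {
  g <- build_graph("modular")
  sim <- exact_subject(g, beta_star = 0.3, r0 = 800, r1 = -700)
  fit <- fit_maxent_subject(sim$data, sim$walk)
  expect_true(is.na(fit$beta_limit))
  expect_lt(abs(fit$beta - 0.3), 1e-3)
  expect_lt(abs(fit$r0 - 800), 1e-6)
  expect_lt(abs(fit$r1 + 700), 1e-6)
  expect_lt(fit$rmse, 1e-6)
  expect_true(fit$converged)
})

test_that("anticipation-independent reaction times fit at a limit with r1 = 0", {
  g <- build_graph("modular")
  sim <- exact_subject(g, n_trials = 400L)
  sim$data$rt_ms <- 650  # constant: no anticipation signal at all
  fit <- fit_maxent_subject(sim$data, sim$walk)
  expect_false(is.na(fit$beta_limit))
  expect_equal(fit$r1, 0)
  expect_equal(fit$rmse, 0)
})

test_that("the candidate grid is 100 log-spaced values spanning 1e-4 to 10", {
  grid <- beta_grid()
  expect_length(grid, 100)
  expect_equal(grid[1], 1e-4)
  expect_equal(grid[100], 10)
  expect_equal(diff(range(diff(log(grid)))), 0, tolerance = 1e-10)
  expect_error(beta_grid(1), "at least 2")
  expect_error(beta_grid(10, c(2, 1)), "increasing")
})

test_that("returned fit is RMSE-minimal over the grid and both limits", {
  g <- build_graph("modular")
  tr <- ground_truth(beta_true = 0.4, noise_sd = 120,
                     button_offsets = rep(0, 15), trial_slope = 0,
                     recency_slope = 0, error_rate = 0, outlier_rate = 0)
  sim <- simulate_subject_rt(g, "random", tr, n_trials = 600L, seed = 77)
  d <- sim$data[sim$data$trial > 100, ]
  fit <- fit_maxent_subject(d, sim$walk)
  rmse_at <- function(beta) {
    a <- sequential_learn(sim$walk, beta)$anticipation[d$trial]
    y <- d$rt_ms
    r1 <- if (var(a) > 0) cov(a, y) / var(a) else 0
    r0 <- mean(y) - r1 * mean(a)
    sqrt(mean((y - r0 - r1 * a)^2))
  }
  cand <- c(beta_grid(), 0, Inf)
  expect_true(all(fit$rmse <= vapply(cand, rmse_at, numeric(1)) + 1e-12))
})

test_that("order-model fits reduce to the mean model at l = 0 and recover structure", {
  g <- build_graph("modular")
  sim <- exact_subject(g, n_trials = 500L)
  d <- sim$data
  f0 <- fit_order_model(d, sim$walk, 0)
  expect_equal(f0$coefficients$c0, mean(d$rt_ms))
  expect_equal(f0$rmse, sqrt(mean((d$rt_ms - mean(d$rt_ms))^2)))
  # reaction times built from the first-order anticipation only
  a1 <- order_anticipation(sim$walk, 1)$anticipation[d$trial, 1]
  d$rt_ms <- 900 - 300 * a1
  f3 <- fit_order_model(d, sim$walk, 3)
  expect_equal(length(f3$coefficients), 4L)
  expect_lt(abs(f3$coefficients$c1 + 300), 1e-6)
  expect_lt(abs(f3$coefficients$c2), 1e-6)
  expect_lt(abs(f3$coefficients$c3), 1e-6)
})

test_that("BIC uses the Gaussian form and penalizes parameters", {
  g <- build_graph("modular")
  sim <- exact_subject(g, n_trials = 400L)
  sim$data$rt_ms <- sim$data$rt_ms + rnorm(nrow(sim$data), 0, 30)
  fits <- c(list(fit_maxent_subject(sim$data, sim$walk)),
            lapply(0:3, function(l) fit_order_model(sim$data, sim$walk, l)))
  tab <- bic_compare(fits)
  expect_equal(nrow(tab), 5L)
  expect_true(!is.unsorted(tab$bic))
  # arithmetic: T = 100, SSE = 1e4, k = 3 gives 100 ln(100) + 3 ln(100)
  expect_equal(graphlearn:::bic_gauss(sqrt(1e4 / 100), 100, 3),
               100 * log(100) + 3 * log(100))
  # equal RMSE: the model with fewer parameters ranks first
  mk <- function(model, k) graphlearn:::new_fit_result(
    model, NA_real_, NA_character_, 0, 0,
    if (model == "maxent") NULL else as.list(setNames(rep(0, k), paste0("c", 0:(k - 1)))),
    rmse = 12, bic = graphlearn:::bic_gauss(12, 200, k), n_trials = 200,
    converged = TRUE)
  expect_equal(bic_compare(list(mk("order-3", 4), mk("maxent", 3)))$model[1],
               "maxent")
  # mismatched trial sets are rejected
  short <- fit_order_model(sim$data[1:50, ], sim$walk, 0)
  expect_error(bic_compare(list(fits[[1]], short)), "different trial sets")
})

test_that("model comparison recovers the generating model when identifiable", {
  g <- build_graph("modular")
  tr <- ground_truth(noise_sd = 50)
  cohort <- simulate_cohort(5, g, "random", tr, seed = 303)
  bics <- sapply(cohort, function(s) {
    r <- nuisance_residualize(filter_trials(add_covariates(s$data, g)))
    c(fit_maxent_subject(r, s$walk)$bic,
      vapply(1:3, function(l) fit_order_model(r, s$walk, l)$bic, numeric(1)))
  })
  med <- apply(bics, 1, median)
  expect_true(all(med[1] < med[2:4]))
})

test_that("group effects detect the cross-cluster contrast and stay null under no signal", {
  g <- build_graph("modular")
  tr <- ground_truth(noise_sd = 120)
  cohort <- simulate_cohort(12, g, "random", tr, seed = 404)
  proc <- lapply(cohort, function(s) {
    nuisance_residualize(filter_trials(add_covariates(s$data, g)))
  })
  ge <- group_effects(proc, "between_minus_within")
  expect_gt(ge$mean_diff_ms, 0)
  expect_lt(ge$p_value, 0.05)
  # null cohort: anticipation-independent reaction times
  null_tr <- ground_truth(r1 = 0, noise_sd = 120)
  null_cohort <- simulate_cohort(12, g, "random", null_tr, seed = 505)
  null_proc <- lapply(null_cohort, function(s) {
    nuisance_residualize(filter_trials(add_covariates(s$data, g)))
  })
  gen <- group_effects(null_proc, "between_minus_within")
  expect_true(gen$ci_lo < 0 & gen$ci_hi > 0)
})

test_that("modular-lattice contrast requires subjects exposed to both graphs", {
  gm <- build_graph("modular")
  gl <- build_graph("lattice")
  tr <- ground_truth(noise_sd = 100)
  cohort <- simulate_cohort(8, gm, "random", tr, second_graph = gl, seed = 606)
  proc <- lapply(cohort, function(s) {
    nuisance_residualize(filter_trials(add_covariates(s$data, gm)))
  })
  ge <- group_effects(proc, "lattice_minus_modular")
  expect_equal(ge$n_subjects, 8)
  expect_gt(ge$mean_diff_ms, 0)
})
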