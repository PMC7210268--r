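# Synthetic serial-response cohorts and n-back sessions with known ground
# truth, so every pipeline stage is testable offline.

#' Ground-truth parameters for a simulated subject
#'
#' Bundles the generative parameters of [simulate_subject_rt()]: the
#' learner's inverse temperature, the linear reaction-time mapping, and the
#' nuisance structure the analysis later regresses out. The defaults
#' (r0 = 900 ms, r1 = -700 ms, noise 150 ms) are arbitrary configuration
#' values of the same order as typical human fits, not measurements.
#'
#' @param beta_true inverse temperature of the simulated learner (> 0, or
#'   `Inf` for an error-free counter).
#' @param r0 intercept: reaction time at zero anticipation (ms).
#' @param r1 slope on anticipation (ms; negative = anticipated transitions
#'   are faster).
#' @param noise_sd Gaussian trial noise SD (ms).
#' @param button_offsets 15 mean-centered per-combination offsets (ms).
#' @param trial_slope practice effect, ms per unit `log(trial)`.
#' @param recency_slope recency effect, ms per trial since last occurrence.
#' @param error_rate probability a trial is marked incorrect.
#' @param outlier_rate probability a reaction time is replaced by an
#'   implausible draw from 2500-6000 ms.
#' @return a `ground_truth` list.
#' @export
ground_truth <- function(beta_true = 0.3, r0 = 900, r1 = -700, noise_sd = 150,
                         button_offsets = NULL, trial_slope = -25,
                         recency_slope = 0.5, error_rate = 0.06,
                         outlier_rate = 0.01) {
  if (length(beta_true) != 1L || is.na(beta_true) || beta_true < 0) {
    stop("`beta_true` must be >= 0 (Inf allowed)")
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (error_rate < 0 || error_rate >= 1) stop("`error_rate` must be in [0, 1)")
  if (outlier_rate < 0 || outlier_rate >= 1) stop("`outlier_rate` must be in [0, 1)")
  if (is.null(button_offsets)) button_offsets <- seq(-35, 35, length.out = 15)
  if (length(button_offsets) != 15L) stop("`button_offsets` must have 15 values")
  button_offsets <- button_offsets - mean(button_offsets)
  structure(list(beta_true = beta_true, r0 = r0, r1 = r1, noise_sd = noise_sd,
                 button_offsets = button_offsets, trial_slope = trial_slope,
                 recency_slope = recency_slope, error_rate = error_rate,
                 outlier_rate = outlier_rate),
            class = "ground_truth")
}

#' Simulate one subject's serial-response session
#'
#' Draws a walk with the requested protocol, runs the memory-error learner
#' at the true inverse temperature to obtain anticipations `a(t)`, and
#' generates reaction times as
#' `r0 + r1 * a(t) + button_offset + trial_slope * log(t) +
#' recency_slope * recency + Normal(0, noise_sd)` (trial 1 has zero
#' anticipation). Each node is mapped to one of the 15 button combinations
#' by a per-subject random assignment. Trials are marked incorrect with
#' probability `error_rate`, and with probability `outlier_rate` the
#' reaction time is replaced by an implausible draw from 2500-6000 ms.
#' Gaussian noise is clamped so reaction times stay positive; the
#' deterministic part must itself be positive or an error is raised.
#'
#' @param graph a [build_graph()] object.
#' @param walk_protocol `"random"` (length `n_trials`), `"hamiltonian"` or
#'   `"violation"` (both fixed 1500-trial protocols).
#' @param truth a [ground_truth()] object.
#' @param subject_id,stage identifiers stored in the table.
#' @param n_trials length of a `"random"` walk (default 1500).
#' @param generate_from `"maxent"` (the memory-error learner) or
#'   `"order1"` (a misspecification toggle: reaction times driven by the
#'   first-order competing anticipation instead).
#' @param seed optional RNG seed; the same seed reproduces the table
#'   exactly.
#' @return list with `data` (the trial table: `subject_id`, `trial`,
#'   `stage`, `node`, `target_combo`, `rt_ms`, `correct`, `segment`,
#'   `violation_distance`, `graph`), `walk`, and `truth`.
#' @export
simulate_subject_rt <- function(graph, walk_protocol = c("random", "hamiltonian", "violation"),
                                truth = ground_truth(), subject_id = "s01",
                                stage = 1L, n_trials = 1500L,
                                generate_from = c("maxent", "order1"),
                                seed = NULL) {
  walk_protocol <- match.arg(walk_protocol)
  generate_from <- match.arg(generate_from)
  stopifnot(inherits(graph, "transition_graph"), inherits(truth, "ground_truth"))
  with_seed(seed, {
    walk <- switch(walk_protocol,
      random      = random_walk(graph, n_trials),
      hamiltonian = hamiltonian_session(graph),
      violation   = violation_walk(graph))
    T_len <- length(walk$nodes)
    a <- if (generate_from == "maxent") {
      sequential_learn(walk, truth$beta_true)$anticipation
    } else {
      order_anticipation(walk, 1L)$anticipation[, 1]
    }
    a[1] <- 0
    combo_of_node <- sample.int(15L)  # node i -> combination combo_of_node[i+1]
    combo <- combo_of_node[walk$nodes + 1L]
    trial <- seq_len(T_len)
    last_seen <- rep(NA_integer_, graph$n_nodes)
    recency <- integer(T_len)
    for (t in trial) {
      nd <- walk$nodes[t] + 1L
      recency[t] <- if (is.na(last_seen[nd])) t else t - last_seen[nd]
      last_seen[nd] <- t
    }
    rt_det <- truth$r0 + truth$r1 * a + truth$button_offsets[combo] +
      truth$trial_slope * log(trial) + truth$recency_slope * recency
    if (any(rt_det <= 0)) {
      stop("deterministic reaction time is non-positive at trial ",
           which(rt_det <= 0)[1], "; increase r0 or shrink the effects")
    }
    rt <- pmax(rt_det + rnorm(T_len, 0, truth$noise_sd), 1)
    outlier <- runif(T_len) < truth$outlier_rate
    rt[outlier] <- runif(sum(outlier), 2500, 6000)
    correct <- runif(T_len) >= truth$error_rate
    data <- data.frame(
      subject_id = subject_id, trial = trial, stage = as.integer(stage),
      node = walk$nodes, target_combo = sprintf("C%02d", combo),
      rt_ms = rt, correct = correct, segment = walk$segment,
      violation_distance = walk$violation_distance, graph = graph$name)
    list(data = data, walk = walk, truth = truth)
  })
}

#' Simulate a cohort of serial-response subjects
#'
#' Convenience wrapper generating `n_subjects` independent subjects with
#' per-subject seeds derived from `seed`. With `second_graph`, each subject
#' responds to both graphs in two stages, with the order counterbalanced by
#' subject parity (as when measuring the modular-lattice contrast).
#'
#' @inheritParams simulate_subject_rt
#' @param n_subjects number of subjects.
#' @param second_graph optional second [build_graph()] object.
#' @param seed base seed; subject `i` uses `seed + i`.
#' @return list (one element per subject) of `simulate_subject_rt()`
#'   results; with two graphs, `data` holds both stages and `walk` is a
#'   list of the two stage walks.
#' @export
simulate_cohort <- function(n_subjects, graph, walk_protocol = "random",
                            truth = ground_truth(), n_trials = 1500L,
                            second_graph = NULL, generate_from = "maxent",
                            seed = NULL) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1")
  lapply(seq_len(n_subjects), function(i) {
    sid <- sprintf("s%03d", i)
    s_seed <- if (is.null(seed)) NULL else seed + i
    if (is.null(second_graph)) {
      simulate_subject_rt(graph, walk_protocol, truth, subject_id = sid,
                          stage = 1L, n_trials = n_trials,
                          generate_from = generate_from, seed = s_seed)
    } else {
      graphs <- if (i %% 2L == 0L) list(second_graph, graph) else list(graph, second_graph)
      parts <- lapply(1:2, function(st) {
        simulate_subject_rt(graphs[[st]], walk_protocol, truth,
                            subject_id = sid, stage = st, n_trials = n_trials,
                            generate_from = generate_from,
                            seed = if (is.null(s_seed)) NULL else s_seed * 2L + st)
      })
      list(data = rbind(parts[[1]]$data, parts[[2]]$data),
           walk = list(parts[[1]]$walk, parts[[2]]$walk),
           truth = truth)
    }
  })
}

#' Simulate an n-back session from a Boltzmann lag-error memory
#'
#' Letters are i.i.d. uniform over B, D, G, T, V with random case. On each
#' scored trial `t > n` the simulated subject tries to recall the target at
#' `t - n` but actually retrieves the letter at `t - n - lag`, with the lag
#' drawn from the Boltzmann distribution at `beta_true` truncated to the
#' available history; the response is `"match"` iff the retrieved letter
#' equals the current letter (case-insensitive), flipped with probability
#' `lapse`.
#'
#' @param beta_true inverse temperature of the lag-error distribution
#'   (> 0, `Inf` = perfect recall).
#' @param n n-back condition, 1, 2 or 3.
#' @param n_trials_session letters per session (default 100).
#' @param lapse probability of flipping the response.
#' @param subject_id identifier stored on the session.
#' @param seed optional RNG seed.
#' @return an `nback_session`: data.frame with `trial`, `letter`, `case`,
#'   `response` (`"none"` for unscored trials), carrying attributes
#'   `condition_n`, `subject_id`, `beta_true`.
#' @export
simulate_nback_session <- function(beta_true, n, n_trials_session = 100L,
                                   lapse = 0, subject_id = "s01", seed = NULL) {
  if (!(n %in% 1:3)) stop("`n` must be 1, 2 or 3")
  if (length(beta_true) != 1L || is.na(beta_true) || beta_true <= 0) {
    stop("`beta_true` must be > 0 (Inf allowed)")
  }
  if (lapse < 0 || lapse > 1) stop("`lapse` must be in [0, 1]")
  with_seed(seed, {
    T_len <- as.integer(n_trials_session)
    letter <- sample(nback_letters, T_len, replace = TRUE)
    lcase <- sample(c("upper", "lower"), T_len, replace = TRUE)
    response <- rep("none", T_len)
    for (t in (n + 1L):T_len) {
      max_lag <- t - n - 1L
      lag <- if (is.infinite(beta_true) || max_lag == 0L) 0L else {
        w <- boltzmann_weights(beta_true, max_lag + 1L)$weights
        sample.int(max_lag + 1L, 1L, prob = w) - 1L
      }
      is_match <- letter[t - n - lag] == letter[t]
      if (lapse > 0 && runif(1) < lapse) is_match <- !is_match
      response[t] <- if (is_match) "match" else "nonmatch"
    }
    shown <- ifelse(lcase == "lower", tolower(letter), letter)
    structure(
      data.frame(trial = seq_len(T_len), letter = shown, case = lcase,
                 response = response),
      condition_n = as.integer(n), subject_id = subject_id,
      beta_true = beta_true, class = c("nback_session", "data.frame"))
  })
}
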