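# Trial filtering, nuisance residualization, per-subject model fitting and
# group-level contrasts for serial-response reaction-time data.

require_columns <- function(data, cols, where) {
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop(where, ": missing column(s) ", paste(miss, collapse = ", "))
  }
}

#' Filter implausible and warm-up trials
#'
#' Applies the exclusion rules used before any reaction-time analysis, in
#' this order: (1) drop trials 1-500 (or, with
#' `scope = "hamiltonian_only"`, keep only Hamiltonian-segment trials);
#' (2) drop incorrect trials; (3) compute the subject's mean and SD of the
#' surviving reaction times and drop rows more than 3 SD from the mean or
#' below 100 ms; (4) drop rows above `rt_cap`. The cap is 2000 ms for model
#' fitting and 3500 ms for network-effect measurement.
#'
#' @param data one subject's trial table (columns `trial`, `rt_ms`,
#'   `correct`; `segment` required for the Hamiltonian scope). Multi-stage
#'   tables are filtered per stage.
#' @param rt_cap implausibility cap in ms.
#' @param scope `"random"` (drop warm-up trials 1-500) or
#'   `"hamiltonian_only"` (keep Hamiltonian-segment trials).
#' @return the filtered table, with attribute `exclusions`, a named count
#'   per rule satisfying `rows_in = rows_out + sum(exclusions)`.
#' @export
filter_trials <- function(data, rt_cap = 2000, scope = c("random", "hamiltonian_only")) {
  scope <- match.arg(scope)
  require_columns(data, c("trial", "rt_ms", "correct"), "filter_trials")
  if (!is.numeric(rt_cap) || rt_cap <= 0) stop("`rt_cap` must be positive")
  n_in <- nrow(data)
  if (scope == "hamiltonian_only") {
    require_columns(data, "segment", "filter_trials")
    d1 <- data[data$segment == "hamiltonian", , drop = FALSE]
  } else {
    d1 <- data[data$trial > 500L, , drop = FALSE]
  }
  excl <- c(warmup_or_scope = n_in - nrow(d1))
  d2 <- d1[as.logical(d1$correct), , drop = FALSE]
  excl["incorrect"] <- nrow(d1) - nrow(d2)
  if (nrow(d2) == 0L) {
    stop("all trials excluded for subject ",
         if ("subject_id" %in% names(data)) data$subject_id[1] else "<unknown>")
  }
  m <- mean(d2$rt_ms)
  s <- sd(d2$rt_ms)
  keep <- d2$rt_ms >= 100 & (is.na(s) | abs(d2$rt_ms - m) <= 3 * s)
  d3 <- d2[keep, , drop = FALSE]
  excl["implausible"] <- nrow(d2) - nrow(d3)
  d4 <- d3[d3$rt_ms <= rt_cap, , drop = FALSE]
  excl["over_cap"] <- nrow(d3) - nrow(d4)
  if (nrow(d4) == 0L) {
    stop("all trials excluded for subject ",
         if ("subject_id" %in% names(data)) data$subject_id[1] else "<unknown>")
  }
  attr(d4, "exclusions") <- excl
  attr(d4, "rows_in") <- n_in
  d4
}

add_covariates_one <- function(data, graph) {
  n <- if (is.null(graph)) 15L else graph$n_nodes
  ord <- order(data$trial)
  data <- data[ord, , drop = FALSE]
  last_seen <- rep(NA_integer_, n)
  rec <- integer(nrow(data))
  trans <- rep(NA_character_, nrow(data))
  comm <- if (!is.null(graph)) graph$communities else NULL
  prev_node <- NA_integer_
  for (k in seq_len(nrow(data))) {
    nd <- data$node[k]
    tr <- data$trial[k]
    rec[k] <- if (is.na(last_seen[nd + 1L])) tr else tr - last_seen[nd + 1L]
    last_seen[nd + 1L] <- tr
    if (!is.null(comm) && !is.na(prev_node)) {
      trans[k] <- if (comm[prev_node + 1L] == comm[nd + 1L]) "within" else "between"
    }
    prev_node <- nd
  }
  data$recency <- rec
  data$log_trial <- log(data$trial)
  if (!is.null(comm)) data$transition_type <- trans
  data
}

#' Add derived per-trial covariates
#'
#' Computes, within each subject (and stage), the nuisance covariates used
#' in residualization: `recency` (trials since the last occurrence of the
#' current node; a first occurrence at trial t gets recency t),
#' `log_trial`, and, when the graph carries community labels,
#' `transition_type` (`"within"`/`"between"`, `NA` on each stage's first
#' trial). Covariates must be computed on the full uncut table, before
#' [filter_trials()], so that recency reflects what the subject saw.
#'
#' @param data trial table with columns `subject_id`, `trial`, `node`
#'   (optionally `stage`).
#' @param graph the [build_graph()] object the walks were drawn on, or
#'   `NULL` (no transition types).
#' @return the table with added columns.
#' @export
add_covariates <- function(data, graph = NULL) {
  require_columns(data, c("subject_id", "trial", "node"), "add_covariates")
  grp <- paste(data$subject_id, if ("stage" %in% names(data)) data$stage else 1L)
  parts <- split(data, factor(grp, levels = unique(grp)))
  out <- do.call(rbind, lapply(parts, add_covariates_one, graph = graph))
  rownames(out) <- NULL
  out
}

#' Regress nuisance structure out of reaction times
#'
#' Per-subject ordinary least squares of `rt_ms` on `log_trial`, `stage`
#' and their interaction (when the subject has two stages), the 15-level
#' button-combination factor, and `recency`. The residuals, re-centered at
#' the subject's mean reaction time to stay on the ms scale, are stored in
#' `rt_resid`. Aliased terms (e.g. a combination never shown) are dropped
#' with a warning.
#'
#' @param data one subject's filtered trial table with covariates (see
#'   [add_covariates()]); columns `rt_ms`, `log_trial`, `recency`,
#'   `target_combo` (and optionally `stage`).
#' @return the table with an `rt_resid` column; the fitted `lm` is attached
#'   as attribute `nuisance_fit`.
#' @export
nuisance_residualize <- function(data) {
  require_columns(data, c("rt_ms", "log_trial", "recency", "target_combo"),
                  "nuisance_residualize")
  if ("subject_id" %in% names(data) && length(unique(data$subject_id)) > 1L) {
    parts <- split_subjects(data)
    out <- do.call(rbind, lapply(parts, nuisance_residualize))
    rownames(out) <- NULL
    return(out)
  }
  d <- data
  d$target_combo <- factor(d$target_combo)
  two_stage <- "stage" %in% names(d) && length(unique(d$stage)) > 1L
  # With one graph per stage, stage and graph are confounded within the
  # subject: removing per-stage means would null the graph contrast. Drop
  # the stage terms in that case; counterbalanced stage order cancels the
  # remaining stage effects across subjects.
  confounded <- two_stage && "graph" %in% names(d) &&
    all(vapply(split(d$graph, d$stage), function(x) length(unique(x)) == 1L,
               logical(1))) &&
    length(unique(tapply(d$graph, d$stage, `[`, 1L))) > 1L
  form <- if (two_stage && !confounded) {
    rt_ms ~ log_trial * factor(stage) + target_combo + recency
  } else {
    rt_ms ~ log_trial + target_combo + recency
  }
  fit <- lm(form, data = d)
  if (anyNA(coef(fit))) {
    warning("rank-deficient nuisance design; dropped: ",
            paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  data$rt_resid <- as.numeric(residuals(fit)) + mean(d$rt_ms)
  attr(data, "nuisance_fit") <- fit
  data
}

# closed-form simple regression of y on a; returns r0, r1, rmse
linear_rt_fit <- function(a, y) {
  va <- stats::var(a)
  if (!is.finite(va) || va == 0) {
    r1 <- 0
    r0 <- mean(y)
  } else {
    r1 <- stats::cov(a, y) / va
    r0 <- mean(y) - r1 * mean(a)
  }
  resid <- y - (r0 + r1 * a)
  list(r0 = r0, r1 = r1, rmse = sqrt(mean(resid^2)))
}

bic_gauss <- function(rmse, n, k) n * log(rmse^2) + k * log(n)

new_fit_result <- function(model, beta, beta_limit, r0, r1, coefficients,
                           rmse, bic, n_trials, converged) {
  structure(list(model = model, beta = beta, beta_limit = beta_limit,
                 r0 = r0, r1 = r1, coefficients = coefficients,
                 rmse = rmse, bic = bic, n_trials = n_trials,
                 converged = converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$model, ": ", sep = "")
  if (x$model == "maxent") {
    b <- if (!is.na(x$beta_limit)) paste0("beta -> ", x$beta_limit)
         else paste0("beta = ", signif(x$beta, 4))
    cat(b, ", r0 = ", round(x$r0, 1), " ms, r1 = ", round(x$r1, 1), " ms",
        sep = "")
  } else {
    cat(paste(names(x$coefficients),
              round(unlist(x$coefficients), 1), sep = " = ", collapse = ", "),
        "ms")
  }
  cat(", RMSE = ", round(x$rmse, 2), " ms, BIC = ", round(x$bic, 1),
      " (", x$n_trials, " trials)\n", sep = "")
  invisible(x)
}

# numerical central-difference gradient of f at b
rmse_gradient <- function(f, b, fb = NULL) {
  h <- 1e-6 * max(b, 1)
  (f(b + h) - f(b - h)) / (2 * h)
}

# gradient descent with backtracking from b0 until |dRMSE/dbeta| < tol
descend_beta <- function(f, b0, tol = 1e-6, max_iter = 200L) {
  b <- b0
  fb <- f(b)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- rmse_gradient(f, b)
    if (abs(g) < tol) { converged <- TRUE; break }
    step <- 0.25 * max(b, 1)
    moved <- FALSE
    while (step > 1e-14) {
      bn <- b - sign(g) * step
      if (bn > 0) {
        fn <- f(bn)
        if (fn < fb) { b <- bn; fb <- fn; moved <- TRUE; break }
      }
      step <- step / 2
    }
    # no improving step down to 1e-14: a numerical minimum (the gradient
    # criterion is unreachable when RMSE sits at floating-point noise)
    if (!moved) { converged <- TRUE; break }
  }
  list(beta = b, rmse = fb, converged = converged)
}

#' Fit the maximum-entropy reaction-time model to one subject
#'
#' Fits \eqn{\hat r(t) = r_0 + r_1 a(t)} where `a(t)` is the learner's
#' anticipation of the observed transition at inverse temperature `beta`.
#' Anticipations are computed by running [sequential_learn()] over the full
#' uncut walk (the subject saw every trial); the loss is the RMS error on
#' the retained trials only. For each candidate `beta` the linear
#' parameters have a closed form, so fitting reduces to a 1-D search:
#' RMSE is scanned along a log-spaced grid (default 100 points in
#' \eqn{[10^{-4}, 10]}), the grid argmin (ties toward smaller `beta`) is
#' refined by gradient descent with backtracking until the absolute
#' finite-difference gradient falls below `1e-6`, and the returned fit is
#' the RMSE-minimal among the refined value and the two limits
#' \eqn{\beta \to 0} and \eqn{\beta \to \infty} (exact ties prefer a limit,
#' the uniform limit first).
#'
#' @param data one subject's filtered (and normally residualized) trial
#'   table; `rt_resid` is used when present, `rt_ms` otherwise. `trial`
#'   indexes into the walk.
#' @param walk the full `walk_sequence` the subject responded to.
#' @param grid_n,grid_range candidate grid specification (see [beta_grid()]).
#' @return a `fit_result` with `model = "maxent"`, the fitted `beta` (or a
#'   `beta_limit` flag `"zero"`/`"inf"`), `r0`, `r1`, `rmse`, `bic`
#'   (Gaussian form, 3 parameters), `n_trials`, and `converged`.
#' @export
fit_maxent_subject <- function(data, walk, grid_n = 100L, grid_range = c(1e-4, 10)) {
  require_columns(data, "trial", "fit_maxent_subject")
  y <- data$rt_resid %||% data$rt_ms
  if (is.null(y)) stop("data must contain `rt_resid` or `rt_ms`")
  idx <- data$trial
  if (length(y) < 10L) stop("fewer than 10 usable trials")
  nodes <- walk_nodes(walk)
  if (any(idx < 1L | idx > length(nodes))) stop("`trial` indexes outside the walk")
  fit_at <- function(beta) {
    a <- sequential_learn(walk, beta)$anticipation[idx]
    linear_rt_fit(a, y)
  }
  rmse_at <- function(beta) fit_at(beta)$rmse
  grid <- beta_grid(grid_n, grid_range)
  grid_rmse <- vapply(grid, rmse_at, numeric(1))
  best <- which(grid_rmse <= min(grid_rmse))[1]  # ties toward smaller beta
  ref <- descend_beta(rmse_at, grid[best])
  lim0 <- rmse_at(0)
  limI <- rmse_at(Inf)
  # exact ties prefer a limit (uniform first: the more parsimonious memory)
  cand_rmse <- c(zero = lim0, inf = limI, finite = ref$rmse)
  pick <- names(cand_rmse)[which(cand_rmse <= min(cand_rmse))[1]]
  beta_fit <- switch(pick, zero = 0, inf = Inf, finite = ref$beta)
  lin <- fit_at(beta_fit)
  n_used <- length(y)
  new_fit_result(
    model = "maxent",
    beta = if (pick == "finite") ref$beta else unname(beta_fit),
    beta_limit = switch(pick, zero = "zero", inf = "inf", finite = NA_character_),
    r0 = lin$r0, r1 = lin$r1, coefficients = NULL,
    rmse = lin$rmse, bic = bic_gauss(lin$rmse, n_used, 3L),
    n_trials = n_used,
    converged = if (pick == "finite") ref$converged else TRUE)
}

#' Fit an l-th-order competing reaction-time model
#'
#' The order-`l` competitor predicts
#' \eqn{\hat r^{(\ell)}(t) = c_0 + \sum_{k=1}^{\ell} c_k a^{(k)}(t)} from
#' the explicit k-step anticipations of [order_anticipation()]; `l = 0` is
#' the intercept-only (mean reaction time) model. Coefficients are ordinary
#' least squares; a collinear design falls back to ridge with a tiny
#' penalty (`1e-8`) and a warning.
#'
#' @inheritParams fit_maxent_subject
#' @param order model order, 0 to 3.
#' @return a `fit_result` with `model = "order-l"`, coefficients `c0..cl`,
#'   `rmse` and `bic` (Gaussian form, `l + 1` parameters).
#' @export
fit_order_model <- function(data, walk, order) {
  require_columns(data, "trial", "fit_order_model")
  if (length(order) != 1L || !(order %in% 0:3)) stop("`order` must be in 0..3")
  y <- data$rt_resid %||% data$rt_ms
  if (is.null(y)) stop("data must contain `rt_resid` or `rt_ms`")
  idx <- data$trial
  n_used <- length(y)
  if (n_used <= order + 1L) stop("too few trials for the requested order")
  if (order == 0L) {
    cf <- c(c0 = mean(y))
    rmse <- sqrt(mean((y - cf[1])^2))
  } else {
    A <- order_anticipation(walk, order)$anticipation[idx, , drop = FALSE]
    X <- cbind(1, A)
    colnames(X) <- paste0("c", 0:order)
    cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    qrX <- qr(X)
    if (is.null(cf) || qrX$rank < ncol(X)) {
      warning("collinear anticipation regressors; using ridge penalty 1e-8")
      XtX <- crossprod(X) + diag(1e-8, ncol(X))
      cf <- drop(solve(XtX, crossprod(X, y)))
    }
    cf <- setNames(as.numeric(cf), paste0("c", 0:order))
    rmse <- sqrt(mean((y - drop(X %*% cf))^2))
  }
  new_fit_result(
    model = paste0("order-", order), beta = NA_real_, beta_limit = NA_character_,
    r0 = unname(cf[1]), r1 = if (order >= 1L) unname(cf[2]) else NA_real_,
    coefficients = as.list(cf),
    rmse = rmse, bic = bic_gauss(rmse, n_used, order + 1L),
    n_trials = n_used, converged = TRUE)
}

#' Rank fitted models by Bayesian information criterion
#'
#' Uses the Gaussian-residual form
#' \eqn{\mathrm{BIC} = T \ln(\mathrm{SSE}/T) + k \ln T} with `k = 3` for the
#' maximum-entropy model and `k = l + 1` for the order-`l` competitors. All
#' fits must be on the same trial set.
#'
#' @param fits list of `fit_result` objects.
#' @return data.frame (one row per model) sorted by ascending BIC.
#' @export
bic_compare <- function(fits) {
  if (!length(fits) || !all(vapply(fits, inherits, logical(1), "fit_result"))) {
    stop("`fits` must be a non-empty list of fit_result objects")
  }
  n <- vapply(fits, function(f) f$n_trials, numeric(1))
  if (length(unique(n)) != 1L) stop("fits were computed on different trial sets")
  out <- data.frame(
    model = vapply(fits, function(f) f$model, character(1)),
    k = vapply(fits, function(f)
      if (f$model == "maxent") 3L else length(f$coefficients), integer(1)),
    rmse_ms = vapply(fits, function(f) f$rmse, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)))
  out[order(out$bic), , drop = FALSE]
}

contrast_diff <- function(d, rtcol, sel_hi, sel_lo) {
  hi <- d[[rtcol]][sel_hi]
  lo <- d[[rtcol]][sel_lo]
  if (!length(hi) || !length(lo)) return(NA_real_)
  mean(hi) - mean(lo)
}

#' Group-level network-effect contrasts
#'
#' For each contrast, computes one mean reaction-time difference per
#' subject (using `rt_resid` when present) and tests the across-subject
#' differences against zero with a two-sided one-sample t-test. Available
#' contrasts, auto-detected from the columns present: `between_minus_within`
#' (cross-cluster surprisal, modular graph), `lattice_minus_modular`
#' (modular-lattice effect, subjects exposed to both graphs), and the
#' violation pairs `short_minus_standard`, `long_minus_standard`,
#' `long_minus_short` (standard transitions have topological distance 1,
#' short violations 2, long violations 3-4). Subjects lacking either level
#' of a contrast are excluded from it with a warning.
#'
#' @param cohort list of per-subject trial tables, or one table with a
#'   `subject_id` column.
#' @param contrasts character vector of contrast names, or `NULL` to
#'   auto-detect.
#' @return data.frame with one row per contrast: `mean_diff_ms`, 95% CI,
#'   `t`, `df`, `p_value`, `n_subjects`.
#' @export
group_effects <- function(cohort, contrasts = NULL) {
  if (is.data.frame(cohort)) cohort <- split_subjects(cohort)
  if (length(cohort) < 2L) stop("need at least 2 subjects")
  has_col <- function(col) any(vapply(cohort, function(d) col %in% names(d), logical(1)))
  if (is.null(contrasts)) {
    contrasts <- character(0)
    if (has_col("transition_type")) contrasts <- c(contrasts, "between_minus_within")
    if (has_col("graph")) {
      both <- vapply(cohort, function(d)
        all(c("modular", "lattice") %in% unique(d$graph)), logical(1))
      if (any(both)) contrasts <- c(contrasts, "lattice_minus_modular")
    }
    if (has_col("violation_distance")) {
      v <- unlist(lapply(cohort, function(d) d$violation_distance))
      if (any(v >= 2L, na.rm = TRUE)) {
        contrasts <- c(contrasts, "short_minus_standard",
                       "long_minus_standard", "long_minus_short")
      }
    }
    if (!length(contrasts)) stop("no contrast is identifiable from the data")
  }
  one <- function(name) {
    diffs <- vapply(cohort, function(d) {
      rtcol <- if ("rt_resid" %in% names(d)) "rt_resid" else "rt_ms"
      switch(name,
        between_minus_within = if (!"transition_type" %in% names(d)) NA_real_ else
          contrast_diff(d, rtcol, which(d$transition_type == "between"),
                        which(d$transition_type == "within")),
        lattice_minus_modular = if (!"graph" %in% names(d)) NA_real_ else
          contrast_diff(d, rtcol, which(d$graph == "lattice"),
                        which(d$graph == "modular")),
        short_minus_standard = contrast_diff(d, rtcol,
          which(d$violation_distance == 2L), which(d$violation_distance == 1L)),
        long_minus_standard = contrast_diff(d, rtcol,
          which(d$violation_distance >= 3L), which(d$violation_distance == 1L)),
        long_minus_short = contrast_diff(d, rtcol,
          which(d$violation_distance >= 3L), which(d$violation_distance == 2L)),
        stop("unknown contrast: ", name))
    }, numeric(1))
    if (anyNA(diffs)) {
      warning(sum(is.na(diffs)), " subject(s) lack both levels of ", name,
              "; excluded")
      diffs <- diffs[!is.na(diffs)]
    }
    if (length(diffs) < 2L) stop("fewer than 2 subjects with contrast ", name)
    tt <- t.test(diffs)
    data.frame(contrast = name, mean_diff_ms = unname(tt$estimate),
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, n_subjects = length(diffs))
  }
  out <- do.call(rbind, lapply(contrasts, one))
  rownames(out) <- NULL
  out
}
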