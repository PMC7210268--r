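# n-back measurement of the memory distribution: lag samples from positive
# responses, log-linear beta fits with add-one smoothing, bootstrap, and the
# comparison against serial-response beta estimates.

nback_letters <- c("B", "D", "G", "T", "V")

new_memory_samples <- function(samples, n_positive, n_negative_lag,
                               n_never_seen, n_early, condition) {
  structure(list(samples = as.integer(samples), n_positive = n_positive,
                 n_negative_lag = n_negative_lag, n_never_seen = n_never_seen,
                 n_early = n_early, condition = condition),
            class = "memory_samples")
}

#' @export
print.memory_samples <- function(x, ...) {
  cat("<memory_samples> ", length(x$samples), " lag samples from ",
      x$n_positive, " positive responses (conditions: ",
      paste(x$condition, collapse = ", "), "); discarded ",
      x$n_negative_lag, " negative-lag, ", x$n_never_seen, " never-seen, ",
      x$n_early, " early\n", sep = "")
  invisible(x)
}

#' Extract memory-lag samples from n-back sessions
#'
#' Each positive (match) response is treated as a sample of the memory
#' distribution: for a positive response at trial `t` in the n-back
#' condition, the lag is \eqn{\Delta t = (t - n) - t_{last}}, where
#' \eqn{t_{last}} is the most recent occurrence of the current letter
#' strictly before `t` (case-insensitive). Samples with negative lag (the
#' letter last occurred after the target) are discarded, as are positives
#' whose letter never occurred before and responses on trials `t <= n`;
#' all discards are tallied so that
#' `positives = samples + negative_lag + never_seen + early`.
#'
#' @param session an `nback_session` (see [simulate_nback_session()]), a
#'   data.frame with columns `trial`, `letter`, `response` and attribute or
#'   column `condition_n`, or a list of such sessions (samples are pooled).
#' @return a `memory_samples` object.
#' @export
measure_delta_t <- function(session) {
  if (is.list(session) && !is.data.frame(session)) {
    parts <- lapply(session, measure_delta_t)
    return(new_memory_samples(
      unlist(lapply(parts, `[[`, "samples")),
      sum(vapply(parts, `[[`, numeric(1), "n_positive")),
      sum(vapply(parts, `[[`, numeric(1), "n_negative_lag")),
      sum(vapply(parts, `[[`, numeric(1), "n_never_seen")),
      sum(vapply(parts, `[[`, numeric(1), "n_early")),
      sort(unique(unlist(lapply(parts, `[[`, "condition"))))))
  }
  require_columns(session, c("trial", "letter", "response"), "measure_delta_t")
  n <- attr(session, "condition_n") %||% session$condition_n[1]
  if (is.null(n) || is.na(n)) stop("session must carry its n-back condition")
  letters_uc <- toupper(session$letter)
  pos <- which(session$response == "match")
  samples <- integer(0)
  neg <- seen0 <- early <- 0L
  for (t in pos) {
    if (t <= n) { early <- early + 1L; next }
    prior <- which(letters_uc[seq_len(t - 1L)] == letters_uc[t])
    if (!length(prior)) { seen0 <- seen0 + 1L; next }
    dlag <- (t - n) - max(prior)
    if (dlag < 0L) { neg <- neg + 1L; next }
    samples <- c(samples, dlag)
  }
  new_memory_samples(samples, length(pos), neg, seen0, early, n)
}

#' Estimate the inverse temperature from lag samples
#'
#' Histograms the lags over `fit_domain`, optionally adds one count per bin
#' (so the logarithm is defined everywhere), and fits a least-squares line
#' to \eqn{\log(\mathrm{count})} versus \eqn{\Delta t}; the estimate is the
#' negative slope. Per-subject fits use the domain 0-4; pooled group fits
#' use 0-10 where the data are dense enough.
#'
#' @param samples a `memory_samples` object or an integer vector of lags.
#' @param fit_domain integer lags over which to fit (default `0:4`).
#' @param smoothing add one count to every bin (default `TRUE`).
#' @return the estimate \eqn{\hat\beta} (a single number).
#' @export
#' @examples
#' fit_beta_from_samples(rep(0:3, c(8, 4, 2, 1)), fit_domain = 0:3,
#'                       smoothing = FALSE)  # exactly log(2)
fit_beta_from_samples <- function(samples, fit_domain = 0:4, smoothing = TRUE) {
  if (inherits(samples, "memory_samples")) samples <- samples$samples
  if (!length(samples)) stop("no lag samples")
  counts <- vapply(fit_domain, function(d) sum(samples == d), numeric(1))
  if (smoothing) counts <- counts + 1
  keep <- counts > 0
  if (sum(keep) < 2L) stop("fewer than 2 distinct lag bins; cannot fit a slope")
  x <- fit_domain[keep]
  fit <- lm(log(counts[keep]) ~ x)
  -unname(coef(fit)[2])
}

#' Bootstrap the inverse-temperature estimate
#'
#' Resamples the lag multiset with replacement, refits
#' [fit_beta_from_samples()] per replicate, and returns the mean and SD of
#' the replicate estimates. Degenerate replicates (fewer than two occupied
#' bins) are skipped and tallied.
#'
#' @inheritParams fit_beta_from_samples
#' @param reps number of bootstrap replicates (default 1000).
#' @param seed optional RNG seed.
#' @return list with `mean`, `sd`, `reps_used`, `reps_skipped`.
#' @export
bootstrap_beta <- function(samples, reps = 1000L, seed = NULL,
                           fit_domain = 0:4, smoothing = TRUE) {
  if (inherits(samples, "memory_samples")) samples <- samples$samples
  if (!length(samples)) stop("no lag samples")
  if (reps < 1) stop("`reps` must be >= 1")
  n <- length(samples)
  with_seed(seed, {
    est <- vapply(seq_len(reps), function(r) {
      s <- samples[sample.int(n, n, replace = TRUE)]
      tryCatch(fit_beta_from_samples(s, fit_domain, smoothing),
               error = function(e) NA_real_)
    }, numeric(1))
    ok <- !is.na(est)
    list(mean = mean(est[ok]), sd = sd(est[ok]),
         reps_used = sum(ok), reps_skipped = sum(!ok))
  })
}

#' Compare n-back and serial-response estimates of the inverse temperature
#'
#' Spearman rank correlation between per-subject direct (n-back) and
#' indirect (reaction-time fit) estimates, with a two-sided permutation
#' test. Subjects whose serial fit landed on a limit (\eqn{\beta = 0} or
#' \eqn{\beta \to \infty}) are excluded.
#'
#' @param beta_nback,beta_serial numeric vectors, one entry per subject.
#' @param serial_limit optional character vector of limit flags for the
#'   serial fits (`NA` for finite; `"zero"`/`"inf"` excluded), e.g. from
#'   `fit_result$beta_limit`.
#' @param n_perm number of permutations (>= 1000; default `1e4`).
#' @param seed optional RNG seed.
#' @return list with `r_s` (Spearman correlation), `p_value`, `n_pairs`.
#' @export
correlate_betas <- function(beta_nback, beta_serial, serial_limit = NULL,
                            n_perm = 1e4L, seed = NULL) {
  if (length(beta_nback) != length(beta_serial)) stop("vectors must have equal length")
  keep <- is.finite(beta_serial) & beta_serial > 0 & is.finite(beta_nback)
  if (!is.null(serial_limit)) keep <- keep & is.na(serial_limit)
  bn <- beta_nback[keep]
  bs <- beta_serial[keep]
  m <- length(bn)
  if (m < 5L) stop("fewer than 5 usable subject pairs after exclusions")
  rx <- rank(bn)
  ry <- rank(bs)
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  if (denom == 0) stop("constant ranks; correlation undefined")
  rs <- sum(rxc * ryc) / denom
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(p) {
      sum(rxc * ryc[sample.int(m)]) / denom
    }, numeric(1))
    p <- (1 + sum(abs(perm) >= abs(rs) - 1e-12)) / (n_perm + 1)
    list(r_s = rs, p_value = p, n_pairs = m)
  })
}

#' Draw lags directly from the Boltzmann memory distribution
#'
#' Samples \eqn{\Delta t \sim P(\Delta t) \propto e^{-\beta \Delta t}} on
#' the non-negative integers (the infinite-horizon geometric form).
#'
#' @param n number of samples.
#' @param beta finite inverse temperature `> 0`.
#' @param seed optional RNG seed.
#' @return integer vector of lags.
#' @export
sample_memory_lags <- function(n, beta, seed = NULL) {
  if (length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop("`beta` must be a finite value > 0")
  }
  with_seed(seed, rgeom(n, 1 - exp(-beta)))
}
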