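# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Logarithmically spaced candidate grid for the inverse temperature
#'
#' The fitting routine scans reaction-time prediction error along
#' log-spaced values of the inverse temperature before refining by
#' gradient descent. The default grid is 100 points spanning
#' \eqn{[10^{-4}, 10]}.
#'
#' @param n number of grid points (>= 2).
#' @param range length-2 positive increasing vector of grid endpoints.
#' @return numeric vector of `n` log-spaced values.
#' @export
#' @examples
#' beta_grid(5)
beta_grid <- function(n = 100L, range = c(1e-4, 10)) {
  if (length(n) != 1L || n < 2) stop("grid must have at least 2 points")
  if (length(range) != 2L || any(range <= 0) || diff(range) <= 0) {
    stop("`range` must be positive and increasing")
  }
  10^seq(log10(range[1]), log10(range[2]), length.out = n)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# apply `fun` per subject (and optionally per stage) to a trial table,
# preserving row order within groups
split_subjects <- function(data) {
  stopifnot(is.data.frame(data), "subject_id" %in% names(data))
  split(data, data$subject_id, drop = TRUE)
}
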