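# Internal helpers: validation, seeded evaluation, small numerics.

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_zero = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper || (!allow_zero && x == 0))
    stop(sprintf("'%s' = %g is outside [%g, %g]", name, x, lower, upper),
         call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x != round(x) ||
      x < lower)
    stop(sprintf("'%s' must be an integer >= %d", name, lower), call. = FALSE)
  invisible(as.integer(x))
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global random-number state so that seeded
#' generator calls do not perturb the caller's stream. A `NULL` seed
#' evaluates the expression with the current state.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation; stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 7919 * offset) %% 2147483629)
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  if (k == 1L || n < 3L) return(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Normal draws truncated below (rejection sampling; bounds are mild in all
# presets so acceptance is near 1).
rnorm_trunc <- function(n, mean, sd, lower) {
  out <- numeric(n)
  need <- seq_len(n)
  guard <- 0L
  while (length(need) > 0L) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal sampler failed to converge")
  }
  out
}

# round-half-up for display percentages (87.5 -> 88)
display_round <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
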