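#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

.check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%g, %g]", name, lower, upper), call. = FALSE)
  invisible(x)
}

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min)
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

# Nearest-rank (inverted empirical CDF) quantile: smallest order statistic
# with at least p*n observations at or below it.
.nearest_rank_quantile <- function(x, p) {
  x <- sort(x)
  k <- max(1L, ceiling(p * length(x)))
  x[min(k, length(x))]
}

# Derive a stream of sub-seeds from one master seed, kept inside 32-bit
# integer range so set.seed() accepts them.
.derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

# Centered running mean with shrinking windows at the edges.
.running_mean <- function(x, k = 5L) {
  n <- length(x)
  half <- k %/% 2L
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    a <- max(1L, i - half)
    b <- min(n, i + half)
    out[i] <- (cs[b + 1L] - cs[a]) / (b - a + 1L)
  }
  out
}

.set_seed_if_given <- function(seed) {
  if (!is.null(seed)) {
    .check_count(seed, "seed", min = 0L)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
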