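# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. Every randomized function in the package takes an explicit seed and
# routes through here; no function relies on global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                      strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if ((strict_min && x <= min) || (!strict_min && x < min) || x > max)
    stop(sprintf("`%s` = %g is outside the allowed range", name, x),
         call. = FALSE)
  invisible(x)
}

check_sorted_times <- function(times, name = "times", strict = TRUE) {
  if (length(times) == 0L) return(invisible(times))
  if (!is.numeric(times) || anyNA(times))
    stop(sprintf("`%s` must be numeric without NA", name), call. = FALSE)
  d <- diff(times)
  if (strict && any(d <= 0))
    stop(sprintf("`%s` must be strictly increasing", name), call. = FALSE)
  if (!strict && any(d < 0))
    stop(sprintf("`%s` must be non-decreasing", name), call. = FALSE)
  invisible(times)
}

# Truncated symmetric moving mean: mean of x over indices [i-h, i+h]
# intersected with [1, n]. O(n) via cumulative sums.
running_mean <- function(x, h) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
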