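# Internal helpers shared across modules.

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

clip01 <- function(x) clip(x, 0, 1)

logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's
#' RNG stream so seeded package operations never disturb user code.
#' A `NULL` seed runs the code on the current stream.
#' @param seed integer seed or `NULL`
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Row-wise softmax with the usual max-subtraction for stability.
softmax_rows <- function(logits) {
  logits <- as.matrix(logits)
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# One categorical draw per row of a probability matrix; returns 1-based
# column indices. `u` can be supplied for reproducibility in tight loops.
sample_rows <- function(prob, u = stats::runif(nrow(prob))) {
  prob <- as.matrix(prob)
  cp <- prob
  for (j in seq_len(ncol(prob))[-1]) cp[, j] <- cp[, j - 1L] + prob[, j]
  1L + rowSums(u > cp[, -ncol(cp), drop = FALSE])
}

# Population standard deviation (divisor n); a single observation has sd 0.
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

fmt_pct <- function(num, den, digits = 1) round(100 * num / den, digits)

iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
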