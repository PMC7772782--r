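# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded generators do not perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seed for (master seed, integer index, purpose tag).
# Keeps per-gene randomness stable when unrelated parts of a config change.
substream_seed <- function(seed, index, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 7919 + h) %%
               2147483629)
}

# Integer range helpers: ranges are length-2 inclusive [lo, hi].
check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2])
    stop(sprintf("'%s' must be a non-empty numeric range c(lo, hi)", name))
  invisible(x)
}

sample_range <- function(range, n) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

# Quantile convention used throughout: linear-interpolation (type 7).
quantile7 <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
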