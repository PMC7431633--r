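# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded internals (tie-breaking,
#' simulation) never perturb the caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Largest-remainder apportionment of n items to proportions p (sums to n).
apportion <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-8)
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1L
  }
  as.integer(k)
}

# Stable per-stage seed derived from a base seed (kept < 2^31).
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage)) * 131L
  as.integer((as.numeric(seed) + offs) %% 2147483647)
}

msg <- function(...) message("[senlineage] ", ...)
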