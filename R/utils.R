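# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never perturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic per-component seed stream: one global seed fans out to named
# streams so changing one component's draws does not perturb the others.
derive_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# round-half-away-from-zero, so masked-edge counts are reproducible across
# platforms (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hgt <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "hgtlink_error")))
}

# canonical "drug|disease" key for unordered pair bookkeeping
pair_key <- function(a, b) paste(a, b, sep = "\r")
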