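# Internal helpers: seeded RNG scoping and deterministic substreams.

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific seed from a root seed, so adding a stage never
# perturbs the draws of earlier stages. Kept below 2^31 (R integers are 32-bit).
#' @noRd
substream <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(as.double(utf8ToInt(stage)) * (31 ^ (seq_along(utf8ToInt(stage)) %% 7)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
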