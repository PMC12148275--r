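#' Derive a reproducible substream seed from a global seed
#'
#' Expands one global seed into independent per-unit seeds (per core, per
#' stage) with a multiplicative-congruential mixing rule, so any single
#' core or stage can be regenerated without replaying the whole cohort.
#' The rule is `s <- 1; for each key k: s <- (s * 48271 + k + 1) mod
#' (2^31 - 1)`, evaluated exactly in double precision (all intermediates
#' stay below 2^53).
#'
#' @param ... integer keys, e.g. `substream_seed(seed, participant, core)`.
#' @return A single integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' substream_seed(42, 1, 1)
#' substream_seed(42, 1, 2)  # differs
substream_seed <- function(...) {
  keys <- c(...)
  if (length(keys) == 0L || any(!is.finite(keys))) {
    stop("substream_seed() needs at least one finite key")
  }
  m <- 2147483647
  s <- 1
  for (k in keys) {
    s <- (s * 48271 + (as.numeric(k) %% m) + 1) %% m
  }
  as.integer(s)
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so simulation calls never perturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
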