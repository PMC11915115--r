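#' Derive a reproducible sub-seed from a top-level seed and a stage name
#'
#' All randomness in the pipeline flows from a single integer seed; every
#' stage (cohort generation, noise injection, splitting, verification run r,
#' ...) draws from its own substream whose seed is a deterministic hash of
#' the stage name combined with the top-level seed.  Stages can therefore be
#' re-run in isolation and still reproduce the full-pipeline result.
#'
#' @param seed integer top-level seed.
#' @param stage character stage label, e.g. `"cohort"` or `"verify:7"`.
#' @return an integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(stage) == 1L)
  h <- 17
  for (code in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((h + (abs(as.numeric(seed)) %% 2147483647) * 48271) %% 2147483647)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so no stage reads or perturbs global
#' RNG state.
#'
#' @param seed integer seed (NULL leaves the RNG alone).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
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
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# truncated normal draws by inverse-CDF; deterministic under set.seed
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(clamp(mean, lo, hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
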