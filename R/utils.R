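#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats rnorm runif predict median sd
#' @importFrom utils head read.csv write.csv write.table
NULL

# Deterministic named RNG substreams.  A single user-facing seed is folded
# with a component label so that, e.g., drawing extra drugs never perturbs
# the cell-line draws.  The fold stays inside 32-bit integer range.
deriveSeed <- function(seed, ...) {
  tokens <- unlist(lapply(list(...), as.character))
  h <- as.double(seed) %% 2147483647
  for (tok in tokens) {
    for (code in utf8ToInt(tok)) {
      h <- (h * 31 + code) %% 2147483647
    }
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clampProb <- function(p, eps = 1e-7) {
  pmin(pmax(p, eps), 1 - eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
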