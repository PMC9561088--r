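# Internal helpers shared across the workflow.

#' Run code with a temporarily seeded RNG
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stable child seed from a global seed and a label
#'
#' Hashes a character label into an integer offset so that, e.g., every
#' district gets an independent, reproducible random stream, and adding a
#' district never perturbs the others.
#'
#' @param seed integer global seed.
#' @param label character scalar.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stable_seed <- function(seed, label) {
  stopifnot(length(label) == 1L)
  bytes <- utf8ToInt(as.character(label))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper around [mclust::adjustedRandIndex()] used to compare recovered
#' ecotype assignments with a reference partition.
#'
#' @param a,b label vectors of equal length.
#' @return Numeric scalar ARI.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}
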