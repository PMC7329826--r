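#' Derive a labelled child seed from a root seed
#'
#' All randomness in the package flows from a single integer root seed.
#' Independent streams (one per subject, cohort, replicate, ...) are derived
#' by hashing a character label together with the root seed, so that adding
#' subjects or replicates never perturbs the streams of existing ones.
#'
#' @param seed integer root seed.
#' @param label character label naming the stream (e.g. `"cohort1/subject07"`).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @examples
#' child_seed(1, "cohortA") != child_seed(1, "cohortB")
#' @export
child_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label), length(label) == 1L)
  # FNV-1a style hash in double arithmetic, kept exact below 2^53
  h <- 2166136261
  bytes <- utf8ToInt(paste0(format(seed, scientific = FALSE), "\x1f", label))
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483629)
}

# xor of a double-held 32-bit value with a byte, without bit64
bitwXor_dbl <- function(x, y) {
  as.numeric(bitwXor(as.integer(x %% 2147483648), as.integer(y)))
}

#' Evaluate an expression under a temporary RNG state
#'
#' @param seed integer seed for the expression.
#' @param expr expression to evaluate.
#' @return The value of `expr`; the caller's RNG state is restored afterwards.
#' @export
with_seed <- function(seed, expr) {
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
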