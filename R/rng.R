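#' Deterministic named RNG substreams
#'
#' Every stochastic stage (cohort generation, weight initialization,
#' augmentation, batch shuffling, perturbation draws) pulls its seed from one
#' master seed through a named substream, so a whole pipeline run is
#' bit-reproducible from a single integer while stages stay independent:
#' adding draws to one stage never shifts another stage's stream.
#'
#' The derivation is a small splitmix-style integer hash of the master seed,
#' the stream label and an index; results are always in `[0, 2^31 - 1]`.
#'
#' @param master integer master seed.
#' @param label character scalar naming the stream (e.g. `"fold"`).
#' @param index non-negative integer distinguishing uses within a stream.
#' @return A single integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(master, label, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.character(label), length(label) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  # mix in 31-bit arithmetic (doubles are exact well beyond 2^31)
  h <- (abs(master) %% 2147483647) + 1
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% 2147483647
  }
  h <- (h * 2654435761 + index * 40503 + 17) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
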