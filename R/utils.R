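`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive independent sub-seeds from a root seed
#'
#' All randomness in a pipeline run flows from one root seed; independent
#' stages (cohort generation, control matching, ...) each get their own
#' sub-seed so they are reproducible in isolation.
#'
#' @param seed integer root seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
substream_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# reference covariate values anchoring template modifier terms (cohort means)
.ref_age <- 32.2
.ref_bmi <- 25.3
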