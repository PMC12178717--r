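# Reproducibility helpers.
#
# All randomness in the package goes through R's Mersenne-Twister stream,
# seeded locally inside each stochastic operation: the caller's RNG state
# is saved and restored, so package functions never disturb user
# randomness, and any operation is independently replayable from its seed.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  eval.parent(substitute(expr))
}

#' Derive a stage seed from a master seed
#'
#' Sub-streams for pipeline stages are derived from one master seed by
#' fixed labeled offsets, so each stage is independently replayable.
#'
#' @param master Master seed (integer).
#' @param label Stage label (character).
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  offsets <- c(simulate = 11L, haploid_a = 101L, haploid_b = 211L,
               tmrca = 307L, mutations = 401L, quartet = 503L,
               artifact = 601L, hap = 701L)
  off <- if (label %in% names(offsets)) offsets[[label]] else {
    sum(utf8ToInt(label)) %% 1000L + 1000L
  }
  as.integer((as.numeric(master) * 2654435761 + off) %% 2147483647)
}
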