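# Internal helpers: seed derivation and circular arithmetic.

#' Derive a child random seed from a root seed and a stream label
#'
#' Generators draw from labelled child streams so that adding a new
#' generator never perturbs the output of existing ones under the same
#' root seed. The derivation is a fixed integer hash; identical
#' (seed, label) pairs always give the same child seed (< 2^31).
#'
#' @param seed integer root seed.
#' @param label character stream label.
#' @return integer seed suitable for [set.seed()].
#' @export
child_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (cp in utf8ToInt(as.character(label))) {
    h <- (h * 131 + cp) %% m
  }
  # final scramble (Lehmer step) so nearby seeds decorrelate
  as.integer((h * 48271 + 11) %% m)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
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

# Acute angular difference between two orientations (degrees, period 180).
# Result is in [0, 90].
acute_orientation_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Wrap orientation angles into [0, 180).
wrap180 <- function(a) {
  a %% 180
}
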