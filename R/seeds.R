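#' Derive a child seed from a master seed
#'
#' Every stochastic stage of a pipeline (sampling, noise generation,
#' bootstrap, each step of the two-stage protocol) draws its randomness from
#' its own child seed, derived deterministically from a single integer master
#' seed. This keeps full runs bit-reproducible while ensuring distinct stages
#' never share a random stream.
#'
#' @param master integer master seed.
#' @param stage integer stage index (>= 0); distinct stages give distinct
#'   child seeds.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(stage), length(stage) == 1L, stage >= 0)
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus of the minstd generator
  s <- (abs(as.double(master)) %% m)
  for (i in seq_len(stage + 1L)) {
    s <- (s * 48271 + 11 + stage) %% m
  }
  as.integer(s)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
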