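#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed
#'
#' Lehmer-style integer mixing so that per-trial / per-stage streams are
#' independent yet fully determined by the master seed. All arithmetic stays
#' below 2^53 so the result is exact in double precision, and the returned
#' seed is always in \[1, 2^31 - 2\].
#'
#' @param master Master seed (integer-valued).
#' @param index Child index (e.g. trial number), integer-valued, >= 0.
#' @param salt Optional extra stream discriminator.
#' @return An integer seed.
#' @export
derive_seed <- function(master, index, salt = 0) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(master) %% m
  h <- (h * 48271) %% m
  h <- (h + as.double(index) + 1) %% m
  h <- (h * 48271) %% m
  h <- (h + as.double(salt)) %% m
  h <- (h * 48271) %% m
  as.integer(h %% (m - 1) + 1)
}
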