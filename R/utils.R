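# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never disturb
# the global stream.
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
  code
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed through this
#' mixer: each analysis stage (a digest replicate, one bootstrap run)
#' derives its own stream from the master seed plus integer indices, so
#' any stage can be reproduced in isolation.  The result is kept strictly
#' below 2^31 - 1.
#'
#' @param seed Master seed (integer).
#' @param ... Integer stream indices.
#' @return A single integer seed.
#' @export
mix_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  m <- 2147483629  # prime < 2^31
  acc <- 0
  for (v in idx) acc <- (acc * 48271 + (as.numeric(v) %% m) + 1) %% m
  as.integer(acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("'", name, "' must be a single non-missing number", call. = FALSE)
  }
}
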