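#' Derive a deterministic RNG seed from a base seed and stream labels
#'
#' All randomness in a federated run (model initialization, per-epoch data
#' shuffling, augmentation draws, synthetic-sample generation) is seeded from
#' the run seed plus integer stream labels such as `(round, client, epoch)`.
#' Client processing order therefore cannot change any result, and any stream
#' can be reproduced in isolation.
#'
#' The combination is a multiplicative fold modulo 2^31 - 1, kept exact in
#' double precision.
#'
#' @param seed Base integer seed.
#' @param ... Further non-negative integer labels identifying the stream.
#' @return A single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, 3, 2) # same labels -> same seed
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (x in c(...)) {
    h <- (h * 69069 + as.numeric(x) + 1) %% m
  }
  as.integer(h %% (m - 2L) + 1)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

sigmoid <- function(x) stats::plogis(x)

# x: array (H, W, C, N) -> per-(channel, sample) column matrix (H*W, C*N)
as_group_mat <- function(x) {
  d <- dim(x)
  matrix(x, nrow = d[1] * d[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop2(name, " must be a single finite number")
  }
  if (strict && x <= min) stop2(name, " must be > ", min)
  if (!strict && x < min) stop2(name, " must be >= ", min)
  invisible(x)
}
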