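# Internal helpers shared across modules.

LOG2 <- log(2)

# Convert a value computed in nats to the requested base.
from_nats <- function(x, base = c("bits", "nats")) {
  base <- match.arg(base)
  if (base == "bits") x / LOG2 else x
}

# Run `code` with a fixed RNG seed, restoring the caller's RNG state afterwards.
# All randomness in the package flows through this; no function perturbs the
# global random state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

# x * log(x / y) with the 0 * log 0 = 0 convention, in nats.
# Entries with x > 0 and y == 0 give +Inf (absolute-continuity violation).
xlogxy <- function(x, y) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * (log(x[pos]) - log(y[pos]))
  out
}

# Matrix power by repeated squaring (n >= 0 integer).
mat_pow <- function(M, n) {
  stopifnot(n >= 0, n == round(n))
  d <- nrow(M)
  acc <- diag(d)
  base <- M
  n <- as.integer(n)
  while (n > 0L) {
    if (n %% 2L == 1L) acc <- acc %*% base
    base <- base %*% base
    n <- n %/% 2L
  }
  dimnames(acc) <- dimnames(M)
  acc
}

# Dense matrix exponential via Matrix::expm.
mat_exp <- function(M) {
  out <- as.matrix(Matrix::expm(Matrix::Matrix(M)))
  dimnames(out) <- dimnames(M)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
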