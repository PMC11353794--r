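#' Seeded simulation of the supported process classes
#'
#' Methods for [stats::simulate()]: a DTMC path is sampled from the stationary
#' distribution and then column-wise from `P`; a CTMC path is sampled from the
#' jump chain with exponential dwell times from `Q`; a stationary Gaussian
#' process is drawn jointly from the Toeplitz covariance induced by its
#' autocovariance (zero beyond the last stored lag). The same seed always
#' produces a bit-identical sequence, and the caller's RNG state is untouched.
#'
#' @param object A [dtmc_model()], [ctmc_model()] or [stationary_gp()].
#' @param nsim Number of events (DTMC/CTMC) or sample length (GP).
#' @param seed Integer seed (required: all package randomness is explicit).
#' @param ... Unused.
#' @return An [event_sequence()].
#' @name simulate-methods
NULL

#' @rdname simulate-methods
#' @export
simulate.dtmc_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) stop("an explicit seed is required")
  nsim <- as.integer(nsim)
  if (nsim < 1L) stop("nsim must be >= 1")
  if (is.null(object$pi)) stop("model has no stationary distribution")
  n_states <- length(object$alphabet)
  path <- with_seed(seed, {
    s <- integer(nsim)
    s[1] <- sample.int(n_states, 1, prob = object$pi)
    for (i in seq_len(nsim - 1L)) {
      s[i + 1L] <- sample.int(n_states, 1, prob = object$P[, s[i]])
    }
    s
  })
  event_sequence(object$alphabet[path])
}

#' @rdname simulate-methods
#' @export
simulate.ctmc_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) stop("an explicit seed is required")
  nsim <- as.integer(nsim)
  if (nsim < 1L) stop("nsim must be >= 1")
  if (is.null(object$pi)) stop("model has no stationary distribution")
  n_states <- length(object$alphabet)
  rates <- -diag(object$Q)
  if (any(rates <= 0)) stop("absorbing state: cannot simulate jump chain")
  res <- with_seed(seed, {
    s <- integer(nsim)
    dwell <- numeric(nsim)
    s[1] <- sample.int(n_states, 1, prob = object$pi)
    for (i in seq_len(nsim)) {
      dwell[i] <- stats::rexp(1, rate = rates[s[i]])
      if (i < nsim) {
        p <- object$Q[, s[i]]
        p[s[i]] <- 0
        s[i + 1L] <- sample.int(n_states, 1, prob = p)
      }
    }
    list(s = s, dwell = dwell)
  })
  onset <- cumsum(c(0, res$dwell[-nsim]))
  event_sequence(object$alphabet[res$s], onset, res$dwell)
}

#' @rdname simulate-methods
#' @export
simulate.stationary_gp <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) stop("an explicit seed is required")
  nsim <- as.integer(nsim)
  if (nsim < 1L) stop("nsim must be >= 1")
  Sigma <- gp_covariance(object, seq_len(nsim))
  L <- psd_chol(Sigma, gamma0 = autocov_eval(object, 0))
  z <- with_seed(seed, stats::rnorm(nsim))
  event_sequence(as.numeric(object$mean + t(L) %*% z))
}
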