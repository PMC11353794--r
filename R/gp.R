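#' Stationary Gaussian process model
#'
#' A stationary GP over the reals, parameterised by a scalar mean and an
#' autocovariance: either a numeric vector `gamma` of values at integer lags
#' `0..L` (discrete time) or a [fit_continuous_autocov()] polynomial
#' (continuous time). Any finite window of the process is the multivariate
#' Gaussian with Toeplitz covariance `Sigma[i, j] = gamma(|t_i - t_j|)`;
#' windows are repaired to positive definite by symmetrisation plus escalating
#' jitter (see [gaussian_joint()]).
#'
#' In discrete time the autocovariance is taken as 0 beyond the last stored
#' lag.
#'
#' @param mean Scalar process mean.
#' @param gamma Numeric autocovariance at lags `0..L` (`gamma[1]` is lag 0 and
#'   must be positive), or a `"continuous_autocov"` object.
#' @return An object of class `"stationary_gp"`.
#' @export
stationary_gp <- function(mean, gamma) {
  mean <- as.numeric(mean)
  stopifnot(length(mean) == 1L)
  if (inherits(gamma, "continuous_autocov")) {
    mode <- "continuous"
    if (autocov_poly_eval(gamma, 0) <= 0) stop("gamma(0) must be > 0")
  } else {
    gamma <- as.numeric(gamma)
    if (length(gamma) < 1L || gamma[1] < 0) stop("gamma[lag 0] must be >= 0")
    mode <- "discrete"
  }
  structure(list(mean = mean, gamma = gamma, mode = mode),
            class = "stationary_gp")
}

#' @export
print.stationary_gp <- function(x, ...) {
  cat(sprintf("<stationary_gp: mean %.4g, %s-time autocovariance>\n",
              x$mean, x$mode))
  invisible(x)
}

#' Evaluate an autocovariance at (possibly real) lags
#'
#' For a fitted `"continuous_autocov"` the polynomial is evaluated at `|t|`
#' inside its domain `[0, t_max]` (outside is an error); for a discrete
#' [stationary_gp()] only integer lags are defined, with 0 beyond the last
#' stored lag.
#'
#' @param x A `"continuous_autocov"` or [stationary_gp()].
#' @param t Lag(s).
#' @return Autocovariance value(s).
#' @export
autocov_at <- function(x, t) {
  if (inherits(x, "continuous_autocov")) return(autocov_poly_eval(x, t))
  if (inherits(x, "stationary_gp")) return(autocov_eval(x, t))
  stop("x must be a continuous_autocov or stationary_gp")
}

autocov_poly_eval <- function(ac, t) {
  t <- abs(t)
  if (any(t > ac$t_max + 1e-12)) {
    stop(sprintf("lag %.4g outside the fitted domain [0, %.4g]", max(t), ac$t_max))
  }
  u <- t / ac$t_max
  out <- numeric(length(u))
  for (i in seq_along(ac$coeffs)) out <- out + ac$coeffs[i] * u^(i - 1)
  out
}

# autocovariance at (possibly real) lags
autocov_eval <- function(model, lag) {
  lag <- abs(lag)
  if (model$mode == "continuous") return(autocov_poly_eval(model$gamma, lag))
  if (any(abs(lag - round(lag)) > 1e-9)) {
    stop("discrete-time autocovariance is defined at integer lags only")
  }
  lag <- as.integer(round(lag))
  L <- length(model$gamma) - 1L
  ifelse(lag <= L, model$gamma[pmin(lag, L) + 1L], 0)
}

# Toeplitz covariance of the window at the given time tags
gp_covariance <- function(model, times) {
  D <- abs(outer(times, times, "-"))
  matrix(autocov_eval(model, as.numeric(D)), nrow = length(times))
}

#' Estimate a stationary Gaussian process from a corpus of sequences
#'
#' Pools all values for the mean, then estimates the autocovariance at lags
#' `0..max_lag` from lagged products of centred values, never crossing
#' sequence boundaries. The default (biased, `1/N` with `N` the total number
#' of values) estimator favours positive semi-definite Toeplitz windows; the
#' unbiased variant divides each lag by its number of products.
#'
#' @param corpus List of numeric vectors (or real-valued [event_sequence()]s).
#' @param max_lag Largest lag (must be `< ` the shortest sequence length).
#' @param biased Use the `1/N` estimator (default `TRUE`).
#' @return A [stationary_gp()].
#' @export
estimate_stationary_gp <- function(corpus, max_lag, biased = TRUE) {
  if (length(corpus) == 0L) stop("corpus is empty")
  seqs <- lapply(corpus, as_numeric_vector)
  lens <- vapply(seqs, length, integer(1))
  if (max_lag >= min(lens)) {
    stop(sprintf("max_lag %d >= shortest sequence length %d", max_lag, min(lens)))
  }
  N <- sum(lens)
  m <- sum(vapply(seqs, sum, numeric(1))) / N
  gamma <- numeric(max_lag + 1L)
  npairs <- numeric(max_lag + 1L)
  for (s in seqs) {
    d <- s - m
    n <- length(d)
    for (l in 0:max_lag) {
      if (l >= n) next
      gamma[l + 1L] <- gamma[l + 1L] + sum(d[1:(n - l)] * d[(1 + l):n])
      npairs[l + 1L] <- npairs[l + 1L] + (n - l)
    }
  }
  gamma <- if (biased) gamma / N else gamma / npairs
  stationary_gp(m, gamma)
}

#' Fit a continuous autocovariance polynomial to discrete lags
#'
#' Least-squares fit of a degree-`degree` polynomial in the lag magnitude
#' `|t|` to autocovariance values at integer lags `0..L`, valid on
#' `[0, t_max = L]`; evaluation outside the domain is an error. The lag axis
#' is scaled to `[0, 1]` internally for numerical stability; the stored
#' coefficients are in that scaled basis. The maximum fit residual is
#' reported, and lags whose induced small Toeplitz windows are indefinite are
#' flagged (without failing): the repair in [stationary_gp()] handles them.
#'
#' @param gamma_hat Numeric autocovariance values at lags `0..L`, or a
#'   discrete [stationary_gp()].
#' @param degree Polynomial degree (`>= 1`; needs at least `degree + 1` lags).
#' @return An object of class `"continuous_autocov"` with fields `coeffs`,
#'   `t_max`, `max_residual`, `indefinite_lags`.
#' @export
fit_continuous_autocov <- function(gamma_hat, degree = 10) {
  if (inherits(gamma_hat, "stationary_gp")) {
    if (gamma_hat$mode != "discrete") stop("expected a discrete-lag autocovariance")
    gamma_hat <- gamma_hat$gamma
  }
  gamma_hat <- as.numeric(gamma_hat)
  L <- length(gamma_hat) - 1L
  if (degree < 1) stop("degree must be >= 1")
  if (L + 1L < degree + 1L) stop("underdetermined fit: need at least degree + 1 lags")
  u <- (0:L) / L
  X <- outer(u, 0:degree, "^")
  coeffs <- as.numeric(qr.solve(X, gamma_hat))
  fitted <- as.numeric(X %*% coeffs)
  ac <- structure(
    list(coeffs = coeffs, t_max = L,
         max_residual = max(abs(fitted - gamma_hat)),
         indefinite_lags = integer(0)),
    class = "continuous_autocov"
  )
  flags <- integer(0)
  for (mlen in 2:min(L + 1L, 8L)) {
    Sg <- matrix(autocov_poly_eval(ac, abs(outer(0:(mlen - 1), 0:(mlen - 1), "-"))),
                 nrow = mlen)
    if (min(eigen((Sg + t(Sg)) / 2, symmetric = TRUE, only.values = TRUE)$values) < 0) {
      flags <- c(flags, mlen - 1L)
    }
  }
  ac$indefinite_lags <- flags
  ac
}

#' @export
print.continuous_autocov <- function(x, ...) {
  cat(sprintf(
    "<continuous_autocov: degree %d on [0, %g], max residual %.3g>\n",
    length(x$coeffs) - 1L, x$t_max, x$max_residual
  ))
  invisible(x)
}

#' Contrast-information profile of a sequence under a stationary GP
#'
#' Discrete time: for each event `n` with a full window, the regimes are the
#' extended past `X = {S[n-j], ..., S[n-1]}`, present `Y = S[n]` and extended
#' future `Z = {S[n+1], ..., S[n+k]}`; the requested variant assigns these to
#' target/source/context and the value is [gaussian_contrast()] on the
#' Toeplitz joint induced by the model at the window's time tags, with the
#' observed source/context values plugged in.
#'
#' Continuous time: point regimes at onsets with the target regime sweeping a
#' grid of step `grid_step`, with the same onset placement as the
#' continuous-time Markov profile (see [markov_profile()]).
#'
#' @param model A [stationary_gp()].
#' @param sequence Real-valued [event_sequence()] (or numeric vector in
#'   discrete mode).
#' @param variant One of [contrast_variants()].
#' @param j,k Integer regime extents (discrete mode).
#' @param grid_step Positive sampling step (continuous mode).
#' @param base `"bits"` (default) or `"nats"`.
#' @return An [info_profile()].
#' @export
gp_profile <- function(model, sequence, variant, j = 1, k = 1,
                       grid_step = NULL, base = c("bits", "nats")) {
  stopifnot(inherits(model, "stationary_gp"))
  base <- match.arg(base)
  roles <- variant_roles(variant)
  if (model$mode == "discrete") {
    s <- as_numeric_vector(sequence)
    N <- length(s)
    if (j < 1 || k < 1) stop("regime extents j and k must be >= 1")
    idx <- seq.int(j + 1L, length.out = max(0L, N - j - k))
    regime_local <- list(
      x = seq_len(j), y = j + 1L, z = (j + 2L):(j + 1L + k)
    )
    vals <- vapply(idx, function(n) {
      tw <- (n - j):(n + k)
      joint <- gaussian_joint(rep(model$mean, length(tw)), gp_covariance(model, tw), tw)
      part <- regime_partition(
        regime_local[[roles[["target"]]]],
        regime_local[[roles[["source"]]]],
        regime_local[[roles[["context"]]]]
      )
      gaussian_contrast(
        joint, part,
        b = s[tw[regime_local[[roles[["source"]]]]]],
        c = s[tw[regime_local[[roles[["context"]]]]]],
        base = base
      )
    }, numeric(1))
    return(info_profile(idx, NA_real_, variant, vals))
  }
  # continuous time: point regimes at onsets, target regime sweeps
  ev <- as_timed_events(sequence)
  vals <- as.numeric(ev$value)
  onset <- ev$onset
  if (is.null(grid_step) || grid_step <= 0) stop("continuous profiles need a positive grid_step")
  N <- length(vals)
  sweeping <- roles[["target"]]
  out_i <- integer(0); out_t <- numeric(0); out_v <- numeric(0)
  for (i in seq_len(N - 1L)) {
    t0 <- onset[i]; t1 <- onset[i + 1L]
    if (sweeping == "z") {
      if (i == 1L) next
      grid <- seq(t0 + grid_step, t1 - grid_step / 2, by = grid_step)
      pts <- function(t) c(x = onset[i - 1L], y = t0, z = t)
      vv <- function(t) c(x = vals[i - 1L], y = vals[i], z = NA_real_)
    } else if (sweeping == "y") {
      grid <- seq(t0 + grid_step, t1 - grid_step / 2, by = grid_step)
      pts <- function(t) c(x = t0, y = t, z = t1)
      vv <- function(t) c(x = vals[i], y = NA_real_, z = vals[i + 1L])
    } else {
      if (i == 1L) next
      grid <- seq(onset[i - 1L] + grid_step, t0 - grid_step / 2, by = grid_step)
      pts <- function(t) c(x = t, y = t0, z = t1)
      vv <- function(t) c(x = NA_real_, y = vals[i], z = vals[i + 1L])
    }
    for (t in grid) {
      tt <- pts(t); ww <- vv(t)
      joint <- gaussian_joint(rep(model$mean, 3), gp_covariance(model, unname(tt)), tt)
      pos <- stats::setNames(1:3, names(tt))
      part <- regime_partition(
        pos[[roles[["target"]]]], pos[[roles[["source"]]]], pos[[roles[["context"]]]]
      )
      val <- gaussian_contrast(
        joint, part,
        b = ww[[roles[["source"]]]], c = ww[[roles[["context"]]]],
        base = base
      )
      out_i <- c(out_i, i); out_t <- c(out_t, t); out_v <- c(out_v, val)
    }
  }
  info_profile(out_i, out_t, variant, out_v)
}
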