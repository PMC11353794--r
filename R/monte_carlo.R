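#' Monte-Carlo estimate of continuous contrast information
#'
#' Estimates the continuous-state definition
#' \deqn{I(A; b | c) = \int p(a | b, c) \log_2 \frac{p(a | b, c)}{p(a | c)}
#'   \, da}
#' by averaging log-density ratios over seeded draws from the numerator
#' conditional. This is the definitional oracle for the closed-form Gaussian
#' path; no density estimation is performed.
#'
#' Draws with a non-finite log ratio are dropped from the average; their count
#' is reported. The standard error is the plain sample standard deviation of
#' the per-draw ratios divided by `sqrt(n_used)`.
#'
#' @param logdensity_num Vectorised function: log density (nats) of
#'   `p(a | b, c)` at its argument.
#' @param logdensity_den Vectorised function: log density (nats) of
#'   `p(a | c)`.
#' @param sampler_num Function of a sample count drawing from the numerator
#'   conditional; called once inside a seeded RNG scope. May return a vector
#'   (1-d state) or a matrix with one row per draw.
#' @param n Number of draws (`>= 2`).
#' @param seed Integer seed; identical seeds give bit-identical estimates.
#' @param base `"bits"` (default) or `"nats"`.
#' @return List with `estimate`, `std_error`, `n_used`, `n_nonfinite`.
#' @export
mc_contrast_continuous <- function(logdensity_num, logdensity_den, sampler_num,
                                   n, seed, base = c("bits", "nats")) {
  stopifnot(is.function(logdensity_num), is.function(logdensity_den),
            is.function(sampler_num))
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  draws <- with_seed(seed, sampler_num(n))
  ratios <- as.numeric(logdensity_num(draws)) - as.numeric(logdensity_den(draws))
  if (length(ratios) != n) stop("densities must return one value per draw")
  ok <- is.finite(ratios)
  n_bad <- sum(!ok)
  if (all(!ok)) stop("all log-density ratios are non-finite")
  ratios <- from_nats(ratios[ok], base)
  list(
    estimate = mean(ratios),
    std_error = stats::sd(ratios) / sqrt(sum(ok)),
    n_used = sum(ok),
    n_nonfinite = n_bad
  )
}
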