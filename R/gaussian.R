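#' Multivariate Gaussian joint over labelled coordinates
#'
#' Mean vector and covariance matrix with optional time tags per coordinate.
#' The covariance must be symmetric within `1e-10` (it is symmetrised) and
#' positive definite up to the package's jitter repair.
#'
#' @param mu Numeric mean vector.
#' @param sigma Covariance matrix.
#' @param index_labels Optional labels (e.g. time tags) per coordinate.
#' @return An object of class `"gaussian_joint"`.
#' @export
gaussian_joint <- function(mu, sigma, index_labels = NULL) {
  mu <- as.numeric(mu)
  sigma <- as.matrix(sigma)
  n <- length(mu)
  if (!all(dim(sigma) == n)) stop("sigma dimensions do not match mu")
  asym <- max(abs(sigma - t(sigma)))
  if (asym > 1e-10 * max(1, max(abs(sigma)))) {
    stop(sprintf("sigma is not symmetric (max asymmetry %.3g)", asym))
  }
  sigma <- (sigma + t(sigma)) / 2
  index_labels <- index_labels %||% seq_len(n)
  structure(list(mu = mu, sigma = sigma, index_labels = index_labels),
            class = "gaussian_joint")
}

#' @export
print.gaussian_joint <- function(x, ...) {
  cat(sprintf("<gaussian_joint: dimension %d>\n", length(x$mu)))
  invisible(x)
}

# Cholesky with jitter escalation; returns upper-triangular factor.
# Starts at 1e-10 * scale and doubles at most 20 times, then falls back to
# eigenvalue clipping at 1e-12 * scale with a warning.
psd_chol <- function(S, gamma0 = NULL) {
  scale <- max(gamma0 %||% 0, diag(S), 1e-12)
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(out)) return(out)
  jit <- 1e-10 * scale
  for (i in seq_len(20)) {
    out <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) NULL)
    if (!is.null(out)) return(out)
    jit <- 2 * jit
  }
  warning("covariance indefinite after maximum jitter; clipping eigenvalues")
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 1e-12 * scale)
  chol(e$vectors %*% (lam * t(e$vectors)))
}

solve_psd <- function(S, B, gamma0 = NULL) {
  U <- tryCatch(psd_chol(S, gamma0), error = function(e) {
    stop(sprintf(
      "singular block after maximum jitter (condition number ~ %.3g)", kappa(S)
    ))
  })
  backsolve(U, backsolve(U, B, transpose = TRUE))
}

logdet_psd <- function(S, gamma0 = NULL) {
  2 * sum(log(diag(psd_chol(S, gamma0))))
}

#' Condition a Gaussian joint on observed coordinates
#'
#' Returns the conditional Gaussian over the remaining coordinates given the
#' block formulas
#' `mu_1|2 = mu_1 + S_12 S_22^-1 (x_2 - mu_2)` and
#' `S_1|2 = S_11 - S_12 S_22^-1 S_21`. Conditioning on the empty set returns
#' the marginal (the joint itself).
#'
#' @param joint A [gaussian_joint()].
#' @param given_idx Integer indices of the observed coordinates.
#' @param given_values Observed values, same length as `given_idx`.
#' @return A [gaussian_joint()] over the coordinates not in `given_idx`.
#' @export
condition_gaussian <- function(joint, given_idx, given_values) {
  stopifnot(inherits(joint, "gaussian_joint"))
  given_idx <- as.integer(given_idx)
  if (length(given_idx) == 0L) return(joint)
  if (length(given_values) != length(given_idx)) {
    stop("given_values length does not match given_idx")
  }
  n <- length(joint$mu)
  if (any(given_idx < 1L | given_idx > n) || anyDuplicated(given_idx)) {
    stop("invalid given_idx")
  }
  keep <- setdiff(seq_len(n), given_idx)
  S <- joint$sigma
  S22 <- S[given_idx, given_idx, drop = FALSE]
  S12 <- S[keep, given_idx, drop = FALSE]
  dev <- as.numeric(given_values) - joint$mu[given_idx]
  W <- solve_psd(S22, cbind(dev, t(S12)))
  mu_c <- joint$mu[keep] + as.numeric(S12 %*% W[, 1])
  sig_c <- S[keep, keep, drop = FALSE] - S12 %*% W[, -1, drop = FALSE]
  gaussian_joint(mu_c, (sig_c + t(sig_c)) / 2, joint$index_labels[keep])
}

#' KL divergence between two multivariate Gaussians
#'
#' \deqn{D(N_1 : N_2) = \tfrac12\left[(\mu_2-\mu_1)^\top \Sigma_2^{-1}
#'   (\mu_2-\mu_1) + \mathrm{tr}(\Sigma_2^{-1}\Sigma_1)
#'   - \ln\frac{|\Sigma_1|}{|\Sigma_2|} - n\right]}
#' computed in nats and converted to the requested base.
#'
#' @param mu1,sigma1 Mean and covariance of the numerator Gaussian.
#' @param mu2,sigma2 Mean and covariance of the denominator Gaussian.
#' @param base `"bits"` (default) or `"nats"`.
#' @return Non-negative scalar.
#' @export
gaussian_kl <- function(mu1, sigma1, mu2, sigma2, base = c("bits", "nats")) {
  mu1 <- as.numeric(mu1); mu2 <- as.numeric(mu2)
  sigma1 <- as.matrix(sigma1); sigma2 <- as.matrix(sigma2)
  n <- length(mu1)
  if (length(mu2) != n || !all(dim(sigma1) == n) || !all(dim(sigma2) == n)) {
    stop("dimension mismatch")
  }
  dev <- mu2 - mu1
  S2inv_dev <- solve_psd(sigma2, cbind(dev))
  quad <- sum(dev * S2inv_dev)
  tr <- sum(diag(solve_psd(sigma2, sigma1)))
  logratio <- logdet_psd(sigma1) - logdet_psd(sigma2)
  from_nats(0.5 * (quad + tr - logratio - n), base)
}

#' Target/source/context partition of a Gaussian joint
#'
#' Disjoint index sets into a [gaussian_joint()] assigning coordinates to the
#' target regime `A` (non-empty), source regime `B` (non-empty) and context
#' regime `C` (possibly empty). The target length is the `n` of the Gaussian
#' KL formula.
#'
#' @param target_idx,source_idx,context_idx Integer index vectors.
#' @return An object of class `"regime_partition"`.
#' @export
regime_partition <- function(target_idx, source_idx, context_idx = integer(0)) {
  target_idx <- as.integer(target_idx)
  source_idx <- as.integer(source_idx)
  context_idx <- as.integer(context_idx)
  if (length(target_idx) == 0L || length(source_idx) == 0L) {
    stop("target and source must be non-empty")
  }
  all_idx <- c(target_idx, source_idx, context_idx)
  if (anyDuplicated(all_idx)) stop("regime index sets must be disjoint")
  structure(
    list(target_idx = target_idx, source_idx = source_idx,
         context_idx = context_idx, n = length(target_idx)),
    class = "regime_partition"
  )
}

#' Contrast information of a Gaussian joint
#'
#' The Gaussian closed form of contrast information: the KL divergence from
#' the conditional `p(A | B = b, C = c)` to `p(A | C = c)`, both obtained by
#' [condition_gaussian()]. For a one-dimensional target, source and context
#' this reduces to the scalar formula
#' \deqn{\tfrac12\left[\frac{(\mu_{A|B,C}-\mu_{A|C})^2}{\sigma^2_{A|C}}
#'   + \frac{\sigma^2_{A|B,C}}{\sigma^2_{A|C}}
#'   - \ln\frac{\sigma^2_{A|B,C}}{\sigma^2_{A|C}} - 1\right].}
#'
#' @param joint A [gaussian_joint()].
#' @param partition A [regime_partition()] valid for `joint`.
#' @param b Observed source values (length of `source_idx`).
#' @param c Observed context values (length of `context_idx`).
#' @param base `"bits"` (default) or `"nats"`.
#' @return Non-negative scalar.
#' @export
gaussian_contrast <- function(joint, partition, b, c = numeric(0),
                              base = c("bits", "nats")) {
  stopifnot(inherits(joint, "gaussian_joint"), inherits(partition, "regime_partition"))
  if (length(b) != length(partition$source_idx)) stop("b length != source size")
  if (length(c) != length(partition$context_idx)) stop("c length != context size")
  n <- length(joint$mu)
  if (max(c(partition$target_idx, partition$source_idx, partition$context_idx, 0)) > n) {
    stop("partition indexes outside the joint")
  }
  num <- condition_gaussian(
    joint,
    c(partition$source_idx, partition$context_idx),
    c(as.numeric(b), as.numeric(c))
  )
  den <- condition_gaussian(joint, partition$context_idx, as.numeric(c))
  # marginalise both conditionals to the target coordinates
  t_num <- match(partition$target_idx, setdiff(seq_len(n), c(partition$source_idx, partition$context_idx)))
  t_den <- match(partition$target_idx, setdiff(seq_len(n), partition$context_idx))
  gaussian_kl(
    num$mu[t_num], num$sigma[t_num, t_num, drop = FALSE],
    den$mu[t_den], den$sigma[t_den, t_den, drop = FALSE],
    base
  )
}
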