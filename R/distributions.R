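#' Discrete probability distribution over a labelled alphabet
#'
#' A light container pairing an ordered alphabet of symbols with a probability
#' vector. Probabilities must be non-negative and sum to 1 (tolerance `1e-9`,
#' after which they are renormalised exactly).
#'
#' @param labels Character vector of distinct symbols.
#' @param probs Numeric vector of probabilities, same length as `labels`.
#' @return An object of class `"distribution"` with fields `labels` and `probs`.
#' @examples
#' d <- distribution(c("a", "b"), c(.25, .75))
#' surprisal(d, "b")
#' entropy(d)
#' @export
distribution <- function(labels, probs) {
  labels <- as.character(labels)
  probs <- as.numeric(probs)
  if (length(labels) == 0L) stop("empty alphabet")
  if (anyDuplicated(labels)) stop("duplicated labels in alphabet")
  if (length(labels) != length(probs)) stop("labels and probs differ in length")
  if (any(probs < 0)) stop("negative probabilities")
  s <- sum(probs)
  if (abs(s - 1) > 1e-9) stop(sprintf("probabilities sum to %.12g, not 1", s))
  probs <- probs / s
  structure(list(labels = labels, probs = probs), class = "distribution")
}

#' @export
print.distribution <- function(x, ...) {
  cat("<distribution over", length(x$labels), "symbols>\n")
  print(stats::setNames(x$probs, x$labels))
  invisible(x)
}

#' Information content (surprisal) of a specific outcome
#'
#' The information content of outcome `x` under a distribution `p` is
#' `-log p(x)`: the unexpectedness of that specific outcome under the model.
#' A zero-probability outcome has infinite surprisal.
#'
#' @param dist A [distribution()].
#' @param outcome A symbol present in `dist$labels`.
#' @param base `"bits"` (default, log base 2) or `"nats"`.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
surprisal <- function(dist, outcome, base = c("bits", "nats")) {
  stopifnot(inherits(dist, "distribution"))
  i <- match(as.character(outcome), dist$labels)
  if (is.na(i)) {
    stop(sprintf(
      "unknown outcome '%s'; alphabet is {%s}",
      outcome, paste(dist$labels, collapse = ", ")
    ))
  }
  p <- dist$probs[i]
  if (p == 0) return(Inf)
  from_nats(-log(p), base)
}

#' Shannon entropy of a discrete distribution
#'
#' The expectation of the surprisal, `H = -sum p log p`, with the
#' `0 log 0 = 0` convention.
#'
#' @inheritParams surprisal
#' @return Non-negative scalar.
#' @export
entropy <- function(dist, base = c("bits", "nats")) {
  stopifnot(inherits(dist, "distribution"))
  p <- dist$probs[dist$probs > 0]
  from_nats(-sum(p * log(p)), base)
}
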