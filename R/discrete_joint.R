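#' Finite joint distribution over (target, source, context)
#'
#' The definitional substrate for contrast information in the discrete case:
#' a three-axis probability mass function `p(a, b, c)` over a target alphabet
#' `A`, source alphabet `B` and context alphabet `C`. Axis order is always
#' (target, source, context).
#'
#' The mass function must be non-negative; a total differing from 1 by at most
#' `1e-9` is accepted and renormalised, anything worse is rejected as the
#' caller's bug.
#'
#' @param pmf Numeric 3-d array with `dim = c(|A|, |B|, |C|)`.
#' @param target_labels,source_labels,context_labels Character vectors naming
#'   the three alphabets (defaults: dimnames of `pmf`, else `a1..`, `b1..`,
#'   `c1..`).
#' @return An object of class `"discrete_joint"`.
#' @examples
#' pmf <- array(1 / 8, dim = c(2, 2, 2))
#' j <- discrete_joint(pmf)
#' contrast_from_joint(j, b = "b1", c = "c1") # independent => 0 bits
#' @export
discrete_joint <- function(pmf, target_labels = NULL, source_labels = NULL,
                           context_labels = NULL) {
  pmf <- as.array(pmf)
  if (length(dim(pmf)) != 3L) stop("pmf must be a 3-d array (target, source, context)")
  if (any(!is.finite(pmf)) || any(pmf < 0)) stop("pmf entries must be finite and >= 0")
  s <- sum(pmf)
  if (abs(s - 1) > 1e-9) stop(sprintf("pmf sums to %.12g, not 1", s))
  pmf <- pmf / s
  d <- dim(pmf)
  dn <- dimnames(pmf)
  target_labels <- as.character(target_labels %||% dn[[1]] %||% paste0("a", seq_len(d[1])))
  source_labels <- as.character(source_labels %||% dn[[2]] %||% paste0("b", seq_len(d[2])))
  context_labels <- as.character(context_labels %||% dn[[3]] %||% paste0("c", seq_len(d[3])))
  if (length(target_labels) != d[1] || length(source_labels) != d[2] ||
    length(context_labels) != d[3]) {
    stop("label lengths do not match pmf dimensions")
  }
  dimnames(pmf) <- list(target_labels, source_labels, context_labels)
  structure(
    list(
      target_labels = target_labels, source_labels = source_labels,
      context_labels = context_labels, pmf = pmf
    ),
    class = "discrete_joint"
  )
}

#' @export
print.discrete_joint <- function(x, ...) {
  cat(sprintf(
    "<discrete_joint: |target| = %d, |source| = %d, |context| = %d>\n",
    length(x$target_labels), length(x$source_labels), length(x$context_labels)
  ))
  invisible(x)
}

joint_index <- function(labels, sym, axis) {
  i <- match(as.character(sym), labels)
  if (is.na(i)) {
    stop(sprintf(
      "symbol '%s' not in %s alphabet {%s}",
      sym, axis, paste(labels, collapse = ", ")
    ))
  }
  i
}

#' Contrast information from a finite joint distribution
#'
#' The definitional (brute-force) evaluation of contrast information
#' `I(A; b | c)`: the relative entropy from `p(A | b, c)` to `p(A | c)`,
#' the information a specific source observation `b` provides about the target
#' regime `A` in a specific context `c`,
#' \deqn{I(A; b | c) = \sum_a p(a | b, c) \log_2 \frac{p(a | b, c)}{p(a | c)}.}
#' The `0 log 0 = 0` convention applies. If some `a` has `p(a | b, c) > 0` while
#' `p(a | c) = 0` the value is `+Inf` and a structured warning (class
#' `"contrastinfo_abscont"`) is raised: the numerator conditional is not
#' absolutely continuous with respect to the denominator.
#'
#' @param joint A [discrete_joint()].
#' @param b Source symbol (must have `p(b, c) > 0`).
#' @param c Context symbol.
#' @param base `"bits"` (default) or `"nats"`.
#' @return Non-negative scalar (possibly `Inf`).
#' @seealso [expected_contrast()] for averages over source/context and the
#'   conditional mutual information.
#' @export
contrast_from_joint <- function(joint, b, c, base = c("bits", "nats")) {
  stopifnot(inherits(joint, "discrete_joint"))
  bi <- joint_index(joint$source_labels, b, "source")
  ci <- joint_index(joint$context_labels, c, "context")
  p_abc <- joint$pmf[, bi, ci]
  p_bc <- sum(p_abc)
  if (p_bc <= 0) {
    stop(sprintf("conditioning event (b = '%s', c = '%s') has zero probability", b, c))
  }
  p_a_bc <- p_abc / p_bc
  p_ac <- rowSums(joint$pmf[, , ci, drop = FALSE])
  p_a_c <- p_ac / sum(p_ac)
  if (any(p_a_bc > 0 & p_a_c == 0)) {
    warning(structure(
      class = c("contrastinfo_abscont", "warning", "condition"),
      list(
        message = sprintf(
          "p(a | b = '%s', c = '%s') is not absolutely continuous wrt p(a | c); contrast is +Inf",
          b, c
        ),
        call = sys.call(-1)
      )
    ))
    return(Inf)
  }
  from_nats(sum(xlogxy(p_a_bc, p_a_c)), base)
}

#' Expected contrast information and conditional mutual information
#'
#' Averages contrast information over the context (leaving a specific source
#' fixed), over the source (leaving a specific context fixed), or over both.
#' Averaging over both regimes yields the conditional mutual information
#' `I(A; B | C)`.
#'
#' The weights are the correct conditionals: over the context with source `b`
#' fixed the weight of `c` is `p(c | b)`; over the source with context `c`
#' fixed the weight of `b` is `p(b | c)`.
#'
#' @param joint A [discrete_joint()].
#' @param over One of `"context"`, `"source"`, `"both"`.
#' @param fixed The non-averaged outcome: a source symbol for
#'   `over = "context"`, a context symbol for `over = "source"`, ignored for
#'   `over = "both"`.
#' @param base `"bits"` (default) or `"nats"`.
#' @return Non-negative scalar.
#' @export
expected_contrast <- function(joint, over = c("context", "source", "both"),
                              fixed = NULL, base = c("bits", "nats")) {
  stopifnot(inherits(joint, "discrete_joint"))
  over <- match.arg(over)
  pmf <- joint$pmf
  if (over == "context") {
    if (is.null(fixed)) stop("over = 'context' needs a fixed source symbol")
    bi <- joint_index(joint$source_labels, fixed, "source")
    p_b <- sum(pmf[, bi, ])
    if (p_b <= 0) stop(sprintf("source symbol '%s' has zero probability", fixed))
    p_c_b <- apply(pmf[, bi, , drop = FALSE], 3, sum) / p_b
    vals <- vapply(seq_along(joint$context_labels), function(ci) {
      if (p_c_b[ci] == 0) return(0)
      contrast_from_joint(joint, fixed, joint$context_labels[ci], base)
    }, numeric(1))
    return(sum(p_c_b * vals))
  }
  if (over == "source") {
    if (is.null(fixed)) stop("over = 'source' needs a fixed context symbol")
    ci <- joint_index(joint$context_labels, fixed, "context")
    p_c <- sum(pmf[, , ci])
    if (p_c <= 0) stop(sprintf("context symbol '%s' has zero probability", fixed))
    p_b_c <- apply(pmf[, , ci, drop = FALSE], 2, sum) / p_c
    vals <- vapply(seq_along(joint$source_labels), function(bi) {
      if (p_b_c[bi] == 0) return(0)
      contrast_from_joint(joint, joint$source_labels[bi], fixed, base)
    }, numeric(1))
    return(sum(p_b_c * vals))
  }
  # over == "both": conditional mutual information I(A; B | C)
  total <- 0
  for (ci in seq_along(joint$context_labels)) {
    p_c <- sum(pmf[, , ci])
    if (p_c == 0) next
    for (bi in seq_along(joint$source_labels)) {
      p_bc <- sum(pmf[, bi, ci])
      if (p_bc == 0) next
      total <- total + p_bc *
        contrast_from_joint(joint, joint$source_labels[bi], joint$context_labels[ci], base)
    }
  }
  total
}

#' Write / read a discrete joint as JSON
#'
#' Serialises the joint as
#' `{target_labels, source_labels, context_labels, pmf}` where `pmf` is a
#' nested array in axis order (target, source, context).
#'
#' @param joint A [discrete_joint()].
#' @param path File path.
#' @return `write_joint` returns `path` invisibly; `read_joint` returns the
#'   reconstructed [discrete_joint()].
#' @export
write_joint <- function(joint, path) {
  stopifnot(inherits(joint, "discrete_joint"))
  # nested list a -> b -> c so the JSON nesting follows the axis order
  pmf_nested <- lapply(seq_along(joint$target_labels), function(ai) {
    lapply(seq_along(joint$source_labels), function(bi) joint$pmf[ai, bi, ])
  })
  jsonlite::write_json(
    list(
      target_labels = joint$target_labels,
      source_labels = joint$source_labels,
      context_labels = joint$context_labels,
      pmf = pmf_nested
    ),
    path,
    auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_joint
#' @export
read_joint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  tl <- unlist(obj$target_labels)
  sl <- unlist(obj$source_labels)
  cl <- unlist(obj$context_labels)
  dims <- c(length(tl), length(sl), length(cl))
  # nesting is a -> b -> c, so unlist() varies c fastest, then b, then a
  pmf <- aperm(array(unlist(obj$pmf), dim = rev(dims)), 3:1)
  obj <- list(target_labels = tl, source_labels = sl, context_labels = cl)
  discrete_joint(pmf, obj$target_labels, obj$source_labels, obj$context_labels)
}
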