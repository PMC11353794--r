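#' Temporal variants of contrast information
#'
#' The six temporal variants arise from assigning the past `X`, present `Y`
#' and future `Z` regimes of a stochastic process to the (target, source,
#' context) slots of contrast information:
#'
#' * `predictive`:   target future, source present, context past — `I(Z; y | x)`
#' * `connective`:   target future, source past, context present — `I(Z; x | y)`
#' * `reflective`:   target present, source future, context past — `I(Y; z | x)`
#' * `b-predictive`: target past, source present, context future — `I(X; y | z)`
#' * `b-connective`: target past, source future, context present — `I(X; z | y)`
#' * `b-reflective`: target present, source past, context future — `I(Y; x | z)`
#'
#' @return Character vector of the six variant names.
#' @export
contrast_variants <- function() {
  c("predictive", "connective", "reflective",
    "b-predictive", "b-connective", "b-reflective")
}

# (target, source, context) regime roles per variant, in terms of x/y/z.
variant_roles <- function(variant) {
  switch(variant,
    "predictive"   = c(target = "z", source = "y", context = "x"),
    "connective"   = c(target = "z", source = "x", context = "y"),
    "reflective"   = c(target = "y", source = "z", context = "x"),
    "b-predictive" = c(target = "x", source = "y", context = "z"),
    "b-connective" = c(target = "x", source = "z", context = "y"),
    "b-reflective" = c(target = "y", source = "x", context = "z"),
    stop(sprintf(
      "unknown variant '%s'; choose one of {%s}",
      variant, paste(contrast_variants(), collapse = ", ")
    ))
  )
}

sym_index <- function(alphabet, sym, what) {
  if (is.null(sym)) stop(sprintf("variant requires the %s symbol", what))
  i <- match(as.character(sym), alphabet)
  if (is.na(i)) {
    stop(sprintf(
      "%s symbol '%s' not in alphabet {%s}",
      what, sym, paste(alphabet, collapse = ", ")
    ))
  }
  i
}

#' Stationary discrete-time Markov chain model
#'
#' A finite-alphabet DTMC parameterised by a column-stochastic transition
#' matrix `P` with `P[j, k] = P(S_{n+1} = j | S_n = k)` (each column sums
#' to 1) and its stationary distribution `pi` (`P pi = pi`). If `pi` is not
#' supplied it is computed by [stationary_distribution()], which requires the
#' chain to be irreducible and aperiodic.
#'
#' @param P Square numeric matrix, columns summing to 1 within `1e-12`.
#' @param alphabet Character vector of state names (default: dimnames or
#'   `s1..`).
#' @param pi Optional stationary vector; validated against `P`.
#' @return An object of class `"dtmc_model"`.
#' @examples
#' light <- dtmc_model(matrix(c(.95, .05, .05, .95), 2), c("RED", "GREEN"))
#' dtmc_contrast(light, "predictive", x = "RED", y = "GREEN")
#' @export
dtmc_model <- function(P, alphabet = NULL, pi = NULL) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("P must be square")
  if (any(P < 0)) stop("P has negative entries")
  cs <- colSums(P)
  if (any(abs(cs - 1) > 1e-12)) {
    stop(sprintf("columns of P must sum to 1 (max deviation %.3g)", max(abs(cs - 1))))
  }
  alphabet <- as.character(alphabet %||% rownames(P) %||% paste0("s", seq_len(nrow(P))))
  if (length(alphabet) != nrow(P)) stop("alphabet length does not match P")
  dimnames(P) <- list(alphabet, alphabet)
  m <- structure(list(alphabet = alphabet, P = P, pi = NULL), class = "dtmc_model")
  if (is.null(pi)) {
    m$pi <- tryCatch(stationary_distribution(m), error = function(e) {
      warning(sprintf("stationary distribution unavailable: %s", conditionMessage(e)))
      NULL
    })
  } else {
    pi <- as.numeric(pi)
    if (length(pi) != nrow(P) || any(pi < 0) || abs(sum(pi) - 1) > 1e-9) {
      stop("pi is not a probability vector of matching length")
    }
    pi <- pi / sum(pi)
    if (max(abs(P %*% pi - pi)) > 1e-10) stop("pi does not satisfy P pi = pi")
    m$pi <- stats::setNames(pi, alphabet)
  }
  m
}

#' @export
print.dtmc_model <- function(x, ...) {
  cat(sprintf("<dtmc_model: %d states: %s>\n", length(x$alphabet),
              paste(utils::head(x$alphabet, 8), collapse = ", ")))
  invisible(x)
}

#' Stationary continuous-time Markov chain model
#'
#' A finite-alphabet CTMC parameterised by a rate matrix `Q` with non-negative
#' off-diagonal entries and columns summing to 0; the finite-time transition
#' matrix is the matrix exponential `P(t) = exp(t Q)`. The stationary
#' distribution satisfies `Q pi = 0`.
#'
#' @param Q Square rate matrix (columns sum to 0 within `1e-12`).
#' @param alphabet Character state names.
#' @param pi Optional stationary vector; computed from the null space of `Q`
#'   when omitted.
#' @return An object of class `"ctmc_model"`.
#' @export
ctmc_model <- function(Q, alphabet = NULL, pi = NULL) {
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q)) stop("Q must be square")
  off <- Q
  diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal entries of Q must be >= 0")
  cs <- colSums(Q)
  if (any(abs(cs) > 1e-12 * max(1, max(abs(Q))))) {
    stop(sprintf("columns of Q must sum to 0 (max deviation %.3g)", max(abs(cs))))
  }
  alphabet <- as.character(alphabet %||% rownames(Q) %||% paste0("s", seq_len(nrow(Q))))
  if (length(alphabet) != nrow(Q)) stop("alphabet length does not match Q")
  dimnames(Q) <- list(alphabet, alphabet)
  m <- structure(list(alphabet = alphabet, Q = Q, pi = NULL), class = "ctmc_model")
  if (is.null(pi)) {
    m$pi <- tryCatch(stationary_distribution(m), error = function(e) {
      warning(sprintf("stationary distribution unavailable: %s", conditionMessage(e)))
      NULL
    })
  } else {
    pi <- as.numeric(pi)
    if (length(pi) != nrow(Q) || any(pi < 0) || abs(sum(pi) - 1) > 1e-9) {
      stop("pi is not a probability vector of matching length")
    }
    pi <- pi / sum(pi)
    if (max(abs(Q %*% pi)) > 1e-10) stop("pi does not satisfy Q pi = 0")
    m$pi <- stats::setNames(pi, alphabet)
  }
  m
}

#' @export
print.ctmc_model <- function(x, ...) {
  cat(sprintf("<ctmc_model: %d states: %s>\n", length(x$alphabet),
              paste(utils::head(x$alphabet, 8), collapse = ", ")))
  invisible(x)
}

# strong connectivity of the positive-support graph (irreducibility check)
strongly_connected <- function(A) {
  n <- nrow(A)
  reach <- function(M) {
    seen <- logical(n)
    seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier) > 0L) {
      nxt <- which(colSums(M[frontier, , drop = FALSE] > 0) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    seen
  }
  all(reach(A)) && all(reach(t(A)))
}

#' Stationary distribution of a Markov model
#'
#' For a DTMC, the normalised unit-eigenvalue eigenvector of `P`; for a CTMC,
#' the normalised null-space vector of `Q`. Irreducibility is checked via
#' strong connectivity of the positive-entry support graph; a DTMC must also
#' be aperiodic (no other eigenvalue of modulus 1). The returned vector is
#' verified to satisfy its defining residual within `1e-10`.
#'
#' @param model A [dtmc_model()] or [ctmc_model()].
#' @return Named probability vector with strictly positive entries.
#' @export
stationary_distribution <- function(model) UseMethod("stationary_distribution")

#' @export
stationary_distribution.dtmc_model <- function(model) {
  P <- model$P
  n <- nrow(P)
  if (!strongly_connected(P)) {
    stop("chain is reducible: positive-support graph is not strongly connected")
  }
  ev <- eigen(P)
  mods <- Mod(ev$values)
  unit <- which(abs(ev$values - 1) < 1e-8)
  if (length(unit) != 1L) stop("multiple unit eigenvalues: chain is reducible")
  if (sum(mods > 1 - 1e-8) > 1L) stop("eigenvalue of modulus 1 besides 1: chain is periodic")
  v <- Re(ev$vectors[, unit])
  v <- v / sum(v)
  if (any(v <= 0)) {
    # power-iteration fallback for numerically awkward eigenvectors
    v <- rep(1 / n, n)
    for (i in seq_len(10000)) {
      v2 <- as.numeric(P %*% v)
      v2 <- v2 / sum(v2)
      if (max(abs(v2 - v)) < 1e-14) break
      v <- v2
    }
    v <- v2
  }
  if (max(abs(P %*% v - v)) > 1e-10) stop("stationary residual exceeds 1e-10")
  if (any(v <= 0)) stop("stationary distribution has non-positive entries")
  stats::setNames(v, model$alphabet)
}

#' @export
stationary_distribution.ctmc_model <- function(model) {
  Q <- model$Q
  off <- Q
  diag(off) <- 0
  if (!strongly_connected(off)) {
    stop("chain is reducible: positive-support graph is not strongly connected")
  }
  sv <- svd(Q)
  d <- sv$d
  scale <- max(d, 1)
  if (sum(d < 1e-10 * scale) != 1L) stop("null space of Q is not one-dimensional")
  v <- sv$v[, which.min(d)]
  v <- v / sum(v)
  if (max(abs(Q %*% v)) > 1e-10 * scale) stop("stationary residual exceeds tolerance")
  if (any(v <= 0)) stop("stationary distribution has non-positive entries")
  stats::setNames(v, model$alphabet)
}

#' Time-reversed transition/rate matrix
#'
#' For a DTMC, the reverse transition matrix `R = D_pi P' D_pi^{-1}` with
#' entries `R[j, k] = pi_j P[k, j] / pi_k = P(S_n = j | S_{n+1} = k)`; every
#' column of `R` sums to 1. For a CTMC, the reverse rate matrix
#' `Q' = D_pi Q' D_pi^{-1}` analogously.
#'
#' @param model A [dtmc_model()] or [ctmc_model()].
#' @return Square matrix with the model's dimnames.
#' @export
reverse_matrix <- function(model) UseMethod("reverse_matrix")

reverse_core <- function(M, pi, alphabet) {
  if (is.null(pi)) stop("model has no stationary distribution")
  if (any(pi <= 0)) stop("zero stationary mass on some state; reverse chain undefined")
  R <- diag(pi) %*% t(M) %*% diag(1 / pi)
  dimnames(R) <- list(alphabet, alphabet)
  R
}

#' @export
reverse_matrix.dtmc_model <- function(model) reverse_core(model$P, model$pi, model$alphabet)

#' @export
reverse_matrix.ctmc_model <- function(model) reverse_core(model$Q, model$pi, model$alphabet)

# forward and backward finite-step/finite-time transition matrices
dtmc_kernels <- function(model, j, k) {
  R <- reverse_matrix(model)
  list(
    Fj = mat_pow(model$P, j), Fk = mat_pow(model$P, k),
    Fjk = mat_pow(model$P, j + k),
    Bj = mat_pow(R, j), Bk = mat_pow(R, k), Bjk = mat_pow(R, j + k)
  )
}

ctmc_kernels <- function(model, u, v) {
  Qr <- reverse_matrix(model)
  list(
    Fj = mat_exp(u * model$Q), Fk = mat_exp(v * model$Q),
    Fjk = mat_exp((u + v) * model$Q),
    Bj = mat_exp(u * Qr), Bk = mat_exp(v * Qr), Bjk = mat_exp((u + v) * Qr)
  )
}

# Closed-form contrast shared between DTMC (matrix powers) and CTMC (matrix
# exponentials). `ker` holds forward kernels over the past gap (Fj), future
# gap (Fk), full window (Fjk) and their reversed-chain counterparts.
markov_contrast_core <- function(ker, pi, alphabet, variant, x, y, z, base) {
  if (is.null(pi)) stop("model has no stationary distribution; contrast undefined")
  kl_sum <- function(p, q, what) {
    if (any(p > 0 & q <= 0)) {
      warning(sprintf("zero denominator probability in %s; contrast is +Inf", what))
      return(Inf)
    }
    sum(xlogxy(p, q))
  }
  val <- switch(variant,
    "predictive" = {
      xi <- sym_index(alphabet, x, "past"); yi <- sym_index(alphabet, y, "present")
      if (pi[xi] * ker$Fj[yi, xi] <= 0) {
        stop(sprintf("conditioning path (x = '%s', y = '%s') has zero probability", x, y))
      }
      kl_sum(ker$Fk[, yi], ker$Fjk[, xi], "p(z | x)")
    },
    "connective" = {
      # all information in the past about the future flows through the present
      0
    },
    "reflective" = {
      xi <- sym_index(alphabet, x, "past"); zi <- sym_index(alphabet, z, "future")
      pzx <- ker$Fjk[zi, xi]
      if (pi[xi] * pzx <= 0) {
        stop(sprintf("conditioning path (x = '%s', z = '%s') has zero probability", x, z))
      }
      w <- ker$Fk[zi, ] * ker$Fj[, xi] / pzx
      ratio_num <- ker$Fk[zi, ]
      ok <- w > 0
      sum(w[ok] * (log(ratio_num[ok]) - log(pzx)))
    },
    "b-predictive" = {
      yi <- sym_index(alphabet, y, "present"); zi <- sym_index(alphabet, z, "future")
      if (pi[zi] * ker$Bk[yi, zi] <= 0) {
        stop(sprintf("conditioning path (y = '%s', z = '%s') has zero probability", y, z))
      }
      kl_sum(ker$Bj[, yi], ker$Bjk[, zi], "p(x | z)")
    },
    "b-connective" = 0,
    "b-reflective" = {
      xi <- sym_index(alphabet, x, "past"); zi <- sym_index(alphabet, z, "future")
      pxz <- ker$Bjk[xi, zi]
      if (pi[zi] * pxz <= 0) {
        stop(sprintf("conditioning path (x = '%s', z = '%s') has zero probability", x, z))
      }
      w <- ker$Bj[xi, ] * ker$Bk[, zi] / pxz
      ratio_num <- ker$Bj[xi, ]
      ok <- w > 0
      sum(w[ok] * (log(ratio_num[ok]) - log(pxz)))
    },
    stop(sprintf("unknown variant '%s'", variant))
  )
  from_nats(val, base)
}

#' Closed-form contrast information of a discrete-time Markov chain
#'
#' Evaluates the `(j, k)`-step contrast information of a stationary DTMC for
#' any of the six temporal variants, with point regimes `X = S_{n-j}`,
#' `Y = S_n`, `Z = S_{n+k}`. Forward variants use matrix powers of `P`;
#' backward variants use powers of the reverse matrix `R`. The connective and
#' backward-connective variants are exactly 0 for every Markov chain: all
#' information in the past about the future is already carried by the present.
#'
#' @param model A [dtmc_model()].
#' @param variant One of [contrast_variants()].
#' @param x,y,z Past / present / future state symbols; only those required by
#'   the variant need be supplied.
#' @param j,k Positive integer step offsets into the past and future.
#' @param base `"bits"` (default) or `"nats"`.
#' @return Non-negative scalar.
#' @examples
#' light <- dtmc_model(matrix(c(.95, .05, .05, .95), 2), c("RED", "GREEN"))
#' round(dtmc_contrast(light, "predictive", x = "RED", y = "GREEN"), 2) # 2.95
#' round(dtmc_contrast(light, "predictive", x = "RED", y = "RED"), 2) # 0.02
#' @export
dtmc_contrast <- function(model, variant, x = NULL, y = NULL, z = NULL,
                          j = 1, k = 1, base = c("bits", "nats")) {
  stopifnot(inherits(model, "dtmc_model"))
  if (j < 1 || k < 1 || j != round(j) || k != round(k)) {
    stop("offsets j and k must be integers >= 1")
  }
  markov_contrast_core(
    dtmc_kernels(model, j, k), model$pi, model$alphabet,
    variant, x, y, z, match.arg(base)
  )
}

#' Closed-form contrast information of a continuous-time Markov chain
#'
#' As [dtmc_contrast()], with point regimes `X = S(t - u)`, `Y = S(t)`,
#' `Z = S(t + v)` and matrix exponentials `exp(uQ)`, `exp(vQ)`,
#' `exp((u + v)Q)` (forward) or of the reverse rate matrix (backward).
#'
#' @param model A [ctmc_model()].
#' @param variant One of [contrast_variants()].
#' @param x,y,z State symbols as required by the variant.
#' @param u,v Positive real times into the past and future.
#' @param base `"bits"` (default) or `"nats"`.
#' @return Non-negative scalar.
#' @export
ctmc_contrast <- function(model, variant, x = NULL, y = NULL, z = NULL,
                          u = 1, v = 1, base = c("bits", "nats")) {
  stopifnot(inherits(model, "ctmc_model"))
  if (u <= 0 || v <= 0) stop("offsets u and v must be > 0")
  markov_contrast_core(
    ctmc_kernels(model, u, v), model$pi, model$alphabet,
    variant, x, y, z, match.arg(base)
  )
}

#' Exact (target, source, context) joint of a Markov model window
#'
#' Assembles the exact finite joint distribution of the window
#' `(S_{n-j}, S_n, S_{n+k})` (DTMC) or `(S(t-u), S(t), S(t+v))` (CTMC) from
#' the stationary distribution and transition kernels, with axes permuted to
#' the (target, source, context) roles of the requested variant. This is the
#' bridge to the definitional oracle [contrast_from_joint()]: closed-form
#' variant values must agree with the brute-force evaluation on this joint.
#'
#' @param model A [dtmc_model()] or [ctmc_model()].
#' @param variant One of [contrast_variants()].
#' @param j,k Step offsets (DTMC) or positive times `u`, `v` (CTMC).
#' @return A [discrete_joint()].
#' @export
markov_joint <- function(model, variant, j = 1, k = 1) {
  roles <- variant_roles(variant)
  if (is.null(model$pi)) stop("model has no stationary distribution")
  if (inherits(model, "dtmc_model")) {
    Fj <- mat_pow(model$P, j)
    Fk <- mat_pow(model$P, k)
  } else if (inherits(model, "ctmc_model")) {
    Fj <- mat_exp(j * model$Q)
    Fk <- mat_exp(k * model$Q)
  } else {
    stop("model must be a dtmc_model or ctmc_model")
  }
  n <- length(model$alphabet)
  # p(x, y, z) = pi[x] * Fj[y, x] * Fk[z, y], axes (x, y, z)
  pxyz <- array(0, dim = c(n, n, n))
  for (xi in seq_len(n)) {
    for (yi in seq_len(n)) {
      pxyz[xi, yi, ] <- model$pi[xi] * Fj[yi, xi] * Fk[, yi]
    }
  }
  axes <- c(x = 1L, y = 2L, z = 3L)
  perm <- unname(axes[c(roles[["target"]], roles[["source"]], roles[["context"]])])
  discrete_joint(
    aperm(pxyz, perm),
    target_labels = model$alphabet, source_labels = model$alphabet,
    context_labels = model$alphabet
  )
}

#' Maximum-likelihood estimation of a DTMC from a symbol corpus
#'
#' Pools transition counts across all corpus sequences (each sequence is an
#' independent realisation of the same stationary chain; no across-sequence
#' transitions are counted) and normalises each column:
#' `P[j, k] = (count(k -> j) + pseudocount) /
#'   (departures from k + pseudocount * |alphabet|)`.
#'
#' @param corpus List of character vectors (or [event_sequence()] objects).
#' @param alphabet Optional ordered state alphabet; default: sorted distinct
#'   observed symbols.
#' @param pseudocount Non-negative additive smoothing count (default 0). With
#'   `pseudocount = 0` a state with no observed departures is an error, since
#'   its column is undefined.
#' @return A [dtmc_model()].
#' @export
estimate_dtmc <- function(corpus, alphabet = NULL, pseudocount = 0) {
  if (length(corpus) == 0L) stop("corpus is empty")
  seqs <- lapply(corpus, as_symbol_vector)
  syms <- unique(unlist(seqs))
  alphabet <- as.character(alphabet %||% sort(syms))
  if (!all(syms %in% alphabet)) {
    stop(sprintf(
      "symbols outside the supplied alphabet: %s",
      paste(setdiff(syms, alphabet), collapse = ", ")
    ))
  }
  n <- length(alphabet)
  counts <- matrix(0, n, n, dimnames = list(alphabet, alphabet))
  for (s in seqs) {
    if (length(s) < 2L) next
    from <- match(s[-length(s)], alphabet)
    to <- match(s[-1L], alphabet)
    counts <- counts + matrix(tabulate(to + (from - 1L) * n, nbins = n * n), n, n)
  }
  dep <- colSums(counts)
  if (pseudocount == 0 && any(dep == 0)) {
    stop(sprintf(
      "state(s) with zero departures and pseudocount 0: %s",
      paste(alphabet[dep == 0], collapse = ", ")
    ))
  }
  P <- sweep(counts + pseudocount, 2, dep + pseudocount * n, "/")
  dtmc_model(P, alphabet)
}

#' Maximum-likelihood estimation of a CTMC from timed event sequences
#'
#' The standard MLE for a stationary CTMC: for states `j != k`,
#' `q[j, k] = (number of k -> j jumps) / (total dwell time in k)`, with the
#' diagonal set so each column sums to 0. Consecutive repeats of the same
#' symbol are merged into a single dwell (a CTMC has no self-jumps).
#'
#' @param corpus List of [event_sequence()] objects (or data frames with
#'   columns `onset`, `duration`, `value`) with positive durations.
#' @param alphabet Optional ordered state alphabet.
#' @return A [ctmc_model()].
#' @export
estimate_ctmc <- function(corpus, alphabet = NULL) {
  if (length(corpus) == 0L) stop("corpus is empty")
  seqs <- lapply(corpus, as_timed_events)
  syms <- unique(unlist(lapply(seqs, function(s) as.character(s$value))))
  alphabet <- as.character(alphabet %||% sort(syms))
  if (!all(syms %in% alphabet)) {
    stop(sprintf(
      "symbols outside the supplied alphabet: %s",
      paste(setdiff(syms, alphabet), collapse = ", ")
    ))
  }
  n <- length(alphabet)
  jumps <- matrix(0, n, n, dimnames = list(alphabet, alphabet))
  dwell <- stats::setNames(numeric(n), alphabet)
  for (s in seqs) {
    v <- as.character(s$value)
    dur <- s$duration
    if (any(dur <= 0)) stop("durations must be > 0")
    # merge consecutive repeats into single dwells
    grp <- cumsum(c(TRUE, v[-1L] != v[-length(v)]))
    mv <- v[!duplicated(grp)]
    mdur <- as.numeric(tapply(dur, grp, sum))
    for (i in seq_along(mv)) dwell[mv[i]] <- dwell[mv[i]] + mdur[i]
    if (length(mv) >= 2L) {
      from <- match(mv[-length(mv)], alphabet)
      to <- match(mv[-1L], alphabet)
      for (i in seq_along(from)) jumps[to[i], from[i]] <- jumps[to[i], from[i]] + 1
    }
  }
  if (any(dwell == 0)) {
    stop(sprintf(
      "state(s) with zero dwell time: %s",
      paste(alphabet[dwell == 0], collapse = ", ")
    ))
  }
  Q <- sweep(jumps, 2, dwell, "/")
  diag(Q) <- 0
  diag(Q) <- -colSums(Q)
  ctmc_model(Q, alphabet)
}
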