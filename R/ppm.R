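#' Train a variable-order PPM model
#'
#' Prediction by Partial Matching with escape method C, backoff smoothing and
#' no update exclusion: context/follower counts for every context length
#' `0..order_bound` are accumulated over the whole corpus. The model is
#' static: it is trained once and then applied, with no online update during
#' profiling.
#'
#' @param corpus List of character vectors (or symbolic [event_sequence()]s /
#'   [link_viewpoints()] outputs).
#' @param order_bound Maximum context length (`>= 0`).
#' @param alphabet Optional ordered alphabet; default: sorted distinct
#'   observed symbols.
#' @return An object of class `"ppm_model"`.
#' @examples
#' m <- train_ppm(list(strsplit("abracadabra", "")[[1]]), order_bound = 1)
#' ppm_predict(m, "a")
#' @export
train_ppm <- function(corpus, order_bound, alphabet = NULL) {
  if (length(corpus) == 0L) stop("corpus is empty")
  order_bound <- as.integer(order_bound)
  if (order_bound < 0L) stop("order_bound must be >= 0")
  seqs <- lapply(corpus, as_symbol_vector)
  syms <- unique(unlist(seqs))
  if (length(syms) == 0L) stop("empty alphabet: corpus has no symbols")
  alphabet <- as.character(alphabet %||% sort(syms))
  if (!all(syms %in% alphabet)) {
    stop(sprintf(
      "symbols outside the supplied alphabet: %s",
      paste(setdiff(syms, alphabet), collapse = ", ")
    ))
  }
  tables <- new.env(parent = emptyenv())
  sep <- "\x1f"
  for (s in seqs) {
    n <- length(s)
    for (i in seq_len(n)) {
      for (ord in 0:min(order_bound, i - 1L)) {
        ctx <- if (ord == 0L) "" else paste(s[(i - ord):(i - 1L)], collapse = sep)
        key <- paste0(ord, sep, ctx)
        tab <- tables[[key]] %||% new.env(parent = emptyenv())
        tab[[s[i]]] <- (tab[[s[i]]] %||% 0) + 1
        tables[[key]] <- tab
      }
    }
  }
  structure(
    list(alphabet = alphabet, order_bound = order_bound,
         tables = tables, sep = sep),
    class = "ppm_model"
  )
}

#' @export
print.ppm_model <- function(x, ...) {
  cat(sprintf("<ppm_model: alphabet of %d, order bound %d>\n",
              length(x$alphabet), x$order_bound))
  invisible(x)
}

# counts stored for a context of length ord, as a named vector (or NULL)
ppm_counts <- function(model, ctx_syms) {
  ord <- length(ctx_syms)
  ctx <- if (ord == 0L) "" else paste(ctx_syms, collapse = model$sep)
  tab <- model$tables[[paste0(ord, model$sep, ctx)]]
  if (is.null(tab)) return(NULL)
  syms <- ls(tab)
  stats::setNames(vapply(syms, function(s) tab[[s]], numeric(1)), syms)
}

#' PPM-C predictive distribution for a context
#'
#' At each order the escape probability is
#' `d / (n + d)` where `n` is the total follower count and `d` the number of
#' distinct followers (escape method C); seen followers receive `count /
#' (n + d)` and the escaped mass is passed to the next-lower order over the
#' full alphabet (no update exclusion), bottoming out at a uniform order
#' `-1` distribution. An unseen context passes its whole mass down. The
#' result always sums to 1 and assigns positive probability to every alphabet
#' symbol.
#'
#' @param model A [train_ppm()] model.
#' @param context Character vector of preceding symbols (may be empty); only
#'   the last `order_bound` symbols are used.
#' @return A [distribution()] over the model alphabet.
#' @export
ppm_predict <- function(model, context = character(0)) {
  stopifnot(inherits(model, "ppm_model"))
  context <- as.character(context)
  if (length(context) > 0L && !all(context %in% model$alphabet)) {
    stop(sprintf(
      "context symbol(s) outside the alphabet: %s",
      paste(setdiff(context, model$alphabet), collapse = ", ")
    ))
  }
  if (length(context) > model$order_bound) {
    context <- context[(length(context) - model$order_bound + 1L):length(context)]
  }
  nA <- length(model$alphabet)
  probs <- rep(1 / nA, nA) # order -1 base
  names(probs) <- model$alphabet
  orders <- seq(from = 0L, to = length(context))
  # blend upward from order -1: p_k = counts/(n+d) + (d/(n+d)) * p_{k-1}
  for (ord in orders) {
    ctx_syms <- if (ord == 0L) character(0) else context[(length(context) - ord + 1L):length(context)]
    cnt <- ppm_counts(model, ctx_syms)
    if (is.null(cnt)) next # unseen context: full mass passes through
    n <- sum(cnt)
    d <- length(cnt)
    esc <- d / (n + d)
    direct <- stats::setNames(rep(0, nA), model$alphabet)
    direct[names(cnt)] <- cnt / (n + d)
    probs <- direct + esc * probs
  }
  distribution(model$alphabet, probs)
}

#' Per-event information profiles under a PPM model
#'
#' For each event `n` of a sequence, with context `x` the (order-truncated)
#' preceding symbols and `y` the observed present symbol:
#'
#' * information content `-log2 p(y | x)`;
#' * entropy of the predictive distribution `p(. | x)`;
#' * forward predictive contrast information `I(Z; y | x)` with the future
#'   regime `Z` a single next event, where the future-given-past distribution
#'   is obtained by marginalising over a hypothetical present,
#'   `p(z | x) = sum_y' p(y' | x) p(z | x, y')`;
#' * expected forward predictive contrast information
#'   `sum_y' p(y' | x) I(Z; y' | x)`.
#'
#' Because PPM-C backs off to a uniform base distribution, all probabilities
#' are positive and no value is infinite. The discrete upper bound (contrast
#' no larger than information content) holds per event.
#'
#' @param model A [train_ppm()] model.
#' @param sequence Character vector (or symbolic [event_sequence()]).
#' @return A data frame of class `"profile_pair"` with columns `event_index`,
#'   `information_content`, `entropy`, `predictive_contrast`,
#'   `expected_predictive_contrast` (all in bits).
#' @export
ppm_profiles <- function(model, sequence) {
  stopifnot(inherits(model, "ppm_model"))
  s <- as_symbol_vector(sequence)
  bad <- which(!(s %in% model$alphabet))
  if (length(bad) > 0L) {
    stop(sprintf("symbol '%s' at event %d is outside the alphabet", s[bad[1]], bad[1]))
  }
  N <- length(s)
  nA <- length(model$alphabet)
  ob <- model$order_bound
  ic <- ent <- ci <- eci <- numeric(N)
  for (n in seq_len(N)) {
    ctx <- if (n == 1L) character(0) else s[max(1L, n - ob):(n - 1L)]
    pred <- ppm_predict(model, ctx)
    py <- stats::setNames(pred$probs, pred$labels)
    ic[n] <- -log2(py[[s[n]]])
    ent[n] <- entropy(pred)
    # next-step distributions given each hypothetical present
    pz_given_y <- matrix(0, nA, nA, dimnames = list(model$alphabet, model$alphabet))
    for (yi in seq_len(nA)) {
      ctx2 <- c(ctx, model$alphabet[yi])
      pz_given_y[, yi] <- ppm_predict(model, ctx2)$probs
    }
    pz <- as.numeric(pz_given_y %*% py)
    contrasts <- vapply(seq_len(nA), function(yi) {
      sum(xlogxy(pz_given_y[, yi], pz)) / LOG2
    }, numeric(1))
    ci[n] <- contrasts[match(s[n], model$alphabet)]
    eci[n] <- sum(py * contrasts)
  }
  structure(
    data.frame(
      event_index = seq_len(N),
      information_content = ic, entropy = ent,
      predictive_contrast = ci, expected_predictive_contrast = eci
    ),
    class = c("profile_pair", "data.frame")
  )
}

#' Link aligned viewpoint streams into a product sequence
#'
#' Combines two or more aligned symbol streams event-wise into tuples (the
#' Cartesian-product "linked viewpoint"); the alphabet of the result is the
#' set of distinct observed tuples, so its size is at most the product of the
#' component alphabet sizes.
#'
#' @param ... Two or more equal-length character vectors (or symbolic
#'   [event_sequence()]s).
#' @param sep Separator used inside the tuple labels.
#' @return Character vector of linked symbols.
#' @export
link_viewpoints <- function(..., sep = "+") {
  streams <- lapply(list(...), as_symbol_vector)
  if (length(streams) < 2L) stop("need at least two streams")
  lens <- vapply(streams, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop(sprintf("stream lengths differ: %s", paste(lens, collapse = ", ")))
  }
  do.call(paste, c(streams, sep = sep))
}

#' Pearson and Spearman correlation between two information profiles
#'
#' Pairs with a non-finite value in either vector are excluded (their count
#' is reported); Spearman uses average ranks for ties.
#'
#' @param x,y Equal-length numeric vectors (at least 3 finite pairs).
#' @return List with `pearson`, `spearman`, `n_used`, `n_excluded`.
#' @export
correlate_profiles <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y differ in length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("fewer than 3 finite pairs")
  xf <- x[ok]; yf <- y[ok]
  if (stats::sd(xf) == 0 || stats::sd(yf) == 0) {
    stop("zero variance in a profile; correlation undefined")
  }
  list(
    pearson = stats::cor(xf, yf, method = "pearson"),
    spearman = stats::cor(xf, yf, method = "spearman"),
    n_used = sum(ok),
    n_excluded = sum(!ok)
  )
}
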