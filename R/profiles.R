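#' Information profile container
#'
#' A per-event (discrete time) or per-grid-point (continuous time) trace of an
#' information measure along a realised sequence: a data frame with columns
#' `event_index`, `time` (NA in discrete time), `variant`, `value_bits`,
#' ordered by index/time.
#'
#' @param event_index Integer vector.
#' @param time Numeric vector or `NA`.
#' @param variant Variant name (recycled).
#' @param value_bits Numeric values, `>= 0` or `Inf`.
#' @return A data frame of class `"info_profile"`.
#' @export
info_profile <- function(event_index, time, variant, value_bits) {
  df <- data.frame(
    event_index = as.integer(event_index),
    time = as.numeric(time),
    variant = as.character(variant),
    value_bits = as.numeric(value_bits),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("info_profile", "data.frame"))
}

#' @export
print.info_profile <- function(x, ...) {
  cat(sprintf("<info_profile: %d rows, variant(s): %s>\n",
              nrow(x), paste(unique(x$variant), collapse = ", ")))
  print.data.frame(utils::head(x, 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Write an information profile as TSV
#'
#' Columns: `event_index`, `time`, `variant`, `value_bits`.
#'
#' @param profile An [info_profile()] (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Contrast-information profile of a sequence under a Markov model
#'
#' Traces a contrast-information variant along a realised symbol sequence.
#'
#' For a DTMC with step offsets `(j, k)`, one value is produced per event that
#' has both a `j`-step past neighbour and a `k`-step future neighbour (so a
#' profile over `N` events with `j = k = 1` has `N - 2` rows); each value is
#' the corresponding single-point [dtmc_contrast()] call with
#' `x = s[n-j]`, `y = s[n]`, `z = s[n+k]` as the variant requires.
#'
#' For a CTMC the profile is a curve sampled every `grid_step` time units
#' between consecutive onsets, with point regimes placed at onsets: for the
#' predictive (and connective) scheme the past and present sit at the two most
#' recent onsets and the future sweeps the current inter-onset gap; for the
#' reflective (and backward-reflective) scheme the past and future sit at the
#' flanking onsets and the present sweeps between them; for the
#' backward-predictive scheme the present and future sit at the flanking
#' onsets and the past sweeps the preceding gap.
#'
#' @param model A [dtmc_model()] or [ctmc_model()].
#' @param sequence An [event_sequence()] or character vector of symbols.
#' @param variant One of [contrast_variants()].
#' @param j,k Integer step offsets (DTMC).
#' @param grid_step Positive sampling step for the CTMC curve.
#' @param base `"bits"` (values are reported in bits by default) or `"nats"`.
#' @return An [info_profile()].
#' @export
markov_profile <- function(model, sequence, variant, j = 1, k = 1,
                           grid_step = NULL, base = c("bits", "nats")) {
  base <- match.arg(base)
  if (inherits(model, "dtmc_model")) {
    s <- as_symbol_vector(sequence)
    check_alphabet(s, model$alphabet)
    N <- length(s)
    idx <- seq.int(j + 1L, length.out = max(0L, N - j - k))
    vals <- vapply(idx, function(n) {
      dtmc_contrast(model, variant,
        x = s[n - j], y = s[n], z = s[n + k],
        j = j, k = k, base = base
      )
    }, numeric(1))
    return(info_profile(idx, NA_real_, variant, vals))
  }
  if (!inherits(model, "ctmc_model")) stop("model must be a dtmc_model or ctmc_model")
  ev <- as_timed_events(sequence)
  v <- as.character(ev$value)
  check_alphabet(v, model$alphabet)
  if (is.null(grid_step) || grid_step <= 0) stop("ctmc profiles need a positive grid_step")
  onset <- ev$onset
  N <- length(v)
  out_i <- integer(0); out_t <- numeric(0); out_v <- numeric(0)
  sweep_between <- variant %in% c("reflective", "b-reflective")
  sweep_before <- variant == "b-predictive"
  for (i in seq_len(N - 1L)) {
    t0 <- onset[i]; t1 <- onset[i + 1L]
    if (sweep_between) {
      # past (or source) at t0, future context/source at t1, present sweeps
      ts <- seq(t0 + grid_step, t1 - grid_step / 2, by = grid_step)
      for (t in ts) {
        val <- ctmc_contrast(model, variant,
          x = v[i], z = v[i + 1L],
          u = t - t0, v = t1 - t, base = base
        )
        out_i <- c(out_i, i); out_t <- c(out_t, t); out_v <- c(out_v, val)
      }
    } else if (sweep_before) {
      # present at t0, future at t1; the past target sweeps the previous gap
      if (i == 1L) next
      tp <- onset[i - 1L]
      ts <- seq(tp + grid_step, t0 - grid_step / 2, by = grid_step)
      for (t in ts) {
        val <- ctmc_contrast(model, variant,
          y = v[i], z = v[i + 1L],
          u = t0 - t, v = t1 - t0, base = base
        )
        out_i <- c(out_i, i); out_t <- c(out_t, t); out_v <- c(out_v, val)
      }
    } else {
      # predictive / connective scheme: past at previous onset, present at the
      # most recent onset, future sweeps the current gap
      if (i == 1L) next
      u <- t0 - onset[i - 1L]
      ts <- seq(t0 + grid_step, t1 - grid_step / 2, by = grid_step)
      for (t in ts) {
        val <- ctmc_contrast(model, variant,
          x = v[i - 1L], y = v[i],
          u = u, v = t - t0, base = base
        )
        out_i <- c(out_i, i); out_t <- c(out_t, t); out_v <- c(out_v, val)
      }
    }
  }
  info_profile(out_i, out_t, variant, out_v)
}
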