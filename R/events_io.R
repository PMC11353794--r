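#' Event sequences
#'
#' The common realisation container: a sequence of events, each with a value
#' (a symbol for discrete-state processes, a real number such as a frequency
#' in Hz for continuous-state processes) and, in continuous time, an onset and
#' a positive duration. Onsets must be strictly increasing; discrete-time
#' sequences carry no onsets.
#'
#' @param value Character (symbolic) or numeric (real-valued) vector.
#' @param onset Optional strictly increasing numeric onsets.
#' @param duration Optional positive durations (required with `onset`).
#' @return A data frame of class `"event_sequence"` with attributes `kind`
#'   (`"symbolic"` or `"real"`) and `time_mode` (`"discrete"` or
#'   `"continuous"`).
#' @export
event_sequence <- function(value, onset = NULL, duration = NULL) {
  kind <- if (is.numeric(value)) "real" else "symbolic"
  if (kind == "symbolic") value <- as.character(value)
  n <- length(value)
  if (n == 0L) stop("empty event sequence")
  if (is.null(onset) != is.null(duration)) {
    stop("onset and duration must be supplied together")
  }
  if (!is.null(onset)) {
    onset <- as.numeric(onset)
    duration <- as.numeric(duration)
    if (length(onset) != n || length(duration) != n) {
      stop("onset/duration lengths do not match values")
    }
    bad <- which(diff(onset) <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("onsets not strictly increasing at event %d", bad[1] + 1L))
    }
    bad <- which(duration <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("non-positive duration at event %d", bad[1]))
    }
    df <- data.frame(onset = onset, duration = duration, value = value,
                     stringsAsFactors = FALSE)
    time_mode <- "continuous"
  } else {
    df <- data.frame(value = value, stringsAsFactors = FALSE)
    time_mode <- "discrete"
  }
  structure(df, class = c("event_sequence", "data.frame"),
            kind = kind, time_mode = time_mode)
}

#' @export
print.event_sequence <- function(x, ...) {
  cat(sprintf("<event_sequence: %d %s events, %s time>\n",
              nrow(x), attr(x, "kind"), attr(x, "time_mode")))
  print.data.frame(utils::head(x, 8), ...)
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

as_symbol_vector <- function(x) {
  if (inherits(x, "event_sequence")) return(as.character(x$value))
  if (is.data.frame(x)) return(as.character(x$value))
  as.character(x)
}

as_numeric_vector <- function(x) {
  if (inherits(x, "event_sequence") || is.data.frame(x)) return(as.numeric(x$value))
  as.numeric(x)
}

as_timed_events <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("onset", "duration", "value") %in% names(x))) {
      stop("timed events need onset, duration and value columns")
    }
    return(x)
  }
  stop("expected an event_sequence (or data frame) with onsets")
}

check_alphabet <- function(syms, alphabet) {
  bad <- which(!(syms %in% alphabet))
  if (length(bad) > 0L) {
    stop(sprintf(
      "symbol '%s' at event %d is not in the model alphabet", syms[bad[1]], bad[1]
    ))
  }
  invisible(TRUE)
}

#' Equal-temperament MIDI-note to frequency mapping
#'
#' `f = 440 * 2^((m - 69) / 12)` Hz; note 69 (A4) maps to 440 Hz.
#'
#' @param m Numeric MIDI note number(s).
#' @return Frequency in Hz.
#' @export
midi_to_hz <- function(m) 440 * 2^((as.numeric(m) - 69) / 12)

#' Read and write event sequences
#'
#' CSV files use the header `onset,duration,value`; rows with empty `onset`
#' and `duration` yield a discrete-time sequence. JSON files store
#' `{values, onsets, durations, kind}`. Standard MIDI files (monophonic,
#' read-only) are mapped to either the note-number symbols (`mode =
#' "symbolic"`) or fundamental frequencies in Hz via [midi_to_hz()]
#' (`mode = "real"`), with onsets/durations in quarter-note units.
#' `read_events(write_events(x))` is the identity for CSV and JSON.
#'
#' @param path File path.
#' @param format `"csv"`, `"json"` or `"midi"` (default: from the file
#'   extension).
#' @param mode For MIDI input: `"symbolic"` or `"real"`.
#' @return An [event_sequence()]; `write_events` returns `path` invisibly.
#' @export
read_events <- function(path, format = NULL, mode = c("symbolic", "real")) {
  format <- format %||% switch(tolower(tools::file_ext(path)),
    "csv" = "csv", "json" = "json", "mid" = "midi", "midi" = "midi",
    stop("cannot infer format from extension; pass format=")
  )
  mode <- match.arg(mode)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!identical(names(df)[1:3], c("onset", "duration", "value"))) {
      stop("CSV header must be onset,duration,value")
    }
    value <- utils::type.convert(df$value, as.is = TRUE)
    if (all(df$onset == "")) return(event_sequence(value))
    onset <- suppressWarnings(as.numeric(df$onset))
    duration <- suppressWarnings(as.numeric(df$duration))
    bad <- which(is.na(onset) | is.na(duration))
    if (length(bad) > 0L) stop(sprintf("malformed row at line %d", bad[1] + 1L))
    return(event_sequence(value, onset, duration))
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    value <- if (identical(obj$kind, "real")) as.numeric(obj$values) else as.character(obj$values)
    if (is.null(obj$onsets) || length(obj$onsets) == 0L) {
      return(event_sequence(value))
    }
    return(event_sequence(value, obj$onsets, obj$durations))
  }
  read_midi_events(path, mode)
}

#' @rdname read_events
#' @param x An [event_sequence()].
#' @export
write_events <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "event_sequence"))
  format <- format %||% switch(tolower(tools::file_ext(path)),
    "csv" = "csv", "json" = "json",
    stop("cannot infer format from extension; pass format=")
  )
  if (format == "csv") {
    if (attr(x, "time_mode") == "continuous") {
      df <- data.frame(onset = x$onset, duration = x$duration, value = x$value)
    } else {
      df <- data.frame(onset = "", duration = "", value = x$value)
    }
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (format == "json") {
    obj <- list(values = x$value, kind = attr(x, "kind"))
    if (attr(x, "time_mode") == "continuous") {
      obj$onsets <- x$onset
      obj$durations <- x$duration
    }
    jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  } else {
    stop("write_events supports csv and json")
  }
  invisible(path)
}

# ---- minimal monophonic Standard MIDI File reader -------------------------

read_varlen <- function(bytes, pos) {
  val <- 0
  repeat {
    b <- as.integer(bytes[pos])
    pos <- pos + 1L
    val <- val * 128 + (b %% 128L)
    if (b < 128L) break
  }
  list(value = val, pos = pos)
}

be_int <- function(bytes, pos, n) {
  sum(as.integer(bytes[pos:(pos + n - 1L)]) * 256^((n - 1L):0))
}

read_midi_events <- function(path, mode) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(bytes[1:4]) != "MThd") stop("not a standard MIDI file")
  division <- be_int(bytes, 13L, 2L)
  if (division >= 32768) stop("SMPTE time division not supported")
  ntrks <- be_int(bytes, 11L, 2L)
  pos <- 15L
  notes <- data.frame(onset = numeric(0), duration = numeric(0), note = integer(0))
  for (trk in seq_len(ntrks)) {
    if (rawToChar(bytes[pos:(pos + 3L)]) != "MTrk") stop("malformed MIDI track header")
    len <- be_int(bytes, pos + 4L, 4L)
    p <- pos + 8L
    trk_end <- p + len
    tick <- 0
    status <- 0L
    active <- list() # note number -> onset tick
    while (p < trk_end) {
      vl <- read_varlen(bytes, p)
      tick <- tick + vl$value
      p <- vl$pos
      b <- as.integer(bytes[p])
      if (b >= 128L) {
        status <- b
        p <- p + 1L
      }
      hi <- status %/% 16L
      if (status == 255L) { # meta event
        p <- p + 1L # type byte
        vl <- read_varlen(bytes, p)
        p <- vl$pos + vl$value
      } else if (status %in% c(240L, 247L)) { # sysex
        vl <- read_varlen(bytes, p)
        p <- vl$pos + vl$value
      } else if (hi %in% c(8L, 9L)) { # note off / note on
        note <- as.integer(bytes[p])
        vel <- as.integer(bytes[p + 1L])
        p <- p + 2L
        key <- as.character(note)
        if (hi == 9L && vel > 0L) {
          if (length(active) > 0L) stop("polyphonic MIDI not supported (melodies only)")
          active[[key]] <- tick
        } else if (!is.null(active[[key]])) {
          notes <- rbind(notes, data.frame(
            onset = active[[key]] / division,
            duration = (tick - active[[key]]) / division,
            note = note
          ))
          active[[key]] <- NULL
        }
      } else if (hi %in% c(10L, 11L, 14L)) {
        p <- p + 2L
      } else if (hi %in% c(12L, 13L)) {
        p <- p + 1L
      } else {
        stop("malformed MIDI event")
      }
    }
    pos <- trk_end
  }
  if (nrow(notes) == 0L) stop("no notes found in MIDI file")
  notes <- notes[order(notes$onset), ]
  value <- if (mode == "real") midi_to_hz(notes$note) else as.character(notes$note)
  event_sequence(value, notes$onset, notes$duration)
}
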