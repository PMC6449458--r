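#' Slice a score into sonorities
#'
#' Creates one sonority (vertical chord slice) at every distinct onset time in
#' any voice, with no reduction: ornamental and passing notes all generate
#' slices. Each slice records all pitches sounding at that instant, the subset
#' that is newly struck there, and per-pitch notated durations expressed in
#' beats of the prevailing meter (for held or tied tones, the remaining notated
#' duration from the slice onset).
#'
#' @param sc a [score] object.
#' @return An object of class `sonority_stream`: a list with `sonorities` (a
#'   data.frame with list-columns `pitches`, `new_pitches`, `dur_beats`),
#'   `n_beats` (beats per measure), `beat_wholes` and `seconds_per_beat`.
#' @export
chordify <- function(sc) {
  ev <- sc$events
  onsets <- sort(unique(ev$onset_ticks))
  ts <- meter_at(sc, onsets[1L])
  bw_ticks <- wholes_to_ticks(beat_wholes_for(ts$numerator, ts$denominator))
  ends <- ev$onset_ticks + ev$duration_ticks
  pos <- score_positions(sc, onsets)
  n <- length(onsets)
  pitches <- new_pitches <- dur_beats <- vector("list", n)
  for (i in seq_len(n)) {
    t <- onsets[i]
    sounding <- which(ev$onset_ticks <= t & (ends > t | (ev$grace & ev$onset_ticks == t)))
    new <- which(ev$onset_ticks == t)
    ps <- sort(unique(ev$pitch[sounding]))
    # per sounding pitch: remaining notated duration in beats (grace notes,
    # having zero duration, are excluded from the duration bookkeeping)
    db <- vapply(ps, function(p) {
      idx <- sounding[ev$pitch[sounding] == p & !ev$grace[sounding]]
      if (!length(idx)) return(NA_real_)
      max(ends[idx] - t) / bw_ticks
    }, numeric(1))
    pitches[[i]] <- ps
    new_pitches[[i]] <- sort(unique(ev$pitch[new]))
    dur_beats[[i]] <- db
  }
  son <- data.frame(index = seq_len(n) - 1L, onset_ticks = onsets,
                    measure = pos$measure, beat = pos$beat)
  son$pitches <- pitches
  son$new_pitches <- new_pitches
  son$dur_beats <- dur_beats
  tempo <- tryCatch(resolve_tempo(sc), error = function(e) NULL)
  structure(list(
    sonorities = son,
    numerator = ts$numerator,
    denominator = ts$denominator,
    n_beats = measure_wholes_for(ts$numerator, ts$denominator) /
      beat_wholes_for(ts$numerator, ts$denominator),
    beat_wholes = beat_wholes_for(ts$numerator, ts$denominator),
    measure_ticks = wholes_to_ticks(measure_wholes_for(ts$numerator, ts$denominator)),
    seconds_per_beat = if (!is.null(tempo)) tempo$seconds_per_beat else NA_real_,
    fast_tempo = if (!is.null(tempo)) tempo$fast else FALSE,
    flags = sc$flags
  ), class = "sonority_stream")
}

#' @export
print.sonority_stream <- function(x, ...) {
  cat(sprintf("<sonority_stream> %d sonorities, %g beats/measure\n",
              nrow(x$sonorities), x$n_beats))
  invisible(x)
}

#' Extract the melodic line from a score
#'
#' @param sc a [score] object.
#' @param strategy `"skyline"` (default; the highest newly struck pitch at
#'   each sonority), `"top_voice"` (the voice whose label sorts highest), or
#'   `"named_voice"` (an explicit voice label via `voice`).
#' @param voice voice label, required for `strategy = "named_voice"`.
#' @return data.frame of melody notes (columns `onset_ticks`, `duration_ticks`,
#'   `pitch`, `measure`, `beat`), time-ordered and monophonic.
#' @export
extract_melody <- function(sc, strategy = c("skyline", "top_voice", "named_voice"),
                           voice = NULL) {
  strategy <- match.arg(strategy)
  ev <- sc$events[!sc$events$grace, , drop = FALSE]
  if (strategy == "named_voice") {
    if (is.null(voice) || !voice %in% ev$voice) {
      stop("voice '", voice %||% "<missing>", "' not found; available voices: ",
           paste(sort(unique(ev$voice)), collapse = ", "))
    }
    mel <- ev[ev$voice == voice, , drop = FALSE]
    mel <- mel[order(mel$onset_ticks, -mel$pitch), , drop = FALSE]
    mel <- mel[!duplicated(mel$onset_ticks), , drop = FALSE]
  } else if (strategy == "top_voice") {
    v <- sort(unique(ev$voice))[1L]
    return(extract_melody(sc, "named_voice", voice = v))
  } else {
    mel <- ev[order(ev$onset_ticks, -ev$pitch), , drop = FALSE]
    mel <- mel[!duplicated(mel$onset_ticks), , drop = FALSE]
  }
  rownames(mel) <- NULL
  mel[, c("onset_ticks", "duration_ticks", "pitch", "voice", "measure", "beat")]
}
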