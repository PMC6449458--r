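#' Construct a symbolic score object
#'
#' A `score` is the uniform internal representation every reader produces and
#' every analysis consumes: a table of note events on an exact rational time
#' grid, plus meter, tempo and style metadata.
#'
#' @param events data.frame with columns `onset` (whole-note units from piece
#'   start), `duration` (whole-note units, > 0 except grace notes), `pitch`
#'   (integer MIDI semitones, middle C = 60), and optionally `voice`,
#'   `measure`, `beat`, `tied`, `grace`. Onsets/durations may also be supplied
#'   pre-converted as integer ticks via `onset_ticks`/`duration_ticks`.
#' @param time_signatures data.frame with columns `onset` (wholes), `numerator`,
#'   `denominator`; at least one row is required.
#' @param bpm numeric beats per minute for the notated beat, or `NA` if only a
#'   tempo word is known.
#' @param tempo_word character tempo indication (e.g. "Andante"), or `NA`.
#' @param style one of `"baroque_classical"`, `"romantic"`, `"late_romantic"`.
#' @param half_time_signature logical; piece notated in a half time signature
#'   (doubles the harmonic-surprise window and the beats-per-bar count).
#' @param consonant_passing_tones logical; piece dominated by consonant passing
#'   tones of beat-comparable duration (halves notated durations for the
#'   horizontal harmonic accent).
#' @param anchor onset (wholes) of the notated downbeat of measure 1; defaults
#'   to 0. Used to phase-align the metrical grid when the piece has an
#'   anacrusis.
#' @return An object of class `score`.
#' @export
score <- function(events, time_signatures, bpm = NA_real_,
                  tempo_word = NA_character_,
                  style = c("romantic", "baroque_classical", "late_romantic"),
                  half_time_signature = FALSE,
                  consonant_passing_tones = FALSE,
                  anchor = 0) {
  style <- match.arg(style)
  if (is.null(time_signatures) || nrow(time_signatures) < 1L) {
    stop("a score needs at least one time signature; supply one via the ",
         "`time_signatures` argument or a config override")
  }
  ev <- as.data.frame(events)
  if (!nrow(ev)) stop("a score needs at least one note event")
  if (is.null(ev$onset_ticks)) ev$onset_ticks <- wholes_to_ticks(ev$onset)
  if (is.null(ev$duration_ticks)) ev$duration_ticks <- wholes_to_ticks(ev$duration)
  ev$onset <- NULL; ev$duration <- NULL
  ev$pitch <- as.integer(ev$pitch)
  ev$voice <- as.character(ev$voice %||% "1")
  ev$tied <- as.logical(ev$tied %||% FALSE)
  ev$grace <- as.logical(ev$grace %||% FALSE)
  stopifnot(all(ev$onset_ticks >= 0), all(ev$pitch >= 0 & ev$pitch <= 127))
  if (any(ev$duration_ticks <= 0 & !ev$grace)) {
    stop("non-grace events must have positive duration")
  }
  ts <- data.frame(
    onset_ticks = wholes_to_ticks(time_signatures$onset %||% 0),
    numerator = as.integer(time_signatures$numerator),
    denominator = as.integer(time_signatures$denominator)
  )
  ts <- ts[order(ts$onset_ticks), , drop = FALSE]
  ev <- ev[order(ev$onset_ticks, ev$voice, ev$pitch), , drop = FALSE]
  rownames(ev) <- NULL
  sc <- structure(
    list(events = ev, time_signatures = ts, bpm = as.numeric(bpm),
         tempo_word = as.character(tempo_word), style = style,
         flags = list(half_time_signature = isTRUE(half_time_signature),
                      consonant_passing_tones = isTRUE(consonant_passing_tones)),
         anchor_ticks = wholes_to_ticks(anchor)),
    class = "score")
  if (is.null(ev$measure) || is.null(ev$beat) ||
      anyNA(ev$measure) || anyNA(ev$beat)) {
    pos <- score_positions(sc, sc$events$onset_ticks)
    sc$events$measure <- pos$measure
    sc$events$beat <- pos$beat
  }
  sc
}

#' @export
print.score <- function(x, ...) {
  ts1 <- x$time_signatures[1L, ]
  cat(sprintf("<score> %d events, %s voice(s), %d/%d, %s, style=%s\n",
              nrow(x$events), length(unique(x$events$voice)),
              ts1$numerator, ts1$denominator,
              if (!is.na(x$bpm)) paste0(x$bpm, " bpm")
              else if (!is.na(x$tempo_word)) x$tempo_word else "tempo n/a",
              x$style))
  invisible(x)
}

# Prevailing time signature at a tick.
meter_at <- function(sc, tick) {
  ts <- sc$time_signatures
  i <- findInterval(tick, ts$onset_ticks)
  if (i < 1L) i <- 1L
  ts[i, , drop = FALSE]
}

# Measure number (1-based) and beat-in-measure (1-based, possibly fractional)
# for a vector of ticks, honouring meter changes and the measure-1 anchor.
score_positions <- function(sc, ticks) {
  ts <- sc$time_signatures
  anchor <- sc$anchor_ticks
  # measure index accumulated across signature segments
  seg_start <- pmax(ts$onset_ticks, anchor)
  meas_len <- wholes_to_ticks(measure_wholes_for(ts$numerator, ts$denominator))
  # measures elapsed before each segment begins
  n_before <- integer(nrow(ts))
  if (nrow(ts) > 1L) {
    for (k in 2:nrow(ts)) {
      span <- seg_start[k] - seg_start[k - 1L]
      n_before[k] <- n_before[k - 1L] + span %/% meas_len[k - 1L] +
        as.integer(span %% meas_len[k - 1L] > 0)
    }
  }
  measure <- integer(length(ticks)); beat <- numeric(length(ticks))
  for (j in seq_along(ticks)) {
    t <- ticks[j]
    i <- findInterval(t, ts$onset_ticks); if (i < 1L) i <- 1L
    bw <- wholes_to_ticks(beat_wholes_for(ts$numerator[i], ts$denominator[i]))
    rel <- t - seg_start[i]
    if (rel < 0) { # anacrusis before the anchored downbeat: count backwards
      m_off <- -((-rel + meas_len[i] - 1L) %/% meas_len[i])
    } else {
      m_off <- rel %/% meas_len[i]
    }
    in_meas <- rel - m_off * meas_len[i]
    measure[j] <- 1L + n_before[i] + as.integer(m_off)
    beat[j] <- 1 + in_meas / bw
  }
  list(measure = measure, beat = beat)
}

# Tick at which a given measure starts (constant-meter fast path used by the
# melodic window rule; falls back to segment arithmetic for meter changes).
measure_start_tick <- function(sc, measure) {
  ts <- sc$time_signatures
  meas_len <- wholes_to_ticks(measure_wholes_for(ts$numerator[1L],
                                                 ts$denominator[1L]))
  sc$anchor_ticks + (measure - 1L) * meas_len
}

#' Resolve the working tempo of a score
#'
#' Converts notated tempo (explicit beats per minute or an Italian tempo word)
#' into seconds per beat, and decides whether the piece counts as fast for the
#' duration-halving rule. Explicit bpm overrides the word; the word still
#' drives the fast/slow classification when present.
#'
#' @param sc a [score] object.
#' @param tempo_map named numeric vector mapping lower-case tempo words to bpm;
#'   defaults to Largo 50, Adagio 60, Andante 72, Andantino 80, Moderato 96,
#'   Allegretto 112, Allegro 132, Vivace 152, Presto 180.
#' @param fast_bpm numeric; a purely numeric tempo at or above this bpm counts
#'   as fast (default 112, the Allegretto mapping).
#' @return list with `bpm`, `seconds_per_beat`, `fast` (logical), `word`.
#' @export
resolve_tempo <- function(sc, tempo_map = default_tempo_map(), fast_bpm = 112) {
  word <- if (!is.na(sc$tempo_word)) tolower(trimws(sc$tempo_word)) else NA_character_
  bpm <- sc$bpm
  if (is.na(bpm)) {
    if (is.na(word)) stop("score has neither a numeric tempo nor a tempo word")
    if (!word %in% names(tempo_map)) {
      stop("unknown tempo word '", sc$tempo_word,
           "'; extend `tempo_map` or set an explicit bpm")
    }
    bpm <- unname(tempo_map[[word]])
  }
  fast <- if (!is.na(word)) word %in% fast_tempo_words() else bpm >= fast_bpm
  list(bpm = bpm, seconds_per_beat = 60 / bpm, fast = fast, word = word)
}
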