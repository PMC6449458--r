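# Deterministic synthetic fixtures: metrically gridded scores, controlled
# melodies, chord-template progressions, a hand-encoded melodic skeleton of
# Chopin's A-major prelude (Op. 28 No. 7), synthetic rater marks, and a small
# synthetic familiarity table. Every generator is a pure function of its
# arguments and seed.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Metrically gridded score fixture
#'
#' A monophonic score with a note on every chosen subdivision of every
#' measure, plus ground-truth metrical-level marks (attribute
#' `ground_truth$levels`, 0-based level indices per note).
#'
#' @param numerator,denominator time signature (one of the nine supported).
#' @param n_measures number of measures.
#' @param bpm tempo in beats per minute.
#' @param subdivision_wholes spacing of the notes in whole-note units
#'   (default: the Level-0 pulse, i.e. every smallest subdivision).
#' @param pitch constant pitch of the notes.
#' @return a [score] with a `ground_truth` attribute.
#' @export
generate_metrical_grid <- function(numerator = 3, denominator = 4,
                                   n_measures = 4, bpm = 60,
                                   subdivision_wholes = NULL, pitch = 72) {
  grid <- pulse_grid(numerator, denominator, 60 / bpm)  # errors if unsupported
  sub_w <- subdivision_wholes %||% grid$level_wholes[1]
  meas_w <- measure_wholes_for(numerator, denominator)
  onsets <- seq(0, n_measures * meas_w - sub_w, by = sub_w)
  ev <- data.frame(onset = onsets, duration = sub_w, pitch = pitch,
                   voice = "1")
  sc <- score(ev, data.frame(onset = 0, numerator = numerator,
                             denominator = denominator), bpm = bpm)
  lv_ticks <- wholes_to_ticks(grid$level_wholes)
  levels <- lapply(wholes_to_ticks(onsets), function(t)
    which(t %% lv_ticks == 0L) - 1L)
  attr(sc, "ground_truth") <- list(levels = levels)
  sc
}

#' Random-walk melody fixture
#'
#' A monophonic beat-grained melody whose intervals are drawn from a
#' controllable leap distribution, with ground-truth contour annotations
#' (attribute `ground_truth`: logical `peak`/`valley` per note from a
#' local-extrema scan).
#'
#' @param n_notes number of notes (>= 2).
#' @param seed RNG seed.
#' @param numerator,denominator time signature; one note per beat.
#' @param bpm tempo.
#' @param start_pitch first pitch.
#' @param intervals candidate signed intervals in semitones.
#' @param interval_weights sampling weights (default favours steps over
#'   leaps, 1/(1+|interval|)).
#' @param range clip range for pitches.
#' @return a [score] with a `ground_truth` attribute.
#' @export
generate_melody <- function(n_notes = 24, seed = 1, numerator = 3,
                            denominator = 4, bpm = 72, start_pitch = 72,
                            intervals = c(-12, -9, -7, -5, -4, -3, -2, -1,
                                          1, 2, 3, 4, 5, 7, 9, 12),
                            interval_weights = NULL, range = c(48, 96)) {
  stopifnot(n_notes >= 2)
  w <- interval_weights %||% (1 / (1 + abs(intervals)))
  pitches <- with_seed(seed, {
    p <- numeric(n_notes)
    p[1] <- start_pitch
    for (i in 2:n_notes) {
      step <- sample(intervals, 1, prob = w)
      p[i] <- min(max(p[i - 1] + step, range[1]), range[2])
    }
    p
  })
  bw <- beat_wholes_for(numerator, denominator)
  ev <- data.frame(onset = (seq_len(n_notes) - 1) * bw, duration = bw,
                   pitch = pitches, voice = "1")
  sc <- score(ev, data.frame(onset = 0, numerator = numerator,
                             denominator = denominator), bpm = bpm)
  d <- diff(pitches)
  peak <- valley <- rep(FALSE, n_notes)
  for (i in 2:(n_notes - 1)) {
    peak[i] <- d[i - 1] > 0 && d[i] < 0
    valley[i] <- d[i - 1] < 0 && d[i] > 0
  }
  attr(sc, "ground_truth") <- list(peak = peak, valley = valley)
  sc
}

# chord templates by name (Tn intervals above the root)
chord_templates <- function() {
  list(major = c(0, 4, 7), minor = c(0, 3, 7), dim = c(0, 3, 6),
       aug = c(0, 4, 8), dom7 = c(0, 4, 7, 10), maj7 = c(0, 4, 7, 11),
       min7 = c(0, 3, 7, 10), dim7 = c(0, 3, 6, 9), sus4 = c(0, 5, 7),
       cluster = c(0, 1, 2), fifth = c(0, 7), single = 0)
}

#' Chord-progression fixture
#'
#' A homophonic sequence of chords built from named Tn-type templates, with
#' optional held (tied) tones and an optional moving second voice, plus
#' ground-truth Tn types per slice (attribute `ground_truth$tn`).
#'
#' @param templates character vector of template names (see source) cycled
#'   over the chords, or `NULL` to sample them.
#' @param n_chords number of chords (default `length(templates)`).
#' @param seed RNG seed (used for sampled templates/roots).
#' @param roots integer root pitches (default: sampled around middle C).
#' @param duration_beats chord duration in beats (scalar or per chord).
#' @param held_from indices i such that the lowest tone of chord i is held
#'   through chord i+1 (tied, not re-struck).
#' @param two_voice logical; if `TRUE`, emit a bass voice holding each chord
#'   root for a whole measure under an upper voice striking the remaining
#'   chord tones per beat, creating distinct onset patterns per voice.
#' @param numerator,denominator,bpm meter and tempo.
#' @return a [score] with a `ground_truth` attribute.
#' @export
generate_progression <- function(templates = c("major", "major", "minor",
                                               "major"),
                                 n_chords = NULL, seed = 1, roots = NULL,
                                 duration_beats = 1, held_from = integer(0),
                                 two_voice = FALSE, numerator = 4,
                                 denominator = 4, bpm = 96) {
  tmpl <- chord_templates()
  n_chords <- n_chords %||% length(templates)
  vals <- with_seed(seed, {
    tnames <- if (is.null(templates)) {
      sample(names(tmpl), n_chords, replace = TRUE)
    } else rep_len(templates, n_chords)
    rts <- roots %||% (60L + sample(-5:6, n_chords, replace = TRUE))
    list(tnames = tnames, roots = rep_len(as.integer(rts), n_chords))
  })
  bad <- setdiff(vals$tnames, names(tmpl))
  if (length(bad)) {
    stop("unknown chord template(s): ", paste(unique(bad), collapse = ", "),
         "; available: ", paste(names(tmpl), collapse = ", "))
  }
  bw <- beat_wholes_for(numerator, denominator)
  dur_b <- rep_len(duration_beats, n_chords)
  onset_b <- cumsum(c(0, dur_b[-n_chords]))
  ev <- list()
  held_pitch <- NA_integer_  # pitch currently tied over from the last chord
  for (i in seq_len(n_chords)) {
    ps <- vals$roots[i] + tmpl[[vals$tnames[i]]]
    dur <- dur_b[i]
    ps_rest <- ps
    if (!is.na(held_pitch)) {  # tone sounding from the previous chord
      ps_rest <- setdiff(ps_rest, held_pitch)
      held_pitch <- NA_integer_
    }
    if (i %in% held_from && i < n_chords) {
      # lowest remaining tone extends through the next chord
      hp <- min(ps_rest)
      ev[[length(ev) + 1L]] <- data.frame(
        onset = onset_b[i] * bw, duration = (dur + dur_b[i + 1L]) * bw,
        pitch = hp, voice = "bass", tied = TRUE)
      ps_rest <- setdiff(ps_rest, hp)
      held_pitch <- hp
    } else if (two_voice && length(ps_rest) > 1L) {
      ev[[length(ev) + 1L]] <- data.frame(
        onset = onset_b[i] * bw, duration = dur * bw, pitch = min(ps_rest),
        voice = "bass", tied = FALSE)
      ps_rest <- setdiff(ps_rest, min(ps_rest))
    }
    for (p in ps_rest) {
      ev[[length(ev) + 1L]] <- data.frame(onset = onset_b[i] * bw,
                                          duration = dur * bw, pitch = p,
                                          voice = "upper", tied = FALSE)
    }
  }
  ev <- do.call(rbind, ev)
  if (two_voice) {
    # bass moves at measure grain: merge bass notes within a measure into one
    # held note to create voices with different onset patterns
    meas_w <- measure_wholes_for(numerator, denominator)
    b <- ev[ev$voice == "bass", , drop = FALSE]
    u <- ev[ev$voice == "upper", , drop = FALSE]
    b$meas <- floor(b$onset / meas_w)
    bm <- do.call(rbind, lapply(split(b, b$meas), function(g) {
      data.frame(onset = min(g$onset),
                 duration = max(g$onset + g$duration) - min(g$onset),
                 pitch = g$pitch[which.min(g$onset)], voice = "bass",
                 tied = FALSE)
    }))
    ev <- rbind(bm, u)
  }
  sc <- score(ev, data.frame(onset = 0, numerator = numerator,
                             denominator = denominator), bpm = bpm)
  stream <- chordify(sc)
  attr(sc, "ground_truth") <- list(
    tn = lapply(stream$sonorities$pitches, tn_type),
    templates = vals$tnames, roots = vals$roots)
  sc
}

#' Melodic skeleton of Chopin's Prelude Op. 28 No. 7
#'
#' A hand-encoded 12-measure monophonic skeleton in 3/4 (one quarter note per
#' beat) consistent with the melodic landmarks of the piece: the rising major
#' sixth E4 to C#5 into measure 1, the perfect fifth B4 to F#5 at the end of
#' measure 2, the perfect fourth E5 to A5 on beat 2 of measure 3, a contour
#' valley at measure 6 beat 3, measure 9 repeating measure 1, and the melodic
#' climax C#6 on beat 2 of measure 11. It is a synthetic skeleton, not an
#' edition of the piece.
#'
#' @return a [score] (monophonic, style `"romantic"`, Andantino).
#' @export
prelude7_skeleton <- function() {
  pitches <- c(
    64, 73, 71,   # m1:  E4  C#5 B4   (M6 leap into C#5)
    69, 71, 78,   # m2:  A4  B4  F#5  (P5 leap into F#5 at the measure end)
    76, 81, 76,   # m3:  E5  A5  E5   (P4 leap into A5 on beat 2)
    73, 74, 73,   # m4:  C#5 D5  C#5
    71, 73, 69,   # m5:  B4  C#5 A4
    71, 68, 59,   # m6:  B4  G#4 B3   (contour valley on beat 3)
    64, 69, 71,   # m7:  E4  A4  B4
    73, 71, 69,   # m8:  C#5 B4  A4
    64, 73, 71,   # m9:  = m1
    69, 71, 76,   # m10: A4  B4  E5
    80, 85, 81,   # m11: G#5 C#6 A5   (climax C#6 on beat 2)
    76, 73, 69)   # m12: E5  C#5 A4
  ev <- data.frame(onset = (seq_along(pitches) - 1) / 4, duration = 1 / 4,
                   pitch = pitches, voice = "1")
  score(ev, data.frame(onset = 0, numerator = 3, denominator = 4),
        tempo_word = "Andantino", style = "romantic")
}

#' Synthetic rater marks around a ground-truth accent vector
#'
#' Each rater is `round(clip(truth + noise, 0, 5))` with i.i.d. Gaussian
#' noise, followed by independent per-note dropout (a dropped mark becomes
#' 0) with probability `1 - mark_prob`.
#'
#' @param truth numeric vector of true saliences (one per note).
#' @param n_raters number of raters (>= 1).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param mark_prob probability that a rater keeps a (nonzero) mark.
#' @param seed RNG seed.
#' @return numeric matrix, raters in rows, notes in columns.
#' @export
generate_ratings <- function(truth, n_raters = 5, noise_sd = 1,
                             mark_prob = 1, seed = 1) {
  stopifnot(n_raters >= 1, noise_sd >= 0, mark_prob > 0, mark_prob <= 1)
  n <- length(truth)
  with_seed(seed, {
    mat <- matrix(0, nrow = n_raters, ncol = n)
    for (r in seq_len(n_raters)) {
      vals <- round(pmin(pmax(truth + stats::rnorm(n, 0, noise_sd), 0), 5))
      keep <- stats::runif(n) < mark_prob
      mat[r, ] <- vals * keep
    }
    rownames(mat) <- paste0("r", seq_len(n_raters))
    mat
  })
}

#' Bundled synthetic familiarity table
#'
#' A small familiarity table counted over a deterministic synthetic corpus of
#' about 200 chord slices in which the major triad is the most frequent type,
#' followed by the minor triad, seventh chords and rarer sonorities. It is
#' synthetic — a stand-in shaped like (but not derived from) real corpus
#' statistics — and is labeled as such in its provenance.
#'
#' @return a [familiarity_table].
#' @export
default_familiarity <- function() {
  mix <- c(rep("major", 10), rep("minor", 6), rep("dom7", 3), rep("min7", 2),
           rep("dim", 2), rep("single", 3), rep("fifth", 2), "maj7", "dim7",
           "sus4", "aug")
  pieces <- lapply(1:6, function(k) {
    generate_progression(templates = rep_len(sample_mix(mix, 9000 + k), 34),
                         n_chords = 34, seed = 9000 + k, duration_beats = 1)
  })
  cs <- count_corpus(pieces)
  tab <- cs$table
  tab$provenance <- sprintf("synthetic default (%d slices; not real corpus statistics)",
                            cs$n_events)
  tab
}

sample_mix <- function(mix, seed) with_seed(seed, sample(mix, 34, replace = TRUE))
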