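# Melodic contour accents: the product of the distance from the running mean
# pitch and the size of the preceding interval, with direction-dependent
# weights, stepwise-middle and three-note local-maximum pruning, a cutoff at
# 1 and saturation at 5.

#' Parameters of the melodic contour accent model
#'
#' @param N_norm normalization divisor applied to the CS1*CS2 product
#'   (default 2.5).
#' @param below_mean_weight weight for notes below the running mean pitch
#'   (default 0.7).
#' @param falling_interval_weight weight for falling preceding intervals
#'   (default 0.2).
#' @param window_measures how many measures before the current note's measure
#'   the running-mean window opens (default 2: the window starts at the
#'   barline two measures back).
#' @param min_context_notes if the window holds fewer notes than this, it is
#'   extended backwards to the last that many notes (default 10).
#' @param cutoff saliences below this become 0 (default 1).
#' @param saturation upper clip (default 5).
#' @param stepwise_max_semitones maximal interval (semitones) still counting
#'   as stepwise motion (default 2).
#' @param include_current logical; include the current note in its own
#'   running-mean window (default `FALSE`: the mean describes the preceding
#'   context the note departs from).
#' @return list of class `melodic_params`.
#' @export
melodic_params <- function(N_norm = 2.5, below_mean_weight = 0.7,
                           falling_interval_weight = 0.2, window_measures = 2,
                           min_context_notes = 10, cutoff = 1, saturation = 5,
                           stepwise_max_semitones = 2,
                           include_current = FALSE) {
  stopifnot(N_norm > 0, below_mean_weight > 0, below_mean_weight <= 1,
            falling_interval_weight > 0, falling_interval_weight <= 1,
            window_measures > 0, min_context_notes > 0, cutoff >= 0,
            saturation > 0, stepwise_max_semitones > 0)
  structure(as.list(environment()), class = "melodic_params")
}

#' Running mean pitch of the melodic context
#'
#' The mean pitch of the melody notes from the barline `window_measures`
#' measures before the current note's measure up to (strictly before) the
#' current note. If fewer than `min_context_notes` notes fall in that range
#' the window is extended backwards to the last that many notes; with no
#' preceding notes at all the note's own pitch is returned.
#'
#' @param melody data.frame from [extract_melody] (columns `pitch`,
#'   `onset_ticks`, `measure`).
#' @param index 1-based note position.
#' @param params a [melodic_params] object.
#' @param barline_ticks optional function(measure) -> tick of that measure's
#'   barline; defaults to constant-meter arithmetic from the melody itself.
#' @return mean pitch in (real) semitones.
#' @export
running_mean_pitch <- function(melody, index, params = melodic_params(),
                               barline_ticks = NULL) {
  stopifnot(index >= 1, index <= nrow(melody))
  idx <- context_indices(melody, index, params, barline_ticks)
  ctx <- c(idx, if (params$include_current) index)
  if (!length(ctx)) return(as.numeric(melody$pitch[index]))
  mean(melody$pitch[ctx])
}

# indices of the running-mean context (excluding the current note)
context_indices <- function(melody, index, params, barline_ticks = NULL) {
  if (index == 1L) return(integer(0))
  if (is.null(barline_ticks)) {
    barline_ticks <- infer_barline_fun(melody)
  }
  from_measure <- melody$measure[index] - params$window_measures
  from_tick <- barline_ticks(from_measure)
  before <- seq_len(index - 1L)
  in_window <- before[melody$onset_ticks[before] >= from_tick]
  if (length(in_window) >= params$min_context_notes) return(in_window)
  n_take <- min(params$min_context_notes, index - 1L)
  tail(before, n_take)
}

# constant-meter barline positions inferred from measure numbers and onsets
infer_barline_fun <- function(melody) {
  m <- melody$measure; t <- melody$onset_ticks
  if (length(unique(m)) >= 2L) {
    firsts <- tapply(t, m, min)
    ms <- as.integer(names(firsts))
    len <- (firsts[[length(firsts)]] - firsts[[1L]]) / (ms[length(ms)] - ms[1L])
    origin <- firsts[[1L]] - (ms[1L] - 1L) * len
    function(measure) origin + (measure - 1L) * len
  } else {
    function(measure) -Inf
  }
}

#' Contour salience terms for one note
#'
#' `CS1` weights the signed distance `I1` from the running mean pitch
#' (full weight above the mean, `below_mean_weight` below); `CS2` weights the
#' signed preceding interval `I2` (full weight rising,
#' `falling_interval_weight` falling).
#'
#' @param I1 signed semitone distance to the running mean pitch (vectorized).
#' @param I2 signed preceding interval in semitones (vectorized).
#' @param params a [melodic_params] object.
#' @return list with components `CS1` and `CS2`.
#' @export
contour_terms <- function(I1, I2, params = melodic_params()) {
  CS1 <- ifelse(I1 > 0, I1, params$below_mean_weight * I1)
  CS2 <- ifelse(I2 > 0, I2, params$falling_interval_weight * I2)
  list(CS1 = CS1, CS2 = CS2)
}

#' Melodic contour accent saliences
#'
#' Computes per-note raw saliences `CS = CS1 * CS2 / N_norm` (kept only when
#' positive, i.e. when the note departs from the mean in the direction it was
#' approached from), then applies, in order: removal on the middle note of
#' three in same-direction stepwise motion; retention of only the maximal
#' positive value within every sliding window of three consecutive notes
#' (ties go to the earliest note); the cutoff; and saturation at 5. The first
#' note, having no preceding interval, scores 0.
#'
#' @param melody data.frame from [extract_melody].
#' @param params a [melodic_params] object.
#' @param barline_ticks see [running_mean_pitch].
#' @return list with `C` (final saliences), `raw` (pre-pruning positive
#'   products), `I1`, `I2`, `running_mean`.
#' @export
melodic_accents <- function(melody, params = melodic_params(),
                            barline_ticks = NULL) {
  n <- nrow(melody)
  p <- as.numeric(melody$pitch)
  if (is.null(barline_ticks)) barline_ticks <- infer_barline_fun(melody)
  rm_pitch <- vapply(seq_len(n), function(i)
    running_mean_pitch(melody, i, params, barline_ticks), numeric(1))
  I1 <- p - rm_pitch
  I2 <- c(NA_real_, diff(p))
  ct <- contour_terms(I1, I2, params)
  raw <- ct$CS1 * ct$CS2 / params$N_norm
  raw[1L] <- 0
  raw[is.na(raw)] <- 0
  raw[raw < 0] <- 0
  cs <- raw
  # (1) middle note of three in same-direction stepwise motion
  if (n >= 3L) for (i in 2:(n - 1L)) {
    d1 <- p[i] - p[i - 1L]; d2 <- p[i + 1L] - p[i]
    if (d1 != 0 && d2 != 0 && sign(d1) == sign(d2) &&
        abs(d1) <= params$stepwise_max_semitones &&
        abs(d2) <= params$stepwise_max_semitones) {
      cs[i] <- 0
    }
  }
  # (2) within every sliding 3-note window only the maximal positive CS
  # survives; evaluated simultaneously on the current values, earliest note
  # winning ties. Equivalently: a note is zeroed if any note within distance
  # two (sharing a window with it) has a larger value, or an equal value at
  # an earlier position.
  if (n >= 3L) {
    before <- cs
    for (i in seq_len(n)) {
      if (before[i] <= 0) next
      nb <- setdiff(max(1L, i - 2L):min(n, i + 2L), i)
      if (any(before[nb] > before[i]) ||
          any(before[nb] == before[i] & nb < i)) {
        cs[i] <- 0
      }
    }
  }
  # (3) cutoff, (4) saturation
  cs[cs < params$cutoff] <- 0
  cs <- pmin(cs, params$saturation)
  list(C = cs, raw = raw, I1 = I1, I2 = I2, running_mean = rm_pitch)
}
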