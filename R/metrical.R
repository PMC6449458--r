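# Metrical accents: four pulse levels per time signature, each weighted by a
# Gaussian of log pulse period, summed over the levels marked on each onset.

# Notated pulse durations (whole-note fractions) per supported time signature,
# Levels 0-3 (Level 1 is the beat).
pulse_table <- list(
  "2/2"  = c(1/4, 1/2, 1,    2),
  "4/2"  = c(1/4, 1/2, 1,    2),
  "2/4"  = c(1/8, 1/4, 1/2,  1),
  "3/4"  = c(1/8, 1/4, 3/4,  3/2),
  "4/4"  = c(1/8, 1/4, 1/2,  1),
  "3/8"  = c(1/8, 3/8, 3/4,  3/2),
  "6/8"  = c(1/8, 3/8, 3/4,  3/2),
  "9/8"  = c(1/8, 3/8, 9/8,  9/4),
  "12/8" = c(1/8, 3/8, 3/4,  3/2)
)

#' Parameters of the metrical accent model
#'
#' @param k base salience assigned to every marked pulse level before the
#'   Gaussian tempo weighting (dimensionless, default 1).
#' @param M mean of the Gaussian of salience against log pulse period, in
#'   seconds (default 2): pulses with a 2-second period are maximally salient.
#' @param S log-normal spread of that Gaussian (dimensionless, default 1.65;
#'   must exceed 1).
#' @param cutoff metrical saliences below this value are set to 0 (default 1).
#' @param hypermeter_phase integer measure offset (default 0) shifting which
#'   measures anchor the two-measure hypermetrical level.
#' @return list of class `metrical_params`.
#' @export
metrical_params <- function(k = 1, M = 2, S = 1.65, cutoff = 1,
                            hypermeter_phase = 0) {
  stopifnot(k > 0, M > 0, S > 1, cutoff >= 0)
  structure(list(k = k, M = M, S = S, cutoff = cutoff,
                 hypermeter_phase = as.integer(hypermeter_phase)),
            class = "metrical_params")
}

#' Pulse grid implied by a time signature
#'
#' Returns the notated durations of the four metrical levels the signature
#' implies, plus their physical periods at the working tempo.
#'
#' @param numerator,denominator the time signature.
#' @param seconds_per_beat physical duration of the notated beat (Level 1).
#' @param extend logical; if `TRUE`, signatures outside the nine supported
#'   ones are given the generic grid (half-beat, beat, measure, two measures)
#'   instead of raising an error.
#' @return list of class `pulse_grid` with `level_wholes` (4 durations in
#'   whole-note units) and `level_periods` (4 periods in seconds).
#' @export
pulse_grid <- function(numerator, denominator, seconds_per_beat = NA_real_,
                       extend = FALSE) {
  key <- paste0(numerator, "/", denominator)
  if (!is.null(pulse_table[[key]])) {
    lw <- pulse_table[[key]]
  } else if (extend) {
    bw <- beat_wholes_for(numerator, denominator)
    mw <- measure_wholes_for(numerator, denominator)
    lw <- c(bw / 2, bw, mw, 2 * mw)
  } else {
    stop("time signature ", key, " has no predefined pulse grid; set ",
         "`extend = TRUE` for the generic half-beat/beat/measure/two-measure ",
         "grid, or supply an explicit grid")
  }
  bw <- beat_wholes_for(numerator, denominator)
  structure(list(numerator = numerator, denominator = denominator,
                 level_wholes = lw,
                 level_periods = lw / bw * seconds_per_beat),
            class = "pulse_grid")
}

#' Salience of a single pulse train
#'
#' Gaussian weighting of pulse salience against the logarithm of the pulse
#' period: `k * exp(-0.5 * ((log P - log M) / log S)^2)`. The expression is a
#' ratio of logarithms, so the result does not depend on the logarithm base.
#'
#' @param P pulse period in seconds (> 0); vectorized.
#' @param params a [metrical_params] object.
#' @return salience in `(0, k]`, maximal at `P = M`.
#' @export
pulse_salience <- function(P, params = metrical_params()) {
  if (any(P <= 0)) stop("pulse period must be positive")
  params$k * exp(-0.5 * ((log(P) - log(params$M)) / log(params$S))^2)
}

#' Metrical accent saliences for a sonority stream
#'
#' Marks each sonority with every metrical level whose subdivision its onset
#' falls on (levels anchored at the downbeat of measure 1; the two-measure
#' hypermetrical level at odd measures by default) and sums the Gaussian
#' pulse saliences of the marked levels. Sums below the cutoff become 0;
#' values above 5 saturate at 5.
#'
#' @param stream a [chordify] sonority stream.
#' @param grid a [pulse_grid]; defaults to the stream's meter and tempo.
#' @param params a [metrical_params] object.
#' @param anchor_ticks tick of the downbeat of measure 1 (internal).
#' @return list with `M` (numeric salience per sonority), `raw` (pre-cutoff
#'   sums) and `levels` (list of marked level indices, 0-based).
#' @export
metrical_accents <- function(stream, grid = NULL, params = metrical_params(),
                             anchor_ticks = 0L) {
  if (is.null(grid)) {
    grid <- pulse_grid(stream$numerator, stream$denominator,
                       seconds_per_beat = stream$seconds_per_beat)
  }
  lv_ticks <- wholes_to_ticks(grid$level_wholes)
  sal <- pulse_salience(grid$level_periods, params)
  onsets <- stream$sonorities$onset_ticks
  phase3 <- params$hypermeter_phase * stream$measure_ticks
  levels <- vector("list", length(onsets))
  raw <- numeric(length(onsets))
  for (i in seq_along(onsets)) {
    rel <- onsets[i] - anchor_ticks
    marked <- integer(0)
    for (l in 1:4) {
      off <- if (l == 4L) rel - phase3 else rel
      if (((off %% lv_ticks[l]) + lv_ticks[l]) %% lv_ticks[l] == 0L) {
        marked <- c(marked, l - 1L)
      }
    }
    levels[[i]] <- marked
    raw[i] <- sum(sal[marked + 1L])
  }
  M <- ifelse(raw < params$cutoff, 0, pmin(raw, 5))
  list(M = M, raw = raw, levels = levels)
}
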