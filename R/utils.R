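# Internal time base: integer ticks, 3072 per whole note (= 1024 * 3, so all
# binary subdivisions down to the 1024th plus triplet-compound beats are exact).
TPW <- 3072L

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert whole-note units to internal ticks
#' @param wholes numeric vector of durations/onsets in whole-note units
#' @return integer tick vector
#' @keywords internal
wholes_to_ticks <- function(wholes) {
  t <- wholes * TPW
  ti <- as.integer(round(t))
  if (any(abs(t - ti) > 1e-6)) {
    stop("time value not representable on the 1/", TPW, " whole-note grid")
  }
  ti
}

ticks_to_wholes <- function(ticks) as.numeric(ticks) / TPW

# Beat duration (in wholes) implied by a time signature: the denominator note,
# except compound meters (numerator divisible by 3, denominator 8) where the
# beat is the dotted quarter.
beat_wholes_for <- function(numerator, denominator) {
  if (denominator == 8 && numerator %% 3 == 0 && numerator >= 3) {
    3 / 8
  } else {
    1 / denominator
  }
}

measure_wholes_for <- function(numerator, denominator) numerator / denominator

# Default mapping from Italian tempo words to beats per minute.
default_tempo_map <- function() {
  c(largo = 50, adagio = 60, andante = 72, andantino = 80, moderato = 96,
    allegretto = 112, allegro = 132, vivace = 152, presto = 180)
}

# Tempo words the duration-halving rule treats as fast.
fast_tempo_words <- function() c("allegretto", "allegro", "vivace", "presto")

fmt6 <- function(x) sprintf("%.6f", x)
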