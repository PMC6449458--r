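# Internal unit-conversion helpers, re-exported for test convenience.
ticks_to_wholes <- accentr:::ticks_to_wholes
wholes_to_ticks <- accentr:::wholes_to_ticks

# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force, staying independent of the implementation paths
# they check.

# Canonical label of the transpositional class of a pitch-class set: the
# minimal 12-bit characteristic-vector integer over all 12 transpositions.
oracle_tn_canon <- function(pcs) {
  pcs <- unique(pcs %% 12L)
  min(vapply(0:11, function(t) sum(2L ^ ((pcs + t) %% 12L)), numeric(1)))
}

# Distinct onset times of a score, by direct enumeration of the event list.
oracle_onset_count <- function(sc) length(unique(sc$events$onset_ticks))

# Highest newly struck pitch at each distinct onset.
oracle_skyline <- function(sc) {
  ev <- sc$events[!sc$events$grace, ]
  vapply(sort(unique(ev$onset_ticks)),
         function(t) max(ev$pitch[ev$onset_ticks == t]), numeric(1))
}

# Direct evaluation of the recency-weighted surprise on explicit profiles.
oracle_surprise <- function(profile, window_profiles) {
  if (!length(window_profiles)) return(1)
  r <- vapply(window_profiles, function(b) {
    if (sd(profile) == 0 || sd(b) == 0) 0 else cor(profile, b)
  }, numeric(1))
  r <- pmax(r, 0)
  w <- 1 / seq_along(window_profiles)
  1 - sum(r * w) / sum(w)
}

# Independent re-implementation of the running-mean context window.
oracle_running_mean <- function(pitches, onsets, measures, index,
                                barline_fun, min_n = 10, win_meas = 2) {
  if (index == 1) return(pitches[index])
  from <- barline_fun(measures[index] - win_meas)
  before <- seq_len(index - 1)
  in_win <- before[onsets[before] >= from]
  ctx <- if (length(in_win) >= min_n) in_win else
    utils::tail(before, min(min_n, index - 1))
  if (!length(ctx)) return(pitches[index])
  mean(pitches[ctx])
}

# Brute-force corpus recount: slices scores independently of chordify by
# enumerating onsets and sounding events directly.
oracle_count_corpus <- function(scores) {
  counts <- list()
  n_events <- 0L
  for (sc in scores) {
    ev <- sc$events
    ends <- ev$onset_ticks + ev$duration_ticks
    for (t in sort(unique(ev$onset_ticks))) {
      sounding <- ev$pitch[ev$onset_ticks <= t & ends > t]
      held <- any(ev$onset_ticks < t & ends > t)
      key <- paste(sort(accentr::tn_type(sounding)), collapse = ",")
      slot <- if (held) "prepared" else "unprepared"
      if (is.null(counts[[key]])) counts[[key]] <- list(prepared = 0L,
                                                        unprepared = 0L)
      counts[[key]][[slot]] <- counts[[key]][[slot]] + 1L
      n_events <- n_events + 1L
    }
  }
  list(counts = counts, n_events = n_events)
}

transpose_score <- function(sc, semitones) {
  sc$events$pitch <- sc$events$pitch + semitones
  sc
}
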