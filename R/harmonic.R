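# Harmonic accents. Vertical: corpus unfamiliarity of the sonority's Tn type
# scaled by duration. Horizontal: surprise, i.e. low recency-weighted Pearson
# correlation between the sonority's pitch-class salience profile and the
# profiles of the sonorities in the preceding one-measure window. Combined:
# either the plain maximum (Model 1) or the style-parameterized Model 2.

#' Transpositional set class (Tn type) of a pitch set
#'
#' Reduces the pitches to pitch classes and returns the transpositional
#' normal form: the normal-order rotation (smallest span, ties broken by
#' packing from the left) transposed to start at 0. Inversionally related
#' sets stay distinct: the major triad is `(0,4,7)`, the minor `(0,3,7)`.
#'
#' @param pitches non-empty vector of integer pitches (any octave).
#' @return integer vector, strictly increasing, starting at 0.
#' @export
tn_type <- function(pitches) {
  if (!length(pitches)) stop("cannot classify an empty pitch set")
  pcs <- sort(unique(as.integer(pitches) %% 12L))
  n <- length(pcs)
  if (n == 1L) return(0L)
  best <- NULL
  for (r in seq_len(n)) {
    rot <- c(pcs[r:n], pcs[seq_len(r - 1L)] + 12L)
    cand <- as.integer(rot - rot[1L])
    if (is.null(best)) { best <- cand; next }
    # normal order: compare spans from the top down (Rahn packing)
    for (k in n:2) {
      if (cand[k] < best[k]) { best <- cand; break }
      if (cand[k] > best[k]) break
    }
  }
  best
}

tn_key <- function(tn) paste(tn, collapse = ",")

#' Tn-type familiarity table
#'
#' Occurrence counts of Tn types over a corpus, split into prepared slices
#' (at least one tone held over from a previous onset) and unprepared slices
#' (all tones struck simultaneously). The combined counts, normalized by the
#' most frequent type, are the familiarity basis of the vertical harmonic
#' accent.
#'
#' @param counts named list: Tn key (e.g. `"0,4,7"`) -> list(prepared,
#'   unprepared).
#' @param total_events total number of slices counted.
#' @param provenance character description of the source corpus.
#' @return object of class `familiarity_table`.
#' @export
familiarity_table <- function(counts, total_events, provenance = "unknown") {
  stopifnot(total_events >= 0)
  for (k in names(counts)) {
    counts[[k]]$prepared <- as.integer(counts[[k]]$prepared %||% 0L)
    counts[[k]]$unprepared <- as.integer(counts[[k]]$unprepared %||% 0L)
    if (counts[[k]]$prepared < 0 || counts[[k]]$unprepared < 0) {
      stop("familiarity counts must be nonnegative")
    }
  }
  structure(list(counts = counts, total_events = as.integer(total_events),
                 provenance = provenance),
            class = "familiarity_table")
}

#' @export
print.familiarity_table <- function(x, ...) {
  cat(sprintf("<familiarity_table> %d Tn types over %d events (%s)\n",
              length(x$counts), x$total_events, x$provenance))
  invisible(x)
}

#' Write / read a familiarity table as JSON
#' @param table a [familiarity_table].
#' @param path file path.
#' @rdname familiarity_json
#' @export
write_familiarity <- function(table, path) {
  jsonlite::write_json(
    list(total_events = table$total_events, provenance = table$provenance,
         counts = table$counts),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname familiarity_json
#' @export
read_familiarity <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  familiarity_table(obj$counts, obj$total_events,
                    obj$provenance %||% path)
}

familiarity_combined <- function(table, prepared = TRUE) {
  vapply(table$counts, function(x)
    x$unprepared + if (prepared) x$prepared else 0L, numeric(1))
}

#' Style parameters for the harmonic accent model
#'
#' The three style classes fix the rescaling powers of the vertical (`P_v`)
#' and horizontal (`P_h`) accents and the Model-2 parameters: `x1` (divisor
#' of the horizontal contribution), `x2` (vertical-accent threshold between
#' the weighted-sum and maximum regimes) and `x3` (final cutoff).
#'
#' @param style `"baroque_classical"`, `"romantic"` or `"late_romantic"`.
#' @param P_v,P_h,x1,x2,x3 optional overrides of the style's values.
#' @param S_scale rescaling from the unit interval to the 0-5 salience scale.
#' @return list of class `style_params`.
#' @export
style_params <- function(style = c("romantic", "baroque_classical",
                                   "late_romantic"),
                         P_v = NULL, P_h = NULL, x1 = NULL, x2 = NULL,
                         x3 = NULL, S_scale = 5) {
  style <- match.arg(style)
  defaults <- switch(style,
    baroque_classical = list(P_v = 2, P_h = 2, x1 = 5, x2 = 0.6, x3 = 1),
    romantic          = list(P_v = 2, P_h = 2, x1 = 4, x2 = 0.3, x3 = 1),
    late_romantic     = list(P_v = 3, P_h = 3, x1 = 4, x2 = 0.2, x3 = 1.5))
  structure(list(style = style,
                 P_v = P_v %||% defaults$P_v, P_h = P_h %||% defaults$P_h,
                 x1 = x1 %||% defaults$x1, x2 = x2 %||% defaults$x2,
                 x3 = x3 %||% defaults$x3, S_scale = S_scale),
            class = "style_params")
}

#' Scaled duration of a sonority
#'
#' Compresses notated durations so that accents on long chords are not
#' overestimated: durations up to one beat pass through, durations between
#' one beat and one bar are square-rooted, durations of a bar or more are
#' capped at the square root of the bar length. Fast notated tempi halve the
#' notated duration before the piecewise rule.
#'
#' @param d_n notated duration in beats (> 0); vectorized.
#' @param n_b beats per bar (>= 1).
#' @param fast_tempo logical; halve `d_n` first.
#' @return scaled duration, in `(0, sqrt(n_b)]`.
#' @export
scaled_duration <- function(d_n, n_b, fast_tempo = FALSE) {
  if (any(d_n <= 0) || n_b < 1) stop("durations and beats per bar must be positive")
  if (fast_tempo) d_n <- d_n / 2
  ifelse(d_n <= 1, d_n, ifelse(d_n < n_b, sqrt(d_n), sqrt(n_b)))
}

#' Vertical harmonic accent of one sonority
#'
#' `H_v = (1 - f)^(P_v^2) * S_scale * d`, where `f` is the sonority's
#' Tn-type count in the familiarity table divided by the table's maximal
#' count (unseen types have `f = 0`), and `d` is the scaled duration of the
#' SHORTEST notated duration in the sonority.
#'
#' @param pitches sounding pitches of the sonority.
#' @param dur_beats per-pitch notated durations in beats (held tones: the
#'   remaining duration from the slice onset).
#' @param table a [familiarity_table].
#' @param style a [style_params] object.
#' @param n_b beats per bar.
#' @param fast_tempo logical, see [scaled_duration].
#' @param prepared_counts logical; include prepared counts in `f`
#'   (default `TRUE`).
#' @return nonnegative salience (pre-saturation; bounded by
#'   `S_scale * sqrt(n_b)`).
#' @export
vertical_accent <- function(pitches, dur_beats, table, style = style_params(),
                            n_b = 4, fast_tempo = FALSE,
                            prepared_counts = TRUE) {
  if (!length(table$counts)) stop("familiarity table is empty")
  comb <- familiarity_combined(table, prepared_counts)
  key <- tn_key(tn_type(pitches))
  f <- if (key %in% names(comb)) comb[[key]] / max(comb) else 0
  dn <- min(dur_beats[!is.na(dur_beats) & dur_beats > 0])
  d <- scaled_duration(dn, n_b, fast_tempo)
  (1 - f) ^ (style$P_v ^ 2) * style$S_scale * d
}

#' Root-support weights for pitch-class salience profiles
#'
#' Weight given to a chord tone lying at each interval (semitones mod 12)
#' above a candidate root. The defaults support the root itself (10), the
#' fifth (5), the major third (3), the minor seventh (2) and the major
#' second (1); all other intervals contribute nothing.
#'
#' @param weights numeric vector of length 12 (index 1 = unison).
#' @return numeric vector of class `root_support_weights`.
#' @export
root_support_weights <- function(weights = NULL) {
  if (is.null(weights)) {
    weights <- numeric(12)
    weights[c(0, 7, 4, 10, 2) + 1] <- c(10, 5, 3, 2, 1)
  }
  stopifnot(length(weights) == 12, all(weights >= 0),
            weights[1] == max(weights))
  structure(as.numeric(weights), class = "root_support_weights")
}

#' Pitch-class salience profile of a sonority
#'
#' For each of the 12 chromatic pitch classes `p`, sums the root-support
#' weights of the chord's pitch classes relative to `p`:
#' `sal[p] = sum_q w[(q - p) mod 12]`. The profile can assign salience to
#' pitch classes absent from the chord (missing fundamentals), e.g. G in the
#' diminished triad B-D-F.
#'
#' @param pitches non-empty vector of integer pitches.
#' @param weights a [root_support_weights] vector.
#' @return numeric vector of length 12 (index 1 = pitch class 0 = C).
#' @export
pc_salience_profile <- function(pitches, weights = root_support_weights()) {
  if (!length(pitches)) stop("cannot profile an empty pitch set")
  pcs <- unique(as.integer(pitches) %% 12L)
  sal <- numeric(12)
  for (p in 0:11) {
    sal[p + 1] <- sum(weights[((pcs - p) %% 12L) + 1L])
  }
  sal
}

# Pearson correlation between two profiles; degenerate (zero-variance)
# profiles correlate as 0.
profile_correlation <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Recency-weighted profile surprise
#'
#' The horizontal-accent core: `1 - sum(r_j * w_j) / sum(w_j)` with
#' `w_j = 1/j` over the window of preceding profiles (`j = 1` the most
#' recent), correlations clamped below at 0 (or rescaled from -1..1 to 0..1
#' when `negative = "rescale"`).
#'
#' @param profile the current sonority's 12-vector.
#' @param window_profiles list of preceding profiles, most recent first.
#' @param negative `"clamp"` (default) or `"rescale"`.
#' @return surprise in `[0, 1]`; 1 when the window is empty.
#' @export
profile_surprise <- function(profile, window_profiles,
                             negative = c("clamp", "rescale")) {
  negative <- match.arg(negative)
  N <- length(window_profiles)
  if (N == 0L) return(1)
  r <- vapply(window_profiles, profile_correlation, numeric(1), a = profile)
  r <- if (negative == "clamp") pmax(r, 0) else (r + 1) / 2
  w <- 1 / seq_len(N)
  1 - sum(r * w) / sum(w)
}

#' Horizontal harmonic accent at one sonority of a stream
#'
#' Correlates the sonority's pitch-class salience profile with the profiles
#' of all sonorities whose onset falls within the preceding measure (two
#' measures under a half time signature), weights the correlations by recency
#' (`w_j = 1/j`), and scales the resulting surprise:
#' `H_h = (1 - sum r_j w_j / sum w_j)^P_h * S_scale * d`, with `d` the scaled
#' duration of the LONGEST notated duration (halved first when the piece is
#' flagged as consonant-passing-tone textured). The first sonority of a
#' piece, having an empty window, scores 0.
#'
#' @param stream a [chordify] sonority stream.
#' @param i 1-based sonority position.
#' @param style a [style_params] object.
#' @param weights a [root_support_weights] vector.
#' @param profiles optional precomputed list of profiles for the stream.
#' @param negative see [profile_surprise].
#' @return nonnegative salience (pre-saturation).
#' @export
horizontal_accent <- function(stream, i, style = style_params(),
                              weights = root_support_weights(),
                              profiles = NULL, negative = "clamp") {
  son <- stream$sonorities
  stopifnot(i >= 1, i <= nrow(son))
  if (is.null(profiles)) {
    profiles <- lapply(son$pitches, pc_salience_profile, weights = weights)
  }
  win_meas <- if (isTRUE(stream$flags$half_time_signature)) 2L else 1L
  n_b <- stream$n_beats * win_meas
  t_i <- son$onset_ticks[i]
  lo <- t_i - win_meas * stream$measure_ticks
  in_win <- which(son$onset_ticks >= lo & son$onset_ticks < t_i)
  if (!length(in_win)) return(0)
  in_win <- sort(in_win, decreasing = TRUE)  # most recent first
  surpr <- profile_surprise(profiles[[i]], profiles[in_win], negative)
  dn <- max(son$dur_beats[[i]], na.rm = TRUE)
  if (isTRUE(stream$flags$consonant_passing_tones)) dn <- dn / 2
  d <- scaled_duration(dn, n_b, stream$fast_tempo)
  surpr ^ style$P_h * style$S_scale * d
}

#' Combine vertical and horizontal harmonic accents
#'
#' Model 1 takes the plain maximum. Model 2 takes, when `H_v` is at most the
#' style threshold `x2`, the weighted sum `H_v + H_h / x1` (clipped at 5) —
#' suppressing consonant root changes in low-dissonance styles — and the
#' maximum otherwise; values below the style cutoff `x3` become 0. Both
#' models saturate at 5. By default the `x3` cutoff applies to Model 2 only.
#'
#' @param H_v,H_h nonnegative component saliences (vectorized).
#' @param model 1 or 2.
#' @param style a [style_params] object.
#' @param cutoff_model1 logical; apply `x3` to Model 1 as well
#'   (default `FALSE`).
#' @return combined salience in `[0, 5]`.
#' @export
combine_harmonic <- function(H_v, H_h, model = 2, style = style_params(),
                             cutoff_model1 = FALSE) {
  stopifnot(all(H_v >= 0), all(H_h >= 0), model %in% c(1, 2))
  if (model == 1) {
    H <- pmax(H_v, H_h)
    if (cutoff_model1) H[H < style$x3] <- 0
  } else {
    H <- ifelse(H_v <= style$x2, pmin(H_v + H_h / style$x1, 5), pmax(H_v, H_h))
    H[H < style$x3] <- 0
  }
  pmin(H, 5)
}

#' All harmonic accent columns for a sonority stream
#'
#' Applies [vertical_accent], [horizontal_accent] and [combine_harmonic]
#' per sonority, saturating the component columns at 5.
#'
#' @param stream a [chordify] sonority stream.
#' @param table a [familiarity_table].
#' @param style a [style_params] object.
#' @param weights a [root_support_weights] vector.
#' @param prepared_counts,negative passed through.
#' @return list with numeric vectors `Hv`, `Hh`, `H1`, `H2` and the raw
#'   (pre-saturation) components `Hv_raw`, `Hh_raw`.
#' @export
harmonic_accents <- function(stream, table, style = style_params(),
                             weights = root_support_weights(),
                             prepared_counts = TRUE, negative = "clamp") {
  son <- stream$sonorities
  n <- nrow(son)
  n_b <- stream$n_beats * (if (isTRUE(stream$flags$half_time_signature)) 2 else 1)
  profiles <- lapply(son$pitches, pc_salience_profile, weights = weights)
  Hv_raw <- vapply(seq_len(n), function(i)
    vertical_accent(son$pitches[[i]], son$dur_beats[[i]], table, style,
                    n_b = n_b, fast_tempo = stream$fast_tempo,
                    prepared_counts = prepared_counts), numeric(1))
  Hh_raw <- vapply(seq_len(n), function(i)
    horizontal_accent(stream, i, style, weights, profiles, negative),
    numeric(1))
  Hv <- pmin(Hv_raw, 5); Hh <- pmin(Hh_raw, 5)
  list(Hv = Hv, Hh = Hh,
       H1 = combine_harmonic(Hv, Hh, 1, style),
       H2 = combine_harmonic(Hv, Hh, 2, style),
       Hv_raw = Hv_raw, Hh_raw = Hh_raw)
}
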