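# Corpus statistics: count Tn-type chord slices, prepared vs unprepared,
# over a collection of scores, producing the familiarity table the vertical
# harmonic accent consumes.

#' Preparedness of a sonority
#'
#' A slice is unprepared when all of its tones are struck simultaneously at
#' the slice onset, and prepared when at least one tone is held over from a
#' previous onset.
#'
#' @param pitches,new_pitches pitch sets of the slice (all sounding / newly
#'   struck).
#' @return `"prepared"` or `"unprepared"`.
#' @export
classify_preparedness <- function(pitches, new_pitches) {
  if (setequal(pitches, new_pitches)) "unprepared" else "prepared"
}

#' Count Tn-type slices over a corpus
#'
#' Chordifies every piece (no reduction: every onset in any voice opens a
#' slice) and classifies each slice by Tn type and preparedness. Results are
#' independent of file order; unreadable pieces are skipped with a warning.
#'
#' @param paths character vector of score file paths, or a list of [score]
#'   objects.
#' @param ... passed to [read_score].
#' @return object of class `corpus_summary`: list with `n_pieces`,
#'   `n_events`, `n_failed`, `per_cardinality` (named event totals) and
#'   `table` (a [familiarity_table]).
#' @export
count_corpus <- function(paths, ...) {
  if (!length(paths)) stop("count_corpus needs at least one score")
  counts <- list()
  n_events <- 0L; n_pieces <- 0L; n_failed <- 0L
  per_card <- integer(12)
  for (p in paths) {
    sc <- if (inherits(p, "score")) p else
      tryCatch(read_score(p, ...), error = function(e) {
        warning("skipping unreadable piece '", p, "': ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(sc)) { n_failed <- n_failed + 1L; next }
    stream <- chordify(sc)
    son <- stream$sonorities
    for (i in seq_len(nrow(son))) {
      key <- tn_key(tn_type(son$pitches[[i]]))
      prep <- classify_preparedness(son$pitches[[i]], son$new_pitches[[i]])
      if (is.null(counts[[key]])) {
        counts[[key]] <- list(prepared = 0L, unprepared = 0L)
      }
      counts[[key]][[prep]] <- counts[[key]][[prep]] + 1L
      card <- length(unique(son$pitches[[i]] %% 12L))
      per_card[card] <- per_card[card] + 1L
      n_events <- n_events + 1L
    }
    n_pieces <- n_pieces + 1L
  }
  if (!n_pieces) stop("no readable pieces in the corpus")
  counts <- counts[order(names(counts))]
  structure(list(
    n_pieces = n_pieces, n_events = n_events, n_failed = n_failed,
    per_cardinality = stats::setNames(per_card, 1:12),
    table = familiarity_table(counts, n_events,
                              provenance = sprintf("counted over %d piece(s)",
                                                   n_pieces))),
    class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf("<corpus_summary> %d pieces, %d events, %d Tn types (%d skipped)\n",
              x$n_pieces, x$n_events, length(x$table$counts), x$n_failed))
  invisible(x)
}

#' Tn-type occurrence percentages
#'
#' Percentage of all counted slices (every cardinality in the denominator)
#' accounted for by each Tn type of the requested cardinality.
#'
#' @param summary a [count_corpus] summary.
#' @param cardinality number of distinct pitch classes (e.g. 3, 4 or 5).
#' @param per_cardinality logical; normalize by the events of that
#'   cardinality only instead of all events (default `FALSE`).
#' @return named numeric vector (Tn key -> percent), decreasing.
#' @export
to_percentages <- function(summary, cardinality, per_cardinality = FALSE) {
  if (!summary$n_events) stop("empty corpus summary")
  comb <- familiarity_combined(summary$table)
  card <- vapply(strsplit(names(comb), ",", fixed = TRUE), length, integer(1))
  sel <- comb[card == cardinality]
  denom <- if (per_cardinality) sum(sel) else summary$n_events
  if (!denom) stop("no events at cardinality ", cardinality)
  sort(100 * sel / denom, decreasing = TRUE)
}
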