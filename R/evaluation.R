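# Rater-agreement machinery: pairwise Pearson correlations over full note
# vectors (unmarked notes coded 0), category combination by element-wise
# maximum, and the m-threshold consensus rating.

#' Mean pairwise correlation between raters
#'
#' Pearson correlation over the full note vector (zeros included) for every
#' unordered rater pair; pairs involving a zero-variance rater are skipped
#' with a warning.
#'
#' @param ratings numeric matrix, raters in rows, notes in columns.
#' @return list with `mean`, `min`, `max`, `r` (named per-pair vector) and
#'   `skipped` (character vector of skipped pairs).
#' @export
pairwise_mean_correlation <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2L) stop("need at least two raters")
  if (ncol(ratings) < 3L) stop("need at least three notes")
  usable <- apply(ratings, 1, stats::sd) > 0
  if (sum(usable) < 2L) stop("fewer than two raters with nonzero variance")
  rn <- rownames(ratings) %||% as.character(seq_len(nrow(ratings)))
  rs <- c(); skipped <- character(0)
  for (i in seq_len(nrow(ratings) - 1L)) for (j in (i + 1L):nrow(ratings)) {
    pair <- paste0(rn[i], "-", rn[j])
    if (!usable[i] || !usable[j]) { skipped <- c(skipped, pair); next }
    rs[pair] <- stats::cor(ratings[i, ], ratings[j, ])
  }
  if (length(skipped)) {
    warning("skipped pair(s) with an all-constant rater: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  list(mean = mean(rs), min = min(rs), max = max(rs), r = rs,
       skipped = skipped)
}

#' Combine accent categories by element-wise maximum
#'
#' Applied identically to rater marks and model outputs to form the MC, CH
#' and MCH combined categories.
#'
#' @param ... two or three aligned numeric vectors.
#' @return numeric vector of element-wise maxima.
#' @export
combine_categories <- function(...) {
  vs <- list(...)
  if (length(vs) == 1L && is.list(vs[[1]])) vs <- vs[[1]]
  if (length(vs) < 2L) stop("need at least two category vectors")
  n <- lengths(vs)
  if (length(unique(n)) != 1L) {
    stop("category vectors are misaligned (lengths ",
         paste(n, collapse = ", "), ")")
  }
  do.call(pmax, vs)
}

#' m-threshold consensus rating
#'
#' A note counts as a consensus accent only when at least `m` raters marked
#' it (nonzero salience); its consensus value is the mean over exactly the
#' raters who marked it, and 0 elsewhere.
#'
#' @param ratings numeric matrix, raters in rows, notes in columns.
#' @param m minimal number of marking raters (1 to `nrow(ratings)`).
#' @return numeric vector of per-note consensus saliences.
#' @export
consensus_rating <- function(ratings, m) {
  ratings <- as.matrix(ratings)
  if (m < 1 || m > nrow(ratings)) {
    stop("m must lie between 1 and the number of raters (", nrow(ratings), ")")
  }
  apply(ratings, 2, function(col) {
    marked <- col[col > 0]
    if (length(marked) >= m) mean(marked) else 0
  })
}

#' Best correlation between a model and the rater consensus
#'
#' Computes the Pearson correlation between the model vector and the
#' m-threshold consensus for every `m` in the grid, and returns the maximum
#' (smallest `m` on ties). Values of `m` whose consensus vector has zero
#' variance are skipped and reported.
#'
#' @param model numeric model salience vector (one value per note).
#' @param ratings numeric matrix, raters in rows, notes in columns.
#' @param m_grid integer vector of thresholds to try (default all).
#' @return list with `r` (best correlation), `m` (its threshold), `by_m`
#'   (named vector of all correlations) and `skipped` (skipped thresholds).
#' @export
model_vs_consensus <- function(model, ratings, m_grid = NULL) {
  ratings <- as.matrix(ratings)
  if (length(model) != ncol(ratings)) {
    stop("model vector and rating matrix are misaligned")
  }
  if (is.null(m_grid)) m_grid <- seq_len(nrow(ratings))
  by_m <- numeric(0); skipped <- integer(0)
  for (m in m_grid) {
    # thresholds beyond the rater count can never be met: empty consensus
    cons <- if (m > nrow(ratings)) rep(0, ncol(ratings))
            else consensus_rating(ratings, m)
    if (stats::sd(cons) == 0 || stats::sd(model) == 0) {
      skipped <- c(skipped, m)
      next
    }
    by_m[as.character(m)] <- stats::cor(model, cons)
  }
  if (!length(by_m)) {
    return(list(r = NA_real_, m = NA_integer_, by_m = by_m, skipped = skipped))
  }
  best <- which.max(by_m)  # which.max takes the first (smallest m) on ties
  list(r = unname(by_m[best]), m = as.integer(names(by_m)[best]),
       by_m = by_m, skipped = skipped)
}

#' Write / read rater marks as CSV
#'
#' Long format with columns `piece_id, sonority_index, rater_id, category,
#' salience`; absent rows mean an unmarked (zero) note.
#'
#' @param ratings numeric matrix (raters x notes).
#' @param path file path.
#' @param piece_id,category identifiers stored alongside.
#' @rdname ratings_csv
#' @export
write_ratings <- function(ratings, path, piece_id = "piece", category = "C") {
  ratings <- as.matrix(ratings)
  rn <- rownames(ratings) %||% as.character(seq_len(nrow(ratings)))
  rows <- which(ratings > 0, arr.ind = TRUE)
  df <- data.frame(piece_id = piece_id,
                   sonority_index = rows[, "col"] - 1L,
                   rater_id = rn[rows[, "row"]],
                   category = category,
                   salience = ratings[rows])
  df <- df[order(df$rater_id, df$sonority_index), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param n_notes total number of sonorities (columns) in the piece.
#' @rdname ratings_csv
#' @export
read_ratings <- function(path, n_notes, piece_id = NULL, category = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(piece_id)) df <- df[df$piece_id == piece_id, , drop = FALSE]
  if (!is.null(category)) df <- df[df$category == category, , drop = FALSE]
  raters <- sort(unique(df$rater_id))
  mat <- matrix(0, nrow = length(raters), ncol = n_notes,
                dimnames = list(raters, NULL))
  for (k in seq_len(nrow(df))) {
    mat[as.character(df$rater_id[k]), df$sonority_index[k] + 1L] <- df$salience[k]
  }
  mat
}
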