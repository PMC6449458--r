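#' Assemble an accent table
#'
#' The accent table is the common currency of the package: one row per
#' sonority with the six model salience columns (all in `[0, 5]`).
#'
#' @param stream a [chordify] sonority stream.
#' @param M,C,Hv,Hh,H1,H2 numeric vectors, one value per sonority (recycled
#'   zeros when omitted).
#' @param provenance character note on how the values were produced.
#' @return data.frame of class `accent_table` with columns `sonority_index`,
#'   `measure`, `beat`, `onset_wholes`, `pitches`, `M`, `C`, `Hv`, `Hh`,
#'   `H1`, `H2`.
#' @export
accent_table <- function(stream, M = 0, C = 0, Hv = 0, Hh = 0, H1 = 0, H2 = 0,
                         provenance = "accentr") {
  son <- stream$sonorities
  n <- nrow(son)
  fix <- function(x) {
    x <- rep_len(as.numeric(x), n)
    if (any(x < -1e-9 | x > 5 + 1e-9)) stop("salience values must lie in [0, 5]")
    pmin(pmax(x, 0), 5)
  }
  tab <- data.frame(
    sonority_index = son$index,
    measure = son$measure,
    beat = son$beat,
    onset_wholes = ticks_to_wholes(son$onset_ticks),
    pitches = vapply(son$pitches, paste, character(1), collapse = " "),
    M = fix(M), C = fix(C), Hv = fix(Hv), Hh = fix(Hh),
    H1 = fix(H1), H2 = fix(H2),
    stringsAsFactors = FALSE
  )
  attr(tab, "provenance") <- provenance
  class(tab) <- c("accent_table", "data.frame")
  tab
}

#' Write an accent table to CSV or JSON
#'
#' CSV columns are exactly `sonority_index, measure, beat, onset_wholes,
#' pitches, M, C, Hv, Hh, H1, H2`; all real values are printed with six
#' decimal places so write/read round-trips are lossless at that precision.
#'
#' @param tab an [accent_table].
#' @param path output file path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @export
write_accent_table <- function(tab, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  num_cols <- c("beat", "onset_wholes", "M", "C", "Hv", "Hh", "H1", "H2")
  out <- as.data.frame(tab)
  for (cl in num_cols) out[[cl]] <- fmt6(out[[cl]])
  if (format == "csv") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(paste(names(out), collapse = ","), con)
    if (nrow(out)) {
      writeLines(do.call(paste, c(unname(out), sep = ",")), con)
    }
  } else {
    jsonlite::write_json(
      list(provenance = attr(tab, "provenance") %||% "accentr", rows = out),
      path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read an accent table written by [write_accent_table]
#' @param path file path (CSV or JSON).
#' @return data.frame of class `accent_table`.
#' @export
read_accent_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    tab <- as.data.frame(obj$rows)
    attr(tab, "provenance") <- obj$provenance
  } else {
    tab <- utils::read.csv(path, colClasses = c(pitches = "character"))
    attr(tab, "provenance") <- "accentr"
  }
  num_cols <- c("beat", "onset_wholes", "M", "C", "Hv", "Hh", "H1", "H2")
  for (cl in num_cols) tab[[cl]] <- as.numeric(tab[[cl]])
  tab$sonority_index <- as.integer(tab$sonority_index)
  tab$measure <- as.integer(tab$measure)
  class(tab) <- c("accent_table", "data.frame")
  tab
}
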