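# Standard MIDI File (types 0 and 1) reader and a minimal writer, built on
# readBin/writeBin. Note on/off pairs become note events; voices are assigned
# per track/channel; tempo and time-signature meta events are honoured.

read_u32 <- function(raw, at) sum(as.integer(raw[at:(at + 3)]) * 256 ^ (3:0))
read_u16 <- function(raw, at) sum(as.integer(raw[at:(at + 1)]) * 256 ^ (1:0))

read_varlen <- function(raw, at) {
  val <- 0
  repeat {
    b <- as.integer(raw[at]); at <- at + 1
    val <- val * 128 + (b %% 128)
    if (b < 128) break
  }
  list(value = val, at = at)
}

#' Read a Standard MIDI File
#'
#' @param path file path to a type 0 or type 1 SMF.
#' @param quantum smallest note value (in whole-note units) onsets and
#'   durations are snapped to, to absorb millisecond-level jitter in
#'   sequencer exports; default 1/64.
#' @param ... passed to [score].
#' @return a [score] object.
#' @export
read_midi <- function(path, quantum = 1 / 64, ...) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 14 || rawToChar(raw[1:4]) != "MThd") {
    stop("cannot parse MIDI file '", path, "': missing MThd header")
  }
  division <- read_u16(raw, 13)
  if (division >= 32768) stop("SMPTE-time MIDI files are not supported")
  at <- 15
  notes <- list(); metas <- list()
  track_no <- 0
  while (at + 8 <= length(raw) + 1) {
    if (rawToChar(raw[at:(at + 3)]) != "MTrk") break
    track_len <- read_u32(raw, at + 4)
    track_no <- track_no + 1
    p <- at + 8; end <- p + track_len
    t <- 0; status <- 0L
    open <- list()  # key -> list(tick, velocity)
    while (p < end) {
      vl <- read_varlen(raw, p); t <- t + vl$value; p <- vl$at
      b <- as.integer(raw[p])
      if (b >= 128) { status <- b; p <- p + 1 } # else running status
      hi <- status %/% 16; ch <- status %% 16
      if (hi == 9 || hi == 8) {
        key <- as.integer(raw[p]); vel <- as.integer(raw[p + 1]); p <- p + 2
        id <- paste(ch, key)
        if (hi == 9 && vel > 0) {
          open[[id]] <- c(open[[id]], t)
        } else if (!is.null(open[[id]]) && length(open[[id]])) {
          on_t <- open[[id]][1]
          open[[id]] <- open[[id]][-1]
          notes[[length(notes) + 1L]] <- data.frame(
            on = on_t, off = t, pitch = key,
            voice = sprintf("t%d.c%d", track_no, ch + 1))
        }
      } else if (hi %in% c(10, 11, 14)) {
        p <- p + 2
      } else if (hi %in% c(12, 13)) {
        p <- p + 1
      } else if (status == 255) {
        type <- as.integer(raw[p]); p <- p + 1
        vl <- read_varlen(raw, p); len <- vl$value; p <- vl$at
        if (type == 81 && len == 3) {
          uspq <- sum(as.integer(raw[p:(p + 2)]) * 256 ^ (2:0))
          metas[[length(metas) + 1L]] <- list(kind = "tempo", tick = t,
                                              bpm = 6e7 / uspq)
        } else if (type == 88 && len >= 2) {
          metas[[length(metas) + 1L]] <- list(
            kind = "timesig", tick = t,
            numerator = as.integer(raw[p]),
            denominator = 2L ^ as.integer(raw[p + 1]))
        }
        p <- p + len
      } else if (status %in% c(240L, 247L)) {
        vl <- read_varlen(raw, p); p <- vl$at + vl$value
      } else {
        stop("cannot parse MIDI file '", path, "': unexpected status byte ",
             status, " at offset ", p)
      }
    }
    at <- end
  }
  if (!length(notes)) stop("MIDI file '", path, "' contains no notes")
  nt <- do.call(rbind, notes)
  q_ticks <- wholes_to_ticks(quantum)
  to_ticks <- function(midi_t) {
    as.integer(round(midi_t / division * (TPW / 4) / q_ticks)) * q_ticks
  }
  ev <- data.frame(onset_ticks = to_ticks(nt$on),
                   duration_ticks = pmax(to_ticks(nt$off) - to_ticks(nt$on),
                                         q_ticks),
                   pitch = nt$pitch, voice = nt$voice,
                   tied = FALSE, grace = FALSE)
  tsm <- Filter(function(m) m$kind == "timesig", metas)
  if (!length(tsm)) {
    ts <- data.frame(onset = 0, numerator = 4L, denominator = 4L)
  } else {
    ts <- unique(do.call(rbind, lapply(tsm, function(m) data.frame(
      onset = ticks_to_wholes(to_ticks(m$tick)), numerator = m$numerator,
      denominator = m$denominator))))
  }
  tpm <- Filter(function(m) m$kind == "tempo", metas)
  # MIDI tempo is quarter-note bpm; convert to the notated beat of the meter
  bpm <- if (length(tpm)) {
    qbpm <- tpm[[1]]$bpm
    qbpm * (1 / 4) / beat_wholes_for(ts$numerator[1], ts$denominator[1])
  } else NA_real_
  score(events = ev, time_signatures = ts, bpm = bpm, ...)
}

write_u32 <- function(x) as.raw(c(x %/% 256^3, x %/% 256^2, x %/% 256, x) %% 256)
write_u16 <- function(x) as.raw(c(x %/% 256, x) %% 256)

write_varlen <- function(x) {
  out <- as.raw(x %% 128)
  x <- x %/% 128
  while (x > 0) {
    out <- c(as.raw(128 + x %% 128), out)
    x <- x %/% 128
  }
  out
}

#' Write a score as a type-1 Standard MIDI File
#'
#' One track per voice plus a conductor track with tempo and time signature.
#' Division is 768 ticks per quarter (the internal grid), so timing is exact.
#'
#' @param sc a [score] object.
#' @param path output path.
#' @export
write_midi <- function(sc, path) {
  division <- as.integer(TPW / 4)
  ts <- sc$time_signatures[1L, ]
  tempo <- resolve_tempo(sc)
  qbpm <- tempo$bpm * beat_wholes_for(ts$numerator, ts$denominator) / (1 / 4)
  uspq <- as.integer(round(6e7 / qbpm))
  den_pow <- as.integer(round(log2(ts$denominator)))
  conductor <- c(
    write_varlen(0), as.raw(c(0xff, 0x58, 0x04)),
    as.raw(c(ts$numerator, den_pow, 24, 8)),
    write_varlen(0), as.raw(c(0xff, 0x51, 0x03)),
    as.raw(c(uspq %/% 256^2, uspq %/% 256, uspq) %% 256),
    write_varlen(0), as.raw(c(0xff, 0x2f, 0x00)))
  chunks <- list(c(charToRaw("MTrk"), write_u32(length(conductor)), conductor))
  voices <- sort(unique(sc$events$voice))
  for (vi in seq_along(voices)) {
    ev <- sc$events[sc$events$voice == voices[vi] & !sc$events$grace, , drop = FALSE]
    msgs <- rbind(
      data.frame(tick = ev$onset_ticks, on = TRUE, pitch = ev$pitch),
      data.frame(tick = ev$onset_ticks + ev$duration_ticks, on = FALSE,
                 pitch = ev$pitch))
    msgs <- msgs[order(msgs$tick, msgs$on), , drop = FALSE]  # offs before ons
    ch <- (vi - 1L) %% 16L
    body <- raw(0); last_t <- 0
    for (k in seq_len(nrow(msgs))) {
      dt <- msgs$tick[k] - last_t; last_t <- msgs$tick[k]
      status <- if (msgs$on[k]) 0x90 + ch else 0x80 + ch
      body <- c(body, write_varlen(dt),
                as.raw(c(status, msgs$pitch[k], if (msgs$on[k]) 64 else 0)))
    }
    body <- c(body, write_varlen(0), as.raw(c(0xff, 0x2f, 0x00)))
    chunks[[length(chunks) + 1L]] <- c(charToRaw("MTrk"), write_u32(length(body)), body)
  }
  header <- c(charToRaw("MThd"), write_u32(6), write_u16(1),
              write_u16(length(chunks)), write_u16(division))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, unlist(chunks)), con)
  invisible(path)
}

#' Read a symbolic score in any supported format
#'
#' Dispatches on `format` or, for `"auto"`, on the file extension
#' (`.musicxml`/`.xml`, `.krn`/`.kern`, `.mid`/`.midi`).
#'
#' @param path file path.
#' @param format one of `"auto"`, `"musicxml"`, `"kern"`, `"midi"`.
#' @param ... passed to the format reader and on to [score] (e.g. `style`).
#' @return a [score] object.
#' @export
read_score <- function(path, format = c("auto", "musicxml", "kern", "midi"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("score file '", path, "' does not exist")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      musicxml = , xml = "musicxml",
      krn = , kern = "kern",
      mid = , midi = "midi",
      stop("cannot infer score format from extension '.", ext,
           "'; pass `format` explicitly"))
  }
  switch(format,
         musicxml = read_musicxml(path, ...),
         kern = read_kern(path, ...),
         midi = read_midi(path, ...))
}
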