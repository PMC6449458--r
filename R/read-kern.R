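# Humdrum **kern reader and a minimal writer. Supported: one or more **kern
# spines (tab-separated), durations with dots, chords (space-separated notes
# in one token), ties ([ ... ]), rests, *M time signatures, *MM tempo, bars.
# Spine splits/merges (*^ / *v) are not supported and raise an error.

kern_pc <- c(c = 0L, d = 2L, e = 4L, f = 5L, g = 7L, a = 9L, b = 11L)

parse_kern_note <- function(tok, path) {
  m <- regmatches(tok, regexec("([0-9]+)(\\.*)", tok))[[1]]
  if (length(m) < 2 || m[2] == "") {
    stop("kern parse error in '", path, "': token '", tok, "' has no duration")
  }
  base <- as.numeric(m[2])          # reciprocal duration: 4 = quarter
  ndots <- nchar(m[3])
  dur <- (1 / base) * (2 - (1 / 2) ^ ndots)
  rest <- grepl("r", tok, fixed = TRUE)
  pitch <- NA_integer_
  if (!rest) {
    lm <- regmatches(tok, regexec("([a-gA-G]+)", tok))[[1]]
    if (length(lm) < 2) {
      stop("kern parse error in '", path, "': token '", tok, "' has no pitch")
    }
    letters_run <- lm[2]
    ch <- substr(letters_run, 1, 1)
    n_rep <- nchar(letters_run)
    if (ch %in% letters) {            # lower case: c = C4 (60), cc = C5 ...
      pc <- kern_pc[[tolower(ch)]]
      octave <- 4L + (n_rep - 1L)
    } else {                          # upper case: C = C3 (48), CC = C2 ...
      pc <- kern_pc[[tolower(ch)]]
      octave <- 3L - (n_rep - 1L)
    }
    # accidentals: count # (sharp) and - (flat) after the pitch letters
    tail_part <- sub(sprintf("^.*?%s", letters_run), "", tok)
    sharps <- nchar(gsub("[^#]", "", tail_part))
    flats <- nchar(gsub("[^-]", "", tail_part))
    pitch <- 12L * (octave + 1L) + pc + sharps - flats
  }
  list(dur_wholes = dur, pitch = pitch, rest = rest,
       tie_start = grepl("[", tok, fixed = TRUE),
       tie_stop = grepl("]", tok, fixed = TRUE))
}

#' Read a Humdrum **kern score
#' @param path file path.
#' @param ... passed to [score].
#' @return a [score] object.
#' @export
read_kern <- function(path, ...) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw)]
  header <- grep("^\\*\\*", raw)
  if (!length(header)) stop("kern parse error in '", path, "': no **kern header")
  spine_types <- strsplit(raw[header[1]], "\t", fixed = TRUE)[[1]]
  kern_spines <- which(spine_types == "**kern")
  if (!length(kern_spines)) {
    stop("kern parse error in '", path, "': no **kern spine")
  }
  n_spines <- length(spine_types)
  t_pos <- rep(0L, n_spines)  # running tick position per spine
  events <- list()
  ts_num <- NA_integer_; ts_den <- NA_integer_
  bpm <- NA_real_; tempo_word <- NA_character_
  for (line in raw[(header[1] + 1):length(raw)]) {
    if (startsWith(line, "!")) next
    toks <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (startsWith(toks[1], "*")) {
      if (any(toks %in% c("*^", "*v"))) {
        stop("kern parse error in '", path, "': spine splits/merges (*^, *v) ",
             "are not supported")
      }
      for (tok in toks) {
        mm <- regmatches(tok, regexec("^\\*M(\\d+)/(\\d+)$", tok))[[1]]
        if (length(mm) == 3) {
          ts_num <- as.integer(mm[2]); ts_den <- as.integer(mm[3])
        }
        tm <- regmatches(tok, regexec("^\\*MM([0-9.]+)$", tok))[[1]]
        if (length(tm) == 2) bpm <- as.numeric(tm[2])
        tw <- regmatches(tok, regexec("^\\*MM\\[(.+)\\]$", tok))[[1]]
        if (length(tw) == 2) tempo_word <- tw[2]
      }
      next
    }
    if (startsWith(toks[1], "=")) next
    for (si in kern_spines) {
      if (si > length(toks)) next
      tok <- toks[si]
      if (tok == "." || tok == "") next
      notes <- strsplit(tok, " ", fixed = TRUE)[[1]]
      dt <- 0L
      for (nt in notes) {
        pn <- parse_kern_note(nt, path)
        dt <- wholes_to_ticks(pn$dur_wholes)
        if (!pn$rest) {
          events[[length(events) + 1L]] <- data.frame(
            onset_ticks = t_pos[si], duration_ticks = dt, pitch = pn$pitch,
            voice = as.character(si), tie_stop = pn$tie_stop, grace = FALSE)
        }
      }
      t_pos[si] <- t_pos[si] + dt
    }
  }
  if (!length(events)) stop("kern file '", path, "' contains no notes")
  if (is.na(ts_num)) {
    stop("kern file '", path, "' has no time signature (*M); supply one via ",
         "a config override")
  }
  ev <- merge_ties(do.call(rbind, events))
  score(events = ev[, c("onset_ticks", "duration_ticks", "pitch", "voice",
                        "tied", "grace")],
        time_signatures = data.frame(onset = 0, numerator = ts_num,
                                     denominator = ts_den),
        bpm = bpm, tempo_word = tempo_word, ...)
}

kern_pitch_token <- function(pitch) {
  pc <- pitch %% 12L; octave <- pitch %/% 12L - 1L
  letters_nat <- c("c", "c#", "d", "d#", "e", "f", "f#", "g", "g#", "a", "a#", "b")
  tok <- letters_nat[pc + 1L]
  base <- substr(tok, 1, 1); acc <- substr(tok, 2, 2)
  if (octave >= 4L) {
    paste0(strrep(base, octave - 3L), acc)
  } else {
    paste0(strrep(toupper(base), 4L - octave), acc)
  }
}

kern_dur_token <- function(dur_wholes) {
  for (base in c(1, 2, 4, 8, 16, 32, 64)) {
    if (isTRUE(all.equal(dur_wholes, 1 / base))) return(as.character(base))
    if (isTRUE(all.equal(dur_wholes, 1.5 / base))) return(paste0(base, "."))
    if (isTRUE(all.equal(dur_wholes, 1.75 / base))) return(paste0(base, ".."))
  }
  stop("duration ", dur_wholes, " wholes has no simple kern representation")
}

#' Write a score as (minimal) Humdrum **kern
#'
#' One spine per voice; notes crossing a barline are written as tied segments.
#'
#' @param sc a [score] object.
#' @param path output path.
#' @export
write_kern <- function(sc, path) {
  ts <- sc$time_signatures[1L, ]
  meas_len <- wholes_to_ticks(measure_wholes_for(ts$numerator, ts$denominator))
  voices <- sort(unique(sc$events$voice))
  # build token stream per voice: (tick, token); gaps become rest tokens so
  # that cumulative token durations reconstruct every onset exactly
  max_tick <- max(sc$events$onset_ticks + sc$events$duration_ticks)
  split_at_bars <- function(on, rem) {
    # returns data.frame(tick, dur, first, last) of barline-split segments
    out <- list(); first <- TRUE
    while (rem > 0L) {
      m <- 1L + as.integer((on - sc$anchor_ticks) %/% meas_len)
      m_end <- measure_start_tick(sc, m + 1L)
      take <- min(rem, m_end - on)
      out[[length(out) + 1L]] <- data.frame(tick = on, dur = take,
                                            first = first, last = rem == take)
      on <- on + take; rem <- rem - take; first <- FALSE
    }
    do.call(rbind, out)
  }
  per_voice <- list()
  for (v in voices) {
    ev <- sc$events[sc$events$voice == v & !sc$events$grace, , drop = FALSE]
    ev <- ev[order(ev$onset_ticks, ev$pitch), , drop = FALSE]
    toks <- list()
    pos <- 0L
    for (on in unique(ev$onset_ticks)) {
      grp <- ev[ev$onset_ticks == on, , drop = FALSE]
      dur <- grp$duration_ticks[1L]
      if (on > pos) {  # gap -> rests
        rseg <- split_at_bars(pos, on - pos)
        for (q in seq_len(nrow(rseg))) {
          toks[[length(toks) + 1L]] <- list(
            tick = rseg$tick[q],
            token = paste0(kern_dur_token(ticks_to_wholes(rseg$dur[q])), "r"))
        }
      }
      seg <- split_at_bars(on, dur)
      for (q in seq_len(nrow(seg))) {
        dt <- kern_dur_token(ticks_to_wholes(seg$dur[q]))
        note_tok <- paste(vapply(grp$pitch, function(p) {
          paste0(if (seg$first[q] && !seg$last[q]) "[" else "",
                 dt, kern_pitch_token(p),
                 if (!seg$first[q]) "]" else "")
        }, character(1)), collapse = " ")
        toks[[length(toks) + 1L]] <- list(tick = seg$tick[q], token = note_tok)
      }
      pos <- on + dur
    }
    if (pos < max_tick) {
      rseg <- split_at_bars(pos, max_tick - pos)
      for (q in seq_len(nrow(rseg))) {
        toks[[length(toks) + 1L]] <- list(
          tick = rseg$tick[q],
          token = paste0(kern_dur_token(ticks_to_wholes(rseg$dur[q])), "r"))
      }
    }
    per_voice[[v]] <- toks
  }
  # merge into lines at every tick where any voice has a token or a barline
  ticks <- sort(unique(c(unlist(lapply(per_voice, function(tv)
    vapply(tv, `[[`, numeric(1), "tick"))),
    seq(sc$anchor_ticks, max_tick, by = meas_len))))
  ticks <- ticks[ticks < max_tick]
  lines <- paste(rep("**kern", length(voices)), collapse = "\t")
  lines <- c(lines, paste(rep(sprintf("*M%d/%d", ts$numerator, ts$denominator),
                              length(voices)), collapse = "\t"))
  if (!is.na(sc$bpm)) {
    lines <- c(lines, paste(rep(sprintf("*MM%g", sc$bpm), length(voices)),
                            collapse = "\t"))
  } else if (!is.na(sc$tempo_word)) {
    lines <- c(lines, paste(rep(sprintf("*MM[%s]", sc$tempo_word), length(voices)),
                            collapse = "\t"))
  }
  bar_no <- 1L
  for (tk in ticks) {
    if (tk > sc$anchor_ticks && (tk - sc$anchor_ticks) %% meas_len == 0L) {
      bar_no <- bar_no + 1L
      lines <- c(lines, paste(rep(paste0("=", bar_no), length(voices)),
                              collapse = "\t"))
    }
    row <- vapply(voices, function(v) {
      tv <- per_voice[[v]]
      hit <- which(vapply(tv, `[[`, numeric(1), "tick") == tk)
      if (length(hit)) tv[[hit[1L]]]$token else "."
    }, character(1))
    lines <- c(lines, paste(row, collapse = "\t"))
  }
  lines <- c(lines, paste(rep("*-", length(voices)), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
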