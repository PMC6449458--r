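# MusicXML (uncompressed .musicxml/.xml, score-partwise) reader and a minimal
# writer. Only the note-level content the accent models consume is handled:
# pitch, duration, voice, chord/grace/rest/tie, divisions, time signature,
# tempo (sound tempo or direction words).

step_to_pc <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)

#' Read a MusicXML score
#' @param path file path to an uncompressed `.musicxml`/`.xml` file.
#' @param ... passed to [score] (e.g. `style`, flag overrides).
#' @return a [score] object.
#' @export
read_musicxml <- function(path, ...) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("cannot parse MusicXML file '", path, "': ", conditionMessage(e))
  })
  if (xml2::xml_name(doc) != "score-partwise") {
    stop("unsupported MusicXML root element <", xml2::xml_name(doc),
         ">; only score-partwise is handled")
  }
  parts <- xml2::xml_find_all(doc, "./part")
  events <- list()
  ts_rows <- list()
  bpm <- NA_real_; tempo_word <- NA_character_
  for (pi in seq_along(parts)) {
    part <- parts[[pi]]
    part_id <- xml2::xml_attr(part, "id") %||% as.character(pi)
    divisions <- NA_real_  # duration units per quarter note
    t <- 0L                 # running tick position
    for (meas in xml2::xml_find_all(part, "./measure")) {
      meas_no <- suppressWarnings(as.integer(xml2::xml_attr(meas, "number")))
      last_onset <- t
      for (el in xml2::xml_children(meas)) {
        nm <- xml2::xml_name(el)
        if (nm == "attributes") {
          dv <- xml2::xml_find_first(el, "./divisions")
          if (!inherits(dv, "xml_missing")) divisions <- xml2::xml_double(dv)
          tm <- xml2::xml_find_first(el, "./time")
          if (!inherits(tm, "xml_missing")) {
            ts_rows[[length(ts_rows) + 1L]] <- data.frame(
              onset_ticks = t,
              numerator = as.integer(xml2::xml_text(xml2::xml_find_first(tm, "./beats"))),
              denominator = as.integer(xml2::xml_text(xml2::xml_find_first(tm, "./beat-type"))))
          }
        } else if (nm == "direction") {
          snd <- xml2::xml_find_first(el, ".//sound[@tempo]")
          if (!inherits(snd, "xml_missing") && is.na(bpm)) {
            bpm <- as.numeric(xml2::xml_attr(snd, "tempo"))
          }
          wd <- xml2::xml_find_first(el, ".//words")
          if (!inherits(wd, "xml_missing") && is.na(tempo_word)) {
            tempo_word <- trimws(xml2::xml_text(wd))
          }
        } else if (nm == "sound") {
          tp <- xml2::xml_attr(el, "tempo")
          if (!is.na(tp) && is.na(bpm)) bpm <- as.numeric(tp)
        } else if (nm == "backup") {
          dur <- xml2::xml_double(xml2::xml_find_first(el, "./duration"))
          t <- t - mx_ticks(dur, divisions, path)
        } else if (nm == "forward") {
          dur <- xml2::xml_double(xml2::xml_find_first(el, "./duration"))
          t <- t + mx_ticks(dur, divisions, path)
        } else if (nm == "note") {
          is_grace <- !inherits(xml2::xml_find_first(el, "./grace"), "xml_missing")
          is_chord <- !inherits(xml2::xml_find_first(el, "./chord"), "xml_missing")
          is_rest <- !inherits(xml2::xml_find_first(el, "./rest"), "xml_missing")
          dur_el <- xml2::xml_find_first(el, "./duration")
          dt <- if (is_grace || inherits(dur_el, "xml_missing")) 0L
                else mx_ticks(xml2::xml_double(dur_el), divisions, path)
          onset <- if (is_chord) last_onset else t
          if (!is_rest) {
            pe <- xml2::xml_find_first(el, "./pitch")
            if (inherits(pe, "xml_missing")) {
              stop("MusicXML parse error in '", path,
                   "': <note> without <pitch> or <rest>")
            }
            stp <- xml2::xml_text(xml2::xml_find_first(pe, "./step"))
            alt_el <- xml2::xml_find_first(pe, "./alter")
            alter <- if (inherits(alt_el, "xml_missing")) 0 else xml2::xml_double(alt_el)
            oct <- as.integer(xml2::xml_text(xml2::xml_find_first(pe, "./octave")))
            pitch <- 12L * (oct + 1L) + step_to_pc[[stp]] + as.integer(alter)
            voice_el <- xml2::xml_find_first(el, "./voice")
            voice <- if (inherits(voice_el, "xml_missing")) "1"
                     else xml2::xml_text(voice_el)
            tie_stop <- length(xml2::xml_find_all(el, "./tie[@type='stop']")) > 0
            events[[length(events) + 1L]] <- data.frame(
              onset_ticks = onset, duration_ticks = dt, pitch = pitch,
              voice = paste0(part_id, ".", voice), tie_stop = tie_stop,
              grace = is_grace)
          }
          if (!is_chord && !is_grace) { last_onset <- t; t <- t + dt }
        }
      }
    }
  }
  if (!length(events)) stop("MusicXML file '", path, "' contains no notes")
  if (!length(ts_rows)) {
    stop("MusicXML file '", path, "' has no time signature; supply a score ",
         "with an explicit time signature via a config override")
  }
  ev <- do.call(rbind, events)
  ev <- merge_ties(ev)
  ts <- unique(do.call(rbind, ts_rows))
  score(events = ev[, c("onset_ticks", "duration_ticks", "pitch", "voice",
                        "tied", "grace")],
        time_signatures = data.frame(onset = ticks_to_wholes(ts$onset_ticks),
                                     numerator = ts$numerator,
                                     denominator = ts$denominator),
        bpm = bpm, tempo_word = tempo_word, ...)
}

mx_ticks <- function(dur, divisions, path) {
  if (is.na(divisions)) {
    stop("MusicXML parse error in '", path, "': <duration> before <divisions>")
  }
  t <- dur / divisions * (TPW / 4)
  ti <- as.integer(round(t))
  if (abs(t - ti) > 1e-6) {
    stop("MusicXML parse error in '", path, "': duration ", dur,
         " not representable at divisions=", divisions)
  }
  ti
}

# Merge tie chains (same voice+pitch, continuation flagged tie_stop and
# starting exactly where the previous segment ends) into one logical note
# carrying the summed duration and tied=TRUE.
merge_ties <- function(ev) {
  ev <- ev[order(ev$voice, ev$pitch, ev$onset_ticks), , drop = FALSE]
  keep <- rep(TRUE, nrow(ev))
  ev$tied <- FALSE
  if (nrow(ev) > 1L) for (i in 2:nrow(ev)) {
    j <- i - 1L
    while (j >= 1L && !keep[j]) j <- j - 1L
    if (j >= 1L && isTRUE(ev$tie_stop[i]) &&
        ev$voice[i] == ev$voice[j] && ev$pitch[i] == ev$pitch[j] &&
        ev$onset_ticks[i] == ev$onset_ticks[j] + ev$duration_ticks[j]) {
      ev$duration_ticks[j] <- ev$duration_ticks[j] + ev$duration_ticks[i]
      ev$tied[j] <- TRUE
      keep[i] <- FALSE
    }
  }
  ev <- ev[keep, , drop = FALSE]
  ev$tie_stop <- NULL
  rownames(ev) <- NULL
  ev[order(ev$onset_ticks, ev$voice, ev$pitch), , drop = FALSE]
}

#' Write a score as (minimal) MusicXML
#'
#' Serializes each voice as its own part; durations are expressed at 768
#' divisions per quarter so everything on the package's internal grid is
#' exactly representable. Notes crossing a barline are split into tied
#' segments on output (the reader re-merges them).
#'
#' @param sc a [score] object.
#' @param path output path.
#' @export
write_musicxml <- function(sc, path) {
  div <- as.integer(TPW / 4)
  ts <- sc$time_signatures[1L, ]
  meas_len <- wholes_to_ticks(measure_wholes_for(ts$numerator, ts$denominator))
  voices <- sort(unique(sc$events$voice))
  pos_all <- score_positions(sc, sc$events$onset_ticks)
  first_meas <- min(pos_all$measure)
  pcs_sharp <- c("C", "C", "D", "D", "E", "F", "F", "G", "G", "A", "A", "B")
  alt_sharp <- c(0, 1, 0, 1, 0, 0, 1, 0, 1, 0, 1, 0)
  note_xml <- function(pitch, d, tie_start, tie_stop) {
    pc <- pitch %% 12; oct <- pitch %/% 12 - 1
    alter <- if (alt_sharp[pc + 1] != 0) "<alter>1</alter>" else ""
    ties <- paste0(if (tie_stop) '<tie type="stop"/>' else "",
                   if (tie_start) '<tie type="start"/>' else "")
    sprintf(paste0("      <note><pitch><step>%s</step>%s<octave>%d</octave>",
                   "</pitch><duration>%d</duration>%s</note>"),
            pcs_sharp[pc + 1], alter, oct, d, ties)
  }
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<score-partwise version="3.1">', "  <part-list>")
  for (i in seq_along(voices)) {
    lines <- c(lines,
               sprintf('    <score-part id="P%d"><part-name>%s</part-name></score-part>',
                       i, voices[i]))
  }
  lines <- c(lines, "  </part-list>")
  for (i in seq_along(voices)) {
    ev <- sc$events[sc$events$voice == voices[i], , drop = FALSE]
    ev <- ev[order(ev$onset_ticks, ev$pitch), , drop = FALSE]
    # pre-pass: split events at barlines into tied segments
    segs <- list()
    for (k in seq_len(nrow(ev))) {
      on <- ev$onset_ticks[k]; dur <- ev$duration_ticks[k]
      repeat {
        m <- 1L + as.integer((on - sc$anchor_ticks) %/% meas_len)
        m_end <- measure_start_tick(sc, m + 1L)
        take <- if (dur == 0L) 0L else min(dur, m_end - on)
        segs[[length(segs) + 1L]] <- data.frame(
          onset = on, dur = take, pitch = ev$pitch[k], measure = m,
          tie_start = dur > take, tie_stop = on > ev$onset_ticks[k])
        on <- on + take; dur <- dur - take
        if (dur <= 0L) break
      }
    }
    segs <- do.call(rbind, segs)
    last_meas <- max(segs$measure)
    lines <- c(lines, sprintf('  <part id="P%d">', i))
    for (m in first_meas:last_meas) {
      m_start <- measure_start_tick(sc, m)
      lines <- c(lines, sprintf('    <measure number="%d">', m))
      if (m == first_meas) {
        lines <- c(lines, "      <attributes>",
                   sprintf("        <divisions>%d</divisions>", div),
                   sprintf("        <time><beats>%d</beats><beat-type>%d</beat-type></time>",
                           ts$numerator, ts$denominator),
                   "      </attributes>")
        if (!is.na(sc$bpm)) {
          lines <- c(lines, sprintf('      <sound tempo="%g"/>', sc$bpm))
        } else if (!is.na(sc$tempo_word)) {
          lines <- c(lines, "      <direction><direction-type>",
                     sprintf("        <words>%s</words>", sc$tempo_word),
                     "      </direction-type></direction>")
        }
      }
      sm <- segs[segs$measure == m, , drop = FALSE]
      sm <- sm[order(sm$onset, sm$pitch), , drop = FALSE]
      pos <- m_start
      k <- 1L
      while (k <= nrow(sm)) {
        if (sm$onset[k] > pos) {
          lines <- c(lines, sprintf("      <note><rest/><duration>%d</duration></note>",
                                    sm$onset[k] - pos))
          pos <- sm$onset[k]
        }
        # notes sharing an onset and duration become a <chord>
        same <- which(sm$onset == sm$onset[k] & sm$dur == sm$dur[k])
        same <- same[same >= k]
        for (q in seq_along(same)) {
          xml <- note_xml(sm$pitch[same[q]], sm$dur[same[q]],
                          sm$tie_start[same[q]], sm$tie_stop[same[q]])
          if (q > 1) xml <- sub("<note>", "<note><chord/>", xml, fixed = TRUE)
          lines <- c(lines, xml)
        }
        pos <- pos + sm$dur[k]
        k <- max(same) + 1L
      }
      if (pos < m_start + meas_len && m < last_meas) {
        lines <- c(lines, sprintf("      <note><rest/><duration>%d</duration></note>",
                                  m_start + meas_len - pos))
      }
      lines <- c(lines, "    </measure>")
    }
    lines <- c(lines, "  </part>")
  }
  lines <- c(lines, "</score-partwise>")
  writeLines(lines, path)
  invisible(path)
}
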