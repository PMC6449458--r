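test_that("a simple MusicXML file is transcribed note for note", {
  xml <- c(
    '<?xml version="1.0"?>',
    '<score-partwise version="3.1">',
    '  <part-list><score-part id="P1"><part-name>x</part-name></score-part></part-list>',
    '  <part id="P1">',
    '    <measure number="1">',
    '      <attributes><divisions>1</divisions>',
    '        <time><beats>3</beats><beat-type>4</beat-type></time></attributes>',
    '      <note><pitch><step>C</step><octave>4</octave></pitch><duration>1</duration></note>',
    '      <note><pitch><step>C</step><octave>4</octave></pitch><duration>1</duration></note>',
    '      <note><pitch><step>C</step><octave>4</octave></pitch><duration>1</duration></note>',
    '    </measure>',
    '  </part>',
    '</score-partwise>')
  f <- withr::local_tempfile(fileext = ".musicxml")
  writeLines(xml, f)
  sc <- read_score(f)
  expect_s3_class(sc, "score")
  expect_equal(nrow(sc$events), 3L)
  expect_equal(ticks_to_wholes(sc$events$onset_ticks), c(0, 1 / 4, 2 / 4))
  expect_equal(sc$events$pitch, rep(60L, 3))
  expect_equal(sc$time_signatures$numerator, 3L)
})

test_that("kern ties merge into one logical note with the tied flag", {
  f <- withr::local_tempfile(fileext = ".krn")
  writeLines(c("**kern", "*M3/4", "*MM72", "[2c", "=2", "4c]", "4d", "*-"), f)
  sc <- read_score(f)
  expect_equal(nrow(sc$events), 2L)
  expect_equal(ticks_to_wholes(sc$events$duration_ticks[1]), 3 / 4)
  expect_true(sc$events$tied[1])
  expect_false(sc$events$tied[2])
})

test_that("MIDI voices come from channels/tracks; sonorities match onsets", {
  sc0 <- generate_progression(seed = 7, two_voice = TRUE,
                              templates = c("major", "minor", "dom7", "major"),
                              duration_beats = 1)
  f <- withr::local_tempfile(fileext = ".mid")
  write_midi(sc0, f)
  sc <- read_midi(f)
  expect_gte(length(unique(sc$events$voice)), 2L)
  st <- chordify(sc)
  expect_equal(nrow(st$sonorities), oracle_onset_count(sc))
  expect_equal(nrow(st$sonorities), oracle_onset_count(sc0))
})

test_that("chordify slices at every onset with held tones carried over", {
  ev <- data.frame(onset = c(0, 0, 1 / 4, 2 / 4),
                   duration = c(3 / 4, 1 / 4, 1 / 4, 1 / 4),
                   pitch = c(48, 60, 64, 67),
                   voice = c("bass", "mel", "mel", "mel"))
  sc <- score(ev, data.frame(onset = 0, numerator = 3, denominator = 4),
              bpm = 60)
  st <- chordify(sc)
  expect_equal(nrow(st$sonorities), 3L)
  expect_equal(st$sonorities$pitches[[1]], c(48, 60))
  expect_equal(st$sonorities$new_pitches[[1]], c(48, 60))
  expect_equal(st$sonorities$pitches[[2]], c(48, 64))
  expect_equal(st$sonorities$new_pitches[[2]], 64)
  # held bass: remaining duration from slice 2 is 2 beats of 3/4
  expect_equal(st$sonorities$dur_beats[[2]], c(2, 1))
})

test_that("a homophonic chorale gives one sonority per chord, all unprepared", {
  sc <- generate_progression(templates = c("major", "minor", "major", "dom7"),
                             seed = 2, duration_beats = 1)
  st <- chordify(sc)
  expect_equal(nrow(st$sonorities), 4L)
  for (i in 1:4) {
    expect_equal(st$sonorities$pitches[[i]], st$sonorities$new_pitches[[i]])
  }
})

test_that("melody extraction strategies behave as documented", {
  mono <- generate_melody(n_notes = 12, seed = 4)
  m1 <- extract_melody(mono, "skyline")
  m2 <- extract_melody(mono, "top_voice")
  expect_equal(m1$pitch, mono$events$pitch)
  expect_equal(m2$pitch, mono$events$pitch)
  # melody over an Alberti-like lower voice: skyline keeps the upper line
  ev <- rbind(
    data.frame(onset = (0:3) / 4, duration = 1 / 4,
               pitch = c(72, 76, 77, 79), voice = "mel"),
    data.frame(onset = (0:7) / 8, duration = 1 / 8,
               pitch = rep(c(48, 55), 4), voice = "alberti"))
  sc <- score(ev, data.frame(onset = 0, numerator = 4, denominator = 4),
              bpm = 96)
  sky <- extract_melody(sc, "skyline")
  expect_equal(oracle_skyline(sc), sky$pitch)
  expect_true(all(sky$pitch[sky$onset_ticks %in% wholes_to_ticks((0:3) / 4)]
                  %in% c(72, 76, 77, 79)))
  expect_error(extract_melody(sc, "named_voice", voice = "nope"),
               "available voices")
})

test_that("crossing voices: skyline equals the per-onset maximum oracle", {
  ev <- rbind(
    data.frame(onset = (0:5) / 4, duration = 1 / 4,
               pitch = c(60, 62, 64, 66, 68, 70), voice = "a"),
    data.frame(onset = (0:5) / 4, duration = 1 / 4,
               pitch = c(67, 66, 65, 64, 63, 62), voice = "b"))
  sc <- score(ev, data.frame(onset = 0, numerator = 3, denominator = 4),
              bpm = 60)
  expect_equal(extract_melody(sc, "skyline")$pitch, oracle_skyline(sc))
})

test_that("accent tables serialize exactly and round-trip", {
  sc <- generate_metrical_grid(3, 4, 2, 60)
  st <- chordify(sc)
  n <- nrow(st$sonorities)
  tab <- accent_table(st, M = c(1.216, rep(0, n - 1)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_accent_table(tab, f)
  lines <- readLines(f)
  expect_equal(lines[1],
               "sonority_index,measure,beat,onset_wholes,pitches,M,C,Hv,Hh,H1,H2")
  expect_match(lines[2], "1\\.216000")
  back <- read_accent_table(f)
  expect_equal(back$M, tab$M, tolerance = 5e-7)
  # empty table -> header-only CSV
  tab0 <- tab[0, , drop = FALSE]
  f0 <- withr::local_tempfile(fileext = ".csv")
  write_accent_table(tab0, f0)
  expect_equal(length(readLines(f0)), 1L)
  # JSON mirrors CSV
  fj <- withr::local_tempfile(fileext = ".json")
  write_accent_table(tab, fj)
  expect_equal(read_accent_table(fj)$M, tab$M, tolerance = 5e-7)
})

test_that("chordify is stable under write/read for both text formats", {
  for (seed in c(7, 21)) {
    sc <- generate_progression(seed = seed, two_voice = seed == 7,
                               templates = c("major", "dim", "minor", "dom7",
                                             "major", "sus4"),
                               duration_beats = 1)
    s0 <- chordify(sc)
    fx <- withr::local_tempfile(fileext = ".musicxml")
    write_musicxml(sc, fx)
    sx <- chordify(read_score(fx))
    expect_equal(sx$sonorities$pitches, s0$sonorities$pitches)
    expect_equal(sx$sonorities$new_pitches, s0$sonorities$new_pitches)
    fk <- withr::local_tempfile(fileext = ".krn")
    write_kern(sc, fk)
    sk <- chordify(read_score(fk))
    expect_equal(sk$sonorities$pitches, s0$sonorities$pitches)
    expect_equal(sk$sonorities$new_pitches, s0$sonorities$new_pitches)
  }
})

test_that("sonority pitch content is a subset of sounding events", {
  sc <- generate_progression(seed = 13, templates = NULL, n_chords = 8,
                             duration_beats = c(1, 2, 1, 1, 3, 1, 2, 1))
  st <- chordify(sc)
  ends <- sc$events$onset_ticks + sc$events$duration_ticks
  for (i in seq_len(nrow(st$sonorities))) {
    t <- st$sonorities$onset_ticks[i]
    sounding <- sc$events$pitch[sc$events$onset_ticks <= t & ends > t]
    expect_true(all(st$sonorities$pitches[[i]] %in% sounding))
    expect_true(all(st$sonorities$new_pitches[[i]] %in%
                      st$sonorities$pitches[[i]]))
  }
  expect_equal(nrow(st$sonorities), oracle_onset_count(sc))
})

test_that("missing or malformed inputs raise informative errors", {
  expect_error(read_score("no-such-file.musicxml"), "does not exist")
  f <- withr::local_tempfile(fileext = ".krn")
  writeLines(c("**kern", "4c", "*-"), f)  # no time signature
  expect_error(read_score(f), "time signature")
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<opus></opus>", f2)
  expect_error(read_score(f2), "score-partwise")
})
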