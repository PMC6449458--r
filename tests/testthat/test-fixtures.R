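test_that("the metrical grid fixture lays out events and level truth", {
  sc <- generate_metrical_grid(3, 4, 4, 60)
  expect_equal(nrow(sc$events), 24L)  # 6 eighths x 4 measures
  gt <- attr(sc, "ground_truth")
  onsets <- ticks_to_wholes(sc$events$onset_ticks)
  downbeats <- which(onsets %% (3 / 4) == 0)
  odd_db <- downbeats[(onsets[downbeats] / (3 / 4)) %% 2 == 0]
  for (i in odd_db) expect_equal(gt$levels[[i]], 0:3)
  even_db <- setdiff(downbeats, odd_db)
  for (i in even_db) expect_equal(gt$levels[[i]], 0:2)
  # 6/8: the beat level sits on dotted quarters
  sc68 <- generate_metrical_grid(6, 8, 2, 60)
  gt68 <- attr(sc68, "ground_truth")
  onsets68 <- ticks_to_wholes(sc68$events$onset_ticks)
  beat_marked <- vapply(gt68$levels, function(l) 1L %in% l, logical(1))
  expect_equal(onsets68[beat_marked], seq(0, 6 / 8 * 2 - 3 / 8, by = 3 / 8))
  expect_error(generate_metrical_grid(5, 4), "extend")
})

test_that("fixture generators are deterministic under a fixed seed", {
  a <- generate_melody(n_notes = 30, seed = 9)
  b <- generate_melody(n_notes = 30, seed = 9)
  expect_identical(a$events, b$events)
  fa <- withr::local_tempfile(fileext = ".krn")
  fb <- withr::local_tempfile(fileext = ".krn")
  write_kern(a, fa); write_kern(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  p1 <- generate_progression(seed = 4, templates = NULL, n_chords = 8)
  p2 <- generate_progression(seed = 4, templates = NULL, n_chords = 8)
  expect_identical(p1$events, p2$events)
  expect_identical(attr(p1, "ground_truth"), attr(p2, "ground_truth"))
  r1 <- generate_ratings(c(1, 0, 4, 2), 5, 1, 0.8, seed = 12)
  r2 <- generate_ratings(c(1, 0, 4, 2), 5, 1, 0.8, seed = 12)
  expect_identical(r1, r2)
})

test_that("melody fixtures annotate contour extremes like a local scan", {
  # sawtooth forced by an alternating interval distribution: +9 then -9
  saw <- generate_melody(n_notes = 12, seed = 2, start_pitch = 60,
                         intervals = c(9, -9), range = c(55, 70))
  gt_saw <- attr(saw, "ground_truth")
  p_saw <- saw$events$pitch
  expect_equal(which(gt_saw$peak),
               which(c(FALSE, diff(p_saw)[-11] > 0 & diff(p_saw)[-1] < 0,
                       FALSE)))
  # seeded random walks agree with the brute-force extrema scan
  for (seed in c(6, 17)) {
    sc <- generate_melody(n_notes = 20, seed = seed)
    gt <- attr(sc, "ground_truth")
    d <- diff(sc$events$pitch)
    for (i in 2:19) {
      expect_equal(gt$peak[i], d[i - 1] > 0 && d[i] < 0)
      expect_equal(gt$valley[i], d[i - 1] < 0 && d[i] > 0)
    }
    expect_false(gt$peak[1] || gt$peak[20] || gt$valley[1] || gt$valley[20])
  }
})

test_that("progression fixtures carry their Tn ground truth", {
  sc <- generate_progression(templates = c("major", "major", "cluster",
                                           "major"),
                             seed = 3, duration_beats = 1)
  gt <- attr(sc, "ground_truth")
  expect_equal(gt$tn[[1]], c(0L, 4L, 7L))
  expect_equal(gt$tn[[2]], c(0L, 4L, 7L))
  expect_equal(gt$tn[[3]], c(0L, 1L, 2L))
  expect_error(generate_progression(templates = "nonsense", seed = 1),
               "unknown chord template")
  # a held tone makes the following slice prepared
  sch <- generate_progression(templates = rep("major", 4), seed = 1,
                              roots = rep(60, 4), duration_beats = 1,
                              held_from = 2)
  st <- chordify(sch)
  expect_equal(classify_preparedness(st$sonorities$pitches[[3]],
                                     st$sonorities$new_pitches[[3]]),
               "prepared")
})

test_that("the prelude skeleton encodes the published melodic landmarks", {
  sc <- prelude7_skeleton()
  expect_equal(sc$time_signatures$numerator, 3L)
  expect_equal(sc$time_signatures$denominator, 4L)
  mel <- extract_melody(sc)
  at <- function(m, b) mel$pitch[mel$measure == m & mel$beat == b]
  # M6 rise into the measure-1 accent
  expect_equal(at(1, 2) - at(1, 1), 9)
  # P5 into the end of measure 2, P4 into beat 2 of measure 3
  expect_equal(at(2, 3) - at(2, 2), 7)
  expect_equal(at(3, 2) - at(3, 1), 5)
  # measure 9 repeats measure 1
  expect_equal(unlist(lapply(1:3, function(b) at(9, b))),
               unlist(lapply(1:3, function(b) at(1, b))))
  # climax C#6 on beat 2 of measure 11, the piece's highest tone
  expect_equal(at(11, 2), 85)
  expect_equal(max(mel$pitch), 85)
  # a contour valley at measure 6 beat 3
  i <- which(mel$measure == 6 & mel$beat == 3)
  expect_lt(mel$pitch[i], mel$pitch[i - 1])
  expect_lt(mel$pitch[i], mel$pitch[i + 1])
})

test_that("synthetic ratings respect their noise and dropout contracts", {
  truth <- c(0, 5, 2, 0, 4, 1, 0, 3)
  exact <- generate_ratings(truth, n_raters = 3, noise_sd = 0,
                            mark_prob = 1, seed = 2)
  for (r in 1:3) expect_equal(unname(exact[r, ]), round(truth))
  # dropout: marked fraction within 3 binomial sigmas of mark_prob
  truth2 <- rep(3, 1000)
  dropped <- generate_ratings(truth2, n_raters = 1, noise_sd = 0,
                              mark_prob = 0.5, seed = 8)
  frac <- mean(dropped > 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("the bundled familiarity table is synthetic and major-led", {
  tab <- default_familiarity()
  expect_match(tab$provenance, "synthetic")
  comb <- vapply(tab$counts, function(x) x$prepared + x$unprepared,
                 numeric(1))
  expect_equal(names(which.max(comb)), "0,4,7")
  expect_gte(tab$total_events, 150)
  expect_identical(default_familiarity()$counts, tab$counts)
})
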