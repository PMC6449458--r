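toy_table <- function(...) {
  counts <- list(...)
  familiarity_table(counts, sum(vapply(counts, function(x)
    (x$prepared %||% 0) + (x$unprepared %||% 0), numeric(1))), "toy")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Tn classification reproduces the triad examples", {
  expect_equal(tn_type(c(60, 64, 67)), c(0L, 4L, 7L))   # major
  expect_equal(tn_type(c(62, 65, 69)), c(0L, 3L, 7L))   # minor
  expect_equal(tn_type(c(71, 62, 65)), c(0L, 3L, 6L))   # diminished
  expect_false(identical(tn_type(c(60, 64, 67)), tn_type(c(60, 63, 67))))
  expect_equal(tn_type(60), 0L)
  expect_error(tn_type(integer(0)), "empty")
})

test_that("Tn classification partitions all 4095 subsets like the oracle", {
  labels_impl <- character(4095)
  labels_orac <- numeric(4095)
  k <- 0L
  for (mask in 1:4095) {
    pcs <- which(bitwAnd(mask, 2^(0:11)) > 0) - 1L
    k <- k + 1L
    labels_impl[k] <- paste(tn_type(pcs), collapse = ",")
    labels_orac[k] <- oracle_tn_canon(pcs)
  }
  # the two labelings induce the same partition
  expect_equal(length(unique(labels_impl)), length(unique(labels_orac)))
  expect_equal(length(unique(paste(labels_impl, labels_orac))),
               length(unique(labels_impl)))
  # representative invariants
  for (mask in c(1, 137, 2048, 4095)) {
    pcs <- which(bitwAnd(mask, 2^(0:11)) > 0) - 1L
    tn <- tn_type(pcs)
    expect_equal(tn[1], 0L)
    expect_true(all(diff(tn) > 0))
    expect_equal(tn_type(pcs + 5L), tn)  # transposition invariance
  }
})

test_that("scaled duration follows the three branches, halving first", {
  expect_equal(scaled_duration(0.5, 3), 0.5)
  expect_equal(scaled_duration(2, 3), sqrt(2), tolerance = 1e-9)
  expect_equal(scaled_duration(4, 3), sqrt(3), tolerance = 1e-9)
  # fast tempo halves before the branch decision: d_n = 2 -> 1 -> first branch
  expect_equal(scaled_duration(2, 3, fast_tempo = TRUE), 1)
  expect_equal(scaled_duration(8, 3, fast_tempo = TRUE), sqrt(3))
  expect_error(scaled_duration(0, 3), "positive")
})

test_that("vertical accents scale with unfamiliarity and duration", {
  tab <- toy_table("0,4,7" = list(prepared = 4, unprepared = 6),
                   "0,3,7" = list(prepared = 1, unprepared = 4),
                   "0"     = list(prepared = 0, unprepared = 2))
  sp <- style_params("romantic")  # P_v = 2
  # most frequent type -> H_v = 0 at any duration
  expect_equal(vertical_accent(c(60, 64, 67), 1, tab, sp, n_b = 3), 0)
  expect_equal(vertical_accent(c(60, 64, 67), 3, tab, sp, n_b = 3), 0)
  # f = 0.5 (minor: 5 of max 10), d = 1: (0.5)^4 * 5 = 0.3125
  expect_equal(vertical_accent(c(60, 63, 67), 1, tab, sp, n_b = 3), 0.3125)
  # unseen cluster, d = 1: full salience 5
  expect_equal(vertical_accent(c(60, 61, 62), 1, tab, sp, n_b = 3), 5)
  # the SHORTEST notated duration drives d
  expect_equal(vertical_accent(c(60, 61, 62), c(3, 0.5, 2), tab, sp, n_b = 3),
               5 * 0.5)
  # H_v is nonincreasing in frequency, nondecreasing in duration
  expect_gt(vertical_accent(c(60, 61, 62), 1, tab, sp, n_b = 3),
            vertical_accent(c(60, 63, 67), 1, tab, sp, n_b = 3))
  expect_gt(vertical_accent(c(60, 63, 67), 2, tab, sp, n_b = 3),
            vertical_accent(c(60, 63, 67), 1, tab, sp, n_b = 3))
})

test_that("H_v decreases strictly in P_v for intermediate familiarity", {
  tab <- toy_table("0,4,7" = list(unprepared = 10),
                   "0,3,7" = list(unprepared = 5))
  hv <- vapply(c(2, 2.5, 3, 4), function(pv)
    vertical_accent(c(60, 63, 67), 1, tab, style_params(P_v = pv), n_b = 3),
    numeric(1))
  expect_true(all(diff(hv) < 0))
})

test_that("pitch-class salience profiles mirror root-support intuitions", {
  w <- root_support_weights()
  # C major: root C strictly maximal; E and G weaker
  p <- pc_salience_profile(c(60, 64, 67), w)
  expect_equal(p[0 + 1], 18)
  expect_equal(p[4 + 1], 10)
  expect_equal(p[7 + 1], 10)
  expect_true(all(p[0 + 1] > p[-1]))
  # B diminished: the missing fundamental G gets salience
  q <- pc_salience_profile(c(71, 62, 65), w)
  expect_equal(q[7 + 1], 10)
  expect_gt(q[7 + 1], 0)
  # single pitch class C: the profile is the weight template itself
  s <- pc_salience_profile(60, w)
  expect_equal(s[c(0, 5, 8, 2, 10) + 1], c(10, 5, 3, 2, 1))
  expect_equal(sum(s), sum(w))
  # octave doublings do not change the profile
  expect_equal(pc_salience_profile(c(48, 60, 64, 67, 76), w), p)
})

test_that("horizontal accents vanish on repetition and at the piece start", {
  sc <- generate_progression(templates = rep("major", 5), seed = 1,
                             roots = rep(60, 5), duration_beats = 1)
  st <- chordify(sc)
  h <- vapply(1:5, function(i) horizontal_accent(st, i), numeric(1))
  expect_equal(h[1], 0)          # empty window
  expect_equal(h[2:5], rep(0, 4))  # perfect correlation with the window
})

test_that("a distant chord after one neighbour matches the hand computation", {
  # C major preceded by one F#-major triad, P_h = 2, d = 1
  sc <- generate_progression(templates = c("major", "major"), seed = 1,
                             roots = c(66, 60), duration_beats = 1)
  st <- chordify(sc)
  sp <- style_params("romantic")
  got <- horizontal_accent(st, 2, sp)
  pa <- pc_salience_profile(c(66, 70, 73))
  pb <- pc_salience_profile(c(60, 64, 67))
  expected <- (1 - max(cor(pa, pb), 0))^2 * 5 * 1
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("windowed weighted correlation equals the brute-force oracle", {
  set.seed(42)
  for (rep in 1:100) {
    n_win <- sample(1:6, 1)
    profs <- replicate(n_win + 1, stats::runif(12, 0, 10), simplify = FALSE)
    if (rep %% 7 == 0) profs[[2]] <- rep(3, 12)  # degenerate profile
    got <- profile_surprise(profs[[1]], profs[-1])
    expect_equal(got, oracle_surprise(profs[[1]], profs[-1]),
                 tolerance = 1e-10)
  }
})

test_that("transposing the whole stream leaves Hv and Hh unchanged", {
  tab <- default_familiarity()
  sc <- generate_progression(seed = 11,
                             templates = c("major", "dim", "minor", "dom7",
                                           "cluster", "major"),
                             duration_beats = 1)
  h0 <- harmonic_accents(chordify(sc), tab)
  for (shift in c(-3, 4)) {
    ht <- harmonic_accents(chordify(transpose_score(sc, shift)), tab)
    expect_equal(ht$Hv, h0$Hv)
    expect_equal(ht$Hh, h0$Hh, tolerance = 1e-12)
  }
})

test_that("combined models follow the published parameterization", {
  sp <- style_params("romantic")  # x1=4, x2=0.3, x3=1
  expect_equal(combine_harmonic(2, 3, 1, sp), 3)
  # low-dissonance regime: 0.2 + 2/4 = 0.7 < x3 = 1 -> 0
  expect_equal(combine_harmonic(0.2, 2, 2, sp), 0)
  # above the threshold the maximum rules
  expect_equal(combine_harmonic(0.5, 2, 2, sp), 2)
  # branch switch exactly at H_v = x2 (<= uses the weighted sum)
  expect_equal(combine_harmonic(0.3, 4, 2, sp), 1.3)
  expect_equal(combine_harmonic(0.3 + 1e-9, 4, 2, sp), 4)
  # weighted sum clips at 5
  expect_equal(combine_harmonic(0.2, 4.9 * 4 + 10, 2, sp), 5)
  # saturation for model 1
  expect_equal(combine_harmonic(7, 1, 1, sp), 5)
})

test_that("Model 2 suppresses weak-vertical root changes relative to Model 1", {
  for (style in c("baroque_classical", "romantic", "late_romantic")) {
    sp <- style_params(style)
    for (Hv in c(0.05, 0.1, sp$x2 * 0.9, sp$x2)) {
      for (Hh in c(2 * Hv, 1, 2.5, 5)) {
        if (Hh < 2 * Hv) next
        h1 <- combine_harmonic(Hv, Hh, 1, sp)
        h2 <- combine_harmonic(Hv, Hh, 2, sp)
        expect_lte(h2, h1)
      }
    }
  }
})

test_that("full harmonic columns match an element-wise recomputation", {
  tab <- default_familiarity()
  sc <- generate_progression(seed = 11,
                             templates = c("major", "dim", "minor", "dom7",
                                           "cluster", "major"),
                             duration_beats = c(1, 1, 2, 1, 1, 4))
  st <- chordify(sc)
  sp <- style_params("romantic")
  h <- harmonic_accents(st, tab, sp)
  comb <- vapply(tab$counts, function(x) x$prepared + x$unprepared, numeric(1))
  son <- st$sonorities
  profs <- lapply(son$pitches, pc_salience_profile)
  for (i in seq_len(nrow(son))) {
    key <- paste(tn_type(son$pitches[[i]]), collapse = ",")
    f <- if (key %in% names(comb)) comb[[key]] / max(comb) else 0
    d_v <- scaled_duration(min(son$dur_beats[[i]]), st$n_beats)
    expect_equal(h$Hv_raw[i], (1 - f)^4 * 5 * d_v, tolerance = 1e-12)
    win <- which(son$onset_ticks >= son$onset_ticks[i] - st$measure_ticks &
                   son$onset_ticks < son$onset_ticks[i])
    if (!length(win)) {
      expect_equal(h$Hh_raw[i], 0)
    } else {
      s <- oracle_surprise(profs[[i]], profs[rev(win)])
      d_h <- scaled_duration(max(son$dur_beats[[i]]), st$n_beats)
      expect_equal(h$Hh_raw[i], s^2 * 5 * d_h, tolerance = 1e-10)
    }
    expect_equal(h$H1[i], pmax(h$Hv[i], h$Hh[i]))
  }
  # a repeated single note: most familiar type in a unison-heavy table
  uni_tab <- toy_table("0" = list(unprepared = 50),
                       "0,4,7" = list(unprepared = 10))
  mono <- generate_metrical_grid(4, 4, 1, 96, subdivision_wholes = 1 / 4)
  hm <- harmonic_accents(chordify(mono), uni_tab)
  expect_true(all(hm$Hv == 0))
  expect_true(all(hm$Hh == 0))
  expect_true(all(hm$H1 == 0) && all(hm$H2 == 0))
  # a single-sonority piece: H_h = 0, H_v per the familiarity formula
  single <- generate_progression(templates = "dim", seed = 1, roots = 60,
                                 duration_beats = 1)
  hs <- harmonic_accents(chordify(single), uni_tab)
  expect_equal(hs$Hh, 0)
  # unseen type: f = 0, d = scaled_duration(1, 4) = 1 -> H_v = 5
  expect_equal(hs$Hv, (1 - 0)^4 * 5 * scaled_duration(1, 4))
})

test_that("Hv and Hh stay within the documented pre-saturation bounds", {
  tab <- default_familiarity()
  for (seed in c(3, 19)) {
    set.seed(seed)
    sc <- generate_progression(seed = seed, templates = NULL, n_chords = 10,
                               duration_beats = sample(c(1, 2, 4), 10, TRUE))
    st <- chordify(sc)
    h <- harmonic_accents(st, tab)
    bound <- 5 * sqrt(st$n_beats) + 1e-9
    expect_true(all(h$Hv_raw >= 0 & h$Hv_raw <= bound))
    expect_true(all(h$Hh_raw >= 0 & h$Hh_raw <= bound))
  }
})

test_that("familiarity tables round-trip through JSON", {
  tab <- toy_table("0,4,7" = list(prepared = 2, unprepared = 5),
                   "0,3,6" = list(prepared = 1, unprepared = 0))
  f <- withr::local_tempfile(fileext = ".json")
  write_familiarity(tab, f)
  back <- read_familiarity(f)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$total_events, tab$total_events)
})
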