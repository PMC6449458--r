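Package: accentr
Title: Immanent Accent Salience Analysis for Tonal Music Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic analysis of immanent (score-inherent) accents in
    tonal music. Reads symbolic scores (MusicXML, Humdrum **kern, Standard
    MIDI Files), slices them into sonorities, and predicts the positions and
    0-5 saliences of metrical accents (Gaussian tempo-weighted pulse
    hierarchy), melodic contour accents (running-mean distance times
    preceding-interval size), and harmonic accents combining vertical
    unfamiliarity of Tn-type chord slices with horizontal surprise from
    pitch-class salience-profile correlations. Includes corpus counting of
    Tn-type frequencies, deterministic synthetic fixtures, and rater
    agreement/consensus statistics for evaluating model output against
    human accent marks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
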