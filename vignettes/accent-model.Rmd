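---
title: "Modeling immanent accent salience in tonal scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling immanent accent salience in tonal scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accentr)
```

Immanent accents are the events in a musical score that draw a listener's
attention by virtue of the notation alone — before any performer adds
emphasis. accentr predicts their positions and strengths on a 0–5 salience
scale in three categories: metrical (where the event sits in the pulse
hierarchy), melodic contour (peaks, valleys and the leaps into them), and
harmonic (how unfamiliar a chord is, and how much it surprises after the
chords just heard). This vignette explains the models, their parameters, the
numerical choices, and what the synthetic test fixtures do and do not
establish.

## The sonority as the atomic event

Every onset in any voice opens a *sonority*: a vertical slice holding all
pitches sounding at that instant, the subset that is newly struck, and each
pitch's notated duration in beats (for a tone held or tied over, the
remaining duration from the slice onset). No reduction is applied —
ornamental and passing notes open slices like any others. Slicing this way
makes the whole pipeline automatic: no analyst decides what "counts" as a
chord. Time is held internally as integer ticks at 3072 per whole note, so
every binary subdivision and every compound (dotted) beat is exact and
repeated runs are byte-identical.

## Metrical accents

A time signature implies four pulse levels. For the nine signatures in the
model's table (2/2, 4/2, 2/4, 3/4, 4/4, 3/8, 6/8, 9/8, 12/8) the notated
level durations are fixed — e.g. 3/4 implies pulses of an eighth, a quarter
(the beat), the measure, and the two-measure hypermeasure. A note starting
on a level's subdivision is marked with that level; levels anchor at the
downbeat of measure 1, and the hypermetrical level defaults to strong odd
measures (a `hypermeter_phase` parameter shifts it). Each marked level
contributes a salience weighted by tempo:

$$PS_i = k \, \exp\!\left[-\tfrac{1}{2}\left(\frac{\log P_i - \log M}{\log S}\right)^{2}\right]$$

with $P_i$ the level's physical period in seconds, $M = 2$ s the most
salient period, and $S = 1.65$ the log-normal spread. The expression is a
ratio of logarithms, so any base gives the same value. The metrical accent
is the sum over marked levels; sums below 1 are cleared and values above 5
saturate. The base salience $k$ is not printed in the source formulation;
$k = 1$ is the default because with $M$ and $S$ as above it makes downbeats
(and only downbeats) survive the cutoff in 3/4 at moderate tempi, matching
the published worked example (downbeat sum 1.216 at 60 bpm, other beats
0.405). The cutoff is applied after summation and before saturation.

## Melodic contour accents

Two factors multiply: the distance of the note from the running mean pitch
of its recent context ($I_1$, semitones), and the size of the interval that
leads into it ($I_2$, semitones). Each is weighted by direction —

* $CS_1 = I_1$ above the mean, $0.7\,I_1$ below;
* $CS_2 = I_2$ for rises, $0.2\,I_2$ for falls;
* $CS = CS_1 CS_2 / N$ with $N = 2.5$, kept only when positive,

so only peaks approached from below and valleys approached from above score,
and a matched valley earns exactly $0.7 \times 0.2 = 0.14$ of its mirror
peak before cutoff and saturation. The running mean covers the notes from
the barline two measures before the current note's measure, extended
backwards to the last 10 notes when sparser; the current note is excluded
(the mean describes the context the note departs from — an
`include_current` switch restores the alternative). Three prunings follow,
in order: the middle of three same-direction stepwise notes (both intervals
at most 2 semitones) is cleared; within every sliding window of three
consecutive notes only the largest positive salience survives (evaluated
simultaneously on raw values, earliest note winning ties — equivalently, a
note yields to any larger value within two positions); then the cutoff at 1
and saturation at 5. The first note of a piece scores 0, having no $I_2$.

The window-maximum rule matters more than it may look. On the package's
skeleton of the A-major Chopin prelude, the F♯5 peak at the end of measure 2
out-scores the A5 peak two notes later and therefore absorbs it entirely;
what remains is the published ordering (F♯5 above A5, the C♯6 climax above
both, the measure-6 valley positive). A centered-window variant that only
compares immediate neighbours would leave both peaks saturated at 5 and
erase the ordering — this is why the simultaneous sliding-window reading is
the default and only implementation.

## Harmonic accents

**Vertical (unfamiliarity).** Each slice is reduced to its transpositional
set class (Tn type): the normal-order rotation of its pitch classes
transposed to start at 0, with inversions kept distinct (major `(0,4,7)` vs
minor `(0,3,7)`). A familiarity table counts how often each Tn type occurs
in a corpus, split into *prepared* slices (some tone held over) and
*unprepared* ones (all tones simultaneous); both are summed for familiarity
$f$, the count normalized by the table's most frequent type. Then

$$H_v = (1 - f)^{P_v^{2}} \cdot 5 \cdot d$$

with $d$ the scaled duration of the slice's *shortest* notated duration.
Durations compress before scaling: $d = d_n$ up to one beat,
$\sqrt{d_n}$ up to a bar, $\sqrt{n_b}$ beyond; fast tempi (the words
Allegretto, Allegro, Vivace, Presto, or a numeric tempo of 112 bpm and
above) halve $d_n$ first. The squared exponent $P_v^2$ balances extremely
rare against extremely common sonorities.

**Horizontal (surprise).** Each slice gets a 12-vector pitch-class salience
profile: candidate root $p$ receives the sum of root-support weights of the
chord tones at intervals above it (unison 10, fifth 5, major third 3, minor
seventh 2, major second 1 — the weights are configurable because they come
from the root-finding tradition the model builds on, not from the accent
model itself). The profile rewards missing fundamentals: B–D–F supports an
absent G. Surprise is one minus the recency-weighted mean Pearson
correlation between the current profile and those of the slices in the
preceding measure (two measures under a half time signature), weights
$w_j = 1/j$ by recency rank, negative correlations clamped to 0 (a
rescale-to-unit-interval variant is available; the two agree closely):

$$H_h = \left(1 - \frac{\sum_j r_{ij} w_j}{\sum_j w_j}\right)^{P_h} \cdot 5 \cdot d$$

here with $d$ from the *longest* notated duration (dissonance is a property
of the sonority itself; surprise belongs to its harmonic function), halved
when the piece is flagged as consonant-passing-tone textured. The first
slice of a piece scores 0. Degenerate (constant) profiles correlate as 0.

**Combination.** Model 1 is `max(Hv, Hh)`. Model 2 keeps the maximum when
$H_v$ exceeds a style threshold $x_2$, but below it uses
$\min(H_v + H_h/x_1,\ 5)$, damping root changes that carry no dissonance
(passing and neighbour chords in Classical textures); results under the
style cutoff $x_3$ are cleared, and everything saturates at 5. The style
rows are Baroque–Classical $(P_v, P_h, x_1, x_2, x_3) = (2,2,5,0.6,1)$,
Romantic $(2,2,4,0.3,1)$, late-Romantic $(3,3,4,0.2,1.5)$. The published
lower branch prints `max(Hv + Hh/x1, 5)`, which as a floor would contradict
the model's own saturation rule (values *higher* than 5 are to be clipped
*down*); it is implemented as `min`. The $x_3$ cutoff applies to Model 2
only, matching where the parameter is defined; a switch extends it to
Model 1. The horizontal exponent is $P_h$ unsquared, as printed, even
though the vertical one is squared.

## The familiarity table and the synthetic default

Real use should count a real corpus: `count_corpus()` ingests kern or
MusicXML files, slices them exactly as the analysis does, and classifies
every slice by Tn type and preparedness; file order and global
transposition provably do not change the result. Because no corpus ships
with the package, `default_familiarity()` builds a ~200-slice synthetic
table from seeded template progressions in which the major triad is the
most frequent type, followed by the minor triad and seventh chords. It is
labeled synthetic in its provenance and is a stand-in with the right
*shape*, not real statistics: absolute vertical saliences under it are not
comparable to those under a counted corpus, which is why `accent_analysis()`
says so when falling back to it.

## Fixtures: what they emulate, and what passing tests show

The generators produce, deterministically under a seed: metrical grids in
any supported signature with ground-truth level marks; random-walk melodies
with controlled leap distributions and local-extrema annotations;
homophonic template progressions with known Tn types, optional held (tied)
tones and an optional two-voice layout; multi-rater mark matrices built as
`round(clip(truth + noise))` with per-note dropout; and the hand-encoded
prelude skeleton described above, which fixes only the landmarks the
source text states (pitches, intervals, meter, measure positions) — the
connective notes are the package's own, chosen once so the skeleton is a
plausible melodic line, and frozen.

Passing tests on these fixtures establish that the arithmetic, windowing,
pruning and counting rules are implemented as specified, against
independent brute-force oracles (onset enumeration, a bitmask canonical
form for all 4095 pitch-class subsets, direct correlation sums, an
independent window re-implementation). They do not establish perceptual
validity on real music: the fixtures have no expressive timing, no real
voice leading, and rater matrices whose noise is Gaussian and independent —
none of which is true of human annotators.

## Numerical and degenerate-input choices

* Exact integer ticks (3072/whole) for all score time; conversion errors
  out rather than rounding silently.
* Ties merge into one logical note at read time; preparedness falls out of
  the merged representation.
* Grace notes keep zero duration: they join pitch sets (corpus counting is
  reduction-free) but are excluded from duration bookkeeping.
* Tempo words map to bpm via a configurable table (Largo 50 … Presto 180);
  an explicit bpm overrides the word, and the word, when present, decides
  the fast-tempo halving.
* The melodic tie-break (earliest note wins) and the consensus tie-break
  (smallest threshold wins) make every reported maximum deterministic.
* Zero-variance raters are excluded pairwise with a warning; thresholds no
  rater count can meet are skipped and reported, not errors.
* Problem sizes in the test-suite simulations (120-note melodies, 8–16
  raters, 3-piece corpora) keep the full suite under half a minute while
  leaving every statistic far from its small-sample regime.

## Known limitations

Octave register, spacing and doubling are invisible to Tn types — a widely
spaced and a close-position triad count as one type. The melodic model
attaches an accent to a single melody note even where a listener might
spread it over several simultaneous sonorities. Meter is taken from the
notation (no induction from note patterns), the melodic line defaults to a
skyline (highest new pitch) because the source leaves the extraction rule
open, and signatures outside the published table need the generic extension
rule or an explicit grid. Style is declared by the user, never inferred.
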