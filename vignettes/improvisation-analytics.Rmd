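---
title: "Quantifying keyboard improvisation: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying keyboard improvisation: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(improv)
```

## The problem

Free keyboard improvisation is widely used in music-therapy assessment, yet
what a session "contains" is usually described verbally. This package turns
the raw MIDI event stream of an improvisation — timestamped key presses and
releases with velocities — into a reproducible set of expressive-behavior
parameters, and provides the statistical machinery to compare cohorts of
improvisations (by task prompt, gender, musical proficiency, or age group).

The analysis view is deliberately event-driven: a session is replayed as a
tiny reactive system that is either *Idle* or *Playing*, whose instantaneous
cluster configuration is the number of simultaneously held keys, and whose
running extrema (loudest/softest dynamics, highest/lowest octave, largest
cluster) are tracked as the events arrive. Every metric below is a
deterministic function of that replay.

## From events to intervals

Raw events are paired per note with FIFO semantics: a release closes the
earliest still-open press of the same key. Two edge rules matter:

* a *dangling press* (never released) is closed at the session end, with a
  warning — this preserves its playing-time mass rather than silently
  discarding data;
* an *unmatched release* is dropped, with a warning.

Intervals are half-open, `[onset, offset)`. A release coincident with
another press therefore never produces a spurious zero-width spike in the
held-key count. Whether a re-pressed sustained key should *extend* rather
than restart an interval is not observable from the stream; FIFO pairing
(restart) was chosen and is applied uniformly.

## The metric set

For a session of duration $T = t_{end} - t_0$ with note intervals
$\{[a_i, b_i)\}$ and held-key count $c(t) = \sum_i \mathbf{1}[a_i \le t < b_i]$:

* **Net playing time** is the measure of $\bigcup_i [a_i, b_i)$, i.e.
  $\int \mathbf{1}[c(t) > 0]\,dt$; idle time is its complement in $T$;
  the start time is the first onset. Playing, idle and start are reported
  as percentages of $T$.
* **Concurrency** is $100 \int c(t)\,dt / \int \mathbf{1}[c(t)>0]\,dt$:
  100% when nothing ever overlaps, 200% when two keys sound throughout the
  playing time, and so on. It is the single best summary of "how chordal"
  a session is.
* **Key use**: press count, distinct keys as a share of the keyboard,
  presses per distinct key, mean press duration, and the share of presses
  on black keys (the five sharp pitch classes).
* **Profiles**: per-press dynamics levels (ten levels, *pppp*..*ffff*) and
  octave numbers are summarised by press-weighted means, per-press extrema
  and a duration-weighted "most used" bin; full histograms give the share
  of note-sounding time per level, per octave and per pitch class.
* **Clusters**: the maximal constant-count positive segments of $c(t)$ —
  how many, the largest count, the duration-weighted modal count, and the
  modal count's share of playing time.
* **Transitions** over the press sequence ordered by (onset, note):
  crescendo/diminuendo/same for velocity pairs, the four black/white color
  pairs, and accelerando/ritardando for consecutive inter-onset-interval
  pairs.

These definitions imply exact identities — playing + idle = 100,
black + white = 100, crescendo + diminuendo + same = 100,
accelerando + ritardando = 100, the four color transitions sum to 100, and
each histogram sums to 100 — which the test suite checks over a thousand
simulated sessions, and which make corrupted inputs conspicuous.

## Conventions and tunable parameters

**Keyboard.** The default instrument is the 76-key controller spanning MIDI
28 (E1) to 103 (G7), which has 31 black and 45 white keys. Any contiguous
range can be configured.

**Octave numbering.** Scientific pitch: middle C (MIDI 60) is C4, i.e.
`floor(note/12) - 1`. On the default keyboard this yields octaves 1–7. The
offset is configurable because the rival convention (middle C = C5) shifts
every octave statistic by one; published octave numbers can only be
compared once the origin is known.

**Dynamics binning.** Velocity (0–127) is mapped onto ten ordered levels.
The literature's "common categorization" is not published with explicit
boundaries, so the default is the equal-width rule
`level = 1 + floor(v * 10/128)`; the nine boundaries are a parameter of
`dynamics_scale()` so any published mapping can be swapped in. Binned
intensity statistics (and to a lesser degree "most used" values) shift
under different boundaries; unbinned quantities do not. This is the main
convention risk when comparing against published intensity tables.

**Chord window.** Human chords are spread over a few tens of milliseconds.
Transition metrics can optionally group presses whose onsets fall within a
window (default 30 ms where grouping is requested) of the group leader and
classify chord representatives instead of raw presses. The default for all
reported statistics is *no grouping* (window 0), which is exactly
reproducible and uses every press; this choice is visible wherever
transitions are reported.

**Tie rules.** Duration-weighted modes resolve ties toward the lower bin;
equal consecutive inter-onset intervals count as ritardando (so
accelerando + ritardando partitions all tempo pairs, with no "same tempo"
category). Both rules are deliberate: they are deterministic, and the
second matches the convention in which the two tempo-transition
percentages are complementary.

**Session bounds.** `t0 = 0` (recording start) and `t_end` = last event
time unless the source encodes explicit bounds. Because idle- and
start-time percentages are relative to `t_end - t0`, an explicit bound
changes them; readers log which convention applied. The "total (minutes)"
parameter is the full session duration; net playing time in minutes is
recoverable as `pct_playing_time/100 * total_session_min` if the other
reading is wanted.

## Statistics

Within-cohort task contrasts use a one-way repeated-measures ANOVA (one
within-subject factor, complete-case by default, with the dropped-subject
count reported), Bonferroni-adjusted paired comparisons, and partial eta
squared, $SS_{cond}/(SS_{cond}+SS_{err})$ — the only eta variant bounded
per effect in within-subject designs. An available-case option fits the
additive subject + condition model on every observed cell instead;
unbalanced within-subject data have no single canonical F, so both routes
are exposed and the degrees of freedom are always reported rather than
forced to match any external table.

Between-collective contrasts (gender, proficiency, median age split) use
independent two-sample t-tests. Both the pooled-variance and Welch
variants are implemented because published degrees of freedom in this
literature are not consistent with a single choice; `compare_collectives()`
can report both. Cohen's d is always computed with the pooled standard
deviation. One-sided tests report the direction of the larger mean, which
is what the significance stars in the cohort table annotate.

The age split classifies sessions of participants *above* the cohort
median as old and the rest as young; the valence grouping collapses
ugly/negative into a negative-valence and beautiful/positive into a
positive-valence pole.

## The synthetic generator

`sample_session()` emits cluster events along a session clock: each event
draws a cluster size (1–12), places that many distinct keys near a drawn
octave center (the per-key black/white choice is an exact Bernoulli draw
with probability `p_black`; collisions move to the nearest free octave of
the same pitch class so the color share is never biased by cluster size),
draws velocities and note durations, and advances by an inter-onset
interval, occasionally inserting an idle gap. All bounded quantities use
lower-truncated normal distributions via inverse-CDF truncation.
`sustain = TRUE` holds notes to the next cluster onset, which pins the
concurrency of a fixed cluster size $k$ near $100k\%$ — the property used
by the desk checks.

Default parameters were chosen once to emulate a cohort-average
improvisation as published for this kind of task cohort: sessions around
0.9 min, about two thirds of the session spent playing, an 18% start
delay, about 150 presses, concurrency in the mid-200s, a 16% black-key
share, mid-keyboard octave placement and mezzo-forte dynamics. The four
task presets (`improv_preset()`) encode only qualitative directions —
"ugly"/"negative" loud, low, black-leaning, cluster-heavy;
"beautiful"/"positive" softer, mid-register, white-leaning, sparse —
because published cohort summaries do not identify generative parameters.

What the generator does *not* emulate: melody, harmony, phrase structure,
tempo curves, pedalling, or any correlation between successive notes
beyond cluster placement. Passing tests on synthetic cohorts therefore
demonstrate that the *metric pipeline* recovers configured statistical
tendencies, not that real improvisations behave like the generator.

## Numerical choices

Interval arithmetic is exact (sweep over sorted breakpoints), not
grid-based; the test suite cross-checks it against a brute-force 1-ms
discretization on a thousand random interval sets, on inputs snapped to
the grid so the oracle itself is exact. Degenerate inputs are defined
explicitly: an empty session has 0% playing time, 100% idle, and every
press-dependent field missing; a zero-length session is an error;
zero-variance t-test inputs with equal means return $t = 0, p = 1$; an
all-equal ANOVA matrix returns $F = 0, \eta^2 = 0$ (detected with a
relative tolerance, since sums of squares of constant data are only
floating-point zero).

Problem sizes used by the shipped checks — 1,000 oracle interval sets,
1,000 invariant sessions, 2,000 null-ANOVA replicates (50 subjects × 4
conditions), and 50-per-group preset cohorts — were chosen to make Monte
Carlo error comfortably smaller than the tolerances being checked while
keeping a full run in the low minutes on one core.

## File formats

Standard MIDI Files (formats 0 and 1) are read natively, tempo-map aware,
with note-on-velocity-0 treated as note-off and running status supported.
The canonical interchange format is a plain TSV of on/off events with
session and participant metadata (`write_event_table()` /
`read_event_table()`, lossless round trip). Deposited datasets whose exact
text dialect is unknown go through `read_s1_dataset()`, which infers the
delimiter, header, column roles and session segmentation, reports the
inference, and refuses with an explicit error naming the detected columns
when the layout cannot be decoded — a tolerant-by-design reader, because
archived supplementary files rarely document their dialect.

## Known limitations

* Only the solo-keyboard modality is modelled: instrument selection,
  multi-performer interaction and therapist-client dynamics are out of
  scope.
* Binned intensity comparisons against published tables inherit the
  unknown velocity-categorization boundaries (see above).
* The repeated-measures ANOVA is the classical univariate one-way design;
  sphericity corrections and mixed-effects alternatives are not provided.
* Duration labels ("extremely short" … "extremely long") are cohort
  quintiles, reported descriptively and never used in statistics.
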