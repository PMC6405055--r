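# improv — quantitative behavioral analysis of keyboard improvisation

`improv` turns MIDI recordings of free piano-keyboard improvisation into
quantified expressive-behavior parameters, and provides the cohort
aggregation and inferential statistics needed to compare how different
people — or the same people under different emotional task prompts —
improvise. It is aimed at music-therapy and music-cognition researchers who
record improvisations as MIDI event streams and want reproducible,
scriptable session analysis instead of manual annotation.

## What it computes

A session is replayed as an event-driven state machine (Idle/Playing, with
the instantaneous *cluster configuration* = number of simultaneously held
keys). With note intervals `[a_i, b_i)` and held-key count
`c(t) = Σ_i 1[a_i ≤ t < b_i]`, the core quantities are

* **net playing time** `∫ 1[c(t) > 0] dt` and its complement (idle), the
  start delay, all as % of session time;
* the **concurrent-playing metric** `100 · ∫ c(t) dt / ∫ 1[c(t) > 0] dt` —
  100 % means purely monophonic playing, two keys held throughout yield
  200 %, three keys 300 %;
* key-use statistics (presses, % of keys used, presses per key, % black
  presses), duration-weighted **dynamics / octave / pitch-class profiles**
  on a ten-level *pppp*–*ffff* scale and scientific octave numbering,
  **cluster statistics** (instances, max, duration-weighted mode), and
  **transition rates** (crescendo/diminuendo, accelerando/ritardando, the
  four black/white color pairs);
* per-group mean (SEM) aggregation, one-way repeated-measures ANOVA with
  Bonferroni pairwise comparisons and partial η², and pooled/Welch
  two-sample t-tests with Cohen's d.

Input formats: Standard MIDI Files (format 0/1, tempo-map aware), a
canonical tab-separated event table, and a tolerant auto-detecting reader
for deposited plain-text datasets. A synthetic session generator with
controllable statistical structure stands in for participant data in all
tests.

## Worked example

Simulate two 20-session cohorts with the "ugly"-like and "beautiful"-like
presets, compute all metrics, and compare the collectives:

```r
library(improv)

co <- sample_cohort(20, profiles = list(ugly = improv_preset("ugly"),
                                        beautiful = improv_preset("beautiful")),
                    seed = 11)
mt <- metrics_table(co)
params <- c("pct_playing_time", "pct_concurrent",
            "pct_black_presses", "octave_most_used")
ag <- aggregate_metrics(mt, by = "task", params = params)
st <- compare_collectives(mt, by = "task", variant = "pooled", params = params)
render_cohort_table(ag, st)
```

```
Cohort parameter table, cells are mean (SEM); * p < .05, ** p < .01, *** p < .001
                             ugly        beautiful
pct_playing_time       56.4 (4.1)    68.9 (2.4) **
pct_concurrent       754 (32) ***        257 (5.9)
pct_black_presses 30.4 (0.73) ***      10.2 (0.63)
octave_most_used       2.5 (0.14) 4.25 (0.099) ***
```

Read: the "ugly"-like cohort plays more concurrently (754 % vs 257 % of
net playing time), presses three times as many black keys (30.4 % vs
10.2 %) and sits two octaves lower (most-used octave 2.5 vs 4.25); stars
mark the one-sided test toward the larger-mean group. A single session
prints as a full textual report:

```r
compute_session_metrics(co[["ugly_001"]])
#> Improvisation session report: ugly_001
#> Time
#>   % playing time               69.5
#>   % idle time                  30.5
#>   start time (sec)             6.5
#>   ...
#>   % concurrent                 508.7
#> Notes/Keys
#>   # of presses                 97
#>   % black presses              32.0
#> ...
```

A thin command-line front end wraps the same functions
(`inst/cli/improv.R`): `ingest`, `metrics`, `aggregate`, `stats`,
`simulate`, `report`.

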