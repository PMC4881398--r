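---
title: "Cue-based retrieval modeling of reflexive binding: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cue-based retrieval modeling of reflexive binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuebind)
```

## The retrieval problem

Binding an English reflexive (*himself*/*herself*) to its antecedent is
modeled here as a single content-addressed retrieval from declarative
memory. At the reflexive, the parser issues a retrieval request — a weighted
set of feature cues — and every discourse referent currently in memory
competes. We deliberately do not model parsing of the whole sentence: memory
holds exactly the two candidate noun phrases of the experimental designs
(the grammatically accessible antecedent and the structurally illicit
distractor), and all predictions concern that one retrieval event.

The retrieval cues are `{gender = masculine/feminine, category = noun,
role = subject, clause = current}`. The grammatical constraint is
approximated by the role and clause cues; `structural_only = TRUE` drops the
gender cue, giving the strictly-structural comparison model that predicts no
gender-based interference at all.

## Activation calculus

A chunk's momentary activation is the sum of four terms:

$$A_i = \underbrace{\ln \sum_r t_r^{-d}}_{\text{base level}}
      + \underbrace{\sum_j W_j \, (S - \ln \mathrm{fan}_j)}_{\text{spreading}}
      + \underbrace{\sum_k P \cdot M_{ki}}_{\text{partial match}}
      + \epsilon_i$$

* **Base level.** $t_r$ are the ages (seconds before the retrieval) of the
  chunk's mentions; recency and frequency both raise activation. Ages come
  from word positions: a referent mentioned $k$ words before the reflexive
  has age $k \times$ `per_word_time`. Because the base-level law is
  logarithmic, only the *ratio* of the two referents' word distances matters
  for their competition; the overall scale of `per_word_time` is absorbed by
  the latency calibration below.
* **Spreading.** Only cues whose value the chunk carries spread activation
  to it. The source activation $W$ is divided evenly over the cues
  ($W_j = W/4$, or $W/3$ without the gender cue), and a cue's associative
  strength falls logarithmically with its fan — the number of chunks sharing
  the cued value. Fans above $e^S$ legitimately yield negative strengths; we
  do not floor them.
* **Partial matching.** Every mismatched cue adds
  $P \times$ `max_difference` (a non-positive similarity), which is what
  allows a structurally illicit but gender-matching distractor to stay in
  the race.
* **Noise.** One independent draw per chunk per retrieval from a logistic
  distribution with scale $s$; there is no permanent (encoding) noise
  component. With $s = 0$ the model is fully deterministic.

The winner is the highest-activation chunk, provided it reaches the
threshold $\tau$; ties (possible only at $s = 0$) go to the first candidate
in encoding order, i.e. the accessible antecedent. Retrieval time is
$F e^{-A}$ of the winning noisy activation plus a constant `fixed_cost`
(below); a failed retrieval is timed at the threshold bound $F e^{-\tau}$,
reported separately, and excluded from mean retrieval times.

## Default parameters and their calibration

| parameter | default | unit | role |
|---|---|---|---|
| `decay` (d) | 0.5 | – | base-level decay exponent |
| `max_assoc_strength` (S) | 1.5 | – | associative strength at fan 1 |
| `max_difference` | −1 | – | similarity of a mismatched value |
| `match_scale` (P) | 1 | – | weight on mismatch penalties |
| `noise_scale` (s) | 0.3 | – | logistic activation noise |
| `retrieval_threshold` (τ) | −1.5 | – | minimum retrievable activation |
| `total_source_activation` (W) | 1 | – | source activation over cues |
| `per_word_time` | 0.05 | s | encoding clock per word |
| `latency_factor` (F) | 0.244 | s | activation-to-time mapping |
| `fixed_cost` | 0.160 | s | constant non-retrieval time |

The first seven are the long-standing canonical values of this model family
and were not adjusted. The last three were calibrated once, jointly, against
the published per-condition retrieval times of the canonical design
(approximately 194 ms in the match condition and 295 ms in the mismatch
condition): we computed the expected winning-activation latencies by numeric
integration over the logistic-noise maximum and solved for $F$ and
`fixed_cost`, and selected the noise scale (within the conventional sweep
range 0.05–0.4) that reproduces the published interference pattern,
including the ~20 ms speed-up of mismatch-interference relative to mismatch.
A constant non-retrieval cost is necessary, not cosmetic: with a full-cue
mismatch penalty of 1 the match/mismatch activation gap is 1.375, so latency
alone would force a mismatch/match time *ratio* of $e^{1.375} \approx 3.9$,
whereas the published times differ by roughly 100 ms at a ratio of 1.5. The
cost is interpretable as encoding plus rule-firing overhead shared by all
conditions; it cancels exactly out of every effect contrast except through
the latency scale. All ten values live in `model_params()` and round-trip
through a JSON config (`read_params()`/`write_params()`), so any of them can
be overridden without touching code.

At these defaults the model makes no retrieval errors without noise, and
with noise it predicts the qualitative pattern E1 > 0, E2 > 0, E3 > 0,
E4 > 0, E5 < 0 — the last meaning the gender-matching distractor *speeds up*
retrieval when the accessible antecedent mismatches, because the distractor
often wins the race and carries a higher activation into the latency map.

```{r}
summ <- simulate_design("sturt_exp1", n_runs = 1000, seed = 42)
summ
compute_effects(summ)
```

## Designs and encoding choices

Three designs ship in `inst/extdata/designs.json`; `design_specs()` accepts
a user file with the same schema.

* `sturt_exp1` — the distractor is the matrix subject (a pronoun picking up
  a context-sentence name), mentioned *before* the accessible embedded
  subject; it matches gender, category and role but not clause.
* `sturt_exp2` — the distractor is the object inside a subject relative
  clause: closer to the reflexive but lacking the subject-role match, which
  weakens its interference.
* `modified` — an object relative clause puts the distractor in a subject
  role *and* closer to the reflexive than the accessible antecedent; both
  interference effects strengthen accordingly.

Encoding decisions worth making explicit: one chunk per discourse referent,
whose age tracks the most recent surface mention (a
`multi_mention` switch adds the context-sentence mention to the history, at
`sentence1_offset_words` before the critical sentence, for sensitivity
analyses); only the two candidate noun phrases populate memory — other
sentence nouns would mostly add fan without changing the contrasts;
stereotypical and definitional gender are encoded identically, which, if
anything, inflates predicted gender effects relative to human data; and both
non-clause-mate positions (matrix subject, relative-clause-internal) are
encoded as `clause = "other"` — the cue is binary.

Condition labels follow the standard 2 × 2: `a` match-interference, `b`
match, `c` mismatch-interference, `d` mismatch, with the accessible noun's
(stereotypical) gender fixed and the reflexive and distractor genders set
relationally. Swapping the base gender flips every gender value and provably
changes no cue-match pattern (tested).

## Simulation and sweep

`simulate_condition()` vectorizes the Monte Carlo over runs but draws the
per-run logistic noise in exactly the order sequential `retrieve_once()`
calls would, so the two routes are interchangeable under a seed (tested
against each other). Each (grid cell, condition) pair of a sweep runs on its
own deterministic substream derived from the user seed, making sweep results
independent of evaluation order. Predictions in this package use 1000 runs
per condition; the full three-parameter sweep (noise 0.05–0.4 by 0.05,
S 1–4 by 0.25, max difference −1–0 by 0.1; 1144 cells, or 1287 with the
optional zero-noise row of `sweep_grid(include_zero_noise = TRUE)`) uses 200
runs per cell in the test suite, which resolves the marginal trends —
error effects growing with noise, the time-based mismatch effect growing
with the penalty magnitude — while keeping a sweep under a minute.

Effects are computed on mean latencies in ms; rounding happens only at
display. Failures (activation below τ) essentially never occur at the
defaults but are counted and excluded from latency means when they do.

## Eye-movement measures

The measure suite consumes fixation records (x, y, onset, duration per
trial) plus a single-line word-box layout. Assignment follows the
conventional rules: a fixation belongs to a word if it falls in the word's
box extended 30 px above and below the line; fixations in the blank space
between words go to the nearer word (split at the midpoint, the midpoint
itself to the following word — boxes are half-open `[left, right)`);
everything else is discarded, never an error.

First pass is the maximal run of consecutive fixations in the region
starting at its first fixation, *provided* no later word was fixated
earlier; a region skipped during first pass has missing FFD/FPRT/FPRP (not
zeros) and all its fixations count as re-reading. TRT = FPRT + RRT wherever
a first pass exists; RRP = 1 iff RRT > 0; FPRP = 1 iff the saccade leaving
the first pass lands on an earlier word.

Cumulative progression is the forward-only running maximum of pixel distance
from the first fixation in the region, sampled every 2 ms for 1000 ms (501
points); regressions and fixations leave it flat, and the pre-saccade value
is carried forward until the landing fixation's onset (the sampler has no
better information during a saccade). Condition averages are taken per
timestamp before differencing. Sign convention for the three difference
curves: each is (condition of interest − baseline) — mismatch = mean(c, d) −
mean(a, b), match-interference = a − b, mismatch-interference = c − d — so a
*negative* value always means the condition of interest has progressed less,
i.e. is being read more slowly. The 95% band pools per-timestamp standard
errors over trials and therefore underestimates participant and item
variance; it is exploratory, not confirmatory, and the package accordingly
exports a model-ready table (`measures_model_table()`: nested contrasts,
centered trial, log reading times) rather than fitting mixed models itself.

The nested contrast matrix codes mismatch as (−½, −½, +½, +½),
match-interference as (+½, −½, 0, 0) and mismatch-interference as
(0, 0, −½, +½); the interference contrasts are nested in the match/mismatch
pairs, every column is centered, and signs are chosen so a positive
coefficient on a reading-time measure is the model-predicted direction
(mismatch-interference is reversed because that condition is predicted
*faster*). Other scalings of the same subspace are admissible; this one
makes coefficients directly interpretable as condition differences.

## The synthetic fixation generator

`generate_fixations()` emulates the reading experiment's shape — 40
participants × 24 items by default, four conditions rotated by Latin square,
one 16-word stimulus line with the reflexive as word 12 — with a minimal
gaze process: left-to-right traversal, log-normal fixation durations
(median 200 ms, σ_log 0.25), occasional skipping of short words, Gaussian
landing-site and vertical noise, and saccades that take no time at measure
resolution. Condition effects are injected directly where each measure is
defined: `ffd_shift` onto the critical first fixation, `regress_prob` as a
first-pass regression (followed by a return, so it also produces
re-reading), `dwell_shift` as an extra first-pass refixation that delays all
forward progression. That makes ground truth exact for parameter-recovery
tests: the suite verifies that a null generator yields null contrasts and
that each injected effect is recovered in the matching measure with the
predicted sign.

What the generator deliberately does *not* emulate: oculomotor control
(no launch-site or word-length effects on landing position, no refixation
strategy), spillover between regions, participant/item random effects, and
blinks or track loss. Passing recovery tests therefore shows that the
measure pipeline is correct and sensitive at the experiment's size — not
that real eye-tracking data are this clean, nor anything about the human
effects themselves, which require the recorded data.

## Numerical choices and limitations

* Tie-breaks: at $s = 0$, equal activations resolve to the accessible
  antecedent (first in encoding order); with noise, ties have probability 0.
* Additivity of the activation breakdown is maintained to 1e−12 and tested.
* Substream seeds are formed as `(seed + 7919·cell + 104729·condition) mod
  (2^31 − 1)`, keeping every derived seed a valid 32-bit integer.
* The latency map is evaluated on the *noisy* winning activation; this is
  what produces the mismatch-interference speed-up (the maximum of two close
  competitors is stochastically larger than the maximum of one dominant and
  one weak competitor).
* The model predicts retrieval behavior at one word; linking it to specific
  eye-movement measures (early vs late) is a theoretical commitment the
  package leaves to the user — the simulator and the measure suite are
  intentionally independent modules.
* Retrieval-history effects (re-activation of a referent by being
  retrieved) are not modeled; creation times come from surface mentions
  only.
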