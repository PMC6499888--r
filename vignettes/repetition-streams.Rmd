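---
title: "Designing, simulating and scoring repetition detection in RSVP streams"
author: "repstream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing, simulating and scoring repetition detection in RSVP streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repstream)
```

## The paradigm

In a rapid serial visual presentation (RSVP) repetition-detection
experiment, an observer watches a continuous stream of natural images at
15 Hz (58.3 ms image + 8.3 ms blank) and presses a key whenever they notice
that an image is repeating.  Embedded in each ~89 s stream are 20
*repetition sequences*: a target image shown six times, separated by
never-repeated distractor images.  The spacing is either *regular* — the
same number of distractors, d in 1..5, in each of the five inter-target
gaps — or *irregular* — the gaps hold 1, 2, 3, 4 and 5 distractors in a
permuted order, so every irregular sequence has 15 distractors and is 21
images long.  After each stream, a four-alternative forced-choice (4AFC)
memory task probes all 20 targets among three foils from the same stream,
with a 0–4 confidence rating.

The scientific question — whether temporal regularity helps repetition
detection and memory — is answered by contrasting regular and irregular
sequences.  This package implements the full pipeline around that
question: session design, a synthetic observer, window-based detection
scoring with a scrambled-timestamp chance level, memory scoring with a
delay-split analysis, and the statistical layer.

## Session design

A session is 12 blocks of 20 sequences.  The 240-condition ledger is fixed:
all 120 permutations of (1..5) appear exactly once as irregular conditions,
and each regular d appears 24 times, giving 120 regular and 120 irregular
sequences.  The ledger is shuffled globally and chunked into blocks, so
conditions are deliberately *not* balanced per block.  Both design-level
contrasts are built into this layout:

* **R3 vs irregular (equal length):** all irregular sequences are 21 images
  long, as is regular d = 3; contrasting R3 against an equal-size random
  subsample of irregular trials equalizes sequence length and the mean
  number of intervening distractors.
* **All regular vs all irregular (equal interval distribution):** each gap
  size 1..5 occurs equally often in both halves, and the mean sequence
  length matches.

```{r design}
design <- build_session("s01", seed = 42)
design
table(vapply(design$condition_ledger, condition_group, ""))
```

Timing follows the 120 Hz screen-refresh arithmetic: the stored durations
are the conventional 58.3/8.3 ms values, but onsets are computed as
`index * SOA` with SOA = 1000/15 ms held at full floating-point precision,
so no rounding drift accumulates over 1300+ events.

Two quantities are reconstructions rather than stated facts, and are
flagged as such:

* **Lead-in and tail.**  Where the padding around the 20 sequences sits is
  not part of the stated design.  We place one gap (same uniform 37–52
  image distribution) before every sequence, including the first, and a
  fixed 22-image tail.  The expected stream length is then
  20·21 + 20·44.5 + 22 = 1332 images, matching the published mean; the
  tail length is the one free constant and was chosen once, by this
  calibration, before any testing.
* **Practice images.**  Participants also saw six short practice blocks.
  These are represented only as a reserved count of image ids
  (`n_practice_images`, default 1200 — a coarse reconstruction of six
  blocks of five to six sequences each).  With it, a session uses ≈16,000
  distinct images, the published per-participant total.  Nothing else in
  the pipeline depends on this count.

One printed-value inconsistency is resolved in favor of arithmetic: with
five distractors per gap the target reappears every 6 images, i.e. at
15/6 = 2.5 Hz, although the published text lists "2 Hz" for that
condition.  The generator follows the arithmetic.

## The synthetic observer

Human data are not reproducible from a design alone, so the observer
module generates button presses and memory responses with the statistical
structure the analysis expects.  It is a first-class, deliberately simple
generative model:

* **Hits.**  Each sequence elicits a detection press with probability
  `hit_prob[group]`, where groups are R1..R5 and I1..I5 (irregular keyed by
  the number of distractors before the first repetition).  The press lands
  at the second-presentation onset plus a reaction time from a shifted
  lognormal (default 300 + lognormal(log 600, 0.5) ms), truncated to the
  (200, 2500) ms response window.  A shifted lognormal is the standard
  positively skewed RT law; the published analysis reports only mean RTs,
  so its parameters are conventional choices, not estimates.
* **Extra presses.**  With probability `extra_press_prob` a detected
  sequence receives a second in-window press, which the strict
  one-and-only-one-press rule then scores as a miss.
* **False alarms.**  A homogeneous Poisson process at `fa_rate`/s over the
  stream plus the final 2.5 s window.  The source study does not model
  false alarms at all; the Poisson process is the minimal assumption that
  still exercises the scoring rule's rejection of out-of-window presses.

The default rates were calibrated *analytically* against two published
anchors — 13.4 button presses per block and 2.2% of trials with more than
one in-window response.  With the default hit probabilities (mean 0.627
across the ten groups), a block expects 20·0.627 = 12.54 hits,
12.54·0.02 ≈ 0.25 extra presses, and 0.0067/s over ≈91.3 s ≈ 0.61 false
alarms: 13.40 presses in total.  Multi-press sequences arise from extra
presses (0.627·0.02) plus a false alarm landing in an already-hit window
(0.627·(1 − e^(−0.0067·2.3)) ≈ 0.0096), together ≈2.2%.  The regular-group
hit and memory-accuracy defaults decrease with d, mirroring the qualitative
difficulty trend.

The memory generator probes targets in a fresh uniform order (the
"probe order differs from stream order" property is treated as a property
of randomization, not an active rejection rule), draws three foils per
probe from the stream's never-repeated distractors without replacement and
disjointly across probes, answers correctly with `mem_acc[group]`, and
draws confidence from separate conditional distributions for correct and
error trials (correct stochastically higher).  An optional
`recency_slope` tilts accuracy with stream position on the logit scale;
it exists purely so the delay-split analysis can be exercised against a
known injected effect.

What the synthetic observer does *not* emulate: attentional blink,
repetition blindness, learning or fatigue across blocks, image content and
foil similarity, and any dependence of memory on whether the sequence was
detected.  Tests that pass on synthetic data therefore validate the
*pipeline arithmetic* — scoring, chance correction, contrasts, interval
procedures — not claims about human vision.

## Detection scoring and the scrambled chance level

A sequence is detected iff **exactly one** press falls strictly inside
(200, 2500) ms after the onset of the target's second presentation; that
onset defines RT = 0.  Signal-detection measures are deliberately out of
scope (continuous streams with mixed conditions make d′ assignment
non-trivial); the chance reference is instead *scrambling*: press
timestamps are redrawn uniformly on [0, stream end + 2500 ms], press count
preserved, and the same scoring is applied.

```{r scoring}
sim <- simulate_session(design, observer_params(), seed = 43)
chance <- chance_session(design, sim$presses, n_scrambles = 100, seed = 44)
head(summarize_detection(sim$scores, chance), 3)
```

For k presses scrambled uniformly on [0, T] and a window of width w, the
per-sequence chance rate has the closed form k·(w/T)·(1 − w/T)^(k−1); the
test suite holds the Monte-Carlo scrambler to this analytic oracle.  The
`pp_difference` column is 100·(rate − chance), the chance-corrected
performance measure.

Numerical choices worth stating:

* Window bounds are open intervals; a press at exactly 200 or 2500 ms
  offset is outside.  (The boundary has measure zero under every
  generator here, so this is a tie-break convention, not a substantive
  choice.)
* With ≥37-image gaps, consecutive response windows cannot overlap (the
  minimal second-presentation separation is ≈3.13 s > 2.5 s).  For
  robustness on arbitrary inputs, a press falling inside two windows is
  assigned to the earlier-opening sequence only, preventing double
  counting.
* `n_scrambles = 1` reproduces the single-scramble procedure;
  `chance_level(..., n_scrambles = K)` averages K independent scrambles
  when a lower-noise chance estimate is wanted.

## Memory scoring and the delay split

`score_memory()` marks a probe correct iff the chosen id equals the target
id (chance = 0.25, fixed — there is no scrambling analogue for 4AFC), and
aggregates within participant before averaging across participants.  The
stream-to-probe delay of a target is the number of intervening targets in
the stream and in the memory task, plus one: for stream position i and
probe position j among 20 targets, delay = 20 − i + j.  This is the only
reading of that definition consistent with the published bin ranges —
short 3–20, long 21–37, extremes excluded — which the bins reproduce
exactly.  `delay_split()` returns short-minus-long differences in
accuracy, RT and confidence with BCa bootstrap CIs; the pooling is
condition-unbalanced by construction, as in the source design.

## Statistics

* **BCa bootstrap** (`bca_bootstrap()`, default 2000 iterations): bias
  correction z0 from the fraction of bootstrap replicates below the point
  estimate (ties counted half, which matters for binary data),
  acceleration from jackknife skewness.  Degenerate input collapses to
  [c, c] with a warning; an undefined z0 (all replicates on one side)
  falls back to the percentile interval with a warning; the interval is
  widened if it ever fails to bracket the point estimate.  The
  implementation is cross-checked against `boot::boot.ci(type = "bca")`
  and held to 93–97% empirical coverage on normal data.
* **One-way ANOVA and Tukey-Kramer** (`oneway_anova()`,
  `tukey_kramer()`): thin wrappers over `stats::aov()` and
  `stats::TukeyHSD()`, which already implement the harmonic-mean
  Tukey-Kramer form for unequal n.  The canonical design here is 5 groups
  of 19 participant means, df = (4, 90).  All-constant input defines
  F = 0 with a warning.
* **JZS Bayes factor** (`jzs_bf()`): one-sample default-prior Bayes
  factor with a Cauchy(0, r) prior on the standardized effect size,
  computed by adaptive quadrature of the normal-scale-mixture integral
  over the mixing variance.  The default r = √2/2 is the convention of
  common Bayesian t-test software; the exact prior of the original
  analysis is not stated, so r is exposed as a parameter.  Tests hold the
  implementation to an *independent* quadrature (noncentral-t likelihood
  marginalized over a Cauchy effect-size prior) to four significant
  figures, and to the published anchor BF01 = 1.56 at t = 2.03, n = 80,
  r = 1.  Paired contrasts are analyzed as two-sided one-sample tests on
  participant-wise Irregular − Regular differences (`contrast_report()`),
  matching the difference-score presentation of such designs; no
  multiplicity correction is applied beyond Tukey-Kramer.

## Problem sizes used in the checks

The package's own validation uses sizes chosen to estimate each quantity
with adequate Monte-Carlo precision: 204–228 streams for stream-length
statistics; 1,000 random small instances against a brute-force scorer;
10,000 scrambles against the analytic chance oracle; 100 simulated
sessions for hit-probability recovery (per-group BCa CIs on 24 trials,
chance from 10 scrambles per block) and 100 for the injected
regular-vs-irregular null (session-level CIs over per-block differences);
2,000 simulations for BCa coverage; 19 simulated participants — the
original sample size — for the delay-split null and injected-recency
checks.

## Known limitations

* The observer is stationary and memoryless; it cannot express
  sequence-level interactions (e.g. detection aiding memory) unless
  extended.
* The lead-in/tail layout and the practice-image count are calibrated
  reconstructions (see above), not documented facts.
* `chance_session()` scrambles within blocks, holding each block's press
  count fixed; alternative nulls (e.g. pooling presses across blocks) are
  not implemented.
* Bootstrap CIs on 19 participants inherit the usual small-sample BCa
  caveats; coverage checks are run at larger n.
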