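---
title: "Modelling the spatio-sequential organization of gaze on faces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the spatio-sequential organization of gaze on faces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeseq)
```

## The analysis problem

During facial-expression recognition, fixation sequences over a face are
strongly structured: most dwell lands on the central region (eyes to
nose), and movements between regions depend on where gaze has just been.
`gazeseq` formalizes this with two complementary lenses on the same
fixation table:

1. a **sequential** lens — Markov models of the fixation-zone sequence and
   the entropy of their transition rows; and
2. a **spatial** lens — displacement between task events, within-zone path
   accumulation, a duration-per-distance stability index, and agreement of
   dwell rankings across participants.

Fixations are discretized into three stacked zones (UFZ, CFZ, LFZ)
bounded by horizontal lines standing in for the supraorbital ridge and
the subnasale. The discretization is deliberately regional: it trades
spatial resolution for robust, anatomically comparable units across
heterogeneous face stimuli.

## Mapping fixations to zones

Zones are axis-aligned rectangles in screen pixels (origin top-left, y
downward), validated to be non-overlapping and stacked in anatomical
order. Membership uses the **half-open convention** `[min, max)` on both
axes, so the shared boundary between two stacked zones belongs to the
lower zone and every in-box point belongs to exactly one zone. Fixations
outside all zones are, by default, dropped with the sequence stitched
across the gap; `break_at_outside = TRUE` instead splits the sequence so
that no transition is counted across the gap. The default favours
continuity (out-of-zone samples on a face task are mostly brief
excursions); the flag exists because the choice measurably affects
transition counts, and neither convention is canonical.

Sequences are built at the **fixation level**: repeated fixations within
the same zone are kept as distinct elements. This is essential — a
central-zone self-transition probability near 0.9 is only meaningful on
uncollapsed sequences; run-length collapsing would delete exactly the
persistence the analysis measures.

## Markov models and entropy

Transition counts are accumulated strictly within each participant ×
item × trial × event sequence and row-normalized — plain maximum
likelihood, no pseudocounts. Contexts never observed are reported as
`NA` and flagged rather than imputed. For the aggregate matrices, counts
pool over participants; for the order comparison, each participant is
fitted separately.

Row entropy is Shannon entropy in bits with `0·log 0 = 0`; normalized
entropy divides by `log2(3)` — three possible destination zones — **at
either model order**. The global value is the mean of row entropies
weighted by **empirical context occupancy** (each context's share of all
observed transitions; unobserved contexts get weight zero). Occupancy
weighting is the only aggregation under which strongly unequal row
entropies can average to a global value dominated by the central zone's
low-entropy row, which is the regime face-viewing data are in: published
aggregate estimates in this paradigm report central rows near 0.3
normalized entropy, peripheral rows near 0.6, and global values near
0.34 (order 1) and 0.32 (order 2), reproduced arithmetically by
`H_bits / log2(3)`.

For the first-versus-second-order comparison, `compare_orders()` takes
paired per-participant global normalized entropies, reports the median
difference, a percentile 95% bootstrap interval obtained by resampling
**participants** (the unit of inference) with replacement — B = 10,000 by
default, seedable — and a two-sided Wilcoxon signed-rank test (zeros
dropped). A subtlety worth stating: the plug-in inequality H₂ ≤ H₁ is
guaranteed only when both models are fitted on the same set of triples;
`estimate_transitions(..., skip = 1)` provides that alignment by
discarding each sequence's first transition from the order-1 fit. On
unaligned fits (all pairs vs all triples) small reversals are possible
in short sequences — which is why the comparison is done per participant
on their full data rather than asserted as an identity.

## Spatial repositioning and stability

`anchor_transitions()` measures between-event re-centering: the Euclidean
distance from the last fixation of the event preceding a target face to
the first fixation on that face. The preceding event is the within-trial
context image (`pre_context`) or the previous trial's response screen
(`post_context`); presentations lacking either endpoint — including the
first trial of a `post_context` block — are skipped and counted, never
silently imputed. Distances are grouped by the **landing zone** of the
first target fixation and compared with a Kruskal–Wallis test
(tie-corrected H, ε² = H/(n−1)) and pairwise two-sided rank-sum tests
with Holm correction (r = |Z|/√n of the pair). The pairwise tests are
independent-sample by design: observations are trial-level and group
sizes are unequal, so a paired statistic is not defined. Whether to pool
items or keep trial-level replicates is genuinely open; trial-level is
implemented because it preserves the skips-and-counts bookkeeping and the
unequal group sizes that motivate the rank tests.

Gaze stability is `total fixation duration / within-zone path length`
(ms/px). Within-zone path length sums consecutive-fixation segments
**whose two endpoints share the zone**; segments spanning zones belong to
neither, which makes "path length within a zone" well defined at the cost
of discarding boundary-crossing movement. Segments never span trial
boundaries; per-zone sums then accumulate across a participant's trials.
Groups with zero path length (zones visited only as isolated single
fixations) are excluded and counted — the alternative, infinite
stability, would poison every downstream rank or model fit.

Two aggregation grains are supported, because the two mixed models need
different ones: `participant_aoi` (participant × zone aggregates,
re-computed as summed duration over summed path, not a mean of ratios)
and `participant_aoi_event` (trial-level rows retaining the event-order
condition).

## Mixed models and concordance

`fit_stability_lmm()` delegates estimation to `lmerTest::lmer()` (REML,
random intercept per participant) — standard machinery, deliberately not
re-derived. Contrasts are reported against the **lower zone** as
reference. Per-term F tests use the Wald F with
**containment/residual denominator df**, `n_obs − rank(X)`: on the
27 × 3 aggregate grain this gives 78, the df structure conventional for
this design in the field's reports. Satterthwaite df (which lmerTest
would otherwise give, e.g. 52 for the balanced aggregate design) are a
defensible alternative; the choice is recorded in the result's
`ddf_method` field so readers know which convention produced the
p-values. Singular fits — common when the participant variance component
is tiny, as on aggregates of well-behaved synthetic data — are flagged,
not hidden.

Kendall's W uses the textbook formula `12S/(m²(n³−n))` with mid-ranks
for dwell ties and **no tie correction**, matching the formula's printed
form; with n = 3 zones, ties are rare and the correction would be
cosmetic. The spatial units default to the three zones; a uniform grid
over the face box is available (`units = "grid"`) since "spatial units"
need not mean AOIs — with the caveat that W values across different unit
systems are not comparable.

## The synthetic generator

The generator exists so that every stage above is testable, at scale and
deterministically, without raw recordings. It emulates the *study
conditions* of a two-procedure facial-expression task:

- **Design**: 27 participants by default; 24 face items shown twice
  (items cycle across sequential trials); every trial carries a context
  image (≈500 ms event), a target face and a response screen, ordered by
  the procedure (`pre_context`: context → face → response;
  `post_context`: face → context → response). Both procedures generate
  the anchor events the repositioning analysis needs.
- **Zone dynamics**: target-face zone sequences realize a first- or
  second-order Markov chain. The default matrices
  (`build_fixture_matrix()`) pin the published aggregate probabilities —
  order 1: U→C 0.694, L→C 0.692, C→C 0.920; order 2: (U,C)→C 0.902,
  (C,C)→C 0.926, (L,C)→C 0.830, (L,L)→L 0.535 — and fill the unpublished
  remainder by rule: cross U↔L transitions set to 0.030 ("infrequent"),
  self-transitions absorbing the order-1 residuals, the central row
  splitting its residual symmetrically; order-2 rows start from the
  order-1 row of the most recent state and rescale proportionally around
  any pinned entry. Every entry carries a provenance tag (`printed` /
  `filled`). Initial states are drawn from the chain's stationary
  distribution (for order 2, of the induced pair chain), so sequences
  start in steady state and pooled re-estimation is unbiased.
- **Fixation counts**: Poisson with mean 10 per 3000 ms face, truncated
  below at 3. Ten fixations in 3 s (~250–300 ms each) is a standard
  figure for scene/face viewing; the mean is a free parameter of the
  config because no published value constrains it.
- **Durations**: log-normal, median 250 ms, σ_log = 0.4 — a typical
  right-skewed fixation-duration profile. No duration model is published
  for this paradigm; this is a configurable default, not an estimate.
- **Geometry**: 1920 × 1080 screen; face box 600 × 800 px centred, split
  30/40/30 into the three bands (plausible proportions for forehead /
  eyes-to-nose / mouth-chin regions). Positions are zone-centre plus
  Gaussian jitter (sd 60 px) truncated to the band via inverse-CDF
  sampling, so the ingest round trip is exact by construction. Context
  fixations scatter about screen centre; response fixations about one of
  four response-icon positions on the horizontal midline.

What the generator **does not** emulate — and therefore what passing
tests do not establish about real data: no saccade kinematics, pupil
data or measurement noise beyond the validity flag; no coupling between
fixation duration and zone or serial position, so the *direction* of
stability differences between zones in synthetic data reflects band
geometry, not the empirical phenomenon (real central-zone stability
advantages must come from real data; the mixed-model machinery is
validated instead on constructed stability tables with known effects);
no emotion-category, congruency or accuracy structure; no participant
heterogeneity in transition style (all participants share one chain).

## Numerical and reproducibility choices

- Fixed seed ⇒ byte-identical generator output; the generator and the
  bootstrap save and restore the caller's RNG state.
- Truncated-normal draws use the inverse-CDF method (exact, vectorized),
  with a 1e-9 px clamp inside the open upper edge.
- Row-stochasticity is enforced to 1e-12 in the reference matrices;
  probability rows of fitted models renormalize counts exactly.
- Unparseable numeric fields at ingest become missing values that are
  *counted* at cleaning, never silently dropped at read time.
- Problem sizes: the test suite re-estimates the order-1 matrix from
  ~240,000 pipeline transitions and the order-2 matrix from a
  500,000-step sequence — the latter because the rarest conditioning
  context (lower, lower) occupies only ~2% of transitions, and its
  conditional estimate needs ~10⁴ visits for a standard error well under
  the 0.015 acceptance band. Oracle-equivalence checks run on ≤10-element
  instances against brute-force reference implementations written
  independently in the test helpers.

## Known limitations

Three-zone discretization obscures fine-grained scanpath structure;
continuous-space trajectory models are out of scope. Participant-level
screening (calibration quality, valid-sample proportion) is not
implemented — only per-fixation validity — because no operational
thresholds are available to encode. The containment-df convention for
mixed-model F tests is one defensible choice among several; switch the
reported df by refitting with `lmerTest` directly if Satterthwaite is
preferred. Kendall's W is reported without a significance test; with
n = 3 units its null distribution is too coarse to be informative.
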