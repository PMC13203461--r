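# gazeseq

Spatio-sequential analysis of eye-tracking fixation data recorded while
observers view expressive faces.

When people categorize facial expressions, their gaze is not scattered at
random over the face: fixations concentrate on the centre of the face and
move between regions in a structured, history-dependent way. `gazeseq`
quantifies that structure. Fixations are mapped to three stacked facial
areas of interest — the Upper (forehead to supraorbital ridge), Central
(supraorbital ridge to subnasale) and Lower (subnasale to chin) Facial
Zones — and the package provides, for researchers in face perception and
eye-movement analytics:

- **Markov transition models** of the zone sequence, first order
  P(X_t = j | X_{t-1} = i) and second order
  P(X_t = k | X_{t-2} = i, X_{t-1} = j), estimated by maximum likelihood
  within participant × item × event sequences;
- **transition entropy**: state-wise Shannon entropy of each conditional
  row in bits, H = −Σ p log₂ p, and a global normalized entropy
  H_norm = H_bits / log₂(3) aggregated with empirical context-occupancy
  weights (0 = fully predictable, 1 = uniform);
- **model-order comparison**: per-participant H₁ − H₂ differences with a
  percentile bootstrap CI (resampling participants) and a Wilcoxon
  signed-rank test;
- **cross-event repositioning**: Euclidean distance from the last fixation
  of the event preceding each target face (context image, or the previous
  trial's response screen) to the first fixation on the face, compared
  across landing zones with Kruskal–Wallis (ε² = H/(n−1)) and pairwise
  rank-sum tests under Holm correction;
- **gaze stability**: per zone, Stability = TotalDuration / PathLength
  (ms/px), with PathLength the summed Euclidean length of within-zone
  consecutive-fixation segments, analysed with random-intercept mixed
  models `stability ~ zone + (1|participant)` (and a zone × event-order
  variant);
- **inter-participant concordance** of dwell-time rankings over spatial
  units, Kendall's W = 12S / (m²(n³ − n));
- a **seedable synthetic fixation generator** whose default transition
  matrices pin the published aggregate probabilities of a
  facial-expression-recognition study (e.g. central-zone self-transition
  0.920), so the entire pipeline is testable without access to raw
  recordings.

## Worked example

Simulate a 27-participant session (24 face items, two presentations each,
context image before each face), rebuild zone sequences from the fixation
table, and fit the sequential models:

```r
library(gazeseq)

cfg  <- synth_config(n_participants = 27, seed = 1)
fx   <- generate_fixations(cfg)
seqs <- build_sequences(clean_fixations(fx), cfg$face_layout)

m1 <- estimate_transitions(seqs, order = 1)
m1
#> Order-1 transition model: 11454 transitions
#>       UFZ   CFZ   LFZ
#> UFZ 0.277 0.690 0.033
#> CFZ 0.042 0.916 0.041
#> LFZ 0.020 0.710 0.270

global_entropy(m1)
#> Order-1 transition entropy
#>   context weight H_bits H_norm
#> 1     UFZ 0.0529  1.045  0.659
#> 2     CFZ 0.8953  0.499  0.315
#> 3     LFZ 0.0518  0.975  0.615
#> global: H_bits = 0.553, H_norm = 0.349
```

The fitted matrix recovers the generating structure: strong central
attraction (U→C 0.690, L→C 0.710), high central persistence (C→C 0.916)
and rare direct upper↔lower exchanges. Entropy is lowest for transitions
out of the central zone (H_norm 0.315) — gaze leaving the centre is the
most predictable — and the global normalized entropy (~0.35) is far below
the value 1 expected under unstructured scanning. About 90% of transition
contexts are the central zone (the `weight` column).

Comparing model orders across participants:

```r
h1 <- participant_entropies(seqs, 1)
h2 <- participant_entropies(seqs, 2)
compare_orders(h1$H_norm, h2$H_norm, seed = 1)
#> Entropy difference H1 - H2 (n = 27 participants)
#>   median = 0.0130, 95% bootstrap CI [0.0046, 0.0178] (B = 10000)
#>   Wilcoxon signed-rank V = 345.0, p = 4.746e-05
```

The second-order model removes a small but systematic amount of
uncertainty: knowing two preceding fixations helps, slightly, beyond
knowing one.

Spatial metrics and concordance follow the same grammar:

```r
st <- stability_table(seqs)                   # participant x zone aggregates
fit_stability_lmm(st, "aoi_only")$anova       # F test with residual df 78
kendall_w(dwell_ranks(seqs))
#> Kendall's W = 0.753 (m = 27 participants, n = 3 units, S = 1098.0)
```

A ready-made shell interface over the same functions is installed at
`inst/scripts/gazeseq-cli.R` (subcommands `simulate`, `ingest`, `markov`,
`spatial`, `concordance`, `lmm`).

## Vignette

`vignettes/gaze-organization.Rmd` documents the statistical model, the
generator's design (what it emulates and what it deliberately does not),
all numerical conventions (half-open AOI rectangles, entropy weighting,
degrees-of-freedom method, zero-path handling) and known limitations.
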