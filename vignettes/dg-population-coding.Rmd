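---
title: "Population coding analysis of sparse dentate-gyrus calcium events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population coding analysis of sparse dentate-gyrus calcium events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dentate-gyrus granule cells are among the most sparsely active neurons in
the hippocampus: miniscope calcium imaging at 3 Hz yields binarized event
trains with mean rates around 0.02 Hz, i.e. one or two events per minute
per neuron. The analytical question this package addresses is how much
behavioural information such sparse population activity carries, and how
that information is distributed across neurons: are position, running
speed, motion direction, and (in a T-maze) current and future left/right
location carried by the same neurons, by mutually exclusive subpopulations,
or by overlapping but statistically independent ones?

The pipeline has five stages, each a package module:

1. **Per-neuron tuning** — occupancy-normalized spatial rate maps
   (Gaussian-smoothed, sigma = 2 cm), speed tuning over the three classes
   0–1, 1–5 and >5 cm/s, and direction tuning over 8 bins (north = 0 rad,
   west positive).
2. **Information content** — the Skaggs per-event statistic in bits per
   calcium transient, with a circular-shift shuffle null (1,000 shuffles)
   per neuron and a population permutation test with Cohen's *d*.
3. **Population decoding** — position, speed and direction from sliding
   windows of population event vectors; left/right location from T-maze
   window counts; chance levels from decoders retrained on shuffled data.
4. **Ordered deletion** — decoding performance at 100..10% of neurons
   remaining under information-ranked or random deletion orders, compared
   via two-way ANOVA and nine-point Cohen's-*d* effect sizes; the
   within-type vs cross-type |d| contrast quantifies independence.
5. **T-maze LR analysis** — per-neuron LR selectivity indices in the
   forced-arm window (current side) and the decision window (future
   side), with trial-label permutation nulls.

Because the in-vivo recordings live in external repositories, the package
ships a first-class synthetic-data generator that reproduces the
recordings' statistical structure, and the whole pipeline is validated
end to end on it.

## The synthetic generator and what it emulates

`simulate_of_trajectory()` produces a 30-min, 3-Hz, 40 × 40 cm open-field
session. Motion is an Ornstein–Uhlenbeck speed process (mean 5 cm/s, SD
4 cm/s, relaxation 2 s, floored at 0) with a diffusing heading
(1.2 rad/√s) and reflecting walls. These values were chosen so that a
session (i) occupies >80% of a 10 × 10 grid, and (ii) spends meaningful
time in all three behavioural speed classes, both of which hold for real
mouse open-field sessions. The arena side is configurable; 40 cm is a
typical mouse open field and no spatial quantity in the pipeline depends
structurally on it.

`make_tuning_spec()` draws per-neuron tuning parameters. Event rates are
modelled as a product of mean-one modulation factors on a baseline:

- place: a Gaussian bump (width 3–8 cm) normalized to unit mean over the
  arena, mixed with a flat component by `place_gain` in [0, 1];
- speed: `1 + slope · (v − mean v)`, slope in [0, 0.3] per cm/s, floored
  at 0;
- direction: a von Mises profile normalized by its circular mean
  (concentration 0–2).

Because every factor has mean ~1 over the session, the population mean
event rate equals the configured baseline (0.02 Hz) regardless of the
gains drawn — the sparse-coding constraint is preserved under arbitrary
tuning. Baseline rates are lognormal across neurons (log-SD 0.7,
population mean 0.02 Hz): granule-cell activity is strongly right-skewed,
and this heterogeneity is also what gives simulated animals realistic
between-animal variability. The `structure` argument encodes the three
competing population hypotheses (independent, dependent, exclusive gain
allocation across information types).

The speed-slope range deserves a note: it was set so that full-population
speed decoding lands at a modest positive correlation (~0.1–0.3) at 70
neurons — weaker tuning leaves speed decoding at floor, where deletion
analyses are uninformative.

`simulate_tmaze_session()` emulates the forced-alternation task: 50
trials, forced side uniform, free choice alternating with probability
`correct_rate` (default 0.714, the observed wild-type rate; 0.5 makes the
choice independent of the forced side and gives the 50% chance level).
Each 30-s trial has a forced turn near 8 s and a free-choice turn near
22 s (±1 s jitter), so the 5-s forced-arm window and the −6..−1 s
decision window always fit. LR-tuned neurons modulate their rate by
`1 ± gain` inside those windows according to their side preference. The
maze trajectory is a schematic piecewise-linear track (40-cm stem, 20-cm
arms), sufficient for window extraction, not a locomotor model.

Events are per-frame Bernoulli draws with probability `rate · Δt`
(clipped to 1 with a warning), i.e. thinning of an inhomogeneous Poisson
process at the 3-Hz frame resolution — exactly the binarized trains the
analysis consumes.

What the generator does **not** emulate: fluorescence kinetics and event
detection noise (events are ideal), slow drift and nonstationarity,
theta/behavioural rhythmicity, spatial correlations between neurons
beyond shared behaviour, and cell-registration artifacts. Tests passing
on synthetic data therefore validate the statistical machinery — not the
biological claims on real recordings.

## Conventions and numerical choices

- Coordinates: x east, y north; motion direction `atan2(−Δx, Δy)` in
  (−π, π], so north = 0 and west spans (0, π). Rotating a path by +π/2
  shifts every direction bin by exactly 2 (mod 8) — a property test.
- Kinematics: positions smoothed by a 3-frame (1 s) centered moving
  average before differencing, suppressing tracker jitter at 3 Hz; frames
  with zero displacement have undefined direction and are excluded from
  direction analyses.
- Spatial bins: 10 × 10 equal-area grid, half-open cells with the last
  row/column closed; bins with under 1 s of occupancy are excluded from
  information computation (rate estimates there are unstable) and the
  occupancy distribution renormalized.
- Tuning maps are rastered at 1-cm pixels and smoothed with a truncated
  (3 sigma) Gaussian, sigma = 2 cm. Smoothing is occupancy-weighted and
  mass-conserving: counts and occupancy are smoothed with a kernel
  renormalized at the arena edge so each source pixel keeps its full mass
  inside the arena, then divided. This design (rather than smoothing the
  ratio map directly) makes the occupancy-weighted mean rate exactly
  invariant under smoothing — total events and total time are conserved —
  which is both physically sensible and testable to 1e-9.
- Information: the Skaggs statistic
  `I = Σ p_i (λ_i/λ̄) log2(λ_i/λ̄)` in bits per transient. For a
  binarized train it reduces exactly to
  `Σ (c_i/C) log2(c_i T /(o_i C))` with per-bin counts and occupancy,
  which is what the code evaluates (and what makes the 1,000-shuffle null
  cheap: only event frames need relabelling per shift). The unit
  "bits per calcium transient" pins this estimator choice.
- Shuffle null: a circular time shift of the event train by ≥20 s,
  preserving event count and within-train temporal structure — the
  standard null for tuning significance and the natural choice for
  continuously recorded sessions. Trial-structured (T-maze) data use
  trial-label permutation instead, since trials are exchangeable under
  the null.
- Population test: each replicate draws one value per neuron from its
  null and averages; the p-value is add-one smoothed and floored at
  1/(n+1) (reported "< 10⁻³" at 1,000 replicates). Cohen's *d* uses the
  pooled SD of the observed values and the per-neuron null means.
- Deletion ranking uses shuffle-debiased information
  (`information_scores(debias = TRUE)`): the plug-in statistic has a
  positive small-sample bias that grows with bin count and shrinks with
  event count, so under heterogeneous rates raw values rank sparse
  neurons first rather than tuned ones. Subtracting each neuron's own
  null mean (100 shuffles) removes the bias; reported information values
  elsewhere remain plug-in.

## Decoders

Three models sit behind one interface:

- `linear` (default): ridge regression on a 10-frame (~3.3 s) sliding
  window of population event vectors, closed form with centered Gram
  matrices, penalty λ = 1. Deterministic, fast, and the model used inside
  the deletion analysis — the per-fold Gram matrix is computed once and
  subset by neuron columns, so each of the thousands of subset refits
  costs one small solve.
- `feedforward`: a single-hidden-layer network (`nnet`).
- `recurrent`: an echo-state network — a fixed random leaky-tanh
  recurrent reservoir (64 units, spectral radius 0.9) driven by the event
  sequence, with a ridge readout over reservoir states plus the raw
  events. This is the package's recurrent sequence decoder: it captures
  temporal context beyond a fixed window while remaining exactly
  seed-reproducible and cheap to train.

Direction is regressed as (sin θ, cos θ) and recomposed with `atan2`,
avoiding the 2π discontinuity. Cross-validation uses 5 contiguous
temporal folds (autocorrelated frames must not straddle the train/test
boundary); T-maze LR decoding uses leave-one-trial-out with a ridge
classifier on window counts. Chance levels retrain the identical pipeline
on per-neuron circularly shifted data (open field) or label-permuted
trials (T-maze) and score it against the true held-out targets, 10
repetitions.

Metrics: position — mean absolute Euclidean error (cm); speed — Pearson
correlation; direction — mean absolute circular error in [0, π] (π/2 is
the uniform-guess chance level); LR — percent of held-out trials correct.

## Deletion analysis

Neurons are deleted in a specified order; at each retention level
(100..10% in steps of 10) the decoder is retrained from scratch on the
survivors — deleting from the dataset, not zeroing inputs of a fixed
decoder. Retention sets are nested by construction. The random-order
curve averages 10 independent permutations per animal to stabilize the
baseline. Pairwise effect sizes are unpaired pooled-SD Cohen's *d* across
animals at the nine levels 90..10%, summarized by mean |d|; the order
comparison ANOVA works on animal-averaged order × level cells (5 orders
× 10 levels gives the F(4, 36) design) with Tukey HSD post hoc contrasts.
When all orders carry identical data both the order and residual sums of
squares vanish; the implementation reports F = 0 rather than 0/0 noise.

## Degenerate inputs and tie-breaks

Zero-event neurons have undefined information and are excluded from
population tests; neurons silent on both T-maze sides get LR index 0 with
an `inactive` flag; classes or bins never visited are flagged undefined
rather than imputed; trials whose analysis window leaves the session are
excluded (not truncated) so per-trial exposure stays constant; event
probabilities above 1 are clipped with a warning. All randomness flows
from explicit integer seeds, with per-neuron and per-repetition
sub-streams derived deterministically.

## Problem sizes used by the tests and scripts

The shipped analysis scripts and the test suite run the full study
geometry — 7 animals × 70 neurons, 30-min sessions, 50-trial T-maze
sessions, 1,000-shuffle nulls — with the linear decoder throughout; the
calibration test uses 200 untuned neurons, and the independence
(deletion) test repeats its 7-animal cohort over 5 seeds. These sizes
were chosen as the smallest at which the population statistics are
stable; all of them run on a laptop-class single core.

## Known limitations

- The plug-in information estimator is biased upward for sparse neurons;
  the package debiases rankings but reports raw values, so absolute
  information magnitudes at 0.02 Hz should be read comparatively (against
  their nulls), not as unbiased information rates.
- With cleanly disjoint tuned subpopulations and statistically identical
  simulated animals, cross-type deletion orders protect same-type neurons
  slightly but systematically relative to random deletion (they delete
  the disjoint subpopulation first), so cross-type |d| values are
  conservative upper bounds on what messier real data shows.
- The LR-index formula `(r_L − r_R)/(r_L + r_R)` is one bounded,
  sign-symmetric choice; it is isolated behind `lr_index()` so an
  alternative normalization can be swapped in one place.
- The echo-state recurrent decoder is not a trained LSTM; it stands in
  for recurrent sequence decoding where exact reproducibility and CPU
  training are required.
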