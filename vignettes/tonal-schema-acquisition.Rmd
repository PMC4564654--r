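---
title: "Simulating the acquisition of a musical tonal schema"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the acquisition of a musical tonal schema}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Listeners raised on Western music acquire a *tonal schema* — an internalized
representation of their culture's pitch regularities — in a characteristic
order: sensitivity to *scale membership* (which of the 12 chromatic pitch
classes belong to the prevailing key) appears years before sensitivity to
*implied harmony* (whether a tone sequence suggests a conventional chord
progression such as I–V–I). `tonalschema` asks whether that ordering falls
out of a generic supervised learner exposed to a realistic melodic diet,
with no music-specific machinery beyond a pitch-class input code and a
key-label teacher signal.

## The model

The learner is a fully connected multilayer perceptron:

* **Input layer** — 2,232 binary units: 186 serial positions x 12 tone
  chromas. A melody of *n* tones activates one chroma unit in each of its
  first *n* position blocks; remaining blocks stay zero and contribute
  nothing to the first affine map. Serial position is coded explicitly so
  that reorderings of the same tones are distinct inputs.
* **Hidden layers** — 45 and 30 units, hyperbolic-tangent activation
  `f(x) = (e^x - e^-x) / (e^x + e^-x)` (computed via the numerically stable
  `tanh`, which agrees with the literal form to machine precision and
  saturates instead of overflowing).
* **Output layer** — 24 tanh units, one per key (12 tonics x major/minor;
  index 0 is C major, 12 is C minor).

Training is online stochastic gradient descent on the squared error between
the raw outputs and a one-hot `{0, 1}` teacher signal, the classic
backpropagation recipe: every corpus melody is presented once per epoch in
a reshuffled order. The `>0 -> 1` binarization of outputs is a readout
convention only; it never enters the gradient, because it is not
differentiable and conceptually marks "identified vs not identified". Two
deliberate consequences of the `{0, 1}` coding with tanh outputs: the "off"
target 0 sits at the midpoint of the output range, and a `{-0.9, +0.9}`
bipolar coding is available (`bipolar_targets = TRUE`) but off by default.

Key readout is the argmax over the 24 raw outputs; an exact tie goes to the
lowest key index with a warning (ties are measure-zero but the rule must be
deterministic).

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `init_scale` | 0.1 | half-width of the uniform weight initializer |
| `learning_rate` | 0.01 | per-item SGD step size |
| `checkpoint_interval` | 5000 | epochs between read-only evaluations |
| `out_of_scale_rate` | 0.05 | cap on chromatic tones per generated melody |
| `exclusion_threshold` | 0.10 | minimum final training agreement to retain a run |

Momentum is not used; update granularity is per item. Both choices follow
the original backpropagation formulation, and the learning rate is exposed
because nothing in the underlying study pins it down.

## The synthetic corpus

The corpus generator emulates a children's-songbook diet: by default 315
major-key and 41 minor-key base melodies of 17–186 isochronous tones.
Each melody is sampled from a tonic-relative scale-degree profile whose
in-scale shape follows the classic probe-tone tonal hierarchy (tonic
heaviest, then dominant and mediant), with 98% of the sampling mass
in-scale and 2% on chromatic degrees; melodies begin and end on the tonic,
which operationalizes "clearly in one stable key". Minor-mode membership is
natural minor plus the raised leading tone at reduced weight. The profiles
are arguments, so published tone distributions can be substituted, and
`profile_correlation()` supports validating a generated corpus against a
reference profile.

Base melodies are generated in C major / A minor and then closed under
same-mode transposition (`augment_by_transposition()`), giving 12 copies of
every melody, one per key — 4,272 items per epoch at the default counts.
After closure every key of a mode has the identical tonic-relative tone
distribution, so the learner cannot prefer specific keys; this is tested as
an exact invariant.

What the generator does *not* emulate: phrase structure, rhythm and note
durations (melodies are isochronous by construction), melodic contour
conventions, motivic repetition, and the long-tailed popularity of real
songs. Passing tests therefore show that the *statistical tone-distribution
structure* of the diet suffices for the phenomena studied here, not that
the corpus is musically realistic in any richer sense.

## The test battery

Fifteen fixed nine-tone sequences, five per condition, all to be judged
against C major:

* **in-scale/regular-harmony** — three 3-tone groups arpeggiating C-major
  triads in I–V–I or I–IV–I order;
* **in-scale/irregular-harmony** — C-major scale tones only, ordered so no
  three consecutive tones outline any major or minor triad;
* **out-of-scale/irregular-harmony** — chromatic sequences drawing on
  C#, D#, F#, G#, A#, likewise avoiding triad outlines.

The three conditions share the same length so comparisons are not
confounded by input size. Scale sensitivity shows up as the two in-scale
conditions separating from the out-of-scale condition; harmony sensitivity
as the regular condition separating from the irregular in-scale condition.
Because the underlying study's sequences exist only as musical notation,
the fixtures here are constructed to the stated membership and
triad-outline criteria and verified property-by-property in the test suite;
start tones are distributed on musical grounds (triad arpeggios mostly
start on the root; the irregular and chromatic sequences start on varied
degrees).

## Experiments and statistics

`run_experiment()` trains `n_runs` networks that differ only in their
initialization and presentation-order seeds, evaluates every checkpoint
read-only (percent correct and normalized correct-key activation per
condition, plus training agreement), and excludes runs whose final
training agreement stays below `max(2 x chance, exclusion_threshold)` —
the operational signature of a run trapped near its random start. All
seeds derive from `base_seed`, and repeated calls are bit-identical.

`rm_anova()` analyses the run x condition x epoch trajectories as a fully
within-subject two-way design: omnibus effects through `stats::aov` error
strata with uncorrected degrees of freedom; simple main effects of
condition at each epoch against the *pooled* within-subject error
(SS(S×C) + SS(S×C×E)), so with 9 runs, 3 conditions and 10 epochs the
simple-effect error has 160 df; pairwise condition contrasts are paired t
tests under a Bonferroni-adjusted alpha (0.05 by default — the most
conservative common reading of an "adjusted alpha"). Greenhouse–Geisser
correction is deliberately not applied by default, matching the uncorrected
df convention of the trajectory analyses this package mirrors. A
zero-variance contrast (all runs identical) is declared significant when
the constant difference is non-zero — saturated trajectories make this
degenerate case routine. `sensitivity_onsets()` reduces the pairwise table
to the two onset epochs whose order is the headline question.

## The scaled-down replication experiment

`reduced_experiment_config()` shrinks the full study to a desk scale while
preserving its structure: 60 base melodies in the original 315:41
major:minor ratio (53:7), closed to 720 items per epoch; 2,000 epochs with
a checkpoint every 200, so there are again 10 test times and the third
checkpoint sits at 30% of training exactly as epoch 15,000 of 50,000 does;
8 runs (the full design uses 10).

Two scaled parameters need care. First, a 720-item corpus drawn from 60
base patterns is far less diverse than 4,272 items from 356, so at the
general-purpose default learning rate the network reaches its asymptote
before the first checkpoint and the recorded trajectory is flat. The
scaled experiment therefore uses a learning rate of 8e-5 and the
2,000-epoch horizon, chosen together so that the learning timeline is
proportional to the full-scale study: training agreement is still climbing
through the middle checkpoints and ends in the high 80s rather than at
ceiling, and the test-condition curves are still rising at the 30%
checkpoint. This is a property of scaling the experiment down, not a
statement about the original model's rate.

Second, the scaled experiment gives every run its own corpus realisation
rather than sharing one. A full-sized experiment trains on a fixed corpus
of real melodies, where there is nothing to resample; a 60-melody
synthetic draw, by contrast, carries substantial sampling noise — one draw
can be unusually triadic and learned almost immediately, another unusually
hard — and under a shared corpus that single draw sets the learning speed
of every run at once. Independent realisations per run integrate the
corpus-sampling noise into the run-to-run variance the analysis already
models, instead of leaving it as a hidden bias of the whole experiment.

One aspect of the original trajectories does not survive the shrinking:
in the scaled runs the out-of-scale condition can score the occasional hit
at the first checkpoints, while the network is still near its random
start, before settling at 0% for the remaining checkpoints. The
under-trained guessing phase that the full-scale study passes through
before its first test time (1/10 of training) overlaps the first
checkpoints here, because learning must be slowed for the curves to be
visible at all.

Problem sizes throughout the package's tests follow the same philosophy:
toy corpora of a few melodies for mechanism tests, the 60-base-melody
reduced experiment for trajectory-level checks.

## Numerical and design choices

* Weight updates, loss, and forward passes are computed in compiled code
  (RcppArmadillo); the input's sparsity (at most 186 of 2,232 ones) makes
  the first layer a sum of active weight rows rather than a dense product.
* The per-item loss is `0.5 * sum((output - target)^2)`; reported epoch
  loss is its mean over items.
* Checkpoints store deep copies; an epoch-0 snapshot of the untrained
  network is always kept as a chance-level reference.
* Degenerate inputs are errors, not silent repairs: empty corpora,
  melodies outside 17–186 tones for the generator (1–186 for encoding),
  profiles that do not sum to 1, out-of-range key indices, non-finite
  training loss (reported with its epoch).
* `generate_corpus()` and `run_experiment()` restore the caller's RNG
  state; all randomness is local to the seeds given.

## Known limitations

* The learner sees pitch class only — no octave, duration, meter, rests,
  or polyphony; these are out of scope by design.
* The 9-tone probe sequences are much shorter than the 17–186-tone
  training melodies, so test inputs lie outside the training length
  distribution; this mirrors the original design but means early
  checkpoints can behave idiosyncratically on single sequences.
* With only 5 sequences per condition, per-run percent correct is
  quantized to multiples of 20, and saturated conditions have zero
  between-run variance; the analysis code handles these degeneracies
  explicitly rather than pretending continuity.
* The scaled-down experiment reproduces the *shape and ordering* of the
  acquisition trajectory; exact percentages at intermediate checkpoints
  depend on corpus realization and seeds.
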