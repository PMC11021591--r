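---
title: "ictalnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ictalnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite does not itself compute.

## The task and the data model

The unit of classification is a fixed-length multichannel EEG window. A
recording is a channels × samples matrix in microvolts with a sampling rate
and zero or more annotated seizure intervals; all intervals are half-open
`[start, end)` in seconds, and window `i` at stride `s` covers
`[i·s, i·s + w)`. Windows default to `w = 30` s with no overlap — the
minimal reading of "equal-length segments" — and a window is labelled
ictal when at least half of its duration lies inside a seizure interval
(`label_rule = 0.5`, configurable). The 50% rule keeps boundary windows
from injecting label noise in either direction; the windowing laws
(`n = ⌊(T−w)/s⌋ + 1`, labels equal to a per-sample brute-force count) are
property-tested.

Raw microvolt scales destabilize gradient training, so per-channel z-score
normalization — fitted on training windows only, then applied unchanged to
test windows — is an explicit, separate step (`fit_normalizer()` /
`apply_normalizer()`). Nothing inside `segment()` filters, resamples or
rescales: windows are verbatim slices.

Seizure recordings are grossly imbalanced (ictal seconds are a small
fraction of a record), and balanced-looking headline metrics imply some
balancing step; the package makes it explicit with
`balance_windows(policy = "undersample")`, which keeps all minority windows
and a seeded random equal-sized subset of the majority. The 70/30 split is
stratified within patients by default; a patient-disjoint option
(`by_patient = TRUE`) exists because the two protocols answer different
questions and the within-patient one is the weaker (easier) claim.

## The classifier

Five learned stages, sized for a small parameter budget:

1. **Conv blocks** (default 2; 32 and 64 filters): 1D convolution with
   kernel 3 and length-preserving ("same") zero padding, ReLU, max-pool
   2/2. Kernel 3, "same" padding and max pooling are the reference
   configuration; the per-block filter counts and pool size are package
   defaults, since only the kernel and pooling type are pinned down.
2. **Attention reconstruction**: the pooled feature sequence
   `F ∈ R^{T×d_in}` is projected to queries, keys and values
   (`Q = F·W_Q` etc., width `d = 32` by default) and each position is
   rebuilt as `softmax(QKᵀ/√d)·V`. The softmax rows are probability
   distributions (asserted to 1e−6 in tests). Scaled dot-product is the
   canonical completion for a Q/K/V attention whose score function is not
   otherwise specified.
3. **GRU** (128 units) over the reconstructed sequence; the final hidden
   state is the window representation. Gate equations:
   `z = σ(W_z[h,x]+b_z)`, `r = σ(W_r[h,x]+b_r)`,
   `h̃ = tanh(W_h[r⊙h, x]+b_h)`, `h′ = (1−z)⊙h + z⊙h̃`. The blend
   convention matches a forward link carrying `1−z` from the previous
   state; the mirrored convention is available as `reverse_gate = TRUE`
   because diagrams of this cell are routinely ambiguous about which arm
   carries `z`.
4. **Dropout** 0.5 on the final GRU state (inverted dropout, training
   only).
5. **Dense sigmoid head** trained with binary cross-entropy — a binary
   task; fractional (mixup) targets are consumed without rounding.

Training: Adam (lr 0.001, β₁ 0.9, β₂ 0.999), shuffled mini-batches of 256
(capped at the data size), 50 epochs by default. All of kernel 3, GRU 128,
dropout 0.5, lr 0.001, 50 epochs, batch 256 reproduce the reference
configuration and are overridable. The forward and backward passes are
hand-written in RcppArmadillo; gradients are verified against central
finite differences (tolerance 1e−5 on randomly probed coordinates) and the
full compiled forward is cross-checked against a pure-R composition of the
exported `attention_reconstruct()` and `gru_step()` primitives.

**Initialization.** Conv filters use He scaling, GRU and projection
matrices Glorot-style scaling, and two deliberate zeros: the dense head
starts at zero (an untrained model outputs exactly 0.5, a tested
contract), and `W_Q` starts at zero while `W_K`, `W_V` are random. Zero
`W_Q` makes the initial attention exactly uniform, so the GRU initially
sees the global average of the value features — a smooth, low-variance
representation that trains stably on small window counts — while the
nonzero keys keep `∂J/∂W_Q = Fᵀ(dS·K) ≠ 0`, so attention can sharpen away
from uniformity during training. With both `W_Q` and `W_K` zero the
attention gradient would vanish identically; this asymmetric zero is the
package's choice where no initialization is prescribed.

## Augmentation

`amplify()` implements the train → perturb → mix → retrain loop: a
classifier is first trained on the raw training windows
(`pretrain_epochs`, default 10, kept short at desk scale), adversarial and
mixup windows are generated against it, and the final model is trained on
original + generated windows.

* **Adversarial**: one fast-gradient-sign step. `ε` defaults to 0.1 in
  normalized (per-channel SD) units; it is not a published value, so it is
  configuration, and a projected multi-step ascent is available via
  `steps > 1`. Generated windows keep their source's true label — the
  point is to train the model to resist the perturbation. The `ε`-ball
  containment `‖x̄−x‖∞ ≤ ε` holds to machine precision and the loss-ascent
  margin on a linear-logit oracle (`logit` change exactly `ε‖w‖₁`) to
  1e−6, both asserted in tests.
* **Mixup**: `λ ~ Beta(0.2, 0.2)` (the conventional small-α default,
  producing mostly near-endpoint mixes), partner sampled uniformly, soft
  label `λyᵢ+(1−λ)yⱼ` recorded with full provenance.
* **Bookkeeping**: the multiplier `n` counts *all* generated windows
  (adversarial and mixup together, split by `mix_ratio`, default 0.5), so
  `|augmented| = (1+n)·|train|` exactly — the reading adopted where "n
  times the original training set" is ambiguous about what is counted.

## The synthetic world

`generate_recording()` emulates what the pipeline needs from real EEG, not
physiology. Background per channel: one sinusoid in each of delta (1–4 Hz),
theta (4–8), alpha (8–13) and beta (13–30) with amplitudes 4:3:2:1 and
random frequency and phase, plus 1/f-shaped noise (amplitude 2) and white
noise (SD 1). Seizure intervals add a 3 Hz rhythm — the classic
spike-and-wave repetition rate — scaled to `amplitude_gain` (default 3)
times the channel's background SD, with narrow Gaussian transients at
2 Hz riding on it. Defaults: 18 channels, 256 Hz, 300 s.

Two placement policies in `generate_dataset()`: `align = TRUE` (default)
puts intervals on a `seizure_len_s` grid so that, when windows are cut at
the same length, every window is entirely ictal or entirely background —
unambiguous labels, which is what a correctness fixture needs;
`align = FALSE` jitters intervals uniformly inside equal blocks, which
produces realistic partial-coverage boundary windows and exercises the
label rule. During development the jittered policy was found to turn the
end-to-end fixture into a *coverage-ranking* task (nearly every window
25–75% covered) on which even an ideal 3 Hz band-power detector loses
accuracy; aligned placement is therefore the default for the separability
guarantee, and the jittered path is kept and tested for the labelling
semantics.

What a green end-to-end test establishes: the pipeline wiring, the
training loop, and that the model can learn a cleanly separable
amplitude/rhythm discrimination from ~70 windows. What it does not
establish: performance on real EEG, robustness to artifacts, inter-patient
generalization, or any clinical claim. The generator's separability
guarantee (≥95% accuracy for a band-power threshold at gain ≥3) is itself
a test, so the end-to-end assertions are not vacuous.

The evaluation-time noise probe (`noise_probe()`, `add_window_noise()`)
adds broadband noise and slow sinusoidal baseline drift to *test* windows
only, mimicking non-denoised input.

## Metrics

Confusion counts partition the sample; ACC/SEN/SPE raise a typed warning
and return `NA` on empty denominators rather than silently returning 0.
The ROC sweeps thresholds over unique descending scores with tied scores
grouped into a single step (tie handling changes AUC, hence documented),
prepends (0,0), appends (1,1), and integrates by the trapezoid rule. This
equals the Mann–Whitney pairwise estimate (ties counted ½) — property-
tested on 200+ random instances to 1e−9. Two printed formula slips are
resolved in the obvious way: the false positive rate is `FP/(FP+TN)` (the
horizontal ROC coordinate), and specificity is `TN/(TN+FP)`. AUC is
implemented on its full mathematical range `[0, 1]`, although a classifier
worth deploying sits in `[0.5, 1]`; a value below 0.5 indicates an
inverted scorer, not an invalid computation.

## Numerical and degenerate-input choices

* Softmax rows are max-shifted before exponentiation.
* Binary cross-entropy is computed in logit space
  (`softplus(s) − y·s`), stable for large |logits|.
* A recording shorter than one window yields an empty window set with a
  warning, not an error; a trailing partial window is discarded.
* A non-finite training loss aborts with the offending epoch/batch in the
  error message.
* The EDF writer emits 1-second records (integer durations and rates
  required) and rounds physical ranges to their printed 8-character header
  form *before* digitizing, so a write/read round trip is exact up to
  int16 quantization (≈ range/65534 per channel, asserted in tests).
* All randomness (generation, splits, balancing, initialization, shuffling,
  dropout masks, mixup draws) flows through seeds derived from
  user-supplied integers; every stage is bit-reproducible, and experiment
  tables regenerate exactly from config + seeds. Seeded operations restore
  the caller's RNG state.

## Replication policy

The experiment grid (`run_experiment()`) defaults to 3 seeds with
mean ± sd per arm, because single-run orderings between augmentation arms
at desk scale are noise-dominated; single published numbers per arm are
the degenerate 1-seed case. Pooled (not per-patient-averaged) evaluation
is the default; a per-patient breakdown can be obtained by running
patient-disjoint splits per patient list.

## Known limitations

* The synthetic generator is a testability caricature: no lead-field
  mixing across channels, no artifacts, no patient-specific morphology.
* The EDF reader supports the 16-bit, equal-rate-per-signal subset (which
  covers the common scalp-EEG corpora) — not EDF+ annotations channels,
  mixed rates, or discontinuous records.
* The compiled training loop stores GRU and attention caches for a whole
  mini-batch; memory grows as `O(B·(H + A)·T + B·T²)`. At the default
  batch of 256 with very long windows this can reach gigabytes — reduce
  `batch_size` or increase pooling for long, high-rate windows.
* Per-window detection only: no event-based metrics, detection latency or
  false-alarms-per-hour.
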