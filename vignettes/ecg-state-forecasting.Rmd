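---
title: "Multi-horizon driver-state forecasting from single-lead ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-horizon driver-state forecasting from single-lead ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A driver's physiological state — stress level (low/medium/high) or
drowsiness stage (awake / sleep stage 1 / sleep stage 2) — changes on a
time scale of tens of seconds and is partially foreshadowed by the
autonomic nervous system: heart rate and beat morphology begin to shift
before the behavioral state does. `ecgfusion` exploits that lead to
predict the state class 1–60 seconds ahead from nothing but a single-lead
ECG, so that an in-vehicle system has time to warn or intervene before an
undesirable status materializes.

The pipeline has four stages, each a package module:

1. **Beat segmentation.** The unit of analysis is the ECG beat, the
   signal between two consecutive R waves. R waves are found with a
   Pan–Tompkins-style chain: DC-offset removal, a 4th-order Butterworth
   10–30 Hz bandpass applied forward–backward (the QRS complex
   concentrates its energy in that band; zero-phase filtering avoids
   displacing the peak), a five-point derivative, squaring,
   moving-window integration (150 ms, followed by a 75 ms stabilizing
   average), and an adaptive dual-threshold scan with running
   signal/noise estimates (threshold = noise + 0.25·(signal − noise)),
   a 200 ms refractory period, and refinement of each detection to the
   bandpassed local maximum within ±50 ms.

2. **Beat-pair features.** Each beat is resampled to a 100 Hz grid,
   z-scored, and standardized to length L = 100 by right zero-padding
   (short beats) or tail truncation (long beats). For every pair of
   consecutive beats X₁, X₂ the features are the full linear convolution
   (199 coefficients, the symmetric content) concatenated with the full
   cross-correlation (199 coefficients, the asymmetric content), giving
   the fixed 398-length input. Because beats are z-scored, amplitude
   scale cancels; the R-R interval survives in the length of the nonzero
   body before the zero pad, which is how heart rate enters the features.

3. **Three recurrent classifiers.** An Elman RNN with the power-sigmoid
   activation, a GRU, and an LSTM, each implemented directly from its
   cell equations and trained by analytically derived
   backpropagation-through-time (no autodiff framework). Each wraps the
   cell in a multi-horizon head: the final hidden state of a sliding
   window of W consecutive beat-pair samples is read out as 60
   independent 3-way softmax heads, one per look-ahead second.

4. **NSGA-III fusion.** The three models disagree systematically — the
   RNN favors short horizons, the LSTM long ones — so a per-horizon
   weighted ensemble is searched by NSGA-III under four simultaneous
   objectives: overall accuracy and the per-class recall of each of the
   three classes. The per-class objectives counter class imbalance: a
   solution that sacrifices the minority class cannot dominate.

## The cell equations

The Elman RNN computes

  hₜ = σ_h(W_ih xₜ + W_h hₜ₋₁ + b_h),  yₜ = σ_o(W_ho hₜ + b_o)

with the power-sigmoid activation

  σ(x) = xᵅ for |x| ≥ 1;  σ(x) = (1+e^(−β))(1−e^(−βx)) / ((1−e^(−β))(1+e^(−βx))) for |x| < 1,

α odd ≥ 3, β > 2. Both branches equal ±1 at x = ±1, so σ is continuous,
odd and strictly increasing; the inner branch is the scaled bipolar
sigmoid c·tanh(βx/2) with c = (1+e^(−β))/(1−e^(−β)), and the outer
polynomial branch is expansive, which speeds convergence away from the
origin. α and β default to (3, 3) and can be grid-searched over
α ∈ {3,5,7}, β ∈ {3,4,5} on validation overall accuracy
(`tune_power_sigmoid()`).

The GRU uses an update gate u, reset gate r and candidate state:

  uₜ = σ(W_u[hₜ₋₁, xₜ]), rₜ = σ(W_r[hₜ₋₁, xₜ]),
  ĥₜ = tanh(W_ĥ[rₜ ⊙ hₜ₋₁, xₜ]), hₜ = (1−uₜ) ⊙ hₜ₋₁ + uₜ ⊙ ĥₜ.

The LSTM uses input/forget/output gates i, f, o, candidate C̃ₜ, cell
state Cₜ = fₜ ⊙ Cₜ₋₁ + iₜ ⊙ C̃ₜ and output hₜ = oₜ ⊙ tanh(Cₜ). Two
deliberate choices here:

* **Cell update.** The update is implemented as
  Cₜ = fₜ ⊙ Cₜ₋₁ + iₜ ⊙ C̃ₜ. A formulation that adds the bare forget
  gate instead of the gated previous cell state leaves the forget gate
  with nothing to gate and erases memory every step; the standard gated
  form is the only one in which the three-gate architecture does what
  its names promise.
* **No bias vectors in GRU/LSTM.** The gate equations are implemented
  exactly as written above, without bias terms; the readout layer has a
  bias, which absorbs any constant offset the heads need.

The RNN's output activation σ_o uses the bounded sigmoid branch for all
inputs rather than the two-branch power-sigmoid (or a hard clip of the
logits at ±1). The polynomial branch would amplify large logits without
bound before the softmax, and a hard clip has zero gradient outside
[−1, 1] and stalls training; the bounded branch is smooth, odd, and
monotone everywhere, preserving the intended saturation while remaining
trainable.

## Training

Each classifier is trained by mini-batch gradient descent on the mean
per-head cross-entropy with global-norm gradient clipping at 1.0 (the
clip also guards the expansive power-sigmoid branch). Defaults: hidden
size 16, window W = 8, learning rate 10⁻³, batch 32, 30 epochs; the
scaled-down study configurations in the tests and the acceptance script
use hidden 8, window 4, learning rate 0.05 and 6–8 epochs, which is the
size at which three cells × several folds train in seconds while still
separating the classes cleanly. Features are standardized per column on
the training data (scaling stored in the model): raw convolution
coefficients of length-100 beats have magnitudes of order 10 and would
saturate or blow up the power-sigmoid immediately. Training is
deterministic given the model seed; ties in the per-head argmax break
toward the lowest class id.

Sequence windows are built on the full time-ordered corpus and carried
into cross-validation folds as precomputed matrices, so a fold's samples
keep their true temporal predecessors; windows never cross a record
boundary, and windows near a record start repeat the first sample.

## NSGA-III

Reference directions are the Das–Dennis simplex lattice (p = 6 for 4
objectives → 84 directions; population 92, the next multiple of 4).
Each generation: random-paired SBX crossover (η = 30) and polynomial
mutation (rate 1/genome-length, η = 20), merge of parents and offspring,
fast nondominated sorting, acceptance of whole fronts, and
niche-preserving selection on the split front — objectives translated by
the ideal point, scaled by achievement-scalarizing extreme-point
intercepts (falling back to per-objective maxima when the intercept
system is singular), members associated to the nearest reference ray by
perpendicular distance, and slots filled from the emptiest niches
(minimum-distance member for an empty niche, random member otherwise).
Maximization is handled by negation at the optimizer boundary. An
archive of all nondominated solutions ever evaluated is maintained; the
final model is the archive member with maximal overall accuracy, ties
broken by the largest minimum per-class accuracy.

The genome is the per-horizon weight triple over (RNN, GRU, LSTM) —
3 × 60 nonnegative reals, simplex-normalized per horizon. This encoding
keeps evaluation cheap (base models are trained once per fold and their
validation scores cached) and makes the three one-hot corners reproduce
the stand-alone baselines exactly; those corners are seeded into the
initial population, so by elitism the selected ensemble can never score
below the best stand-alone model on the selection folds. Objectives are
averaged unweighted over folds and horizons; fold/horizon cells where a
class is absent are excluded from that class's mean.

Evaluation protocol: stratified k-fold cross-validation (default k = 10;
stratified on the horizon-1 label), with a `group_by_record` switch that
assigns whole records to folds when within-record leakage is a concern.
The boosting baseline trains B same-architecture models with different
seeds per fold and averages their score arrays weighted by validation
overall accuracy; B = 1 reduces exactly to the stand-alone baseline.

## The synthetic data generator

`generator_config()` emulates a three-class driving study so that every
stage is testable without external recordings:

* **Class dynamics** are a semi-Markov chain: exponential dwell times
  (mean 40 s by default, a realistic scale for stress episodes and
  light-sleep bouts) and a zero-diagonal transition matrix. By default
  the next state is drawn proportionally to the target mix m among the
  other states, P(i→j) = mⱼ/(1−mᵢ); this chain's embedded stationary
  distribution is νᵢ ∝ mᵢ(1−mᵢ) (check: Σᵢ νᵢ P(i→j) ∝
  mⱼ Σ_{i≠j} mᵢ = mⱼ(1−mⱼ) ∝ νⱼ), so scaling the per-class dwell means
  by 1/(1−mᵢ) makes the stationary *time* fraction of class i exactly
  mᵢ. The default mixes, 0.425/0.404/0.170 (stress profile) and
  0.580/0.267/0.153 (drowsiness profile), mirror the class imbalance of
  real three-class driving corpora.
* **Beats** are placed at intervals 60/HR with 3 % multiplicative
  Gaussian jitter. Per-class mean heart rates default to 70/85/100 bpm
  (stress rises with sympathetic activation) and 72/62/55 bpm
  (drowsiness lowers heart rate); per-class R amplitudes scale the
  morphology. These are generator parameters chosen as physiologically
  oriented defaults, not measured facts.
* **Morphology** is a Ricker (second-derivative-of-Gaussian) QRS
  template, 40 ms main lobe, plus small P and T Gaussian bumps, a DC
  offset and white noise. The Ricker is used rather than a
  first-derivative-of-Gaussian because its sharp central maximum defines
  the R time unambiguously (a first derivative is zero at its center),
  and its spectral peak (~19 Hz) sits inside the 10–30 Hz detector band.
* **Predictability by construction.** During the final
  `pre_transition_drift_s` seconds (default 10) of each dwell, heart
  rate and amplitude interpolate linearly toward the next state. Future
  labels are therefore partially recoverable from current beats, which
  is the structure the forecaster assumes; with the drift at 0 and short
  dwells, accuracy collapses toward the majority rate, which the tests
  use as the negative control. What the generator does **not** emulate:
  true 12-lead morphology, arrhythmias, movement artifacts,
  electrode-contact noise, or inter-subject variability. Passing tests
  on this generator show the pipeline recovers structure that is present
  and degrades when it is absent — not that real-world accuracy levels
  are reached.

## Numerical choices

* Bandpass edges at 10 and 30 Hz require fs > 60 Hz; `filtfilt` keeps
  length and phase.
* Beat resampling uses linear interpolation onto the 100 Hz grid;
  z-scoring guards zero variance with ε = 10⁻⁸.
* The cross-correlation lag axis is normalized to −(L−1)…(L−1) stored
  left-to-right (zero lag at the center index), the ordering consistent
  with a 199-length output; `xcorr(x1, x2) = conv(x2, rev(x1))`.
* Softmax per head subtracts the row maximum; probabilities are floored
  at 10⁻¹² inside the log.
* Intercept fallback and uniform-weight fallback (an all-zero horizon
  triple becomes 1/3, 1/3, 1/3) keep degenerate inputs from failing.
* All stochastic steps derive 32-bit sub-seeds from the run seed and a
  fixed tag, and restore the caller's RNG state afterwards.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script studies are deliberately desk-scale:
records of 120–600 s at 250 Hz, two to five records per corpus, horizons
1–10 (1–30 for the decay check), 2–3 folds, hidden size 8, and NSGA-III
at population 24 × 10 generations for the fusion (92 × 100 for the
reference-geometry check on the analytic three-objective sphere). These
sizes keep the full pipeline in the tens of seconds while leaving every
qualitative property — detector quality, class separation, fusion
dominance over the stand-alone models, monotone accuracy decay with
horizon — measurable.

## Known limitations

* The evaluation is synthetic-only by design; adapters read real
  two-column CSV or WFDB format-16 records, but no claim is made about
  accuracy on clinical data.
* The WFDB adapter covers single-channel format 16 only.
* Boosting is interpreted as accuracy-weighted score averaging of
  independently seeded models; other boosting schemes (sample
  re-weighting) are out of scope.
* The genome searches ensemble weights only, not architecture
  hyperparameters.
* Per-beat z-scoring discards absolute amplitude, trading a real
  physiological cue for cross-recording robustness; heart rate remains
  encoded via the zero-pad length.
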