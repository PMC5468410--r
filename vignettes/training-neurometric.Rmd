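---
title: "A machine-learning neurometric for EEG-based training assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A machine-learning neurometric for EEG-based training assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotrain)
```

## The problem

Standard training assessment scores what an operator *does* — tracking error,
reaction times, missed calls — but says nothing about how many cognitive
resources the task still demands. Two trainees can reach identical task
performance while one of them is still working at the edge of capacity. This
package implements a neurometric that complements behavioral scores with an
EEG-derived measure of *cognitive stability*: once a task has become
automatic, the spatial/spectral pattern of workload-related brain activity
stops changing between sessions, so a classifier calibrated on one session
keeps working on the next. Training level is then summarized per pair of
consecutive sessions by a single number in [0, 1] combining mean performance,
performance stability and cognitive stability.

## Pipeline and model

1. **Preprocessing.** Each recording is band-pass filtered 1–30 Hz with
   fifth-order Butterworth high- and low-pass sections, applied
   forward–backward (zero phase) so filter delay cannot smear condition
   labels across epochs. The signal is cut into 2-s epochs slid by 0.125 s
   inside each condition block (a block of duration $T$ yields
   $\lfloor (T-L)/S \rfloor + 1$ epochs; epochs never straddle block
   boundaries). Three artifact criteria flag an epoch if **any** channel
   violates **any** of: absolute amplitude above 100 µV; least-squares linear
   trend steeper than 3 µV/s; sample-to-sample step above 25 µV. The trend
   criterion is computed as an ordinary least-squares slope over the epoch —
   the only reading that yields a single slope per epoch.

2. **Spectral features.** One Hanning taper spanning the full 2-s epoch, one
   FFT, one-sided density scaling: 0.5 Hz bins. Band edges are anchored to
   the individual alpha frequency (IAF), estimated as the dominant rest
   spectrum peak over parieto-occipital channels within 7–13 Hz (the standard
   alpha-peak convention): theta = [IAF−6, IAF−2] Hz, alpha = [IAF−2, IAF+2]
   Hz. The combined span [IAF−6, IAF+2] holds 17 bins at 0.5 Hz resolution —
   the shared IAF−2 edge bin is counted once. Features are (channel, bin)
   powers over 13 frontal and 9 parietal channels, i.e. 22 × 17 = 374
   columns, identified by channel and *offset from the IAF* so feature
   matrices align across sessions. (The canonical feature-domain count quoted
   for this kind of montage, 25 × 17 = 425, presumes 25 channels; the two
   printed channel sets contain 22, and the package follows the channel
   lists rather than padding.) Powers enter the classifier untransformed; a
   `log10_features` switch exists but is off by default, and the linear
   discriminant is affine-invariant per feature, so the PSD scaling
   convention is immaterial.

3. **asSWLDA.** Stepwise regression of the labels coded −1/+1 on the feature
   columns: the candidate with the smallest partial-F p-value enters while
   below α_ENTER = 0.05; after each entry, included features with partial-F
   p above α_REMOVE = 0.1 are removed, least significant first. After every
   completed iteration the overall model F p-value (*pModel*) is recorded —
   in log space, because separable data underflow p to zero in double
   precision. The automatic stop min–max normalizes the realized
   (iteration, log10 pModel) points to the unit square — the two axes are
   not otherwise commensurable — and keeps the iteration closest to the
   origin; equivalently, the elbow where successive differences of the
   normalized curve vanish (an `elbow` method with tolerance 1e−3 on raw,
   unsmoothed differences is provided; `distance` is the default). The
   final discriminant is a least-squares refit on the retained features;
   scores are oriented so that higher means more HARD-like. Ties in
   candidate p-values break toward the lower column index, so the fit is
   fully deterministic. `max_iter` defaults to
   `min(n_features, n_samples/3)` as a saturation guard; the stop, not the
   cap, is the intended terminator.

   Two properties of the stopping rule are worth knowing. First, the pModel
   trace is *not* strictly monotone: an entering feature that adds little
   explained variance can raise the overall p-value through the
   degrees-of-freedom change. Second, with only a handful of candidate
   features the realized curve has few points and the normalized-distance
   elbow gravitates toward mid-curve, occasionally retaining one feature
   fewer than the ground truth; in the intended regime (hundreds of
   candidates, long forward path) it reliably keeps the informative features
   and cuts the chance tail.

4. **Evaluation.** Seeded, shuffled, *stratified* 10-fold cross-validation
   (stratification guarantees both classes in every test fold). Intra
   analysis: calibrate on 9 folds, test on the held-out fold, within one
   session. Inter analysis, for consecutive sessions: for fold *k*, calibrate
   on session *n* minus fold *k* and test on session *n+1*'s fold *k*, and
   vice versa; the fold AUC is the mean of the two directions. AUC is the
   rank statistic (normalized Mann–Whitney U with midranks). Sharing the
   per-session fold partitions between intra and inter runs pairs the ten
   AUCs by fold index, which is what makes the paired t-test well defined.
   The raw **Cognitive Stability Index** of a session pair is the mean of
   the two paired t statistics t(n) = t(Intra(n), Inter(n, n+1)) and
   t(n+1) = t(Intra(n+1), Inter(n, n+1)); signed values are used, so a
   stable pair scatters around zero.

   One caveat is inherited from the 0.125-s epoch shift: overlapping epochs
   leak between shuffled folds and inflate intra-session AUC optimistically.
   For honest cross-session stability assessment, use non-overlapping
   epochs (`shift = epoch_length`), as the package's own stability study
   does; the default parameters reproduce the canonical, optimistic
   protocol.

5. **Behavioral indexes.** The four concurrent-subtask indexes are
   percentages in [0, 100]: TRCK = 100·(1 − mean distance / max distance);
   COMM and SYSM = 100·(w₁·accuracy + w₂·mean(1 − rt/rt_max)) with equal
   weights ½/½ (the only symmetric default; the linear-combination weights
   are configurable); RMAN = 100·mean closeness of the main-tank levels to
   the 2,500 lbs target, 100·(1 − |level − 2500|/2500) averaged over
   samples — a literal "mean fuel level × 100" is dimensionally inconsistent,
   and closeness-to-target matches the task goal while landing on the same
   0–100 scale as the other three. The global performance index is the
   unweighted mean of the defined subtask indexes (an index with no events is
   undefined and excluded with a warning).

6. **Training level.** For a pair of consecutive sessions with global
   performances P(n), P(n+1): mean performance A = ((P(n)+P(n+1))/2)/P_ref,
   performance stability B = 1 − |P(n) − P(n+1)|/100, and cognitive
   stability C = 1 − min(|CSI|, CSI_max)/CSI_max where CSI_max is the
   subject's largest |CSI| across session pairs. P_ref defaults to the
   subject's best observed session performance; this per-maximum
   normalization is what lets a subject who plateaus at, say, 91% reach
   A ≈ 1 — and hence a training level near 1 — which is the intended
   behavior of the metric (normalizing by an absolute 100 caps the metric
   at ~0.94 for such a subject; it remains available via `reference = 100`).
   All three measures live in [0, 1] with 1 = best. They are drawn as
   centroid-to-vertex distances 120° apart and the training level is the
   summed area of the three sub-triangles,
   $\mathrm{Area} = \tfrac12 \sin 120° (AB + AC + CB)$, normalized by its
   maximum $\tfrac32 \sin 120° = 1.299$ (sin 120° is evaluated exactly as
   √3/2). The area is symmetric, homogeneous of degree 2, and monotone in
   each measure.

## The synthetic course

Because the original multi-session recordings are not distributable, the
package ships a generator whose ground truth exercises every stage:

- **EEG.** Per channel, 1/f (β = 1) background noise, independent across
  channels — a standard EEG-like spectrum that keeps PSD estimation honest.
  Band-limited theta (centered IAF−4 Hz) and alpha (centered IAF) rhythms
  ride on the frontal and parietal sets with a fixed, jittered amplitude
  topography; each channel mixes a common and a channel-specific rhythm
  (30% / 70% variance), because scalp band power fluctuates
  semi-independently across sites, and a spatially rank-one rhythm would cap
  single-epoch separability near the single-sample limit r/(1+r) however
  strong the effect. Oscillator phase is stochastic (narrowband-filtered
  noise), so epoch-scale segments are mutually incoherent.
- **Condition effect.** In HARD blocks, channel c's oscillator power is
  multiplied by 1 + (effect − 1)·m_c, where m ∈ [0, 1] is the session's
  *signature pattern*; the channel with m = 1 realizes the configured
  HARD/EASY power ratio exactly (theta ratio > 1 frontally, alpha ratio < 1
  parietally — workload-related alpha suppression).
- **Drift.** The signature pattern, not the rhythms, drifts: m is the
  squared cosine-sine mixture of two orthogonal patterns supported on
  complementary channel subsets, rotated by the session's δ (radians);
  oscillator center frequencies also shift by 0.5·δ Hz. A δ step of ~π/2
  relocates the discriminative channels almost entirely — emulating the
  functional reorganization of practice, where the sites expressing the
  workload effect move while the rhythms persist. δ = 0 between sessions
  means identical signatures, hence full classifier transfer. (An earlier
  design that rotated the oscillator *amplitude* weights turned out to be
  nearly transfer-invariant: a band-power classifier keys on the per-channel
  HARD/EASY ratio, which amplitude rotation preserves.)
- **Behavior.** Session-level global performance follows
  P(s) = P_max − (P_max − P0)·exp(−s/τ) plus truncated-Gaussian noise
  (σ = 2 points, truncated at ±2σ), with defaults P0 = 60, P_max = 91,
  τ = 0.8 sessions — an early-rapid, ~91%-plateau curve. Raw subtask logs
  (cursor distances, event outcomes and reaction times, tank levels) are
  constructed so the scorers reproduce P(s); the correct-event count is the
  rounded expectation, keeping accuracy noise at the event-quantization
  floor.
- Defaults elsewhere: 25 channels (13 frontal + 9 parietal + POz/O1/O2 for
  the rest-alpha estimate), fs = 256 Hz, 6 sessions of four alternating
  EASY/HARD blocks, noise SD 10 µV, oscillator amplitude 12 µV on the
  strongest channel, theta effect 2, alpha effect 0.5. Everything is a
  deterministic function of the configuration seed (bit-identical
  regeneration).

What the generator does **not** emulate: ocular/muscle artifact components
(the rejection criteria are exercised by constructed epochs instead),
volume-conduction correlations between neighboring channels, non-stationary
within-session fatigue. Passing tests therefore demonstrate the machinery is
correct under the stated model, not that effect sizes in real recordings
match.

## The stability study shipped with the tests

The end-to-end property — drift early, stability later, training level
rising toward 1 — is checked on a fixed course: 5 sessions, fs 256 Hz,
4 × 75 s blocks, non-overlapping 2-s epochs (honest folds; see the caveat
above), theta effect 4 and alpha effect 0.3 (a strongly separable task,
within-session AUC ≈ 0.95), drift schedule δ = (0, 0.8, 1.5, 1.5, 1.5) —
signature reorganization across the first two session pairs, none after —
and learning curve (60, 91, τ = 0.6) so the behavioral plateau coincides
with the cognitive one. Twenty seeds keep the run inside a few minutes on
one CPU; the problem sizes were chosen once, as the smallest course in which
the paired-t noise floor (≈ t₉ scale) is well below the drifted-pair t
values.

## Numerical choices and degenerate inputs

- Collinear stepwise candidates are skipped, never entered; a numerically
  perfect fit clamps log10 pModel at −320 instead of −∞.
- Paired t with zero-variance differences: 0 when the mean difference is 0,
  an error otherwise (the statistic would be infinite).
- A rest spectrum with no interior peak above 1.5× the median in-range power
  (e.g. white noise, or a monotone 1/f slope) raises an error asking for a
  manual IAF rather than guessing.
- All raw Cognitive Stability Indexes exactly zero maps every pair to
  C = 1 ("stable from the start"), with a warning.
- Epoch-count arithmetic uses a 1e−9 guard before `floor` so durations that
  are exact multiples of the shift are not lost to floating point.

## Limitations

- The CSI is a signed average of t statistics; its noise floor is set by the
  t distribution (SD ≈ 1 under stability), so the normalized cognitive
  stability of a genuinely stable pair is ≈ 0.85–0.95, not exactly 1, unless
  the drifted-pair reference t is large.
- Overlapped epoching (the default 0.125-s shift) inflates within-session
  cross-validated AUC; conclusions about cross-session transfer should use
  non-overlapping epochs or contiguous-block folds.
- Cohort-level statistics from multi-subject studies (ANOVAs, post-hoc
  tests, behavioral-neurometric correlations) are runnable on simulated
  cohorts but are not reproduced as published values; the original subject
  recordings are unavailable.
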