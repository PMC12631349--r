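---
title: "Methods: synthetic engagement-state EEG and its analysis pipeline"
author: "engageEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic engagement-state EEG and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question and the package's approach

Active control and passive observation of the *same* visual scene place
very different demands on the brain: executive monitoring (frontal-midline
theta), top-down visual regulation (occipito-parietal alpha), sensorimotor
preparation (motor beta, mu desynchronization) and fronto-parietal
coordination all shift with the operator's engagement mode, and road
complexity modulates them further. `engageEEG` re-implements this analysis
as a tested pipeline over a 2 × 2 within-subject design — engagement mode
(manual driving `MD` vs automated replay `AD`) × task complexity (`Easy`
vs `Hard` road segments) — with one deliberate substitution: because
recordings of this kind are not generally shareable, a **synthetic-data
generator with planted, parameterised effects** stands in for the
recorded EEG, so that every downstream stage can be verified against a
known ground truth.

Everything quantitative in this vignette is computed by the package's
test suite (`tests/testthat/`) or by `scripts/acceptance.R`; nothing is
asserted that the code does not measure.

# The generator: what it emulates, and what it does not

A recording is built per subject as

1. **Background**: per-channel 1/f^`noise_exponent` noise (spectral shaping
   of white noise; default exponent 1, sd 10 µV), mixed with six shared
   low-rank latent 1/f sources so channels are spatially correlated —
   without this the baseline noise covariance used by the inverse stage
   would be trivial. White sensor noise (sd 2 µV) is added last.
2. **Session structure**: `laps_per_subject` manual-driving laps followed
   by the same number of replay laps (the fixed session order of the
   emulated protocol), each lap holding `segments_per_lap` contiguous
   segments alternating Easy/Hard ("approximately 10 versus 10 per lap"
   maps to the default of 20 alternating segments). The segment duration
   in seconds is not stated by the protocol description; 6 s is this
   package's choice, exposed in the configuration. Segment onsets become
   the event markers; because segments are contiguous, the pre-onset
   baseline of one segment contains the tail of the previous segment —
   a deliberate, realistic property.
3. **Planted effects**: each effect is a band-limited oscillation
   (narrow-band filtered noise, *not* a sinusoid — so coherence and
   entropy features are non-degenerate) on a channel group, with
   **condition multipliers defined on the band-power scale** (amplitudes
   scaled by the square root). Event-locked effects are present only
   during the segment; *tonic* effects run continuously and are rescaled
   during segments, which is how a mu-rhythm desynchronization
   (a genuine power *drop* relative to the pre-onset baseline) is
   planted.
4. **Planted couplings**: two channel groups share a band-limited common
   source mixed with private band-limited noise. With shared-power
   fraction $a^2$ per channel the analytic magnitude-squared coherence is
   $(a^2)^2$, so the generator uses $a^2 = \sqrt{c}$ to target coherence
   $c$. The recovery tests confirm monotone recovery across targets
   $\{0, 0.3, 0.6, 0.9\}$ (the realized channel-level values are diluted
   by the in-band background, as expected).

The default effect table plants the study's reported directions: frontal
theta MD > AD (strongest under MD-Hard), occipito-parietal alpha MD > AD,
motor beta raised under MD-Hard, tonic mu suppressed under MD-Easy
(power multiplier 0.4, i.e. roughly −50% before background dilution), and
fronto-parietal theta/beta coherence MD > AD.

**Between-subject heterogeneity.** The emulated study reports strong
inter-individual variability of the *mode* signature (between-subject
coefficient of variation above 17%; cross-subject decoding of mode much
weaker than within-subject decoding) while *complexity* signatures
generalized comparatively well. The generator therefore decomposes each
effect's log-multipliers into a mode component and a difficulty
component and jitters them per subject with independent log-normal
factors — sd 0.6 for the mode component, 0.2 for the difficulty
component, plus an overall amplitude jitter of sd 0.2. These values were
fixed once, from that qualitative description.

**What the generator does not emulate**: eye/muscle artifacts beyond the
optional stereotyped injector (blinks, EMG bursts); volume conduction of
cortical sources through a head model (scalp effects are planted directly
on channels; the inverse stage has its own toy forward model); any
behavioural or vestibular coupling. Passing tests therefore demonstrate
the *correctness of the analysis machinery* and the recoverability of
planted statistical structure — not performance on real recordings.

# Preprocessing

Default chain, in order: earlobe re-referencing (mean of A1/A2,
references dropped) → 2–36 Hz band-pass → 50/100 Hz notches → epoching
−0.4…1.6 s around segment onsets → baseline correction over −0.2…0 s.
The band-pass is a Hamming windowed-sinc FIR whose order follows from the
lower transition width `min(lo, 0.25·lo + 2)` Hz (≈ 825 taps at 500 Hz);
it is applied by FFT convolution with exact group-delay compensation
(linear phase, zero net shift) and reflection padding, so window-mean
statistics near epoch edges stay unbiased. Notches are FIR band-stops
(±2.5 Hz stop edges, 1.5 Hz transitions). The notch frequencies are
redundant after the 36 Hz low-pass but are kept as part of the documented
feature-extraction chain. Epochs crossing recording edges are dropped and
counted in the epoch log. The common-average reference is applied (to the
epoched data) before the inverse stage, which always receives
average-referenced input.

The z-score normalizer (`fitChannelNorm`/`applyChannelNorm`) deliberately
separates fitting from application; only the classification module's fold
plans decide what it may be fitted on.

# The toy inverse

The forward model is a quasi-dipolar leadfield on a spherical toy
geometry (sources on an inner Fibonacci sheet, radius 0.75; sensors on an
outer shell, radius 1), with gain columns in orientation triplets
(two tangents, then the radial normal). Six contiguous azimuthal sectors
are labelled Motor, mPFC, ACC, Visual, PPC, DLPFC — the labels organize
the analysis; **no anatomical fidelity is claimed**.

The inverse kernel is $K = R G^\top (G R G^\top + \lambda^2 C)^{-1}$ with

- $\lambda^2 = 1/\mathrm{SNR}^2$ (SNR 3 → $\lambda^2 = 0.111$, asserted
  to three decimals in the acceptance tests),
- per-source depth weights $w_i = \lVert G_i \rVert_F^{-2\,\mathrm{depth}}$
  on each orientation triplet (depth 0.8),
- transverse orientation variance scaled by $\mathrm{loose}^2$
  (loose 0.2),
- $R$ rescaled so that $\mathrm{trace}(G R G^\top) = \mathrm{trace}(C)$ —
  whitening is implicit in the $\lambda^2 C$ term rather than applied as
  a separate transform; at this scale the two formulations give the same
  dSPM ratios, and the rescaling keeps $\lambda^2$ on its conventional
  scale.

dSPM divides each source's normal-component estimate by
$\sqrt{\sum_{\text{orientations}} \mathrm{diag}(K C K^\top)}$, giving
noise-normalized, dimensionless values: noise-only epochs produce mean
absolute dSPM of order 1, and a planted source at 10× noise localizes to
the true toy source or its nearest neighbours in 100/100 seeds. The
normal component is extracted *after* kernel application, matching the
loose-orientation formulation; for `loose = 1, depth = 0` the kernel
provably equals the ridge-regression solution (tested against a directly
computed inverse on a 5 × 4 instance).

# Spectral metrics and a measured estimator choice

Band power is the mean squared amplitude of the band-passed signal over
the 0.1–0.8 s analysis window. On 2-s epochs the FIR order is capped at a
third of the signal length (transition ≈ 5 Hz at 250 Hz), which is the
price of time-domain filtering on short epochs; the band partition of
2–36 Hz still sums to broadband power within 10%.

**ERD/ERS aggregation.** The defining formula
$(P_{\text{active}} - P_{\text{baseline}})/P_{\text{baseline}} \times 100$
leaves open whether epoch-level ratios are averaged, or powers are
averaged first. With a 0.2 s baseline the per-epoch baseline estimate has
roughly $2BT \approx 2$ effective degrees of freedom, so the per-epoch
ratio is severely upward-biased: on controlled epochs with a planted
−50% step the per-epoch average measured **+90%**, while the
ratio-of-averaged-powers measured the correct sign and magnitude. The
pipeline therefore aggregates ERD/ERS as the ratio of condition-averaged
powers (`erdErsAveraged`); `erdErs` keeps the single-series formula.
Residual dilution by the in-band 1/f background and by filter smearing at
epoch scale leaves the planted mu ERD at about −35 to −45% for a planted
−60% (multiplier 0.4 against a previous-segment baseline near 0.8).

Welch spectra use Hann windows, mean detrending and 50% overlap with the
segment count as the controlling parameter; all auto-/cross-spectra and
the coherence match an independent direct windowed-DFT oracle to 1e-10.
Coherence of $K$ averaged segments is upward-biased by roughly $1/K$
under independence, which is why a minimum segment count is enforced.
Correlation connectivity is computed on broadband ROI time courses;
coherence is band-resolved — mirroring the distinction between linear
coupling and frequency-specific synchronization.

# Wavelet features

Each channel of each epoch is decomposed with a 5-level Daubechies-4
(8-tap) DWT; the five kept sub-bands A5, D5, D4, D3, D2 cover 0–125 Hz at
500 Hz (D1, above the filtered content, is discarded but still counted in
the energy balance). The transform is **periodized** after zero-padding
to the next multiple of $2^5$: unlike symmetric extension, the periodized
filter bank is exactly orthogonal, so sub-band energies satisfy Parseval
to 1e-8 — a property the test suite asserts — and the implementation is
phase-exact against an independently computed PyWavelets
(`mode = "periodization"`) reference vector frozen in the tests. Entropy
uses natural logarithms with $0 \log 0 = 0$; a uniform coefficient vector
gives $\log n$, a point mass 0.

Per epoch: 29 channels × 5 sub-bands × 3 statistics (mean amplitude,
energy, entropy) + 11 electrode pairs × 5 sub-bands of coefficient
Pearson correlations = 490 named features. The 11-pair default
(Fz–Pz, F3–P3, F4–P4, F3–C3, F4–C4, C3–P3, C4–P4, F3–F4, C3–C4, P3–P4,
O1–O2) is a documented, replaceable choice consistent with the pairs the
emulated study names as discriminative. Feature extraction is strictly
per-epoch, so the table is fold-safe by construction.

# Leakage-safe validation

All dataset-statistics transformations — class balancing (seeded
down-sampling), per-feature z-scoring, and the two-stage selection
(random-forest impurity ranking to `k1 = 200`, ANOVA-F refinement to
`k2 = 100`; counts are configurable, the emulated study states none) —
are fitted inside training folds only. `runCV` asserts per fold that no
test group appears in training, that no training epoch lies within the
purge gap (default: one segment each side, the protocol says "temporally
adjacent" without a number) of any held-out segment, and that the
normalizer statistics equal a train-only recomputation.

**Fold grouping.** Both segment- and lap-level grouping are offered; the
default is segment-level with the purge gap. The reason is measured, not
aesthetic: with two laps per mode, holding out a whole lap leaves the
held-out subject's remaining training epochs imbalanced toward the other
mode, and the forest exploits subject-identity features (spatial
covariance of the background) to map that subject to its training-set
majority mode — pushing *null-data* accuracy to 8%, far **below**
chance. That is a small-scale confound rather than leakage; segment-level
grouping with purging removes it and restores null accuracy to the exact
binomial chance band, where the acceptance tests require it to be.

LOSO evaluates four binary tasks (mode; difficulty pooled; difficulty
within MD; difficulty within AD) with the same nested pipeline, reporting
per-subject accuracies, a one-sample t against 0.5 and Cohen's d. The
inter-individual-variability finding is asserted on the matched task:
within-subject grouped-CV accuracy on the binary mode labels
(≈ 0.85–0.92 at test scale) strictly exceeds LOSO mode accuracy
(≈ 0.58–0.79). The four-class CV accuracy is asserted above chance
separately — at desk scale it is deflated by task difficulty, so
comparing it directly against a binary LOSO accuracy would conflate task
hardness with subject generalization. Cross-mode transfer (train
Easy-vs-Hard on MD, test on AD) succeeds when the difficulty effect is
planted identically in both modes and stays at chance when it is planted
MD-specifically.

# Statistics

One-sample and paired t-tests use the closed form (verified against
`t.test` to 1e-12); one-tailed p-values require an explicit predicted
direction, everything else is two-tailed. Benjamini–Hochberg adjustment
is applied within four test families (whole-brain maps, ROI activation,
frequency modulation, connectivity); the implementation is checked
against a brute-force step-up on all input sizes up to 10. Bootstrap
confidence intervals are percentile-based (5000 iterations by default;
percentile rather than BCa for determinism), with the two-sided bootstrap
p defined as $2\min(P(\hat\theta^* \le 0), P(\hat\theta^* \ge 0))$.
Fisher's combination uses the $\chi^2_{2k}$ upper tail; note that two
p-values of 0.5 combine to 0.597, not 0.5 (the corresponding statistic is
below the $\chi^2_4$ median) — the tests assert the value computed by a
numeric-integration oracle. Subregional consistency uses directional
agreement (threshold 80%), mean pairwise correlation (threshold 0.5) and
a one-way ANOVA read as homogeneity when p > 0.05.

# Problem sizes and numerical choices

The study-condition defaults (11 subjects, 500 Hz, 5 laps per mode, 20 ×
6 s segments) are what `simConfig()` produces. The test suite and the
acceptance script run reduced configurations chosen as the package's own
verification scale — typically 1–3 subjects, 250 Hz, 2 s segments, 20
segments per lap (240 epochs for three subjects), 100 seeds for the
localization experiment, 500 micro-replicates for the null type-I
calibration (measured rejection rate 0.06 at nominal 0.05), and 200-tree
forests. The planted-ratio recovery experiment uses a theta amplitude
(12 µV) that dominates the in-band background (~8 µV² against 144 µV²),
since the ratio of *total* band powers otherwise reflects the
background mixture rather than the planted ratio; the recovered ratio is
within 3% of the planted factor 2.

Other fixed numerical choices: variance floors of 1e-8 in all z-scoring;
covariance shrinkage 0.1 toward the scaled identity (enforced when the
baseline covariance is rank-deficient, as it always is after common-
average referencing); Cholesky solves with an explicit conditioning error
for singular systems; seeded substreams derived from one master seed via
an integer hash (`childSeed`), so every stage is reproducible and
bit-identical under a fixed configuration.

# Known limitations

- The toy leadfield supports method verification (localization,
  linearity, regularization behaviour), not anatomical claims.
- Planted scalp effects bypass volume conduction; channel-level coherence
  targets are diluted by the background, so coupling recovery is asserted
  as monotone rather than exact.
- Per-epoch ERD at 2-s epoch scale remains diluted relative to the
  planted modulation even with ratio-of-means aggregation.
- The classifier's absolute accuracies at desk scale are far below the
  headline numbers of the emulated study (whose recordings are
  unavailable); all classifier-level claims are therefore directional or
  calibration claims, by design.
- ICA-based artifact removal is intentionally out of scope; the pipeline
  accepts externally cleaned data, and the artifact injector exists to
  support robustness experiments, not to model real ocular dynamics.
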