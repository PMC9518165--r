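---
title: "Methods: cepstral laughter analysis for Parkinson's disease screening"
author: "laughcep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cepstral laughter analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`laughcep` analyses individual laugh bouts as candidate biomarkers of the
hypokinetic dysarthria of Parkinson's disease. The premise is that laughter
shares the speech motor apparatus while being less voluntarily shaped, so
the dysarthric signature — reduced pitch excursion, raised cycle-to-cycle
perturbation (jitter, shimmer), breathiness, imprecise articulation —
survives in a short, stereotyped vocalisation. The analysis treats each
laugh as a bag of quasi-stationary 25 ms frames, summarises the spectral
envelope of each frame by 13 cepstral coefficients under an auditory
frequency warp, adds first- and second-order temporal differences, and
pools each coefficient track into four moments. One laugh therefore becomes
a 156-component vector (3 streams × 4 moments × 13 coefficients), and
screening reduces to binary classification of such vectors under
subject-wise cross-validation.

The key modelling assumptions, and where they bite:

* *Frame stationarity.* Laugh acoustics are treated as static within 25 ms.
  Voiced "ha" bursts satisfy this about as well as vowels do; onset/offset
  transients violate it mildly and simply contribute to the moment spread.
* *Bag-of-frames pooling.* Moments discard the ordering of frames beyond
  what Δ and ΔΔ capture locally. Global temporal structure (burst rhythm,
  bout-level prosody) is deliberately not a feature.
* *Gain invariance.* The n = 0 cepstral term — a pure log-energy sum — is
  excluded, so recording level is not a feature. This matters for field
  recordings made at unknown microphone gain.

## Front-end parameters

| parameter | default | units | rationale |
|---|---|---|---|
| sample rate | 16000 | Hz | standard speech-recognition rate; sources are resampled with an anti-aliased polyphase filter |
| window | 25 | ms | quasi-stationarity horizon for laugh signals (< 30 ms) |
| overlap | 10 | ms | the stated protocol gives *overlap*, not hop; hop = window − overlap = 15 ms. Both readings exist in the literature; the literal reading is the default and both are configurable |
| pre-emphasis k | 0.97 | — | midpoint of the conventional 0.95–0.98 range; `y(0) = x(0)` (zero pre-history) |
| DFT size | 512 | samples | inferred from the published centre-frequency table, whose entries are multiples of 16000/512 = 31.25 Hz |
| filters | 26 | — | the customary 20–40 range; 26 is the published design |
| coefficients | 13 | — | the standard truncation; higher orders are largely redundant |

## Filter banks

Centres are placed equally spaced on the warped scale (Mel for MFCC and
HFCC, Bark for BFCC) between 0 Hz and Nyquist, unwarped, and snapped to the
nearest DFT bin, exact midpoints going to the lower bin. Triangles span
adjacent centres (outer edges at the band limits) with unit peak. For the
HFCC bank the triangle half-width is instead `E·ERB(fc)/2` with `E = 1`
(no widening factor is published) and the Moore–Glasberg ERB polynomial
evaluated with the centre frequency in kHz — evaluated in Hz the quadratic
term is absurd, so the canonical kHz convention is adopted.

Three numerical caveats discovered while validating against the published
26-filter centre table, all handled explicitly:

1. *Mel, filter 9.* The constructive rule reproduces 25 of the 26
   published Mel centres exactly. Filter 9 unwarps to 921.46 Hz, which is
   below the 921.875 Hz midpoint and therefore snaps to 906.25 Hz, while
   the published table prints 937.50 Hz. No top-of-scale choice can
   satisfy filters 9 and 20 simultaneously (the feasible interval for the
   Mel-scale top is empty), so the published entry is not reachable by
   this construction. The package keeps the constructive rule for the Mel
   bank and documents the one-bin disagreement; the packaged reference
   table stores the printed value verbatim.
2. *HFCC and Bark centres.* The published HFCC/BFCC columns are not
   reproduced by equal spacing plus snapping (deviations up to several
   bins), and no derivation is published. The packaged reference table is
   therefore normative for those two banks at the default geometry; the
   constructive rule remains available (`centers = "constructive"`) for
   non-default geometries.
3. *Off-grid centre.* One published HFCC centre (filter 24, 5537.50 Hz)
   does not lie on the 31.25 Hz bin grid at all; its triangle peaks
   between bins, with a maximum bin weight of ≈ 0.98.

The Bark map is implemented as `13·atan(0.00076·f) + 3.5·atan((f/7500)²)`
(the printed expression is typographically ambiguous about a factor of
1000; the canonical form is used) and inverted numerically by bisection.

## Cepstra, dynamics, pooling

Band energies are floored at 1e-10 before `log10` so silent frames remain
finite. Coefficients are `c_n = Σ_m log10 s(m)·cos(πn(m−0.5)/M)`,
`n = 1..13`. Δ is the central difference `(c(t+1) − c(t−1))/2` with edge
replication (the difference is undefined at the track ends; replication
keeps Δ = 0 for constant tracks and halves the slope at the edges), and
ΔΔ is Δ applied twice.

Pooling conventions: SD uses the n−1 denominator; "standard deviation of
the mean" is read as the SD of the coefficient across frames, not the
standard error — the SEM would shrink with laugh duration and confound
bout length with pathology. Skewness is `m3/m2^1.5` and kurtosis is
non-excess `m4/m2²` (normal → 3); zero-variance columns get skew = kurt =
0 by convention. The protocol text mentions both 156- and 176-component
vectors; 13 × 4 × 3 = 156 is the arithmetic-consistent count and is what
the package produces.

## Synthetic data

Two generators make the analysis testable without the original recordings.

*Feature-space MVN cohorts.* Per class × sex group, the generator fits the
per-component sample mean and variance of the group's laugh vectors and
draws new vectors from the diagonal-covariance normal (the published
augmentation builds the covariance "from the variance of each feature";
a full-covariance option exists behind a flag but is off by default).
Per-class pooling instead of class × sex is available, since the original
grouping is not stated. Generated vectors have no subject; for
cross-validation each generated laugh is its own grouping unit. Using the
source group as the unit would leave only four groups — fewer than the
folds — so that reading is documented but not implemented as the default.

*Waveform simulator.* A laugh bout is 3–6 voiced bursts (glottal half-sine
pulse trains with per-cycle jitter and shimmer, a falling intra-burst pitch
contour, three-formant /a/-like filtering, sinusoidal burst envelopes)
separated by aspiration gaps, plus a breath-noise floor. The healthy →
PD-like axis interpolates five parameters: F0 excursion 0.30 → 0.10,
jitter 0.012 → 0.045, shimmer 0.06 → 0.18, breath noise −28 → −13 dB,
formant-bandwidth scale 1.0 → 2.4. Subjects carry log-normal multipliers
on these axes plus a sex-typed base F0 and a tempo factor, drawn once per
subject, so laughs within a subject correlate and the class distributions
overlap. The magnitudes were fixed by a single calibration so that the
default `effectSize = 0.6` puts subject-wise cross-validated accuracy in
the mid-80s — the regime reported for real laughs — and were not revisited;
this is a calibration choice, not a claim of acoustic fidelity. What the
simulator does **not** emulate: perceptual realism, room acoustics,
recording-channel variation, disease staging, medication state, or
laughter's social/contextual variability. Passing tests on synthetic data
therefore demonstrate that the pipeline detects dysarthria-like spectral
signatures under the stated generative model, not clinical performance.

All randomness flows through explicit integer seeds (subject and clip
seeds are derived deterministically from the master seed); no function
touches the session RNG state.

## Classification and evaluation

* Folds partition grouping units (subjects), shuffled by seed and dealt
  round-robin; records of one unit never straddle folds.
* Features are z-scored by training-fold statistics for kNN and SVM
  (distance- and margin-based learners are scale-sensitive); forests are
  scale-equivariant and are left unstandardized. Standardising on the full
  set would leak validation statistics into training and is deliberately
  not offered.
* Scores: forest tree-vote fraction for the PD class, kNN neighbour-class
  fraction, SVM decision value oriented toward PD. kNN breaks distance
  ties by the smaller training-record index and even-k vote ties toward
  PD, favouring sensitivity — the clinically preferred error direction for
  a screening tool.
* Metrics are computed on the pooled out-of-fold predictions (not averaged
  per fold; the protocol does not say which, and pooling gives the
  confusion matrix a single consistent n). Confusion rates follow the
  per-class convention (TPR + FNR = 1, TNR + FPR = 1), which is the
  reading under which the published summary confusion reproduces its
  printed Matthews correlation. The ROC treats tied scores as one
  threshold step, making the trapezoidal AUC equal the Mann–Whitney
  concordance statistic.
* The random-forest backend is `ranger` (100 unpruned trees, √p features
  per split, seeded); `randomForest` serves as an independent cross-check
  in the test suite, and `pROC` as the AUC oracle.

## Problem sizes in the test suite

The automated checks run the null calibration at 1,000 MVN laughs per
class (10-fold), the separation dose–response at 2,000 per class (5-fold,
five separation points), cohort-model recovery at 10,000 draws, and the
waveform experiments (pitch ablation, duplicate-record leakage) at 120–144
synthesized laughs — sizes chosen so the full suite completes in a few
minutes on one core while keeping the binomial error bars well inside the
asserted margins. The orchestrated `runStudy()` default is likewise
desk-scale (250 MVN laughs per group); all sizes scale up by configuration
only.

## Known limitations

* The published derivation of the HFCC/Bark centre tables is not
  reproducible; those banks are table-driven at the default geometry.
* The pre-emphasis "cut-off frequency" quoted alongside the filter (1840
  Hz) follows from no stated criterion and no operation is derived from it.
* Pitch statistics are available only as an ablation input: on matched-F0
  synthetic cohorts they classify at chance, mirroring the published
  negative finding, and they are not part of the default feature set.
* Synthetic-cohort results quantify pipeline behaviour, not clinical
  accuracy; the headline accuracies reported for the original 120-laugh
  cohort depend on recordings that are not deposited and are out of scope.
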