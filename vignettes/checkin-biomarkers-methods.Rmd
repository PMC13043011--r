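---
title: "Multimodal digital biomarkers from conversational check-ins: methods and design"
author: "CheckinBiomarkers authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal digital biomarkers from conversational check-ins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Short conversational "check-in" sessions — a few prompts from a voice agent,
a few spoken responses from a participant, a webcam pointed at their face —
carry measurable traces of depression, fatigue and cognitive state. This
package implements a complete, testable version of that measurement
pipeline:

1. a **session data model** (facial landmark/blendshape streams, mono audio
   per response, timed transcripts, clinical scores) with strict validity
   checking and a plain-text bundle format;
2. a **66-feature library** — 13 visual, 28 acoustic, 25 linguistic — frozen
   in a registry so downstream counts are meaningful;
3. the **baseline correlation stage**: earliest session per participant,
   single-pass 2-SD outlier removal per feature, Pearson r with two-sided
   p per feature × clinical measure (PHQ-9; CFS total and its
   physical/affective/cognitive subscales; TMT parts A, B and total);
4. a **within-person composite risk score** for longitudinal monitoring;
5. a **synthetic cohort generator** with sign-controlled couplings between
   latent symptom severities and the parameters that generate the raw
   streams, so every stage is testable without access to any operational
   data.

Real cohort data of this kind are not publicly released; the synthetic
generator is therefore first-class, tested code, not a fixture.

## Temporal normalization

Webcam landmark streams arrive at irregular 30–60 fps. `interpolateStream()`
re-grids them to a uniform 30 fps: output timestamps are
`t_k = t_0 + k/30` up to the last raw timestamp, each value a linear
interpolation between the two bracketing raw frames. No extrapolation is
performed — a linear interpolant is undefined outside the observed range,
so the grid ends at or before the last raw frame. Audio is resampled to a
common 22,050 Hz analysis rate (`resampleAudio()`, polyphase).

## Feature definitions and the registry expansion

The visual features follow the implemented-feature names of the evidence
tables for depression, fatigue and cognition: gaze distributions, blink
and yawn event statistics, eyelid droop, facial-affect variability and
movement during speech. Two of them deserve comment:

* **`affect_measure`** is defined here as the mean temporal standard
  deviation over the expression blendshapes (everything except the
  eye-look and eye-blink groups, whose dynamics reflect gaze rather than
  affect). The production definition of this quantity is proprietary; ours
  is a declared substitute, not a reconstruction.
* **`movement_speech_measure`** is mean landmark displacement per second in
  the x–y image plane restricted to participant speech segments. Depth (z)
  is excluded because relative depth from a monocular landmarker has a
  different, less stable scale.

The acoustic and linguistic registries realize every named feature stem
(pitch, volume, ealvi, jitter, shimmer, timbre, formant, pauses; speech
rate, latency, transcript length, complexity, sentiment, hesitations)
expanded to the printed modality counts of 28 and 25. The exact
decomposition used in production is not published, so the expansion here is
frozen — the counts 13/28/25 are structural constants of the package and
are asserted in the acceptance suite. `ealvi` is never expanded in the
source literature; the definition adopted here (fraction of speech frames
with RMS below half the median speech-frame RMS) is a placeholder and is
documented as such.

## Signal processing choices

Analysis frames are 2,048 samples with a 512-sample hop at 22,050 Hz.
Frames are *speech* when their RMS exceeds −40 dB relative to the
response's peak frame RMS, and *voiced* when additionally the normalized
autocorrelation peak in the 75–500 Hz lag range exceeds 0.45. f0 uses
parabolic interpolation of the autocorrelation peak, which is what brings
pure-tone recovery inside ±1 Hz.

Jitter and shimmer are computed from glottal-cycle marks found by
period-guided peak picking (seeded by the median voiced f0, refined
parabolically) over the longest contiguous voiced stretch; periods more
than 30% away from the median period are discarded as octave/transient
errors. Formants come from order-12 Burg LPC at a dedicated 11,025 Hz
formant analysis rate — at the full rate an order-12 model must also spend
poles on the 5.5–11 kHz band and biases F1 upward; halving the rate is the
standard remedy and brings programmed 500/1,500/2,500 Hz resonances back
within a few percent.

Volume statistics (`vol_mean/std/range/slope`, `ealvi`) are computed over
speech frames only; including silence would let pause structure dominate
the envelope statistics. `vol_slope` is the least-squares slope of frame
RMS against time, in RMS units per second.

Undefined features (no blinks for `blink_len`, silent track for volume, no
voiced frames for pitch) are reported as `NA`, never silently zero, and
are excluded pairwise downstream.

## The synthetic cohort

Each participant carries three correlated standard-normal latent
severities (depression–fatigue correlation 0.5, both weakly coupled to
cognition at 0.2 — the constructs overlap in practice), with AR(1)
session-to-session wander (ρ = 0.7, innovation scale 0.3) so longitudinal
monitoring is exercisable. Session-level generator parameters are
`baseline + effects × latents + noise` in standardized units, clipped to
physically plausible ranges (f0 in 90–350 Hz, rates nonnegative,
proportions in [0, 1]). Default effect signs mirror the reported
directions: depression and fatigue raise mean pitch and volume slope and
lower volume variability and linguistic complexity; fatigue additionally
raises F2 and eyelid droop; cognitive impairment raises shimmer. Default
magnitudes are calibration choices — the source study's n = 8 baseline
correlations cannot identify effect sizes.

Full synthesis produces standard session bundles: source-filter audio
(impulse-train glottal source with per-cycle jitter/shimmer perturbations,
three formant resonators, programmed RMS envelope, inserted pauses;
impulses are split across adjacent samples so programmed jitter is not
floored by sample quantization), an irregular 30–60 fps blendshape stream
with Poisson blink/yawn events, and transcripts assembled from word banks
to hit programmed filler rate, sentence length, long-word proportion and
sentiment. Clinical scores are monotone maps of the latents with noise,
clipped to instrument ranges (PHQ-9 0–27; CFS subscales 0–28/0–16/0–16,
summed for the total; TMT times log-normal around 30 s and 70 s).

**The fast path.** `simulateFeatureTable()` draws the same latents and
parameters but maps parameters directly to expected feature values plus
measurement noise, skipping raw-stream synthesis and re-analysis. The
statistical calibration and power checks run on this path: 100 replicates
of a 40-participant cohort through full audio/landmark synthesis and
extraction would take hours, while the property they test — type-I error
and sign recovery of the correlation stage — lives entirely above the
extraction layer. The extraction round trip itself (parameters → raw
session → extracted features) is validated separately at small n by the
signal-processing tests. What the fast path does *not* emulate: extraction
error correlated across features within a session, nonlinear
parameter-to-feature distortion, and missingness patterns of degenerate
audio. Passing calibration tests therefore speak to the statistical stage,
not to robustness of the DSP on real-world recordings.

## Statistical stage

The correlation analysis intentionally matches a small-cohort exploratory
design: earliest session per participant (ties broken to the lowest
session id), single-pass removal of values more than 2 sample SDs from the
mean (computed once; selection on the feature alone does not bias the
Pearson null since the score remains independent of the feature under H0),
pairwise-complete observations with `n_used` reported per pair, and **no
multiple-testing correction by default** — matching the exploratory
uncorrected design; a Benjamini–Hochberg flag exists but is off.
TMT parts A and B are correlated separately and as a summed total.

The composite risk score z-scores each significant feature within a
participant's own sessions (sample SD; constant series → all zeros), aligns
signs with the baseline correlation direction, and sums — an unweighted sum,
per the construct's definition of "summing deviations from the mean";
weighting by |r| would pretend the n = 8-scale correlations estimate effect
sizes. Feature sets per measure use the *total* score (PHQ-9, CFS total),
not subscales. Missing values contribute 0 (flagged) so series stay
contiguous; participants need at least 2 sessions; a single-feature
composite is emitted with a warning.

## Problem sizes in the test and acceptance suites

The suites are sized for a single CPU: oracle-equivalence checks use 100
randomized instances per operation at n = 5–40; signal ground truth uses
2–4 s synthetic utterances; calibration and sign-recovery use 100
replicates of 40-participant cohorts on the fast path; full-synthesis
round trips use 2–4 sessions with shortened utterances. These sizes are
the package's choices for a reproducible desk-scale validation; all of
them are set in code and scale up by changing one argument.

## Known limitations

* The acoustic/linguistic registry decomposition and the `affect_measure`,
  `movement_speech_measure` and `ealvi` definitions are declared
  substitutes for unpublished production definitions; values are
  internally consistent but not comparable to other implementations.
* The sentiment/emotion lexicons are small, deterministic lists shipped
  with the package — adequate for testing couplings, not for production
  sentiment analysis.
* Synthetic speech is an impulse-train vowel, not natural speech; formant
  and perturbation extraction accuracy on real voices will be worse.
* The correlation stage is deliberately simple (no mixed-effects or
  longitudinal modeling); it reproduces an exploratory baseline design,
  not a recommended inferential procedure at scale.
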