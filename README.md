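# CheckinBiomarkers

Digital biomarkers of depression, fatigue and cognition from short
conversational "check-in" sessions — a few spoken prompts from a voice
agent, a few spoken responses from a participant, and a webcam landmark
stream of their face. The package is aimed at digital-phenotyping
researchers who need a complete, testable version of this measurement
pipeline: from raw session bundles to a feature table, baseline
correlations against clinical instruments, and within-person risk
trajectories.

## What it computes

**A 66-feature library** per session, frozen in a registry of 13 visual,
28 acoustic and 25 text features:

* *Visual* (from 478-point landmark frames with 52 blendshape activations,
  interpolated to 30 fps): facial-affect variability, mouth curvature,
  brow droop, gaze distributions (including downward gaze), movement
  during speech, eyelid droop, blink/yawn rates and durations, saccade
  rate.
* *Acoustic* (per response, resampled to 22,050 Hz, averaged over the
  session): f0 statistics and slope, RMS volume statistics and slope, a
  low-volume index, jitter (local, RAP), shimmer (local, dB), HNR,
  spectral centroid/bandwidth/flatness/rolloff, LPC formants F1–F3 with
  dispersions and F2/F1, pause rate and length, voiced fraction.
* *Text* (from timed transcripts): speech rate, response latency,
  transcript length, ARI / Flesch–Kincaid / Gunning-Fog readability,
  lexicon sentiment and emotion-keyword proportions, hesitations,
  transcript pauses, and lexical descriptors.

**The statistical stage** mirrors a small-cohort exploratory design: the
earliest session per participant is the baseline sample; per feature,
values more than 2 sample SDs from the mean are removed (single pass);
each feature is Pearson-correlated with PHQ-9, CFS total and its
physical/affective/cognitive subscales, and TMT part A / part B / total
(two-sided p from the t transform, uncorrected by default, optional
Benjamini–Hochberg). A modality-by-measure significance count table is
produced against the 13/28/25 denominators.

**The composite risk score** z-scores each significant feature within a
participant's own sessions, aligns the sign with the feature's baseline
correlation, and sums:

    risk(session) = Σ_f sign(r_f) · z_f(session)

**A synthetic cohort generator** stands in for operational data (which is
not publicly released): participants carry correlated latent severities
(depression, fatigue, cognition) with AR(1) session wander; an effect
matrix with controlled signs couples latents to generator parameters; full
synthesis produces standard session bundles (source-filter audio with
programmed jitter/shimmer/formants, irregular 30–60 fps blendshape
streams with Poisson blink/yawn events, word-bank transcripts), and a
fast parameter-level path makes replicate studies cheap.

## Worked example

```r
library(CheckinBiomarkers)

cfg  <- cohortConfig(nParticipants = 8, sessionsPerParticipant = 4, seed = 11)
tab  <- simulateFeatureTable(cfg)              # cohort SummarizedExperiment
corr <- correlateAll(selectBaseline(tab$se))   # baseline Pearson stage

subset(corr$results, significant & measure == "cfs_total")
#>                 feature   measure n_used      r       p
#> 154           vol_range cfs_total      8 -0.873 0.00465
#> 170               ealvi cfs_total      8 -0.832 0.01032
#> 386 gunning_fog_complexity cfs_total   8 -0.758 0.02942
#> 442     hesitation_prop cfs_total      8  0.901 0.00226
#> 522      long_word_prop cfs_total      8 -0.773 0.02462
#> ...
```

With the default effect matrix, fatigue lowers volume variability and
linguistic complexity, so `vol_range` and the readability indices come out
negatively correlated with the CFS total at the n = 8 baseline — the
planted directions, recovered from the synthetic cohort. The risk stage
then turns all sessions into within-person trajectories:

```r
risk <- compositeRisk(tab$se, corr$results, "fatigue")
head(risk[, c("participant_id", "session_id", "risk_score")], 4)
#>   participant_id session_id risk_score
#> 1            P01    P01_S01      6.241
#> 2            P01    P01_S02      0.987
#> 3            P01    P01_S03     -3.790
#> 4            P01    P01_S04     -3.438
```

Positive scores are sessions whose significant features deviate from the
participant's own baseline *in the direction associated with worse
fatigue*; each participant's scores are zero-mean by construction.

Full-synthesis bundles work the same way end to end:

```r
sim <- simulateCohort(cohortConfig(nParticipants = 2,
                                   sessionsPerParticipant = 2, seed = 3),
                      outDir = "bundles")
se  <- extractCohort("bundles")     # read + extract all 66 features
```

or from the shell, `Rscript scripts/pipeline.R run --n 4 --sessions 2
--seed 1 --out pipeline_out` (subcommands `simulate`, `extract`,
`correlate`, `riskscore`, `run`).

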