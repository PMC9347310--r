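---
title: "Methods: models, parameters and design choices in caldrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in caldrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`caldrift` quantifies how stable sound-evoked responses of individual
auditory cortical neurons are across daily two-photon imaging sessions,
and whether that stability differs between spectrotemporally complex
sounds (CxS) and pure tones (PT). This vignette is the package's account
of the underlying models, the parameters that matter, and the choices we
made where the design was genuinely open.

## The measurement model

A session provides a neurons × frames raw fluorescence matrix at a slow
galvo frame rate (3 frames/s by default), an event table of stimulus
onsets, and a locomotion mask. ΔF/F uses the session **median** as F₀ —
robust to sparse transients, and implying that prestimulus ΔF/F means sit
near zero, which matters for the responsiveness margin below. Response
magnitude is the mean ΔF/F over frames whose start time falls in
[0, 1.5) s from onset; the prestimulus magnitude uses [−1.5, 0) s. We
adopt the half-open frame-in-window convention (a frame belongs to
[a, b) by its start time): at 3 frames/s this yields five response frames
and four prestimulus frames per trial, and no frame is ever counted
twice. Trials whose response window touches a locomotion epoch are
excluded outright — the overlap rule is deliberately conservative since
any masked frame contaminates a five-frame mean.

ROI quality gates (compactness > 0.8, full-session ΔF/F skewness > 1.1,
both strict) mirror the post-segmentation curation applied to such data.
A "clear transients" criterion used in manual curation is subjective and
is not enforced; the skewness gate is the objective part of it.

## Nonparametric tests

**Responsiveness.** Per (neuron, day, stimulus): observed statistic =
mean sound response − mean prestimulus magnitude pooled over all stimuli
of the protocol; null = 1000 relabelings of the pooled trials preserving
group sizes (sampling without replacement within each shuffle); declared
responsive iff the observed difference strictly exceeds the empirical
97.5% quantile *and* the magnitude margin passes. The published margin —
the sound response must be "at least 10% greater" than the prestimulus
magnitude — is ill-posed when the prestimulus mean is non-positive, which
the median-based ΔF/F makes the typical case. We implement it literally
on positive baselines (mean_sound ≥ 1.1 × mean_prestim) and as
mean_sound > 0 otherwise. This keeps the gate defined everywhere and
makes the test conservative: its null false-positive rate sits at or
below the nominal 2.5% (verified by calibration tests). Neuron-day
sound-responsiveness applies a Bonferroni-tightened quantile
1 − 0.025/n_stimuli, evaluated on the position of the observed statistic
in the empirical null CDF.

**Cross-day change.** Trials of the two compared days are z-scored per
neuron across both days and all stimuli of the protocol (population-SD
denominator, fixed for determinism; the choice of n vs n−1 cancels from
every downstream decision). The change statistic is the **absolute**
difference of day means, compared against shuffled absolute differences
at the 95% quantile — direction-agnostic because drift is reported as
"change", not increase. The 10% magnitude gate needs a referent on
z-scored data; we use |m₂ − m₁| / max(|m₁|, |m₂|) ≥ 0.10, symmetric in
day order. A response enters the analysis iff it was responsive on at
least one of the two days; a change is only ever reported for included
responses. Multi-day aggregation pools all pairs of a given interval
(four 1-day pairs down to one 4-day pair for five sessions), with
repetitions.

**Stimulus specificity.** Per neuron and day pair, a fixed-effects
day × stimulus ANOVA with interaction on the z-scored trial responses; a
significant interaction means stimulus-specific drift rather than a
global gain change. Effect size is Hays' ω² =
(SS_int − df_int·MS_err)/(SS_total + MS_err) — slightly negative under
the null on average, invariant to additive shifts. Balanced designs use
the sequential decomposition (exact there); designs left unbalanced by
trial exclusions switch to Type II sums of squares. F and ω² are
scale-invariant, so running on z-scored rather than raw magnitudes does
not change them; z-scored is used for consistency with the change test.
Cells with fewer than two trials are dropped stimulus-wise; neurons with
fewer than two usable stimuli are skipped.

**Group statistics.** χ² on 2×2 tables is Pearson's without continuity
correction — this choice reproduces the reference statistics exactly and
is paired with Fisher's exact test. We report the *sample* odds ratio
(a·d)/(b·c) alongside `fisher.test()`'s conditional-MLE estimate, p and
CI; the sample OR is what the reference tables print. The two-proportion
z test uses the pooled variance, with the one-sided p in the observed
direction (also two-sided). The rank-sum test reports the rank sum of
the first sample with midranks; its p-value is exact (Wilcoxon null
distribution) for tie-free samples of at most 12 per group, else a
tie-corrected normal approximation. The multi-category bootstrap
proportion test draws, per category, k* ~ Binomial(n_test, p_ref) 10,000
times and counts rounds that are at least as extreme as the observed
test-group proportion **in every category simultaneously**; the phrase
"across categories" could also mean the across-category mean, so that
reading is available behind `rule = "mean"`.

## Acoustic complexity metrics

The spectrum estimator is a full-signal periodogram at the next
power-of-two FFT length — deterministic and line-preserving, which
matters because pure tones must show near-zero occupied bandwidth
(Welch averaging would smear them). Occupied bandwidth takes the first
frequencies at which cumulative power reaches 0.5% and 99.5% of the
total. Spectral entropy uses log base 2 (bits); any base preserves the
PT/CxS ordering. The modulation index computes a Hann-window spectrogram
(1024 samples, 50% overlap: ~10.5 ms frames at 97.6 kHz, ≥ 90 columns
for a 500 ms sound), drops trailing frames whose broadband power falls
below 1% of the peak frame (an objective, scale-free reading of
"excluding brief periods of silence at the end"), averages columns into
20 equal time bins, and returns one minus the mean Pearson correlation
over all C(20,2) unordered distinct bin pairs (self-pairs excluded;
zero-variance vectors drop their pairs with a warning). Linear rather
than log spectrogram power enters the correlations — the reference
procedure does not specify, and linear power is the more direct reading
of "power distribution". For 20 bins the index is bounded by 1 + 1/19 ≈
1.053; stationary sounds sit at 0. All four metrics are invariant to
amplitude scaling. Tone-overlap ranking integrates complex-sound power
within ±1/3 octave of each candidate tone, ties broken toward the lower
frequency.

## The synthetic-data generator

The generator is the package's test bed: it emulates the statistical
structure of the recordings — not their optics — with known ground truth.

*Stimuli.* Eight log-spaced tones, 2–32 kHz, 500 ms, 5 ms cosine ramps,
97.6 kHz sampling; eight complex sounds, each a sum of 3–5 band-limited
noise components whose amplitude envelopes are re-drawn every 50–100 ms
(~30% near-silent segments). This recipe guarantees, by construction,
complete separation from the tones in bandwidth, entropy and modulation
index — so the group rank sums under complete separation (36 for the
lower group of 8, 100 for the upper) are reproduced deterministically —
without shipping any third-party vocalization recordings.

*Recordings.* Baseline ~100 a.u. with 1/f (pink) noise; responsive
(neuron, stimulus) pairs emit transients with a one-frame rise and a
single-exponential 0.7 s decay — GCaMP6f-like and sufficient at
3 frames/s, where a finer rise time would be invisible. Trial amplitude
variability is multiplicative lognormal (scale-dependent, as ΔF/F
variability is) plus the additive trace noise; a single `noise_sd` knob
drives both so that `noise_sd = 0` makes repeated trials bit-identical.
Sessions hold 10 pseudorandom repetitions of each stimulus at an
interstimulus interval of 1.5 ± 0.3 s; locomotion epochs are
Poisson-count, 1–3 s long. Day-to-day evolution assigns each responsive
pair a label: *stable*, *gain* (a neuron-level multiplicative lognormal
gain random walk, sdlog `gain_drift_sd`), or *remap* (the pair's
amplitude is re-drawn, probability `tuning_drift_prob` per day step,
settable per sound class). Baseline level and transient SNR are free
parameters — the reference recordings report neither — and the defaults
(baseline 100 a.u., median amplitude 0.4 ΔF/F, `noise_sd` 0.1) were
fixed once as plausible for GCaMP6f somatic imaging and not revisited.

*What passing tests do and do not show.* The generator emulates trial
statistics, drift structure, and session bookkeeping; it does not
simulate raw movies, neuropil contamination, spike-to-fluorescence
nonlinearity, or correlated network variability. Calibration and
recovery results on it validate the pipeline's logic and its nominal
error rates, not the biological effect sizes of any particular dataset.

*Field-of-view pairs.* Anisotropic Gaussian cell bodies at
non-overlapping positions over a smooth neuropil-like background texture
that translates with the scene; the second image applies an integer
shift plus per-cell lognormal brightness/size/orientation perturbations
of scale `morph_noise`. The background texture is what anchors patch
identity — with featureless cells on a flat background, structural
similarity cannot distinguish equally bright somata, and neither could
it in real data without surrounding context. Matching uses FFT
cross-correlation for the shift, then 39 × 39 px patches scored with the
standard structural similarity index (11 × 11 Gaussian window, σ = 1.5,
K₁ = 0.01, K₂ = 0.03), row-normalized, argmax-assigned per day-1 cell
(no one-to-one constraint, since each neuron's matches are ranked
independently; a greedy one-to-one mode exists behind a flag). On
synthetic pairs the reference pairing is ground truth, which
reinterprets the published manual-vs-automated agreement figure as
recovery of a known correspondence.

## Problem sizes used by the test suite

Simulation sizes are the package's own balance of statistical resolution
against runtime. Null calibration uses ~1000 (neuron, stimulus) pairs at
1000 shuffles for both shuffle tests and 2000 simulated neurons for the
ANOVA rejection rate (binomial SE ~0.5 percentage points). Parameter
recovery runs 20 seeded two-protocol experiments (56 neurons, 2 days,
remap 0.2 vs 0.1, 500 shuffles) and requires the correct
percent-changed and profile-distance ordering in at least 19; the
specificity contrast compares remap-only against gain-only drift of
matched log-scale magnitude (72 neurons each). Unit tests use smaller
sizes throughout.

## Storage formats

Sessions round-trip through a plain-text container (a directory holding
`meta.json`, `traces.csv`, `events.csv`, `locomotion.csv`,
`roi_stats.csv`) with schema validation before any computation; stimuli
are written as 16-bit PCM WAV. Reports embed no timestamps, so reruns of
the same configuration are byte-identical, and carry an FNV-1a hash of
the analysis-relevant configuration.

## Known limitations

- The responsiveness margin on non-positive baselines is a package
  decision (documented above); alternative readings would shift absolute
  responsiveness rates, though not the PT/CxS contrasts that share the
  rule.
- Exact rank-sum p-values fall back to a normal approximation under
  ties, which arise for discretized metrics (e.g., several tones sharing
  a periodogram main-lobe width). The rank sums themselves are exact.
- The Fisher CI comes from the conditional exact method; other software
  may print unconditional intervals.
- Cross-session matching handles rigid translation only; rotation or
  non-rigid deformation is out of scope, as is tracking across more than
  two sessions by graph closure.
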