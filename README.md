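# caldrift

Day-to-day stability analysis of sound-evoked calcium responses in
auditory cortex.

## The problem

Two-photon calcium imaging can follow the same layer 2/3 auditory cortical
neurons across days and ask how stable their sound responses are — and
whether responses to spectrotemporally complex sounds (CxS: vocalizations,
environmental sounds) drift less than responses to simple pure tones (PT).
`caldrift` implements that analysis as a tested, reusable R pipeline for
anyone working with longitudinal trial-based imaging data: per-session
ΔF/F extraction, nonparametric responsiveness and change testing,
drift metrics, and the group-level statistics — together with a
synthetic-data generator with known ground truth, so every stage is
verifiable without any recording.

## What it computes

**Acoustic complexity** of each stimulus waveform:

- occupied bandwidth — span between the 0.5% and 99.5% crossings of the
  cumulative spectral power;
- spectral entropy — Shannon entropy of the normalized power spectrum
  (bits);
- spectrotemporal modulation index — `1 − mean pairwise Pearson
  correlation` of the spectrogram's 20 time-binned frequency-power
  vectors (0 for stationary sounds, above 1 for anticorrelated frequency
  content);
- spectral centroid.

**Trial responses.** ΔF/F = (F(t) − F₀)/F₀ with F₀ the session median;
response magnitude = mean ΔF/F in [0, 1.5) s from sound onset, prestimulus
magnitude over [−1.5, 0) s; ROI gates (compactness > 0.8, trace skewness
> 1.1); trials overlapping locomotion excluded.

**Responsiveness** (per neuron, day, stimulus): the observed mean response
minus the pooled prestimulus mean is compared against 1000 random
relabelings of the pooled trials; responsive iff it exceeds the 97.5%
shuffle quantile and the sound magnitude clears a 10% margin over the
prestimulus baseline. A neuron-day is sound responsive if at least one
stimulus passes with Bonferroni correction for the number of stimuli.

**Cross-day change** (per neuron, stimulus, day pair): trial responses are
z-scored per neuron across the pair, and `|Δmean|` is compared with its
95% shuffle quantile plus a 10% relative-magnitude gate. Aggregates:

    percent changed = 100 × (# significant changes) / (# included responses)

with a response included if the neuron was responsive on at least one of
the two days; neuron-level change fractions (Bonferroni across stimuli);
Euclidean distance √Σᵢ(xᵢ−yᵢ)² between per-day response profiles; all
pooled over 1- to 4-day intervals with repetitions.

**Stimulus specificity**: per-neuron day × stimulus ANOVA with
interaction, with Hays' ω² = (SS_int − df·MS_err)/(SS_tot + MS_err) for
the interaction term.

**Group statistics**: Pearson χ² (no continuity correction) and Fisher's
exact test on changed/unchanged counts, pooled two-proportion z,
exact small-sample rank-sum, Fisher r-to-z, and a multi-category
bootstrap proportion test (10,000 simulated reference-given proportions,
jointly extreme across categories).

**Cross-session matching**: rigid translation registration of
mean-fluorescence images plus structural-similarity scoring of 39 × 39 px
cell-body patches, with row-normalized similarity and agreement against a
reference pairing.

## Worked example

Simulate a 3-day, two-protocol experiment in which pure-tone tuning
remaps twice as often as complex-sound tuning (0.2 vs 0.1 per day), then
run the full analysis:

```r
library(caldrift)
cfg <- run_config(out_dir = "demo_run", seed = 42,
                  synth = list(n_neurons = 24, n_days = 3,
                               frac_responsive = 0.4,
                               tuning_drift_prob = c(PT = 0.2, CxS = 0.1)),
                  n_shuffles = 500)
rep <- run_pipeline(cfg)
rep$summary
```

```
  protocol interval_days included changed percent_changed
1       PT             1      127      29           22.83
2       PT             2       68      26           38.24
3      CxS             1      133      11            8.27
4      CxS             2       67       7           10.45
  neurons_changed_fraction mean_distance anova_prop_significant
1                    0.311         1.042                 0.3111
2                    0.391         1.245                 0.5217
3                    0.093         0.876                 0.0698
4                    0.227         1.034                 0.2273
```

Reading this: 22.8% of included pure-tone responses changed significantly
across consecutive days against 8.3% for complex sounds — the pipeline
recovers the doubled drift rate it was given — and drift accumulates with
interval (38.2% and 10.4% at 2 days). The between-protocol tests land in
`rep$group`:

```
chi2: 10.59  p: 0.0011
OR:   0.30
multi-interval bootstrap p: 0
```

`run_pipeline()` also writes every intermediate table (trial table,
responsiveness, change records, profile distances, ANOVA results) as CSV
plus a JSON/Markdown report under `out_dir`; reruns with the same
configuration are byte-identical.

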