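# gonogo2p

Analysis of two-photon calcium imaging recorded while head-fixed mice
perform a go/no-go visual discrimination task — and a synthetic session
generator with planted ground truth that makes every stage testable
without recorded data.

## Who this is for

Labs analysing chronic volumetric GCaMP imaging (here: 5 Hz stack rate)
during engaged/passive go/no-go behaviour who need, in one tested
package:

* **Preprocessing** — rigid motion correction by cross-correlation to the
  mean image, activity-map segmentation with local adaptive thresholds,
  neuropil subtraction `F_corrected(t) = F_raw(t) − 0.7 F_neuropil(t)`,
  ΔF/F with F₀ = the mode of the fluorescence density, and semi-automated
  cross-session ROI alignment with a 5 px flagging rule.
* **Behaviour** — trial labelling under either reward contingency,
  lick-bout detection (inter-lick interval < 1 s), and truncated
  d′ = Φ⁻¹(R_HIT) − Φ⁻¹(R_FA) with rates clipped to [0.01, 0.99]
  (ceiling 4.65), plus the d′ > 1 / rate-gap > 30-point session criterion.
* **Selectivity statistics** — ROC-based indices 2·(auROC − 0.5) over the
  last 1.6 s of the stimulus, label-shuffling permutation significance
  (central-95% rule), time-resolved (200 ms bin) variants, responsiveness
  and task-gating classification, engagement/contrast/error modulation
  indices, lick-count-matched comparisons, per-field bootstrap fractions
  and clustered rank tests for field-correlated data.
* **Encoding model** — the 112-coefficient ridge GLM with lagged binary
  predictors (stimulus onsets, engagement offset and duration terms, lick
  bouts with anti-causal lags), condition-stratified 20% holdout,
  five-fold cross-validated λ ∈ [10⁻², 10⁴], component decomposition in
  z-scored ΔF/F units, and bootstrap comparison against 43/27/86-column
  partial models.
* **Contrast-response fitting** — joint engaged/passive Naka-Rushton fits
  `R(C) = R_max·Cⁿ/(Cⁿ + C₅₀ⁿ) + R₀` with a shared exponent,
  variance-weighted least squares, a bootstrap goodness-of-fit test with
  a 10% exclusion rule, modulation-group classification and spatial
  statistics in 40 µm distance bins.
* **Reversal analysis** — matched-cell selection across a contingency
  reversal, quadrant classification into stimulus-stable (StimA/StimB)
  versus choice-coding (Go/NoGo) groups, and per-group modulation
  summaries.

## A worked example

```r
library(gonogo2p)

cfg <- generator_config(n_neurons = 20,
                        archetype_mix = c(stimulus = 0.5, choice = 0.5),
                        noise_sd = 0.08, n_trials_per_block = 50, seed = 9)
pair <- generate_reversal_pair(cfg)
print(pair$before)
#> Imaging session (pre): 20 neurons, 200 trials, 5 Hz, contingency original
#>   outcomes: CR=35 FA=6 Hit=52 Miss=7 PassiveA=59 PassiveB=41

summary_before <- performance_summary(pair$before$trials)
print(summary_before)
#> hit rate 0.881 (n=59), FA rate 0.146 (n=41), d' = 2.234, passes criterion

matched <- select_matched_cells(pair$before, pair$after)
rec <- reversal_records(pair, matched, n_perm = 500, seed = 2)
table(pair$ground_truth$archetype[rec$neuron], rec$group)
#>            Go StimA StimB
#>   choice   10     0     0
#>   stimulus  0     6     4
```

Every planted choice-coding neuron flips its apparent stimulus preference
with the reward contingency and is classified Go; every stimulus-coding
neuron keeps its grating tuning and lands in StimA or StimB according to
its planted preferred stimulus. The same sessions feed the encoding
model:

```r
fit <- fit_encoding_glm(pair$before, neuron = 1, variant = "full", seed = 5)
print(fit)
#> Encoding model (full), neuron 1: 112 coefficients, lambda = 0.01
#>   R2 train = 0.998, R2 test = 0.998 (161 train / 39 test trials)
component_prediction(fit, "motor")$strength   # z-scored dF/F units
#> [1] -0.009508422  (neuron 1 is a stimulus-coding cell: no motor drive)
```

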