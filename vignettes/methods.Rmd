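---
title: "Models and methods behind gonogo2p"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gonogo2p}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonogo2p)
```

# The setting

`gonogo2p` analyses volumetric two-photon calcium imaging (GCaMP6s, 5 Hz
stack rate) recorded from mouse visual and posterior parietal cortex while
the animal performs a head-fixed go/no-go visual discrimination: an
auditory cue (0.5 s), a 1 s delay, a 2 s drifting-grating stimulus
(Stimulus A rewarded, Stimulus B not), a 1.5 s response window in which a
lick spout is within reach, and a 3 s inter-trial interval. Blocks of
engaged behaviour alternate with passive-viewing blocks in which the spout
is withheld and each passive block replays the stimulus sequence of the
preceding engaged block. Three task variants matter: the full-contrast
task, a variable-contrast task (2–64%), and a contingency-reversal
paradigm in which the rewarded grating is swapped and the same field of
neurons is imaged before and after.

All events are snapped to the imaging frame grid. At 5 Hz a trial is 40
frames; the stimulus onset (nominally 1.5 s after cue) falls between
frames and is placed at frame `round(1.5 * rate) + 1`, i.e. 1.6 s. The
windows the analyses use are then exactly the frame counts the design
calls for: an 8-frame stimulus analysis window (the last 1.6 s of the
stimulus), a 5-frame (1 s) pre-stimulus baseline, and a 25-frame (5 s)
encoding-model window from cue onset.

# The synthetic session generator

No public recording exists for this paradigm, so the generator
(`generator_config()`, `generate_session()`, `generate_reversal_pair()`,
`generate_movie()`) is the package's canonical input source and is itself
first-class, tested code. It emulates what the analyses assume and no
more:

* **Behaviour.** Engaged go trials produce a lick (Hit) with probability
  `hit_rate` (default 0.9), no-go trials with probability `fa_rate`
  (default 0.2) — a well-trained animal whose session passes the d' > 1
  and 30-point rate-gap criterion. Lick trials carry a bout of 4–8 licks
  at about 7 Hz starting just after spout presentation. Miss trials are
  i.i.d.; the end-of-session motivation confound is not simulated, but the
  trailing-Miss exclusion filter is still applied by the analyses.
* **Calcium kinetics.** Each neuron's instantaneous drive is convolved
  with a peak-normalised double exponential (rise 0.2 s, decay 1.5 s),
  GCaMP6s-like and slow enough that offset dynamics span several frames at
  5 Hz — the reason the encoding model carries 21 lags. Noise is additive
  i.i.d. Gaussian on dF/F; photobleaching is not modelled.
* **Archetypes.** Neurons are allocated exactly (largest-remainder) to
  five archetypes: `stimulus` (drive on preferred-grating trials, engaged
  and passive alike), `engagement_gated` (same but only when engaged),
  `mixed` (stimulus drive with a random engagement gain plus a
  choice-locked component), `choice` (drive on engaged lick trials
  only), and `silent`. The choice drive starts 0.4 s into the stimulus
  (a premotor ramp) and lasts through the lick bout; choice-related
  signals must be visible in the stimulus-period analysis window —
  a drive confined to the bout itself would begin only after that window
  closes and the archetype would be invisible to the analyses it exists
  to exercise.
* **Contrast dependence.** With more than one contrast level each tuned
  neuron gets a planted Naka-Rushton curve (C50 uniform in 5–30%,
  exponent 2).
* **Movies.** Somata are rendered as disks whose brightness follows
  `F0 (1 + dF/F)` plus a `neuropil_coeff` fraction of a smooth background
  field, with optional integer rigid jitter — exactly the contamination
  model that the 0.7-coefficient neuropil subtraction inverts.

What the generator does **not** emulate: spiking-to-calcium nonlinearity,
correlated (shared) noise across neurons, slow drift, non-rigid motion,
pupil/arousal covariates, reward/punishment dynamics beyond outcome
labels. Tests passing on this generator therefore demonstrate that the
implementations are correct and calibrated under the stated statistical
structure, not that the biological conclusions transfer to real data.

# Preprocessing

Motion correction registers every frame to the pixel-wise mean image by
integer-pixel 2-D cross-correlation (FFT); no sub-pixel interpolation is
attempted. Segmentation computes an activity map — the temporal variance
of high-pass-filtered pixel traces, a standard stand-in for the published
activity-map statistic, which is cited rather than restated in the source
text — thresholds it adaptively (local mean over a 50 µm window plus an
offset in global SD units) and splits oversized components by recursive
threshold raising. Somatic traces are corrected as
`F_corrected = F_raw − 0.7 F_neuropil`, the neuropil being the 0–15 µm
annulus around the ROI border excluding all ROI pixels (the printed
"0–15 mm" is treated as a typo for µm). dF/F uses F0 = the mode of a
kernel density estimate (Silverman bandwidth) of the trace — robust to
sparse positive transients and invariant to positive rescaling.

Cross-session ROI alignment predicts each ROI's displacement as the
inverse-distance-weighted mean of manually defined anchor vectors,
computes a normalized cross-correlation of the ROI's square neighbourhood
(about 4x the ROI size) against the other session's mean image, multiplies
it by a Gaussian mask centred on the prediction (sd 10 px), smooths it
(sd 1 px), and takes the peak. The smoothing uses validity-weighted
(normalized) convolution so displacements that could not be evaluated near
the image border do not drag the peak. The smoothing width of 1 px was
chosen because on the discrete search grid a broader kernel can displace
the peak by a pixel even for identical images; both widths are exposed as
parameters since the design only requires "gradual" decay and "a"
Gaussian filter. ROIs whose computed vector differs from the prediction by
more than 5 px in either coordinate are flagged.

# Selectivity statistics

All comparative indices are `2 (auROC − 0.5)` computed on
baseline-subtracted stimulus-window responses, ties credited 0.5
(Mann-Whitney). Significance comes from a label-shuffling permutation test
(2000 shuffles by default): an index outside the central 95% interval of
the shuffled distribution is significant, and the reported two-sided p is
`2 min(tail fractions)` capped at 1. Comparisons require at least five
trials per class; sessions failing that are excluded rather than scored.
Time-resolved selectivity evaluates the index independently in 200 ms bins
(one frame at 5 Hz) over the first 5 s of the trial.

A neuron is *task-responsive* when its stimulus-window response exceeds
the pre-stimulus baseline on Hit or CR trials — a two-sample, two-tailed
t-test across trials at p < 0.01 combined with a positive mean difference
(the two-tailed form reconciles "greater than baseline" with the
everything-two-tailed convention), plus a signal-to-noise criterion: the
trial-averaged waveform must exceed the baseline mean by two baseline SDs
somewhere in the stimulus or response period (the response period is
taken as the 1.5 s after stimulus offset). Preference (target vs
non-target) follows the larger mean engaged response, ties resolving to
target with an explicit flag; *task-gated* neurons are responsive when
engaged but fail the same test on passive trials of their preferred
stimulus.

Population fractions are computed per imaging field and bootstrapped
across fields (2000 resamples). Pooled-neuron comparisons across areas
use a clustered rank test: each cluster (imaging field) is reduced to its
within-cluster mean and the standard Wilcoxon rank-sum or signed-rank
test is applied across clusters. This cluster-summary estimator was
chosen over weighted-rank formulations because it is exact where
exactness is testable — with singleton clusters it *is* the textbook
Wilcoxon test, and duplicating observations within a cluster cannot move
the p value — while holding the nominal type-I rate under intra-cluster
correlation. Its cost is power when cluster sizes are very unbalanced,
which the analyses here do not encounter.

# The encoding model

Each neuron's z-scored trace over the first 5 s of every trial
(concatenated) is regressed on lagged binary predictors: target and
non-target stimulus onsets (lags 0–20 frames), a constant engagement
offset, engaged-stimulus duration predictors per identity (lags 0–20),
and a lick-bout predictor (lags −10…15; the anti-causal lags capture
premotor activity). With the bias that is 112 coefficients; the
stimulus-only, motor-only and stimulus+engagement variants have 43, 27
and 86. Lags are zeroed outside their own trial window, so late stimulus
lags whose support falls entirely past the 5 s window are structurally
empty columns; ridge drives their coefficients to zero and they are
excluded when parameter recovery is assessed.

Fitting is ridge regression with an unpenalised bias (closed-form normal
equations). 20% of trials per condition (Hit, CR, Miss, FA, passive
target, passive non-target) are held out; the penalty is chosen by
five-fold, trial-wise, condition-stratified cross-validation over a
13-point log grid spanning 1e-2 to 1e4 (two points per decade — the
design fixes only the range), taking the first maximiser of mean
held-fold R². z-scoring is per session, and CV folds are stratified like
the holdout; both choices are flagged as conventions rather than
requirements. Holdout performance is `R² = 1 − SSE/SST` on concatenated
test frames and may be negative. Component predictions zero all other
coefficient groups; component strength averages the component trace over
0–4 s after stimulus onset (clipped to the trial window) on the preferred
trial type (Hit trials for the motor component). Model comparisons
resample the held-out trials 2000 times; a model is significant when
fewer than 5% of resampled R² values fall at or below zero, and a partial
model is worse than the full one when its resampled R² reaches the full
model's in fewer than 5% of iterations.

# Contrast-response fitting

Per-contrast mean responses (engaged and passive jointly) are fit to the
Naka-Rushton function `R(C) = R_max C^n / (C^n + C50^n) + R_0` with the
exponent shared across conditions — seven parameters — by minimising the
variance-weighted squared error, the weight being the variance of the
mean at each point (the variance-of-what question is open in the source
design; the variance of the mean makes the objective approximately
chi-square). Optimisation is multi-start bounded L-BFGS-B (R_max in
[0, 10], C50 in [1, 100]%, n in [0.5, 6], R_0 in [−10, 10]; starts on a
log-spaced C50 grid crossed with n in {1, 2, 4}); all-zero variances
trigger an unweighted fallback with a warning.

Goodness of fit is a bootstrap test of the null that the per-point mean
responses equal the model predictions: trials are shifted so each cell
mean equals its prediction, resampled 1000 times within contrast x
condition, and the achieved significance level is the fraction of
bootstrap errors at least as large as the observed error; fits with
ASL < 0.10 are excluded. The prediction-error statistic is the plain SSE
of per-point means rather than the variance-weighted fitting objective:
with weights frozen at their observed values the bootstrap understates
the observed statistic's spread (noisy weight estimates give it
F-like tails) and excludes about twice the nominal fraction, while
re-estimating weights inside every resample adds a second layer of
variance noise and makes the test conservative. The unweighted statistic
lets the bootstrap replicate the observed statistic exactly, and the 10%
rule then excludes close to 10% of true-model cells, which is what the
calibration suite checks.

Contrast modulation compares engaged target-stimulus responses at high
(32, 64%) versus low (2, 4%) contrast; engagement modulation compares
engaged versus passive at high contrast only; both use the permutation
machinery, and the four groups (contrast-only, engagement-only, both,
neither) follow the two significant-positive flags. Spatial statistics
collapse planes to 2-D positions, compute per-cell mean within- and
across-group distances, bin pairwise |index differences| by distance in
40 µm bins, and test within-versus-across with the clustered signed-rank
test.

# Reversal analysis

Neurons are analysed only if significantly responsive (p < 0.01, same
machinery) to either grating in both sessions of a matched pair.
Selectivity toward Stimulus A is computed per session with permutation
significance; neurons significant in both sessions are classified by
sign pattern: stable positive StimA, stable negative StimB,
positive-then-negative Go (the preference follows the rewarded grating),
negative-then-positive NoGo; anything else NS. The source figures number
these quadrants inconsistently; the sign logic above matches their colour
key and is what the code implements. Engagement and error (FA vs CR)
modulation indices are computed per session and averaged across the two
sessions; the Go group is compared against the stimulus-stable groups
with the clustered rank-sum (field-by-group clusters when several fields
are present; with a single field there is no between-field correlation to
absorb and the test reduces to the per-neuron rank-sum).

# Numerical choices and degenerate inputs

* Permutation p uses add-one tail counts, so it can never be exactly 0;
  degenerate all-equal data returns index 0, not significant.
* `auroc` errors on empty groups; selectivity returns NULL (exclusion)
  below the five-trial minimum — exclusion and a negative finding are
  never conflated.
* Zero-variance movie frames shift by (0, 0) with a warning; a
  zero-variance response trace selects the largest ridge penalty with a
  warning; nonpositive F0 is an error because it signals a corrupted
  trace rather than a tolerable edge case.
* d' truncates rates to [0.01, 0.99] (ceiling 4.65); the session
  criterion uses strict inequalities as printed.
* A lick gap of exactly 1 s separates bouts (strict `< 1 s` within a
  bout).
* Tie in stimulus preference resolves to target and carries a flag.

# Problem sizes in the test and acceptance suites

Exhaustive and closed-form checks run at their natural size (all 3-vs-3
auROC samples on {0,1,2}; 50x20 ridge instances at 1e-8). Calibration and
recovery suites use 100–200 simulated cells, 500 permutations, and 1000
bootstrap samples — sizes at which binomial error on a 5% or 10% rate is
about 1.5–2 percentage points, small relative to the acceptance bands,
while a full run stays in the minutes range. The reversal-recovery
fixture uses 200 neurons (half stimulus-coding, half choice-coding) at
noise SD 0.08 with 50-trial blocks. The engagement-gain rank-order check
runs at moderate SNR (noise SD 0.8) deliberately: at very high SNR the
ROC index saturates at 1 for most cells and rank order degenerates into
ties — a ceiling property of the index, not an implementation defect.

# Known limitations

* The activity-map statistic is a variance-based stand-in; segmentation
  quality on real movies will depend on the true statistic and on manual
  curation, which the package does not attempt to replicate.
* The clustered test trades power for exactness and validity (see above);
  users wanting weighted-rank variants should use a dedicated package.
* Only integer-pixel motion is corrected, and only rigid jitter is
  simulated.
* The generator's archetypes operationalise the coding groups the
  analyses are designed to find; they are a modelling convenience, not a
  biological claim.
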