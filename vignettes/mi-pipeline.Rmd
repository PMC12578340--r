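---
title: "Statistical channel reduction and regularized CSP for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical channel reduction and regularized CSP for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mieeg)
```

## The problem and the model

Motor imagery (MI) — imagining a movement without executing it — attenuates
the power of the sensorimotor mu rhythm (8–12 Hz) and adjacent beta band over
the cortical areas representing the imagined limb. This event-related
desynchronization (ERD) is the physical signal that two-class MI
brain–computer interfaces decode. High-density EEG montages sample far more
scalp locations than the task modulates, and the redundant channels cost
noise, preparation time and compute.

`mieeg` implements a pipeline of five stages, each exposed as ordinary
functions and combined in the fitted-model object `mi_fit()`:

1. **Preprocessing** (`resample_recording`, `bandpass_recording`,
   `epoch_recording`): all recordings are brought to a common 100 Hz rate,
   band-passed 0.5–30 Hz with a 5th-order Butterworth filter, and cut into
   3-s marker-aligned epochs. The band covers delta through beta; the
   discriminative content for MI sits in the 8–30 Hz range.
2. **Channel selection** (`select_channels`): per channel, a two-sided Welch
   t-test on a per-trial feature at family level $\alpha = 0.10$ with
   Bonferroni correction $\alpha/n$, combined with a correlation criterion —
   a significant channel is kept only if $|r| \ge 0.5$ against at least one
   other significant channel.
3. **Feature extraction** (`class_cov_estimate`, `csp_filters`,
   `csp_log_features`): Ledoit–Wolf-shrunk class covariances, common spatial
   pattern (CSP) filters from the generalized eigenproblem
   $C_1^{reg} w = \lambda (C_1^{reg}+C_2^{reg}) w$, and log-variance
   features of the filtered trials.
4. **Refinement** (`ridge_refine`): a linear map $W$ minimizing
   $\|XW - y\|^2 + \lambda \|W\|_2^2$, whose discriminant scores are appended
   to the feature vector.
5. **Classification and evaluation** (`train_classifier`, `kfold_cv`): a
   small feed-forward network (64–64–100–2, ReLU, dropout 0.5, softmax) or a
   16-unit LSTM comparator, trained with Adam on categorical cross-entropy
   and scored by stratified 5-fold cross-validation.

Key assumptions: exactly two classes; the class difference is expressed in
second-order statistics (band power / covariance), which is what both the
selection statistic and CSP respond to; trials are exchangeable within class
(no session drift modelling); and artifacts are handled by band-passing
alone — no ICA or artifact subspace removal.

## Design decisions in the open points

Several points of the procedure admit more than one reading; the package
resolves them as follows.

**What the per-channel t-test compares.** Band-passed EEG is essentially
zero-mean, so a t-test on raw amplitudes has no power against ERD. The
default per-trial feature is therefore the log band power in 8–30 Hz — the
physiologically discriminative quantity. Log-transforming symmetrizes the
skewed power distribution, improving the normality the t-test assumes. A
`raw-amplitude` mode is available for sensitivity analysis
(`selection_config(feature = )`).

**The correlation criterion.** "Deprioritize highly correlated channels" and
"require strong correlation (|r| > 0.5)" pull in opposite directions. The
resolution: the $|r| \ge$ `r_min` requirement is applied *against other
significant channels* — task channels participate in a coherent network, and
an isolated significant channel is more plausibly a false positive — while
redundancy pruning at `r_redundant` (default 0.95, off by default) is a
separate step that drops the larger-p member of a nearly duplicate pair.

**Two channel-reduction statistics.** The reduction *rate* 1 − rc/oc and the
retention *ratio* rc/oc are both in circulation under the same acronym; the
tabulated convention truncates (not rounds) the ratio to two decimals
(93/118 = 0.78813 → 0.78). `crr()` returns both, and every report prints
both, so no reader has to guess.

**CSP from two per-class eigendecompositions.** Decomposing each regularized
class covariance separately does not produce spatial filters that contrast
the classes. The package implements the standard simultaneous
diagonalization: whiten $C_1^{reg}+C_2^{reg}$, eigendecompose the whitened
$C_1^{reg}$, giving $\lambda \in (0,1)$ with $w^\top C_1 w + w^\top C_2 w = 1$
per filter — which is exactly the "maximize one class's variance while
minimizing the other's" objective. `m_pairs` defaults to 3 filter pairs
(capped at half the channel count): the conventional CSP choice balancing
information against estimation noise.

**Shrinkage target.** The literal identity target $I$ is scale-inconsistent
for microvolt-scale covariances (it would barely regularize entries of order
100 µV²). The default target is $\nu I$ with $\nu = \mathrm{tr}(C)/n$
(Ledoit–Wolf's scaled target); `shrink_target = "identity"` reproduces the
plain form. The intensity $\gamma = 1 - \alpha$ is computed per class from
the pooled, per-trial-centered samples by the closed-form Ledoit–Wolf
estimator, clipped to $[0,1]$.

**The "deep" refinement.** The refinement stage is specified only through the
penalized linear loss above, so it is implemented as what that loss defines:
a ridge-regularized linear layer, solved in closed form
$(X^\top X + \lambda I)^{-1} X^\top Y$ (with a gradient-descent solver kept
as an independent check). Its two discriminant scores are appended to the
CSP log-variances before the classifier, so the nonlinear learning lives in
the downstream network. λ defaults to `"auto"`: 5-fold selection on the
training data over the grid $10^{-3} \ldots 10^{3}$.

**Stage order.** Selection operates on band-passed, epoch-aligned data — the
log-band-power statistic needs band-limited epochs — even though one could
also read the pipeline as selecting channels before preprocessing. A literal
`stage_order = "select-first"` mode is provided: selection then sees raw
epochs, and preprocessing follows.

**Epoch convention.** A "3-s epoch at 100 Hz" is stored with both endpoints
inclusive: `round(3 * 100) + 1 = 301` samples. This convention is pinned by
the sample-count bookkeeping of the datasets the pipeline targets.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha` | 0.10 | — | family-wise level of the selection test |
| `r_min` | 0.5 | — | "strong correlation" criterion |
| `low_hz`, `high_hz`, `order` | 0.5, 30, 5 | Hz | Butterworth band covering delta–beta |
| `target_fs` | 100 | Hz | common rate across heterogeneous recordings |
| `window_s` | 3 | s | epoch length (301 samples at 100 Hz) |
| `m_pairs` | 3 | pairs | CSP filters kept per extreme |
| `lambda` | `"auto"` | — | ridge penalty, CV-selected on training data |
| `epochs`, `batch_size` | 100, 32 | — | training budget; 32/64/128 are the benchmarked batch sizes |
| `lr` | $10^{-3}$ | — | Adam default, with $\beta_1=0.9$, $\beta_2=0.999$ |

## What the synthetic generator emulates — and what it does not

`simulate_epochs()` builds each trial as 1/f (pink) plus white noise on every
channel; the informative channels additionally carry a shared mu-band
sinusoid (random frequency in 8–12 Hz and random phase per trial) whose
amplitude in class 1 is scaled by $\sqrt{1-\texttt{erd\_depth}}$ —
multiplicative band-power attenuation, the ERD signature. A fraction
`mixing_corr` of the background variance is shared among the informative
channels so that they satisfy the selection stage's correlation criterion,
as volume conduction makes neighbouring electrodes do in real recordings.

Default scales are realistic for scalp EEG: pink background 10 µV, white
sensor noise 2 µV, mu amplitude 8 µV, signals within roughly ±50 µV. The
defaults (20 channels, 4 informative, 100 trials per class, ERD depth 0.8,
mixing 0.7) were fixed once as the package's desk-scale study conditions.

The generator deliberately does **not** model: evoked (additive, phase-locked)
potentials; a forward head model with realistic lead fields; ocular or
muscular artifacts; non-stationarity across a session; or subject-specific
spectral peaks. Passing tests on this generator therefore demonstrate that
the pipeline recovers multiplicative band-power class structure planted
among correlated channels in 1/f noise — not that it handles artifact-laden
or drifting real recordings.

Under the default conditions the planted class difference is a rank-one
covariance perturbation shared with the background direction, so one CSP
eigenvalue carries the class information and the end-to-end 5-fold accuracy
sits at about 94–98 % across generator seeds (binomial fold noise at 200
trials is ±1.5 %). This ceiling is a property of the simulated
signal-to-background ratio, not of the classifier: a linear discriminant on
the same features performs equivalently.

## Numerical choices

* **Band power** is computed spectrally: the per-epoch periodogram weighted
  by the squared zero-phase magnitude response of the Butterworth band-pass
  (its power transfer). By Parseval this equals the mean square of the
  filtered epoch up to circular-convolution edge effects, and it vectorizes
  across all trials and channels in one FFT.
* **Zero-phase filtering** of continuous recordings uses forward–backward
  application (`filtfilt`), doubling the stop-band attenuation in dB; a
  causal single-pass mode exists for completeness. Filtering happens on the
  continuous record *before* epoching so start-up transients stay outside
  the trials.
* **Resampling** is an explicit polyphase chain — upsample, FIR low-pass at
  `min(1/p, 1/q)` of the upsampled Nyquist (`fir1`, order `20*max(p,q)`),
  downsample — accurate to ~0.1 % in the pass band. Marker indices rescale
  with half-up rounding.
* **Covariances** use the `1/m` normalization with per-trial mean removal.
  The CSP whitening refuses numerically singular composite covariances and
  directs the user to shrinkage.
* **Degenerate inputs**: zero-variance channels get correlation 0 with a
  warning; zero-variance CSP projections are floored at machine epsilon
  before the log; undefined confusion-matrix ratios (zero denominators)
  report 0 and are flagged by name; identical paired vectors give t = 0,
  p = 1, while constant non-zero differences raise a degeneracy error.
* **Wilcoxon signed-rank**: zero differences are excluded, ties share
  average ranks (the statistic, the smaller signed-rank sum, can be
  fractional), and the null is exact up to n = 25 via dynamic programming
  over doubled ranks; beyond that, a normal approximation with tie
  correction.
* **Determinism**: every stochastic stage draws from a seed passed in
  explicitly; a global pipeline seed fans out to per-stage seeds by fixed
  offsets, and a cross-validation report is bit-reproducible for a given
  seed.

## Problem sizes used in the test suite

The suite exercises the pipeline at desk scale, chosen so the full run stays
in the range of a few minutes: 100 trials per class and 20 channels for the
end-to-end property, 20 generator seeds for the planted-recovery rate, 100
null simulations of 59 channels for the family-wise error rate, and 10–50
trials for unit fixtures. The family-wise error check allows the one-sided
binomial sampling band around the nominal 0.10 at 100 runs (≤ 0.15), which
is the standard Monte-Carlo reading of a rate guarantee.

## File formats

* **MAT (level 5)**: the continuous-EEG competition layout — `cnt`
  (time × channels on disk, transposed to channels × time in memory), `mrk`
  (`pos`, `y`), `nfo` (`fs`, `clab`). Uncompressed and zlib-compressed
  elements are read; v7.3 (HDF5) containers are rejected with an explicit
  error. Signals stored as int16 are scaled by 0.1 to microvolts per the
  competition convention; unlabeled (NaN) markers are dropped with a count.
* **EDF**: 16-bit quantization per channel over the observed physical range
  (~range/65000 resolution). Plain EDF has no annotation track, so markers
  ride in a dedicated `MI_STATUS` channel holding the class label at each
  onset sample; the reader converts it back and removes the channel.
* **Internal container**: compressed R serialization of the validated
  fields; lossless.

## Known limitations

* Binary classification only; the four-class extension of some MI datasets
  is out of scope.
* MAT v7.3, GDF, BrainVision and FIF readers are not provided.
* The LSTM comparator is trained by full backpropagation through time in
  plain R; it is intended for architecture comparison at benchmark scale,
  not for long sequences.
* Channel selection and CSP are fit on the full dataset before
  cross-validation (the evaluation protocol the package reproduces);
  per-fold refitting of the whole chain would give more conservative
  estimates.
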