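---
title: "Single-trial ERP estimation by classifier inversion: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial ERP estimation by classifier inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Event-related potentials (ERPs) are stimulus-locked voltage deflections
buried in ongoing EEG at signal-to-noise ratios that are often strongly
negative. The classical remedy — averaging hundreds of trials — destroys
exactly the trial-to-trial variation in component **amplitude** (µV) and
**latency** (ms) that many cognitive questions are about. `erptrial`
estimates both descriptors for *single* trials.

The idea is to recycle a detector. A binary classifier is trained to tell
spontaneous EEG from ERP-bearing EEG at the level of a single
*point-sample* — the vector of potentials across a small electrode region
at one time point. Once trained, the classifier is not just a detector:
its distance-to-boundary is a continuous measure of "how spontaneous"
any channel-vector looks, and the two ERP descriptors can be recovered by
asking *where* the epoch looks least spontaneous (latency) and *how much
template must be subtracted* before it looks spontaneous again
(amplitude).

## The generative model

An epoch is modelled as a rank-one component on top of spontaneous EEG:

$$E_{d \times t} \;=\; \sigma\, s(\tau) + X_{d \times t},
  \qquad d \in \Omega,$$

where $\Omega$ is a brain region (electrodes a few centimetres apart,
over which the component is taken as identical), $X$ is spontaneous EEG,
and the component waveform is a monophasic Gaussian template

$$f(t) = \exp\!\left(-\frac{(t-\tau)^2}{2\theta^2}\right),$$

with latency $\tau$, amplitude $\sigma$ and fixed width $\theta$. Within
a prudently chosen analysis window a single component is present, so only
two numbers per trial are unknown.

**Width units.** `theta` is expressed in samples throughout the API, and
the template converts times to sample units internally, so the shape is
sampling-rate invariant. The *default study* sets the width to 8 ms
(`theta_ms = 8`, about 2 samples at 256 Hz). Three considerations fix
this choice: an 8 ms-SD Gaussian has a FWHM of about 19 ms, which is what
an N170 deflection actually looks like (a 31 ms SD bump would span most
of a 200 ms epoch); the training window 162–178 ms is then exactly
$\tau \pm \theta$, which is how the near-latency window is meant to
scale; and with the wider interpretation the latency objective is
provably unidentifiable near the epoch edge (see *Window geometry*
below), so no estimator could reach single-sample precision.

## The classifiers and the distance $\Delta$

Three interchangeable back-ends are provided, each exposing the same
scalar $\Delta(x, Z)$ through `distance()` — positive for
spontaneous-looking vectors, zero on the decision boundary, strictly
increasing in the predicted probability of the spontaneous class:

* **Logistic regression** (`train_logistic`): maximum-likelihood fit;
  $\Delta = w^\top x + b$, the logit. If the training data are separable
  the MLE diverges and a lightly ridge-penalized fit is used, flagged in
  the model metadata.
* **MLP** (`train_mlpnn`): single-hidden-layer perceptrons with
  skip-layer (input-to-output) connections, trained by batch BFGS on the
  cross-entropy loss with L2 decay. $\Delta$ is the log-odds of the
  positive output. Skip connections nest the logistic solution inside
  every candidate, so added capacity can only refine, not forfeit, the
  linear baseline — which matters at low SNR, where heavy decay shrinks
  the net toward its linear part. Structure (2/4/8/16 hidden units),
  decay (0.01/0.1/1) and restarts are selected on the validation split,
  with chunked early stopping on validation accuracy; ties break toward
  fewer weights. Features are standardized internally.
* **SVM** (`train_svm`): Gaussian-kernel soft-margin machine;
  $\Delta$ is the signed decision value oriented
  positive-toward-spontaneous. When not supplied, the kernel width is
  tuned around the median pairwise distance and the cost over
  $\{0.1, 1, 10\}$ on the validation split.

The estimators only ever call `distance()`, so anything trained — or a
hand-built `linear_classifier()` — plugs in.

## The two-step estimator

**Latency.** Temporal resolution makes $\tau$ a discrete variable, so
the search is exhaustive over all sample times in a plausibility window
(default 130–200 ms for an N170):

$$\hat\tau = \arg\min_\tau \sum_{t \in T^-(\tau)} \Delta(E(t), Z),$$

where $T^-(\tau)$ holds the samples within `t_minus_halfwidth` samples
(default `round(theta)`) of the candidate. Near the true latency the
point-samples look least spontaneous, so the summed distance dips there.
Ties break toward the earliest candidate, and the full objective trace is
returned for inspection.

**Amplitude.** With $\hat\tau$ fixed, subtracting the right amount of
template should leave a residual indistinguishable from background. The
far window $T^+$ (post-stimulus samples more than `t_plus_margin`
samples from $\hat\tau$, default $2\,\theta$) provides the trial's own
reference level $D$ — the mean distance of its genuinely spontaneous
samples. The estimate solves, by bounded scalar minimization,

$$\hat\sigma = \arg\min_{\sigma}
  \sum_{t \in T^-}\bigl[\Delta(E(t) - \sigma f(t-\hat\tau)\,\mathbf{1},\, Z) - D\bigr]^2 ,$$

over `amplitude_bounds` (default 0–30 µV, covering the 3–15 µV study
range with headroom) at tolerance `tol` (default $10^{-4}$ µV). A
config switch (`objective = "pooled"`) replaces the per-point squared
deviations by the squared deviation of the pooled sum, for comparison;
the per-point form is the default because the approximation
"$\Delta(X(t), Z) \approx D$" is a statement about each residual sample.

### Window geometry and edge handling

Everything is nearest-sample, half-open, ms-denominated: a 200 ms epoch
at 256 Hz holds $\lceil 200 \cdot 256/1000\rceil = 52$ samples, the last
at 199.2 ms. Candidates near the epoch end would have truncated near
windows, making their sums incomparable; each missing sample is imputed
with the candidate's far-window mean $D$ (the same assumption the
amplitude step rests on: far-from-latency samples score about $D$). A
`truncate` option keeps the raw truncated sum instead. With the 8 ms
template this is a one-to-two-sample correction; with much wider
templates no edge rule rescues identifiability — the deterministic part
of the objective is flat over tens of ms — which is the measured reason
the width is not interpreted in samples in the default study.

### The amplitude objective is only locally identified

For an affine $\Delta$ the amplitude objective is an exact quadratic.
For a nonlinear classifier, a grossly overshot $\sigma$ produces residual
vectors far outside the training distribution, and nothing pins their
score: empirically the net scores such extreme vectors near $D$ (they
resemble high-amplitude bursty background), opening a spurious basin at
the upper bound. `estimate_amplitude()` therefore takes the *first*
basin of the objective scanned upward from the lower bound — the
smallest amplitude whose residual looks spontaneous — located on a
0.5 µV grid smoothed with a 3-point moving average (so one-point noise
dimples on a steep descent are not mistaken for basins) and refined by
Brent's method. For any affine distance the first basin *is* the global
minimum, so the oracle equivalences in the test suite are untouched. A
flat objective (degenerate classifier) returns the lower bound with a
warning.

## Reference estimators

* **Woody filter** (`woody_filter`): the classic iterate — grand
  average, per-trial cross-correlation alignment within the search
  window, re-average — until lags settle (0.5 samples by default, at
  most 20 iterations). Single-channel by construction; one channel
  stands in for the region.
* **SingleTrialEM** (`single_trial_em`): the earlier joint objective
  combining a data-fidelity term over $T^+$ with the summed residual
  distance over $T^-$, minimized by alternating exact minimization
  (exhaustive in $\tau$, bounded scalar in $\sigma$) from $\sigma = 0$.
  The fidelity term equals $\sigma^2 |\Omega| \sum_{T^+} f^2$ and pulls
  amplitudes toward zero — the simulation reproduces its systematic
  underestimation. With the fidelity term off and $D$-centering on, its
  amplitude step coincides with the proposed estimator's
  (regression-tested).

Both consume the same study objects, so a three-method comparison is one
`run_pipeline()` call with `methods = c("proposed", "em", "woody")`.

## The synthetic spontaneous-EEG generator

Real resting-state EEG is not redistributable inside a package, so the
study conditions are defined by a generator (`noise_model()`,
`generate_spontaneous()`) with these ingredients:

* **1/f colored Gaussian noise** (`spectral_exponent = 1`), the
  canonical broadband EEG background slope; an exponent of 0 gives white
  noise for calibration tests.
* **Cross-channel correlation 0.3** via a shared source, typical for
  electrodes a few cm apart within one region.
* **Per-trial amplitude heterogeneity** (`trial_std_spread = 0.6`): each
  trial's noise is scaled by a unit-RMS lognormal factor, so one-sigma
  trials are ~1.8× quieter or louder than the median. Resting EEG is
  bursty (alpha waxing/waning, arousal drift), and this matters
  qualitatively: under *homogeneous* Gaussian noise no single noise
  level can make a weak 3 µV component detectable at ~65% while holding
  a 15 µV component near 90% — the required accuracy-quantile ratio
  exceeds even a Cauchy's. Scale mixing is the simplest mechanism that
  reproduces the full accuracy-versus-amplitude profile of real
  recordings.
* **Per-epoch DC drift** (±1 µV uniform), because spontaneous EEG is
  only approximately zero-mean.
* **Pooled channel std 7 µV**: calibrated analytically (not by running
  the tests) so that the Bayes-level accuracy for the 15 µV condition is
  about 90%: with the six training points at template gains
  $f \in \{0.47, 0.76, 0.97\}$ (twice each) and channel-mean noise
  $7\sqrt{(1+3\rho)/4}\,F$ µV, the mixture average of
  $\Phi\!\left(f\sigma / (2 \cdot 0.689 \cdot 7 F)\right)$ at
  $\sigma = 15$ is 0.906, and the whole profile
  (0.65/0.75/0.84/0.91 at 3/6/10/15 µV) matches what such classifiers
  achieve on real resting-EEG superpositions.

What the generator does **not** emulate: oscillatory structure (alpha
peaks), heavy-tailed artifact transients, realistic 10-5 montage
geometry and volume conduction, spectral nonstationarity within a trial,
or any nonlinear class structure. One honest consequence shows up in the
tests: under this generator the Bayes boundary between spontaneous and
shifted vectors is essentially linear, so the MLP *matches* logistic
regression (paired differences within two standard errors) rather than
beating it; on real EEG, where the background is richer, nonlinear
classifiers have more to exploit. Passing tests therefore demonstrate
correct mechanics and calibrated statistical behavior under a realistic
noise model — not performance on any particular recording system.

## The simulated study and the paired-click analysis

`default_run_config()` fixes the reference N170 study: 100 trials per
amplitude level $\sigma \in \{3, 6, 10, 15\}$ µV, 4 channels, 200 ms
epochs at 256 Hz, template at $\tau = 170$ ms, 6 point-sample pairs per
trial drawn without replacement from 162–178 ms (widened symmetrically
by one sample per side when the window holds fewer distinct samples than
requested), exact 1:1 class balance, stratified 7:1.5:1.5
train/validation/test split, one classifier per condition. One global
seed fans out to per-stage child seeds (`seed + 10007k`), making every
run reproducible from its config snapshot.

`gating_study()` emulates the P50 paired-click paradigm: 100 ms epochs,
a narrow template (default width 4 samples ≈ 16 ms) at 50 ms, positives
drawn from 0–16 ms and negatives from 42–58 ms of the same epochs, and a
paired two-sided t-test (Wilcoxon on request) on the per-trial amplitude
difference between first (3 µV) and second (1.5 µV) clicks. The two
epochs of a pair share their spontaneous background — clicks follow each
other within well under a second, inside one EEG state — which is what
gives the paired design its power; real pairs share the state only
partially, so the synthetic power is an upper bound. The noise std
defaults to 4 µV: auditory paired-click epochs are far less dispersive
than eyes-closed resting EEG, and the per-trial amplitude spreads this
produces (~1–2 µV) are the ones reported for such tests. Identical
paired lists are degenerate for any location test and are reported as
$P = 1$ with a flag.

## Problem sizes in the test suite

The shipped tests run the full study at 100 trials/condition for the
headline latency check and the three-method ranking, 60
trials/condition across 5 seeds for the monotonicity suite, 50
replicates of the 20-trial gating study, and 200–400 trials for
generator calibration checks — sizes at which the Monte-Carlo error of
each checked quantity is several times smaller than the tolerance it is
checked against, while a full run stays in the minutes range on one
core.

## Known limitations

* Latency at the lowest amplitude (3 µV) is near the information limit:
  an oracle linear distance achieves a mean bias of about −3 ms (failed
  trials scatter over the 130–200 ms grid, whose centre is below
  170 ms), and the trained-MLP estimator tracks that limit. Individual
  simulated studies can exceed a 4 ms mean error at 3 µV by draw of the
  shared noise realization.
* Amplitude estimates are truncated at 0, which inflates the mean for
  small true amplitudes (half-normal folding); the reference tables this
  package emulates show the same effect.
* Only one component per analysis window is estimated; overlapping
  multi-component windows are out of scope.
* EDF/BrainVision readers are not bundled; epochs come in through the
  documented CSV-directory format.
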