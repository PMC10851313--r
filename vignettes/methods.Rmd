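---
title: "Deconvolving continuous reward responses from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving continuous reward responses from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contrerp)
```

## The scientific problem

When feedback arrives continuously -- here, a bar that rises towards an
outcome the participant has bet on -- the brain's response cannot be read
off an ordinary event-related average. Reward-related activity ramps slowly
while the bar approaches the guessed height, and it is superimposed on
transient visual/motor responses at the start and end of the bar animation.
Because these events follow each other within a couple of seconds, their
scalp potentials overlap, and a naive average time-locked to any one of
them is contaminated by the others.

`contrerp` treats the continuous EEG of one participant as a linear
superposition of unknown finite impulse responses ("regression ERPs"):

$$
y_e(t) \;=\; \sum_{k \in \{\text{start, reward, end}\}} \;
\sum_{\ell} x_k(t - \ell)\, \beta_{k,e}(\ell) \;+\; \varepsilon_e(t),
$$

where $x_k$ is the regressor of event class $k$ (1 during modelled times, 0
otherwise, or a parametric modulator), and $\beta_{k,e}(\ell)$ is the
response kernel of electrode $e$ at lag $\ell$. Solving the joint least-
squares problem unmixes the overlapping responses.

The package covers the whole experiment: a behavioural simulator of the
betting task, a forward EEG synthesizer with known injected kernels,
continuous-EEG preprocessing, the penalized deconvolution, and group-level
inference (zero-lag correlation maps, cluster-mass permutation tests,
repeated-measures ANOVA). Because the synthesizer's ground truth is stored,
every analysis step can be validated by parameter recovery.

## The task and its simulator

One session has 6 pre-trial cues x 25 encounters = 150 trials. Each cue is
randomly assigned one outcome distribution (all outcomes are proportions of
the 3-degree bar): two tight Gaussians (SD 0.01) at 1/3 and 2/3 ("high"
predictability), 80/20 and 20/80 mixtures of those ("medium"), and a 50/50
mixture or a uniform on [0.2, 0.8] ("low"). The trial timeline is fixation
(400-600 ms, uniform), cue (1500 ms), response, delay (400-600 ms), bar
animation at 1 degree/s, and a 1000 ms outcome display. Points are
$100\,(1 - |g - o|)$ for guess $g$ and outcome $o$.

Two quantities drive the EEG analysis:

* **Continuous predicted reward.** The moment-to-moment counterpart of the
  points rule: $r(t) = 1 - |g - h(t)|$ with $h(t)$ the instantaneous bar
  height as a proportion, zero outside animations, sampled at 250 Hz. It
  peaks -- at 1 for reachable guesses -- at the *time of maximum possible
  reward*, when the bar matches (or would have matched) the guess. No
  closed form for this signal is printed anywhere we could adopt it from;
  applying the points formula instantaneously is the simplest form
  consistent with a signal that "peaks at maximum possible reward", and the
  functional form is confined to one function
  (`continuous_reward_signal()`) so alternatives are easy to substitute.
* **Expectancy.** For each trial, the mean reward (points/100) obtained on
  that cue's strictly earlier trials. First encounters have no history and
  are flagged `NA`; in the parametric model they enter as 0 after
  mean-centring, i.e. at the average expectancy.

Simulated guesses follow a running-mean tracker: the mean of the cue's
previous outcomes (0.5 before any history) plus Gaussian response noise
(SD 0.05 of bar height, configurable). This is the simplest policy that
reproduces the qualitative behavioural effect -- guesses converge on each
cue's mean outcome, so the guess-outcome distance is ordered by
predictability. Response times are log-normal (median 1.5 s, log-SD 0.3);
only the induced event spacing matters downstream. Out-of-range Gaussian
draws are clipped to [0, 1]; with SD 0.01 this is astronomically rare.

What the simulator does **not** emulate: human learning curves (the tracker
converges faster and more cleanly than people do, which is why the
behavioural ANOVA's F statistic on synthetic data is far larger than any
plausible human effect), response biases, and trial-to-trial strategy
shifts. Tests that pass on this behaviour validate the arithmetic and the
direction of effects, not the psychology.

## The EEG synthesizer

30 scalp channels (fixed 10-20 montage; the montage ships with schematic
2-D coordinates and a distance-based neighbour graph, ~5 cm threshold) plus
two mastoids at 250 Hz. Three deterministic kernels are injected per trial:

* a **reward kernel**: smooth negative ramp
  $-5\,e^{-(\ell/1.6)^2}\,\mu V$ over lags $-4.0$ to $+0.2$ s, aligned to
  the time of maximum possible reward, truncated to samples inside the bar
  animation (so ground truth and model agree on the "modelled times"), with
  a centro-parietal topography peaking at CP2 -- a stimulus-preceding-
  negativity-like configuration;
* biphasic **start/end transients** (0-0.8 s, vertex-maximal), amplitudes
  of a few microvolts, as stand-ins for visual/motor evoked responses.

The reward kernel is scaled per trial by a predictability gain, default
(high, medium, low) = (0.5, 1.0, 1.2): the most predictable outcomes evoke
the smallest anticipatory response. Background noise is stationary Gaussian
with a power spectrum mixing $1/f$ (80% of power, slope $-1$) and white
(20%) components at 10 uV total RMS -- typical broadband scalp EEG
amplitude. Channels are independent; real EEG has strong spatial
correlation, so detection power on synthetic data is optimistic in absolute
terms (the calibration of the permutation test does not depend on this).
Square-pulse artifacts of configurable amplitude can be injected to
exercise the artifact detector. Ocular and myogenic components are not
simulated, and no volume-conduction head model is used.

## Preprocessing

`preprocess()` chains: downsampling to 250 Hz (FIR anti-aliased
decimation), a zero-phase 0.1-30 Hz Butterworth band-pass (4th-order
edges) with a 50 Hz notch biquad, re-referencing to the mastoid average
(after which the mastoids are dropped), and sliding-window artifact
detection (2 s window, 100 ms step, 150 uV peak-to-peak threshold read in
microvolts; every sample of an offending window is flagged, tail windows
included). The zero-phase filter is applied as the squared-magnitude
response of the cascade on a zero-padded FFT grid -- the response that a
forward-backward IIR pass realizes -- which behaves identically in the
passband (verified against `signal::filtfilt` by the filter tests) and
avoids per-channel recursive passes over long recordings.

One consequence matters for interpretation: a 0.1 Hz high-pass attenuates
the very slow reward ramp by roughly 20% and reshapes its tails. The
deconvolution recovers the *band-limited* kernel, as any analysis of
filtered data must. Correlation-based recovery checks are immune to this
scale loss; amplitude comparisons between conditions share it and are
therefore ordered correctly.

## Deconvolution model

The sparse design matrix has one column per (block, lag): stick expansions
over 0-0.8 s for animation start and end, and a reward-aligned block over
$-4.0$ to $+0.2$ s whose columns are nonzero only at samples inside a
trial's animation. The reward regressor window is chosen to cover the
cluster search window used in inference; lags earlier than $-3$ s can only
be populated by guesses near the top of the bar and are typically
unsupported -- the smoothness penalty then extrapolates them flat, and they
carry no inferential weight. Three model variants: `pooled` (one set of
blocks), `condition_split` (every block duplicated per predictability
level, the literal reading of modelling all three events separately per
condition; sharing transients across conditions is available as an option),
and `parametric_expectancy` (pooled blocks plus a reward-aligned block
modulated by mean-centred expectancy).

Artifact-flagged samples are dropped from the regression rows. Coefficients
solve

$$
\hat\beta = \arg\min_b \; \|y - Xb\|^2 + \lambda \|D b\|^2,
$$

with $D$ the block-diagonal first-difference operator (differences never
span block boundaries), via the normal equations and one Cholesky
factorization shared by all electrodes. An explicit conditioning check
turns rank deficiency (e.g. $\lambda = 0$ with unsupported lags) into an
informative error. $\lambda$ is selected per participant by 10-fold
cross-validation over the grid $\{10^2, 10^3, 10^4, 10^5, 10^6\}$; folds
are contiguous blocks of sample rows, not random samples, so that
autocorrelated neighbours of a test sample never sit in the training set;
the fold error is the mean squared prediction error averaged across all
electrodes, and ties are broken towards the larger (smoother) lambda. On
synthetic data at study scale the CV consistently selects $10^4$. An
optional baseline correction subtracts each electrode's mean reward-block
coefficient over $-4$ to $-1$ s.

## Inference

* **Zero-lag correlation**: Pearson r per electrode between preprocessed
  EEG and the continuous reward signal (flagged samples dropped), group
  one-sample t tests with Bonferroni correction 0.05/30. Whether zero-
  reward samples belong in the correlation is ambiguous; both scopes are
  implemented (`all_samples`, the default, and `modeled_only`).
* **Cluster-mass permutation test**: one-sample t at every (electrode,
  lag); clusters are connected electrode sets (montage neighbour graph)
  together with temporal runs over which *every* member is supra-threshold
  with a common sign; the cluster-forming threshold is the two-tailed
  critical t at the map's degrees of freedom (the natural reading of
  thresholding at the 2.5th/97.5th percentile). All maximal such clusters
  are enumerated exactly (a C++ kernel; electrode sets as 32-bit masks),
  and the enumeration is tested against a brute-force oracle over all
  connected subsets x all runs. Mass is $\sum |t|$ over the cluster. The
  null distribution records the maximum mass under 1000 whole-map sign
  flips per participant; a cluster is significant when its mass exceeds
  95% of the permuted maxima, and the reported p is the plain proportion
  of permuted maxima at or above the observed mass (a +1-corrected variant
  is available). Note the enumeration's maximality semantics report
  overlapping clusters (a large brief cluster and a smaller persistent one
  are both maximal); the familywise test uses only the maximum mass, so
  this redundancy costs no validity.
* **Condition contrasts** are paired difference maps through the same
  machinery -- sign-flipping a difference map is exchanging condition
  labels within a participant.
* **Effect sizes**: Cohen's d as mean/SD across participants, either of
  per-participant correlation coefficients or of per-participant cluster-
  mean voltages.
* **Behaviour**: one-way repeated-measures ANOVA on the mean guess-outcome
  distance per predictability, from the explicit sum-of-squares
  decomposition, with partial eta^2 $= SS_P/(SS_P + SS_{sP})$ and
  generalized eta^2 $= SS_P/(SS_P + SS_S + SS_{sP})$ (cross-checked
  against `stats::aov` in the tests).

## Numerical and design choices

* Event times are continuous; sample indices are derived once (`round` for
  event alignment, `ceiling`/`floor` for animation support) and shared
  between the synthesizer and the design-matrix builder, so ground truth
  and model agree exactly on the modelled samples.
* The solver is validated against dense reference solves to 1e-8 relative
  error; with non-overlapping events and $\lambda = 0$ the rERP equals the
  classical epoch average exactly.
* The artifact detector's windowed extrema are computed chunk-wise (an
  exact algorithm when the window is a multiple of the step, the standard
  2000/100 ms case; a direct evaluation covers other settings).
* Thresholds printed in "mV" in descriptions of such pipelines are read as
  microvolts; scalp EEG never reaches hundreds of millivolts.
* Sessions are deterministic functions of their seed; every pipeline run
  is reproducible from its configuration alone and outputs carry a content
  hash of that configuration.

## Validation experiments and their scale

The acceptance script (`scripts/acceptance.R`) and the heavyweight tests
run these experiments at the following sizes, chosen to make each check
decisive while keeping a full run in the tens of minutes on one core:

* **Parameter recovery**: 20 participants x 150 trials, default noise and
  gains, full preprocessing, CV-selected lambda. The grand-average reward
  kernel at CP2 correlates > 0.99 with the injected kernel (threshold
  0.95); the condition-split fit (reward window restricted to the
  supported $-2$ to $+0.2$ s) recovers the amplitude ordering
  high < medium < low by projecting each condition's grand average onto
  the injected kernel map.
* **Overlap correction**: on the same 20-participant set, the deconvolved
  and the naive reward-aligned grand averages at CP2 are both scored
  against the band-limited estimand -- the reward-only response each
  session would produce with noise and transients silenced, passed through
  the same filter chain. Deconvolution beats the naive average (RMSE ratio
  ~1.3 at this scale). The margin is noise-limited: with the default
  kernel geometry the transient contamination surviving naive
  reward-aligned averaging at CP2 is ~0.25 uV RMS, comparable to the
  grand-average noise floor at n = 20; the noiseless overlap test in the
  unit suite, where the bias term dominates, shows the > 2x reduction.
  Two things we learned designing this check: the 0.1 Hz high-pass is
  load-bearing for the regression approach (without it, slow 1/f drift
  leaks into the deconvolution coefficients and its error becomes unstable
  across noise realizations, while epoch averaging over 150 trials cancels
  drift rather well), and the raw injected kernel is not the right
  reference, because every estimate made from filtered data can only
  recover the band-limited kernel.
* **Type-I calibration**: 500 null datasets (reward kernel silenced,
  transients and noise retained), 8 participants with short sessions
  (6 trials), reward window $-1.2$ to $+0.2$ s, fixed $\lambda = 10^4$,
  200 permutations. Session geometry and design factorizations are fixed
  across replicates and only noise is redrawn (a conditional-on-design
  calibration; the permutation test itself is untouched). The
  any-significant-cluster rate lands inside the binomial 95% band around
  0.05. Band-pass filtering is skipped here: it is a fixed linear map
  applied identically to every participant, which commutes with the
  sign-flip null and only adds cost.
* **Correlation topography**: the 20-participant set yields a negative
  group-mean zero-lag correlation peaking at CP2 (mean r around $-0.17$),
  significant under Bonferroni correction.

## Known limitations

* Independent channel noise and deterministic kernels make absolute power
  optimistic relative to real recordings; use the calibration machinery,
  not the synthetic effect sizes, to reason about real-data power.
* ICA-based ocular cleaning is out of scope; the synthesizer produces no
  ocular components, and real data imported through the BrainVision bridge
  should be cleaned beforehand.
* The cluster enumeration supports up to 32 electrodes (bitmask
  representation) -- ample for this montage family, not for high-density
  caps.
* The BrainVision reader/writer covers the multiplexed IEEE-float32
  dialect the package writes, not every variant in the wild.
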