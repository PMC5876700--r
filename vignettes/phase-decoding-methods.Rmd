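---
title: "Methods: phase-encoded SSVEP decoding from 0.5-s epochs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-encoded SSVEP decoding from 0.5-s epochs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvephase)
```

## The decoding problem

A phase-coded SSVEP interface flickers two targets at the same frequency
$f$ (12 or 15 Hz here) with stimulation phases $0$ and $\pi$. The occipital
EEG of a gazing subject resonates at $f$ with a phase offset that tracks the
stimulus phase, but shifted by an unknown subject-, electrode- and
session-specific lag. With epochs of only $n = 256$ samples (0.5 s at
512 Hz) the discrimination has to work from a handful of carrier cycles, so
the decoder never compares an epoch against the absolute stimulus phase:
every feature is either learned from training epochs of the same recording
(families II–IV) or fed to a classifier that can absorb a constant rotation
(family I).

## Signal conditioning

Epochs are band-pass filtered (Butterworth, default 5–20 Hz, order 4),
decimated to 512 Hz and cropped to the first 0.5 s after stimulation onset.
Two choices deserve comment:

* **Zero-phase filtering** (forward–backward) is the default. A causal
  band-pass would add a frequency-dependent phase shift; it would be *common*
  to both classes and thus harmless for binary discrimination, but zero-phase
  keeps the phase features interpretable against the stimulus convention. A
  causal mode (`filter_spec(zero_phase = FALSE)`) is kept for fidelity
  experiments.
* **Decimation without an extra anti-alias stage** is sound only because the
  20 Hz low-pass edge precedes it; `downsample()` refuses non-integer rate
  ratios rather than resampling.

## Feature families

**I — maximum-likelihood carrier phase.** The ML estimate of the phase of a
known-frequency sinusoid in noise is the arctangent of the quadrature
projections,
$$\hat\varphi = \operatorname{atan2}\!\Big(-\!\sum_t r[t]\sin(2\pi f t/f_s),\; \sum_t r[t]\cos(2\pi f t/f_s)\Big),$$
wrapped to $(-\pi, \pi]$. A plain arctangent of the ratio would identify
$\varphi$ with $\varphi + \pi$ — exactly the two classes to be separated — so
the quadrant-aware form is essential, not cosmetic. Phases are reported
relative to a **cosine** carrier; a sine stimulus convention differs by a
constant $\pi/2$ that is irrelevant downstream. Projections are plain Riemann
sums, exact for integer-period epochs (12 Hz: 6 periods in 256 samples). The
estimator is amplitude-invariant and maps $-r \mapsto \hat\varphi + \pi$.

**II — class-template correlation.** Per signal and per phase class, the $k$
training epochs are stacked into $E \in \mathbb{R}^{k \times n}$ and the
right singular vector of the largest singular value is the class template —
the direction of maximal shared energy, which under phase-locked signal plus
independent noise approximates the clean class waveform better than the
plain mean. Templates are unit-norm (Pearson correlation is scale-invariant;
unit norm is numerical hygiene) and sign-fixed so that their correlation
with the class-mean epoch is non-negative — otherwise an arbitrary SVD sign
flip between folds would invert feature polarity.

**III — template phase.** The ML phase of the epoch measured against a class
template $p$: with $q$ the unit-normalised imaginary part of the analytic
signal of $p$ (frequency-domain Hilbert transform, computed in-package),
the feature is $\operatorname{atan2}(-\langle r, q\rangle, \langle r, p\rangle)$.
For a sinusoidal template this reduces exactly to the family-I estimator,
which is the property the tests pin down (to $10^{-3}$ rad, the Hilbert
edge effect on non-integer-period templates).

**IV — one-period segment correlation.** Epochs are folded into
$\lfloor n/x \rfloor$ consecutive non-overlapping segments of one stimulus
period $x = \lfloor f_s/f \rfloor$ and averaged, suppressing activity not
locked to the stimulus. Rounding the period *down* is deliberate: $x = 43$
at 12 Hz would fit only 5 segments into 256 samples, whereas $x = 42$ and
$x = 34$ give the intended 6 and 7 segments. From the training trials'
segment correlation matrix $R[i,j]$, five reference segments per channel are
selected:

1. the column of $R$ whose Pearson correlation with the $\pm 1$ label vector
   is largest in absolute value (sign carries no information for selection);
2. per class, the column holding the **lower-median rank** of the mean
   within-class correlations (diagonal excluded) — the most representative
   exemplar of its class. A "closest to the median of the means" rule sounds
   equivalent but degenerates for even class sizes, where the two middle
   columns are always exactly equidistant from the median; the rank form
   selects the same kind of column without that structural tie;
3. the columns of maximal and minimal standard deviation, computed over each
   column with its diagonal entry excluded (the constant 1 would only damp
   the spread).

Any genuine tie breaks to the lowest trial index with a warning. Selection
is computed **per channel** (5 × 3 = 15 features), which is what the
feature-set dimension dictates.

Feature vectors concatenate families in the order I, II, III, IV; within a
family the signals are Oz, O1, O2 and then the SVD-aligned channel
(families I–III only). Dimensions are 4/8/8/15, so e.g. the combination
{II, III, IV} (C14) has 31 features. Phase features enter the classifier as
raw wrapped angles rather than sine/cosine pairs, preserving those
dimensions; the RBF kernel can represent the induced circular geometry.

## SVD alignment

The three occipital channels of one epoch, $X \in \mathbb{R}^{3\times n}$,
are collapsed into a virtual channel $s_1 v_1$ — the dominant temporal
component scaled by its singular value — which favours the phase-locked
component shared across electrodes. The sign is fixed against the
channel-mean signal (falling back to the first channel, then to a positive
leading coefficient, for degenerate means). Rank-0 input is an error, not a
zero vector.

## LS-SVM classification

The least-squares SVM replaces the SVM's quadratic program with one linear
system: with $\Omega_{ij} = y_i y_j K(x_i, x_j)$,
$K(x,z) = \exp(-\|x-z\|^2/\sigma^2)$,
$$\begin{bmatrix} 0 & y^\top \\ y & \Omega + I/\gamma \end{bmatrix}
\begin{bmatrix} b \\ \alpha \end{bmatrix} =
\begin{bmatrix} 0 \\ \mathbf{1} \end{bmatrix},$$
and the latent output is $f(x) = \sum_i \alpha_i y_i K(x_i, x) + b$. Tests
assert the solution satisfies this system to a relative residual of
$10^{-8}$.

* **Standardisation** (per training fold) precedes the kernel. The feature
  sets mix correlations in $[-1,1]$ with phases in $(-\pi,\pi]$; a single
  shared bandwidth $\sigma^2$ is only meaningful on a common scale.
  Zero-variance columns are dropped with a warning.
* **Posteriors** come from a Platt-style sigmoid
  $P(y{=}+1\mid f) = (1 + e^{Af+B})^{-1}$ fitted on training latents by a
  damped Newton iteration with smoothed targets $(N_+{+}1)/(N_+{+}2)$ and
  $1/(N_-{+}2)$, which keeps the fit finite on separable data; $A$ is
  clamped to $\le 0$ so the posterior is monotone in the latent. This is the
  simplest monotone calibration consistent with using "the classifier's
  confidence" downstream.
* **Tuning** minimises stratified 10-fold CV misclassification over
  $(\log_{10}\gamma, \log_{10}\sigma^2)$ with Nelder–Mead (`optim`,
  `reltol = 1e-4`, at most 200 iterations), initialised at $\gamma = 1$ and
  $\sigma^2 =$ the median pairwise squared distance of the standardised
  features — the standard RBF heuristic — and clipped to $[10^{-3}, 10^6]$.
  The CV error surface is piecewise constant, so exact ties are common; a
  vanishing penalty ($10^{-9}$ on $\log_{10}\gamma$, $10^{-12}$ on
  $\log_{10}\sigma^2$) makes the search prefer stronger regularisation and
  smaller bandwidth among equals, keeping selection deterministic.

## Evaluation protocol

Binary decoding uses a stratified 5-fold outer CV; all fitted artifacts —
templates, reference segments, scaler, tuned classifier — are re-estimated
per fold from training trials only (a poisoning test corrupts held-out
trials with NaN and asserts the artifacts are unchanged). The combination
sweep C1–C15 shares one fold assignment so accuracies are paired across
combinations, and analyses run per subject, matching the strong inter-subject
phase variability the features are designed around.

Four-target decoding trains one binary pipeline per frequency; a test trial
is featurized under both frequency assumptions and the classifier with the
higher posterior confidence, $\max(p, 1-p)$, contributes its frequency and
phase prediction. Features extracted under the wrong frequency assumption
correlate poorly with that frequency's templates, so the wrong classifier
sits near its calibration midpoint. Exact confidence ties (probability zero
in floating point) break to the lower frequency, deterministically, with a
warning. The 4-class CV stratifies over all four cells.

Group comparisons use the paired two-sided Wilcoxon signed-rank test with
zero differences dropped; up to 25 non-zero differences the null is computed
exactly by a convolution over the (tied) signed ranks — equivalent to
enumerating all $2^n$ sign assignments and exact under ties — otherwise the
tie-corrected normal approximation is used. The Bonferroni threshold is
$0.05/m$ for $m$ comparisons, applied strictly.

## The synthetic generator

No public recording matches this stimulation design, so the package ships a
generator whose defaults mirror the study conditions: 3 channels, 512 Hz,
0.5-s epochs, targets $\{12, 15\}\,\text{Hz} \times \{0, \pi\}$, 15 trials
per target per subject (60 in total, 30 per frequency).

Each channel carries
$g_c\big[\cos(2\pi f t + \varphi + \ell_c) + 0.3\cos(2\pi\,2f\,t + 2(\varphi + \ell_c))\big]$
plus noise. The cosine convention makes the family-I estimator recover
$\varphi$ exactly in the noiseless case, which is what makes the
construction testable; a sine stimulus merely shifts all phases by $\pi/2$.
The second harmonic at 0.3 relative amplitude reflects the typical SSVEP
harmonic content; per-subject lags are uniform on $(-\pi, \pi]$ with
$\pm 0.2$ rad per-channel jitter, emulating the reported inter-subject and
inter-electrode phase dependence without claiming a literature value, and
channel gains (1, 0.85, 0.9) mimic mild electrode differences.

Noise is Gaussian, synthesized in the frequency domain with a $1/f$ power
profile (80%) plus a flat component (20%), both confined to the 5–20 Hz
analysis band — the band the decoder sees after preprocessing. Synthesizing
in the frequency domain avoids IIR edge transients, which would contaminate
a 256-sample epoch, and makes the SNR definition exact: the noise is scaled
so that the evoked-to-noise power ratio in the analysis band equals the
configured `snr` (at `snr = 0` the evoked part is absent and the noise keeps
the nominal signal power). A projection-based estimate of the realized SNR
(least squares onto the carrier and harmonic pairs) runs about 15% above the
configured value because the projection also captures the noise energy in
those four dimensions; the test suite checks agreement within 20%.

What the generator does **not** emulate: volume conduction and realistic
channel covariance, eye blinks and other artifacts (the corresponding
corrections are out of scope), latency jitter of the evoked response, and
non-stationarity within an epoch. Passing the end-to-end tests therefore
shows the pipeline is correct and well-conditioned under the stated signal
model, not that the reported accuracies transfer to any particular
recording.

## Problem sizes and determinism

The end-to-end checks simulate 21 subjects per condition for binary decoding
(the study's cohort size) and 3 (noiseless) plus 9 (SNR 10) subjects for the
4-class decoder, sizes at which the full analysis runs in about a minute on
a single core. Every stochastic step — generation, fold assignment, label
permutation — flows from an explicit integer seed, and seeded runs are
bit-reproducible; `generate_trial()` and `stratified_folds()` restore the
caller's RNG state.

## Known limitations

* The binary features are deliberately frequency-specific; the 4-class
  arbitration rests entirely on the posterior confidence gap. Under heavy
  noise, both classifiers drift toward their calibration midpoints and the
  frequency decision degrades faster than the phase decision — consistent
  with the view that joint frequency–phase decoding needs a dedicated
  frequency feature or a prior frequency-selection step.
* Posterior calibration on small training folds (24 trials) is coarse; the
  smoothed-target sigmoid is robust but its absolute probabilities should
  not be over-interpreted.
* The exact Wilcoxon null is computed for up to 25 non-zero differences;
  beyond that the tie-corrected normal approximation (without continuity
  correction) takes over.
* `read_dataset()`/`write_dataset()` use a plain-text container designed for
  transparency and diffability, not bulk storage.
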