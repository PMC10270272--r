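---
title: "Cardiodynamicsgram analysis: model, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiodynamicsgram analysis: model, conventions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiodyn)
```

## The problem and the method

Resting 12-lead ECGs read by eye are insensitive to stable coronary artery
disease: most patients with significant stenosis have an unremarkable
tracing. The cardiodynamicsgram (CDG) tries to extract a more sensitive
marker from the same recording by looking not at ST-T *amplitudes* but at
the beat-to-beat *consistency of ST-T dynamics*. The chain implemented
here is:

1. **Denoise** the 12-lead ECG (mains notch, baseline drift, EMG).
2. **Kors transform** the eight independent leads (I, II, V1--V6) to an
   orthogonal 3-lead vectorcardiogram (X, Y, Z).
3. **Fiducials**: locate R peaks, J points, T apices and T ends; cut the
   repolarization segment (J point to T end) of every beat and resample it
   to L points, giving one 3-D *ST-T loop* per beat.
4. **Deterministic learning**: train a radial-basis-function (RBF) network
   to reproduce the per-step state change of the concatenated loop orbit;
   evaluate the learned dynamics along the orbit. The N = n_beats x L
   3-D outputs are the CDG trajectory.
5. **Heterogeneity indices**: summarise the trajectory by a spatial index
   (SHI, a Lyapunov-style mean log divergence rate) and a temporal index
   (THI, the minimiser of an exponentially damped Fourier objective).
6. **Classifier**: the CDG value is the frozen linear score
   `-0.0556*THI + 30.8131*SHI - 2.7719` (version tag `paper-2023`);
   scores at or above 0 are called positive.
7. **Cohort evaluation**: label patients by composite reference standards
   (CCTA stenosis cut OR CT-FFR cut), and report confusion metrics, ROC
   AUC and the Spearman association between CDG value and CT-FFR.

The intuition for step 4--5: if every beat repolarises the same way, the
learned dynamics along each beat's loop is the same, the trajectory is a
tight repeating figure and nearest-neighbour divergence (SHI) is small.
Beat-to-beat repolarization dispersion makes the per-beat segments
disagree, which SHI picks up as divergence.

## Model details and the conventions we had to pin

### Filtering

Zero-phase (forward-backward) filtering so fiducial timing is unbiased:
a second-order Butterworth high-pass at 0.5 Hz, a fourth-order low-pass at
45 Hz, and an RBJ biquad notch at the mains frequency (default 50 Hz,
quality factor 30). The high-pass stage is fixed at order 2 because at
0.5 Hz / 1 kHz the normalized cutoff is 1e-3 and higher-order designs are
numerically fragile. Signals are odd-extended by 2 s at each edge before
each pass and each pass starts at its DC steady state, which removes
settling transients from the record interior. A narrow notch still rings
for a few hundred milliseconds *at the record boundaries* under any edge
rule; attenuation figures in the tests are therefore measured with the
first and last second excluded. Steady-state mains attenuation is below
1e-5 in amplitude.

### Fiducials

The detector is Pan-Tompkins-style on the VCG magnitude (band-pass 5--15
Hz, derivative, squaring, 150 ms integration, adaptive relative threshold,
200 ms refractory), refined to the raw-magnitude maximum. All thresholds
are relative, so detection is invariant to amplitude scaling. The J point
is the first sample in R+20..R+80 ms where the magnitude slope stays below
5% of the QRS slope for 10 ms (fallback R+40 ms). The T end uses the
tangent method on the dominant T lead, crossing the *local baseline*
estimated from the TP segment (the raw zero line is biased after
high-pass filtering because the mean of the beat is removed). Beats whose
repolarization window is clipped by the record edge are dropped. Indices
are 1-based and segments inclusive, the R convention.

### Deterministic learning

Kernels are Gaussians `exp(-d^2 / width^2)` truncated at three widths
(exactly local), centred on a regular lattice covering the loop bounding
box expanded by one spacing; default spacing is 1/5 of the largest axis
range (about 8 centers along the longest axis) and width 1.5 spacings.
The trainer is a discrete-time observer with a sigma-modified gradient
update:

    xhat(k+1) = xhat(k) - a (xhat(k) - x(k)) + W' S(x(k))
    W        <- W - g S(x(k)) (xhat(k+1) - x(k+1))' - g sigma W

with defaults a = 0.5, gamma = 0.5, sigma = 1e-4, 20 epochs. Two
implementation choices matter and were made on numerical-stability
grounds, not to fit any particular dataset:

* **Normalised adaptation.** `g = gamma / (1 + |S(x)|^2)` by default.
  With overlapping kernels `|S|^2` is O(10) and a plain gradient at
  gamma = 0.5 diverges (the package raises an instability error if you
  ask for it); the normalised update is stable for any kernel overlap.
* **Posterior error pairing.** The weight update uses the one-step-ahead
  error `xhat(k+1) - x(k+1)` together with `S(x(k))`. Pairing the
  regressor with the error it actually produced (series-parallel
  identification) is what makes the update a true stochastic gradient;
  pairing with the stale prior error destabilises on fast-moving orbit
  segments, where a kernel is traversed in one or two steps.

The orbit is the concatenation of per-beat loops with **no inter-beat
blending**: the observer is re-initialised at each loop seam and the
artificial seam step (loop end to next loop start) is never a training
target. The reported dynamics use the time average of the weights over
the final epoch, which removes residual adaptation ripple. Training is
fully deterministic; no randomness enters anywhere in the per-subject
pipeline.

On a noiseless closed limit cycle the learned one-step prediction is
accurate to well under 5% of the mean step; on pipeline-extracted ST-T
loops the residual is typically 10--15% against a least-squares floor of
about 1--2%, dominated by beat-to-beat fiducial variation.

### Heterogeneity indices

**SHI** = mean over usable points of `ln(d_n2 / d_n1)`, where `d_n1` is
the distance from point n to its nearest neighbour j and `d_n2` the
distance between the two images 10 steps later. The bare definition
leaves three things open, pinned as follows (all configurable):

* temporal neighbours within a Theiler window are excluded from the
  neighbour search (default: one loop length L), the Rosenstein
  convention — without it the nearest "neighbour" is almost always the
  adjacent sample on the same orbit and the index measures nothing;
  set `theiler = 0` for the literal reading;
* points whose 10-step image falls off the end are skipped and the count
  adjusted; a coincident nearest neighbour (zero distance) falls through
  to the nearest *distinct* one; non-finite log ratios are skipped;
* SHI is exactly zero on periodic orbits and invariant under scaling and
  translation, which the tests assert, along with equality to an
  exhaustive brute-force implementation to 1e-12.

**THI** = the candidate `lambda` minimising `|F(lambda)| * exp(-0.1 lambda)`.
Whether `lambda` indexes a frequency bin, a frequency in hertz, or
something else is not recoverable from the defining expression, so the
package pins one documented reading: `F` is the magnitude spectrum of the
mean-removed Euclidean norm series of the trajectory, `lambda` an integer
DFT bin index, default grid 1..floor(N/2); an alternative per-axis
averaged spectrum is available (`spectrum_mode = "per_axis"`). Exact ties
break to the smallest candidate. This is a convention of this
implementation, not a claim about the original software; it is frozen by
oracle tests.

### Classifier and evaluation

The shipped decision function is frozen (`paper-2023`): its coefficients
are constants of the method, trained elsewhere on clinical data that is
not distributed. `train_cdg_classifier()` reproduces the *procedure*
(linear-kernel SVM on (THI, SHI)) for research use; it cannot reproduce
those coefficients without that population. Diagnostic percentages are
rounded half-up to two decimals to match clinical-table formatting; a
metric with a zero denominator is reported missing, never 0. AUC is the
empirical (trapezoidal) area, equal to the normalized Mann-Whitney
statistic, with a DeLong or stratified-bootstrap 95% CI.

## The synthetic generator: what it emulates and what it does not

`simulate_ecg()` builds each beat as a sum of per-wave Gaussians (P, Q,
R, S, T) with per-lead amplitudes from one canonical normal-morphology
table, at 1 kHz for at least 20 s (the acquisition conditions of the
study design this package targets), plus a smaller, later repolarization
component (T2) whose per-lead pattern differs from T. T2 is what opens
the vectorcardiographic T loop: with a single shared T wave the "loop"
degenerates to a line traced out and back, per-position dynamics is
two-valued, and no static map can represent it — real T loops are open.
The generator emits exact ground truth: R at onset+210 ms, J at R+40 ms,
T apex at R+240 ms, and the tangent-rule T end at R+360 ms (for a
Gaussian the tangent at the steepest descent crosses baseline exactly two
widths after the apex, so the truth is analytical, not detector-derived).

Dispersion knobs: `stt_jitter` (per-beat multiplicative noise on T
amplitude and width — the parameter the end-to-end monotonicity tests
sweep), `st_shift_mv`, `alternans`, additive noise, and sinusoidal
baseline wander. `simulate_cohort()` draws latent CAD status, CDG values
(class separation `effect`, class SD 1.5, matching the spread of the
published class medians), CT-FFR rank-coupled to the CDG value within
class (so a null `effect` yields AUC 0.5), and stenosis bands from
class-conditional frequencies; standard-1 labeling recovers the latent
class by construction.

What passing these tests does **not** show: that the pipeline's absolute
SHI/THI scale matches the clinical scale of the frozen classifier. The
synthetic generator makes no pathophysiological claim — "CAD-like" is a
labeled convention (elevated jitter plus ST shift) — and synthetic
subjects routinely score positive against the `paper-2023` boundary
because that boundary was calibrated on real recordings. The generator
validates *relative* behaviour (recovery of known fiducials, monotonicity
of SHI and CDG value in dispersion, null/strong-effect AUC brackets), not
clinical calibration. Atrial fibrillation, ectopy and pacemaker spikes
are out of scope by design.

## Problem sizes and runtime

Defaults were chosen as the sizes a desk validation of this design needs:
20 s records at 1 kHz (about 20 beats), L = 100 points per loop, at
least 8 beats per subject, roughly 300--500 lattice centers, 20 training
epochs. A full per-subject run takes on the order of a second; the
dispersion sweep in the acceptance tests (5 levels x 10 seeds) runs in a
few minutes. The SHI neighbour search materialises the N x N distance
matrix, fine for N up to a few thousand trajectory points.

## Worked example

```{r example, eval = FALSE}
library(cardiodyn)

sim <- simulate_ecg(dispersion = dispersion_spec(stt_jitter = 0.2, seed = 42))
out <- run_subject(sim$record)
out$result
autoplot(out$trajectory)

ev <- run_cohort(fixture_cohort(), standard = 1)
ev
tidy(ev)
```

## Known limitations

* WFDB input is not supported in this build; the CSV dialect (one header
  row of lead names, one column per lead, millivolts) is the interchange
  format.
* The THI spectral convention and the deterministic-learning
  discretisation are documented choices among several defensible ones;
  both are isolated behind their module interfaces and frozen by tests.
* The J-point and T-end locators are tuned for sinus rhythm at normal
  rates; extreme tachycardia shortens the repolarization search window
  and can drop beats.
* `run_cohort()` evaluates recorded CDG values against reference labels;
  it does not re-derive CT-FFR or stenosis from images (out of scope).
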