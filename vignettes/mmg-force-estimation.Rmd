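---
title: "Estimating isometric knee-extension force from MMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating isometric knee-extension force from MMG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mmgforce)
```

## The problem

Mechanomyography (MMG) records the low-frequency lateral vibration of
contracting muscle fibers, usually with accelerometers strapped over the
muscle belly. Because MMG amplitude and spectral content track motor-unit
recruitment, it can serve as a noninvasive proxy for muscle force — useful
wherever force must be monitored without a dynamometer in the loop, e.g.
rehabilitation robotics or powered prostheses. `mmgforce` implements a
complete estimation chain for isometric knee extension from three MMG
channels (rectus femoris, vastus lateralis, vastus medialis):

1. **Preprocessing** — zero-phase Butterworth filtering (4th-order 5–100 Hz
   band-pass for MMG, 3rd-order 2 Hz low-pass for force), admission of a
   6-s force segment whose relative fluctuation is below 5 %, and sliding
   windows of 1000 samples with 100-sample overlap (step 900).
2. **Features** — 25 features per channel and window: 7 time-domain (RMS,
   kurtosis, SD, SSC, MAV, ZC, WL), 2 spectral (MPF, MDF), 9
   time–frequency (total and per-band energies of a 3-level wavelet-packet
   decomposition), and 7 nonlinear-dynamics (LZC, SampEn, ApEn, FuzzyEn,
   DistEn, box-counting FD, largest Lyapunov exponent) — 75 features per
   3-channel window.
3. **Feature selection** — gray relational analysis (GRA): the relational
   degree $r_i \in (0,1]$ measures how closely each feature sequence tracks
   the force sequence; thresholded combinations A–E (0.60/0.75/0.80/0.85/
   0.90) nest by construction.
4. **Regression** — $\varepsilon$-SVR with RBF kernel
   $\exp(-\lVert u-w\rVert^2 / 2\sigma^2)$, the penalty $C$ and width
   $\sigma$ tuned over $[0.001, 500]^2$ by an improved cuckoo search (ICS).
5. **Evaluation** — repeated 90/10 shuffled splits; RMSE, MAPE and Pearson
   R, reported as mean ± SD over repetitions.

## Gray relational analysis

With force reference $F(k)$ and feature sequences $x_i(k)$, the difference
is $\Delta_i(k) = |F(k) - x_i(k)|$ and the relational coefficient

$$\xi_i(k) = \frac{\min_i\min_k \Delta_i(k) + \rho\,\max_i\max_k \Delta_i(k)}
                  {\Delta_i(k) + \rho\,\max_i\max_k \Delta_i(k)},$$

with the degree $r_i$ the mean of $\xi_i(k)$ over $k$. The resolution
coefficient $\rho$ defaults to the customary 0.5 (any value in $(0,1)$ is
accepted; discrimination is sharpest for $\rho \le 0.5463$). Because
$\Delta$ compares raw magnitudes, GRA is computed on Z-scored sequences —
features *and* force share a scale; without that, the difference sequence
is dominated by whichever feature has the largest units. Degrees are
computed per dataset; when several subjects or sessions are analyzed, run
the analysis per dataset and compare rankings rather than pooling, since
pooling mixes between-subject scale differences into $\Delta$.

## The improved cuckoo search

Plain cuckoo search (CS) moves each nest by a Lévy flight scaled by the
distance to the current best,
$X_i^{t+1} = X_i^t + a_0\,\phi\mu|v|^{-1/\beta}(x_i^t - x_{best}^t)$, with
$\mu, v \sim N(0,1)$ and Mantegna's scale
$\phi = \{\Gamma(1+\beta)\sin(\pi\beta/2) /
[\Gamma((1+\beta)/2)\,\beta\,2^{(\beta-1)/2}]\}^{1/\beta}$
($\phi(1.5) \approx 0.6966$), and re-seeds nests discovered with
probability $P_a$ by a biased random walk toward the difference of two
random nests. The improved variant changes two things:

* **Tent-chaotic initialization.** Initial positions come from iterating
  the Tent map $x \mapsto 2x$ ($x \le 1/2$), $2(1-x)$ (else), mapped
  affinely onto the bounds. The Tent map's invariant density is uniform,
  and short orbits spread more evenly than i.i.d. draws. Two numerical
  hazards are handled explicitly: the unstable set $\{0, 1/2, 1\}$ and
  fixed point $2/3$ (iterates within $10^{-12}$ are nudged by $10^{-6}$),
  and the silent mantissa drain by which every double-precision Tent orbit
  collapses to 0 within ~50 iterations (a seeded jitter of $\pm 10^{-9}$
  per step restores ergodicity without perceptibly moving any iterate).
* **Adaptive schedules.** The step control decays from $a_{max} = 0.2$ to
  $a_{min} = 0.001$ along
  $a_0(t) = a_{min} + \tfrac12(a_{max}-a_{min})(\cos(\pi \ln(1+(e-1)t/T))+1)$
  (natural log — the only reading for which $a_0(T) = a_{min}$ exactly),
  and the discovery probability decays quadratically from 0.70 to 0.10 as
  $P_a(t) = P_{a,min} + (P_{a,max}-P_{a,min})((T-t)/T)^2$: wide exploration
  early, fine exploitation late.

Two details of the engine were settled empirically against the repeated-run
statistics of the four 2-D benchmarks (Rosenbrock, Griewank, cross-in-tray,
Schaffer; population 20, 200 iterations, 50 runs): the Lévy proposal
competes greedily against *its own* nest, and the discovery walk is applied
to every nest with a per-coordinate retention mask of probability $P_a$ —
the formulation of the field's reference implementation. The alternative
(random-host comparison, per-nest abandonment) converges one to five orders
of magnitude slower on every benchmark and cannot reproduce the published
behavior of either algorithm. The Schaffer denominator uses the coefficient
0.01; both it and the textbook 0.001 leave the minimum at the origin.

## The SVR model

Features and targets are standardized with scalers fitted on the training
split only (fitting on everything leaks test-set location/scale into
training). The tuning fitness is 5-fold cross-validated RMSE on the
training split, folds fixed by seed, so the fitness is deterministic given
(position, data, seed). The tube width $\varepsilon = 0.01$ on Z-scored
targets is deliberately small: window-level force targets of stable
isometric segments are nearly noise-free, so a wide tube would only blur
the fit. The backing library parameterizes the RBF kernel as
$\exp(-\gamma\lVert\cdot\rVert^2)$; the package maps $\gamma = 1/(2\sigma^2)$
and this mapping is covered by a test. The default tuning budget is 8 nests
and 12 iterations (about 200 fitness evaluations): the 2-D $(C, \sigma)$
CV-loss surface is smooth, and enlarging the budget (compared against
12 nests × 20 iterations) leaves the held-out metrics statistically
indistinguishable. Each evaluation
repetition redraws both the 90/10 split and the optimizer seed, so the
reported SD reflects the full pipeline variability, not just SVR
refitting noise.

## The synthetic generator

No public MMG + force corpus matches the acquisition protocol this package
targets, so the generator produces the study conditions directly: 8 levels
at 10–80 % MVC (MVC 300 N), 6-s trials at 1 kHz, 3 channels. Each channel
is white Gaussian noise shaped by the package's own 5–100 Hz band-pass and
rescaled so its RMS equals `channel_gain * amp_gain(level)`; the defaults
are the affine gain $0.2 + 0.8\,l$ and per-channel factors (1.0, 0.9, 1.1).
Additive white measurement noise has SD 0.05. The force trace is the level
scaled by MVC times $1 +$ a slow sinusoid (0.1–0.3 Hz) $+$ smoothed bounded
noise, with component amplitudes summing to half of `fluctuation_frac`
(default 0.04) so the peak-to-peak excursion stays under the 5 % admission
rule with margin. Nine trials per level yield 54 windows, trimmed to 50, so
the default dataset is 8 × 50 = 400 windows.

What the generator emulates: the monotone amplitude–force relationship that
motivates MMG force estimation, band-limited stochastic waveforms, stable
isometric force with physiological fluctuation. What it does not emulate:
motor-unit firing statistics, fatigue drift, inter-subject variability,
motion artifacts, or any genuine spectral shift with force (the passband is
level-independent by default, which is also what makes the
amplitude-vs-spectral GRA ranking test meaningful). Passing tests therefore
demonstrate that the pipeline recovers force when the assumed
amplitude–force coupling holds — not that it would reach the same accuracy
on human recordings.

## Numerical choices

* **Zero-phase filtering** is applied as the squared Butterworth magnitude
  response in the frequency domain, which is exactly the transfer function
  of forward-backward IIR filtering but avoids its round-off floor: at the
  2 Hz force cutoff (normalized 0.004 at 1 kHz) a direct-form cascade is
  accurate only to ~5×10⁻⁴ relative. Records are padded by symmetric
  reflection (2 s per side) after mean removal; symmetric rather than odd
  reflection because an odd pivot on an oscillating endpoint injects a
  spurious DC step that a 2 Hz filter smears visibly into the data.
* **Welch spectra** use Hann windows of 512 samples with 50 % overlap — at
  the 1000-sample window length this gives ~2 Hz bins, fine enough to place
  MPF/MDF of a pure tone within a bin of its frequency.
* **Wavelet packets** use the 8-tap Daubechies filter (db4), 3 levels,
  periodic extension; terminal nodes are mapped from Paley to frequency
  order by the Gray-code permutation (1 2 4 3 7 8 6 5) so WP1 is always the
  lowest band. Orthogonality makes the band energies an exact partition of
  signal energy, which the tests assert to 10⁻¹⁰.
* **Entropies** use the literature defaults m = 2, r = 0.2·SD; FuzzyEn uses
  Chen's exponential membership exp(−d^n/r) with gradient n = 2 on
  baseline-removed templates; DistEn uses 512 equal-width bins. The
  O(n²) template matching is compiled code; the R test suite checks it
  against direct-definition oracles to 10⁻¹⁰. SampEn with zero matches
  returns +Inf, which feature extraction converts into an explicit error —
  no silent NaN rows.
* **LZC** binarizes at the median and applies the exhaustive-history LZ76
  parse (overlap allowed), normalized by n / log₂ n.
* **Lyapunov exponent** follows Rosenstein: embedding dimension 5, delay at
  the first autocorrelation zero crossing, Theiler window of one mean
  period (from the spectral centroid), slope of the mean log-divergence
  curve over its first 30 steps. For 1000-sample windows longer fit ranges
  run into saturation; the value functions as a relative feature, not an
  absolute dynamical invariant.
* **Windowing arithmetic**: window count is floor((n − length)/step) + 1;
  a 5999-sample record with length 1000 and step 900 holds 6 windows (the
  sixth spans samples 4500–5499).
* **Degenerate inputs** error loudly: constant windows (kurtosis
  undefined), all-zero spectra, zero-variance feature columns (dropped with
  a warning by the scaler), empty combination selections.

## Problem sizes

The shipped tests and the acceptance script run the study-scale protocol:
400 windows (8 levels × 50), 75 features, 10 evaluation repetitions, and
50-run benchmark comparisons at population 20 and 200 iterations. The
pipeline unit tests use a reduced 64-window configuration with a 5×5
tuning budget, which exercises every stage end to end at a fraction of the
cost.

## Known limitations

* The synthetic generator is an amplitude-coded null model; spectral and
  nonlinear features correlate with force only through residual coupling,
  so GRA rankings on synthetic data compress into a narrower band than on
  real recordings.
* GRA degrees depend on the Z-scoring convention; combinations selected at
  the fixed thresholds can be empty on weakly coupled data (an explicit
  error, by design).
* MAPE is undefined at zero force; the implementation excludes zero
  targets with a warning, which matters only outside the isometric
  protocol (targets here are strictly positive).
* The Lyapunov and fractal-dimension estimators are window-scale
  heuristics; treat them as comparable features across windows, not as
  precise invariants.

## Reproducibility

Every stochastic stage takes an explicit integer seed: trial generation
derives per-trial seeds from a master seed, cross-validation folds and
90/10 splits are seed-fixed, and both optimizers record their seed in the
returned trace. `run_pipeline()` writes the resolved configuration next to
its outputs; re-running with the same configuration and seed reproduces
the report byte for byte (asserted in the test suite).
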