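---
title: "Methods: time-varying phase synchronization, tensor communities, and the Kuramoto model on a connectome"
author: "boldsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-varying phase synchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldsync)
```

This vignette is the package's account of its methods: the models and
statistics it implements, the assumptions behind them, the parameters that
matter and their defaults, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the methodology is
genuinely open.

## From BOLD signals to instantaneous phases

The pipeline starts from region-averaged BOLD time series (frames x
regions, sampling period `TR`, 2 s for typical resting-state data). Two
steps turn them into phases:

1. **Band-pass filtering** to a narrow band, default 0.04–0.07 Hz. A
   narrow band is a methodological requirement: the analytic-signal phase
   is only meaningful for signals with a single dominant spectral
   component. `bandpass()` uses a second-order Butterworth section applied
   forward and backward (`signal::filtfilt`), so the net response has
   exactly zero phase — any group delay would corrupt instantaneous
   phases. The effective (squared) magnitude response keeps the band
   centre within 5% and is more than 20 dB down one octave outside either
   band edge; both properties are asserted in the test suite against
   tones.
2. **Analytic signal.** The Hilbert transform is applied through the FFT
   (the standard construction: double the positive frequencies, zero the
   negative ones). Phase is the argument, the amplitude envelope the
   modulus. Because the transform assumes circularity, `trim` frames are
   discarded at each border (default 10, so a 300-frame session keeps
   280). No installed package provides the analytic signal, so it is
   implemented in-package; it is a ten-line FFT identity, verified against
   the closed form for sinusoids (a cosine's analytic signal is
   `exp(jwt)`, a sine lags it by pi/2).

From the phases: the order parameter `R(t)` (mean resultant length of the
unit phasors), the PLV matrix (time-averaged pairwise phasor), the pooled
histogram of pairwise phase differences `Pr(dphi)` over ordered pairs (so
it is symmetric by construction), and the per-frame count `N(t)` of pairs
with wrapped `|dphi| < pi/6` with its histogram `Pr(N)`. All wrapped
comparisons use the interval `(-pi, pi]`, and the synchronization
threshold is a *strict* inequality; the wrapping function passes in-range
values through untouched so that boundary cases (exactly `pi/6`) are not
perturbed by modulo round-off.

**Null models.** Phase-randomized Fourier surrogates keep each region's
amplitude spectrum exactly and draw new Fourier phases uniformly, with
Hermitian symmetry imposed so the inverse transform is real. (The naive
construction without the symmetry constraint would produce complex
series; the Hermitian form is the standard one and is what the package
implements.) Surrogates feed two analyses: the global-synchrony null for
`R`, and the PLV bias correction, which subtracts from each off-diagonal
PLV entry its surrogate expectation (default 1000 surrogates) and floors
at zero. Note that for narrowband signals the PLV bias is set by the
*effective* number of independent samples — roughly `T x bandwidth /
Nyquist`, about 34 for 280 frames of a 0.03 Hz-wide band at TR = 2 s — so
the bias level is near 0.2, much larger than the broadband `T^{-1/2}`
intuition. A degenerate caveat tested explicitly: a pair of pure
same-frequency tones is *not* a valid "locked pair" fixture for the
correction, because every surrogate of a delta-spectrum signal is again a
tone and the pair's surrogate PLV is 1.

**Spectra.** The spectrum of `R(t)` is the mean-removed single-taper
periodogram (`stats::spec.pgram`); the peak frequency is the argmax over
positive frequencies. Welch-style averaging was considered and rejected as
a default: the series are short (280 frames) and the quantity of interest
is the location of a broad low-frequency peak, not its amplitude.

**Amplitude versus phase information.** `amplitude_and_signal_correlations()`
computes Pearson correlations of the narrowband signals and of
`log(A^2)` (the log renders envelope statistics closer to normal;
amplitudes are floored at machine epsilon with a warning since narrowband
envelopes can touch zero numerically). `uncertainty_reduction()` computes
`Delta(y) = MI(r_signal, y)/H(r_signal)` from equal-width histograms with
20 bins spanning each variable's range — a choice tested against a
brute-force joint-histogram oracle and calibrated so that independent
variables at the 2145-pair scale give `Delta < 0.1`.

## Synchronization tensor and community detection

The binary tensor `T(i,j,t) = 1{|dphi_ij(t)| < pi/6}` (diagonal unused and
stored as zero) collects the instantaneous pair synchronizations. Pairs
synchronized in fewer than 20% of frames are zeroed everywhere
(`occupancy_min = 0.2`) — with uniform independent phases a pair sits
below `pi/6` about 1/6 of the time, so the rule removes precisely the
accidental-synchronization floor while keeping genuinely coupled pairs.

`nntf()` factorizes the tensor as a sum of `K` nonnegative rank-one
components by alternating nonnegative least squares with hierarchical
(column-wise) updates, minimizing the squared Frobenius error. Because
every time slice is symmetric the two spatial factor matrices must agree;
the solver first converges with free factors, then ties them by a
rescaled average (geometric mean of the column norms) and continues with
symmetry-constrained iterations, accepting a step only if the objective
does not increase. The returned object always has identical spatial
factors, the best of `restarts` random initializations (default 10), and
records its seed. Scale indeterminacy is fixed by balancing the two
spatial norms and absorbing the remainder into the temporal factors, so
participation weights are reported unnormalized — which is what makes
absolute thresholds on `a_k(i)` (such as the 0.1 used for binarization
against reference maps) meaningful.

Two caveats about interpretation, both exercised in the tests:

- A "community block with the diagonal removed" is *not* a rank-one
  tensor; the best rank-one fit of an off-diagonal-only block of `m`
  regions has `F ~ 0.55` for `m = 5`, not 1. Fit values on real
  synchronization tensors are therefore moderate (0.2–0.5) even when the
  community structure is recovered essentially perfectly — `F` is a
  model-selection statistic here, not a variance-explained summary.
- The strength threshold `s_k > 0.1` used for activation durations
  presumes factor scales like those of the empirical analysis; for
  planted-structure recovery experiments the tests use a half-maximum
  threshold, which is invariant to the factorization's overall scale.

`diffit_select()` computes `F(K)` over a contiguous range (each `K` with
the stated restarts — best-of-restarts, since the selection should compare
models, not initializations) and selects the `K` maximizing
`DIFIT(K) = [F(K) - F(K-1)]/F(K+1)`. That denominator is implemented
exactly as stated even though the conventional difference-in-fit statistic
divides by the *next increment* `F(K+1) - F(K)`; the conventional form is
available via `conventional = TRUE`. On the curves produced by planted
tensors both forms select the planted `K`; the printed form is kept as the
default for fidelity. Ties break to the smallest `K` with a warning.

Communities are compared by Pearson correlation of the membership vectors
`a_k` (not their outer products — the vectors are the lower-dimensional,
more interpretable representation), clustered with average linkage on
`1 - r`, and summarized by the cophenetic correlation. Jaccard similarity
against binary reference maps uses the 0.1 binarization threshold. The
permutation null for the best model-to-reference match permutes the `n`
region entries of each reference community (1000 draws) and takes the
95th percentile of the null's largest correlation.

## The synthetic-data generator

`generate_synthetic_bold()` is the ground-truth engine for the whole
pipeline. Each region carries a phase that advances at its own frequency
(drawn uniformly in the band), diffuses under per-frame Gaussian jitter,
and, while a planted community is active, is pulled toward that
community's carrier phase by a fraction `coupling` of the wrapped gap per
frame (pull applied after the jitter, so `coupling = 1` locks exactly).
The signal is the cosine of the phase plus white noise. Design choices,
made once:

- **Epochs**: piecewise-constant on/off with exponential durations, mean
  12 s on (the empirically observed activation timescale) and 24 s off.
  The off-mean keeps the expected number of simultaneously active
  communities near one, which is what the empirical synchronization
  matrices look like (one community or a superposition of few).
- **Phase jitter** (`phase_noise_sd = 0.8` rad/frame): the mechanism that
  *dissolves* a community once its epoch ends. Without it, members would
  coast on coherently after the pull stops and the planted epochs would
  not mark the synchronized periods — the ground truth would be wrong,
  not merely noisy.
- **A common carrier with spread offsets.** All communities ride one
  band-centre carrier frequency with fixed per-community phase offsets
  spread over `[0, pi/2]`. A common frequency means no beating between
  community carriers, so fluctuations of global synchrony are
  attributable to the planted activations; offsets wider than the `pi/6`
  tensor threshold keep co-active communities from merging into one
  clique, while offsets under `pi/2` keep concurrent activations adding
  (rather than cancelling) in the order parameter.
- **What it does not emulate**: hemodynamics (no HRF convolution),
  scanner drift and physiological artifacts, amplitude dynamics (unit
  envelopes by construction), and spatially correlated noise. Passing
  tests on this generator therefore demonstrates that the *pipeline*
  recovers planted phase-synchronization structure under realistic
  timing, band, and noise conditions — not that real BOLD data contains
  such structure.

A timing consequence worth stating: the 0.04–0.07 Hz band-pass has an
impulse response of roughly `1/bandwidth ~ 30 s`, so 12 s epochs are
detected (memberships, strengths, selected `K` are all recovered at the
defaults) but their *edges* are smeared; frame-accurate epoch overlap is
only achievable when epochs outlast the filter response, which is why the
epoch-overlap test plants 60 s epochs.

`generate_synthetic_connectome()` plants block-modular structure with
log-normal weights (tractography fiber densities are heavy-tailed),
directed, zero diagonal. The weights are *not* normalized: for Kuramoto
experiments the tests scale `weight_scale` so that mean row strength is
near 1, which puts the interesting coupling range on a convenient `G`
grid — the same role the region-count normalization plays for the
empirical connectome.

## The Kuramoto model and its controls

`simulate_kuramoto()` integrates

d&phi;<sub>i</sub>/dt = &omega;<sub>i</sub> + G &Sigma;<sub>j</sub> C<sub>ij</sub> sin(&phi;<sub>j</sub> &minus; &phi;<sub>i</sub>) + &sigma;&xi;<sub>i</sub>(t)

with explicit Euler at `dt = 0.01` s (Euler–Maruyama increment
`sigma*sqrt(dt)*N(0,1)` when noisy; `sigma` in rad/sqrt(s), reading the
noise as a delta-correlated process of intensity `sigma^2`). Units are the
only self-consistent reading of "0.04–0.07 Hz" oscillators with a "10 ms"
step: `omega_i = 2*pi*f_i` rad/s, so the default run of 1.2e6 steps
simulates 12,000 s and discards a 5,000 s transient. Row `i` of the
connectome collects couplings *incoming* to oscillator `i`, which is the
orientation the equation states; conduction delays are neglected (signal
periods of ~20 s dwarf axonal delays of tens of milliseconds). Phases are
sampled every 2 s by default so model statistics are directly comparable
to TR-sampled data; this choice matters for spectral estimates of `R` and
is configurable.

The integrator is compiled (RcppArmadillo) because the inner loop runs
~10^6 steps of two matrix–vector products; noise draws come from R's RNG
so `set.seed` governs everything. Correctness anchors, all in the test
suite: decoupled oscillators integrate their phases exactly; a global
phase shift translates deterministic trajectories exactly; the
two-oscillator system locks precisely above the Adler boundary
`G = dw/2`; halving `dt` changes mean `R` by less than 1e-3.

The four variants map onto the mechanistic question "what produces
transient synchronization?": heterogeneous-on-connectome (the model
proper), shuffled-connectivity (destroys topology, keeps weights — plain
i.i.d. resampling of the off-diagonal weights, with no row/column-sum
preservation), homogeneous (destroys heterogeneity — collapses into full
synchrony at any appreciable coupling), homogeneous-noisy (replaces
deterministic heterogeneity with stochastic forcing). In the metastable
range the model's `R(t)` fluctuates at least an order of magnitude below
the oscillator band, mirroring the ultra-slow empirical fluctuations.

## Scoring model against data

`kl_divergence()` is computed in nats with the model histogram floored at
`eps = 1e-10` and renormalized — bins where the model is empty contribute
a large finite penalty, never infinity. Similarities `1/D_KL` are capped
at `1/1e-6` so coincident distributions remain plottable, and each
similarity profile is normalized to the maximum of the reference
(heterogeneous) model's profile, each statistic independently. `Pr(N)`
histograms are rebinned to 50 equal-width bins before KL so model and
data share a support. PLV agreement is the Pearson correlation of
upper-triangle entries with a Fisher-z 95% interval.

No single scalar "best G" is defined (the methodology reports ranges, and
any weighting of the four criteria would be arbitrary): `run_model_fit()`
reports each criterion's argmax and the intersection of their top-quartile
`G` sets. The package-level validation of the harness is a recovery
experiment: data simulated at a known `G*` on a synthetic connectome, swept
over a five-point grid — every criterion's argmax lands within one grid
step of `G*`.

## Problem sizes and determinism

The test suite and the acceptance script run on deliberately scaled-down
problems — 12–30 regions, 150–300 frames, simulations of 1,000–12,000
model seconds, 2–5 restarts, 5-seed Monte-Carlo — sizes chosen so the
whole suite completes in well under a minute per module on one CPU while
leaving every statistic far from its decision boundary. Every stochastic
stage takes an explicit integer seed, recorded in the returned objects and
manifests; reruns with the same configuration are bit-identical, which the
suite asserts.

## Known limitations

- The NNTF solver is HALS-based alternating nonnegative least squares;
  it optimizes the same objective as block-principal-pivoting solvers but
  can differ in iteration path, so only seed-for-seed reproducibility
  within this package is guaranteed, not across solvers.
- `F(K)` from best-of-restarts is monotone in `K` only up to optimizer
  noise (the tests allow 1e-3).
- The empirical-data acceptance checks require the deposited dataset and
  a structural connectome supplied by the user; they are not
  redistributable with the package.
- Phase statistics assume the narrowband regime; the package deliberately
  offers no wavelet/time-frequency phase estimation and no global-signal
  regression.
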