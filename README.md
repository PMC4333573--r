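# boldsync

Time-varying phase synchronization of resting-state BOLD signals, and the
Kuramoto-on-connectome model that explains it.

Resting-state fMRI activity is not stationary: the coherence between brain
regions waxes and wanes, with communities of regions that transiently
synchronize, dissolve, and reoccur. `boldsync` implements an analysis
pipeline for region-averaged BOLD time series that quantifies this
phenomenon through instantaneous phases, and a mechanistic phase-oscillator
model on the structural connectome that reproduces it.

## What the package computes

**Phase statistics.** Signals are band-pass filtered to a narrow band
(default 0.04–0.07 Hz), and instantaneous phases φ_k(t) and amplitude
envelopes A_k(t) are extracted from the analytic signal
z(t) = a(t) + j·H[a(t)]. From the phases the package computes

- the Kuramoto order parameter R(t) = |Σ_k e^{jφ_k(t)}| / n — the global
  level of synchrony (R = n^{-1/2} in expectation for independent phases,
  1 at full synchrony) — and the power spectrum of its slow fluctuations;
- the phase-locking value PLV(k,l) = |⟨e^{j(φ_k−φ_l)}⟩_t| for every region
  pair, with a surrogate-based bias correction;
- the distribution Pr(Δφ) of pairwise phase differences and the
  distribution Pr(N) of the number of instantaneously synchronized pairs
  (|Δφ| < π/6);
- phase-randomized Fourier surrogates (amplitude spectra preserved exactly,
  phases randomized under Hermitian symmetry) as the null model of
  accidental synchronization;
- the uncertainty reduction Δ(y) = MI(r_signal, y)/H(r_signal), comparing
  how much PLV versus amplitude-envelope correlations tell about the
  signal correlations.

**Synchronization communities.** Per session a binary tensor
T(i,j,t) = 1{|φ_j(t) − φ_i(t)| < π/6} (pairs synchronized for < 20% of
frames are pruned) is factorized by nonnegative canonical (CP)
decomposition, T ≈ Σ_k a_k ∘ a_k ∘ c_k: the spatial factors a_k are the
communities, the temporal factors c_k their activations. The number of
components K is selected by DIFFIT on the goodness-of-fit curve
F(K) = 1 − ‖T − T̂(K)‖/‖T‖. Community strengths
s_k(t) = c_k(t) Σ_i a_k(i) and their total S(t) = Σ_k s_k(t) track the
order parameter. Communities are compared across sessions (correlation,
average-linkage clustering, cophenetic coefficient), against binarized
reference resting-state-network maps (Jaccard index), and against
permutation nulls (largest-correlation bound).

**Kuramoto model on a connectome.** Phases on n = 66 cortical regions
evolve as

    dφ_i/dt = ω_i + G Σ_j C_ij sin(φ_j − φ_i)  (+ σ ξ_i(t))

with C the weighted (directed, zero-diagonal) anatomical connectivity and
G a global coupling gain. Four variants: (1) heterogeneous ω_i estimated
from the data's regional spectral peaks; (2) heterogeneous with the
connectome's weights shuffled (topology control); (3) homogeneous
ω_i ≡ 0.05 Hz (heterogeneity control — collapses to full synchrony);
(4) homogeneous with white phase noise (stochastic control). Integration
is explicit Euler (Euler–Maruyama when noisy) at dt = 0.01 s with a
discarded transient, phases sampled every 2 s to match the empirical TR.
A G-sweep harness scores each coupling against the data: 1/D_KL similarity
of Pr(Δφ) and Pr(N), PLV-matrix correlation, mean-R match, and recovery of
the empirical communities.

**Synthetic data.** Generators for modular, heavy-tailed, directed
connectomes and for region-resolved oscillatory signals with planted,
transiently activated synchronization communities give every stage a known
ground truth, so the whole pipeline is testable without any data download.

## Worked example

```r
library(boldsync)

# synthetic session: 30 regions, 300 frames at TR = 2 s, three planted
# transiently synchronized communities
g  <- generate_synthetic_bold(n = 30, T_frames = 300, sampling_period = 2,
                              n_communities = 3, noise_sd = 0.1, seed = 1)
ph <- analytic_phases(bandpass(g$session, 0.04, 0.07), trim = 10)
ph
#> Analytic phase set: 280 frames x 30 regions (10 frames trimmed per border)

st <- phase_statistics(ph)
st
#> Phase statistics: mean R = 0.5759, R-peak frequency = 0.0104 Hz, 280 frames

tens <- build_sync_tensor(ph)
tens
#> Synchronization tensor: 30x30x280 (threshold 0.5236 rad, 129 pairs pruned
#> at occupancy < 0.2)

sel <- diffit_select(tens, 2:6, seed = 1, restarts = 3)
sel$K
#> [1] 3
dec <- sel$decompositions[[match(sel$K, 2:6)]]
dec
#> Nonnegative CP decomposition: K = 3, fit F = 0.2715 (3 restarts, seed 1)

cs <- community_strengths(dec)
cor(cs$S_series, st$R_series)
#> [1] 0.736
```

The mean order parameter (0.58) sits between incoherence and full
synchrony; the R-peak frequency (0.0104 Hz) is an order of magnitude below
the 0.04–0.07 Hz signal band — global synchrony fluctuates slowly. DIFFIT
selects the planted K = 3 communities, the recovered memberships match the
planted ones (mean best correlation 0.93 on this draw), and the total
community strength S(t) tracks R(t) (r = 0.74): the slow fluctuations of
global synchrony are the intermittent activations of the communities.

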