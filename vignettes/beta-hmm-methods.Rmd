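---
title: "Segmenting band-limited spectral dynamics with a beta-observation HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting band-limited spectral dynamics with a beta-observation HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betahmm)
```

## The model

`betahmm` targets recordings whose spectral content switches abruptly among a
small set of profiles — for example the alternating gamma (25–50 Hz) and
slow-delta (0–4 Hz) oscillations seen in LFP and EEG under dissociative
anesthesia. The observation at window $n$ is the vector
$y_n \in (0,1)^H$ of logistically scaled band powers in $H$ frequency bands.
Conditional on a latent state $z_n \in \{1,\dots,K\}$, bands are independent
beta variables,

$$p(y_n \mid z_n = k) = \prod_{h=1}^{H}
  \frac{y_{nh}^{a_{hk}-1}(1-y_{nh})^{b_{hk}-1}}{B(a_{hk}, b_{hk})},$$

and the state sequence is a first-order Markov chain with initial
distribution $\pi$ and row-stochastic transition matrix $A$. Each marginal is
required to be unimodal: shapes with both $a_{hk} \le 1$ and $b_{hk} \le 1$
would let a single state stand for two different spectral profiles, which
defeats the interpretation of states as profiles. The beta family is the
natural choice for (0,1)-valued data, is an exponential family (so weighted
maximum likelihood in the M-step reduces to two digamma stationarity
equations), and can place its mode anywhere in the unit interval.

### Assumptions worth stating

* **Conditional band independence.** Within a state, bands are modelled as
  independent. Real band powers are correlated (neighboring bands share
  spectral leakage); the HMM absorbs shared structure into the state, and the
  remaining within-state correlation is ignored. This mainly affects
  likelihood magnitudes, not the segmentation, which is driven by the large
  between-state separation.
* **First-order, time-homogeneous dynamics.** Dwell times are geometric and
  the transition matrix is constant over the recording. Slow drifts (e.g.
  changing drug level) are not modelled.
* **Whole-recording scaling.** The quartiles behind the logistic map are
  computed over the entire sequence, so the method is inherently offline.

## Spectral reduction and its parameters

| parameter | default | meaning |
|---|---|---|
| `window_length` | 1 s | multitaper analysis window $\Delta_{MT}$ |
| `overlap_fraction` | 0.9 | consecutive-window overlap; hop = 0.1 s |
| `time_halfbandwidth` | 2 | DPSS concentration half-bandwidth $W$ = 2 Hz |
| `n_tapers` | 3 | Slepian tapers averaged (must be $\le 2NW-1$) |
| `bands` | canonical 7 | slow 0–1, delta 1–4, theta 4–8, alpha 8–12, beta 12–25, low gamma 25–35, gamma 35–50 Hz |

The hop (0.1 s at defaults) is the time unit of everything downstream: one
observation window, one Markov step, and the factor converting durations from
windows to seconds. It is carried in metadata, never hard-coded.

Numerical choices in the spectral stage:

* DPSS tapers are computed from the symmetric tridiagonal matrix whose
  extremal eigenvectors are the Slepian sequences; no external multitaper
  library is used.
* Each window is demeaned before tapering (standard multitaper practice).
  Because the demeaned 0 Hz coefficient is not a PSD estimate, the DC bin is
  excluded from the frequency grid. The FFT is zero-padded to twice the next
  power of two so that narrow low-frequency bands cover several bins.
* Band power is the arithmetic mean of the **dB** values over the bins inside
  the half-open interval $[lo, hi)$ — averaging in dB rather than averaging
  linear power and then converting; the two differ by Jensen's inequality,
  and the dB-domain mean is what the scaling quartiles are computed from.
* Quartiles use linear interpolation between order statistics (R's default
  type 7). With $\lambda_h = 2\log 3 / (Q3_h - Q1_h)$, the median maps to 0.5
  exactly and, for quartile-symmetric bands, $Q1 \to 0.25$ and $Q3 \to 0.75$
  exactly. A band with $Q3 = Q1$ has no usable dynamic range and is a
  reported error.
* Scaled values are clipped to $[10^{-12}, 1-10^{-12}]$: the logistic never
  reaches 0 or 1 analytically, but floating-point underflow can, and the
  log-likelihood requires strictly interior values.

## Estimation

The E-step is the scaled forward–backward recursion; per-window
log-densities are shifted by their row maximum before exponentiation, so
sequences of $10^4$+ windows run without underflow. Multiple recording
sessions are treated as **mutually independent**: each session gets its own
E-step, and the M-step pools sufficient statistics — $\pi$ is the average of
the per-session first-window posteriors, $A$ the ratio of pooled pairwise
posteriors, and each $(a_{hk}, b_{hk})$ the responsibility-weighted beta MLE
over all sessions. Sessions are never concatenated, so no artificial
transition is created at session boundaries.

The weighted beta MLE runs Newton iterations on the digamma stationarity
conditions in $(\log a, \log b)$, starting from weighted method-of-moments
estimates, with step halving to guarantee ascent (gradient-norm tolerance
$10^{-8}$, at most 200 iterations). The unimodality restriction is enforced
by projection: if an update lands with both shapes at or below 1, the larger
is lifted to $1 + 10^{-6}$. The restriction's enforcement mechanism is a
design choice of this package; projection keeps the M-step closed-form fast
and in practice only triggers for nearly-empty states.

Other estimation choices, all open in principle:

* **Initialization**: seeded k-means on the pooled scaled observations,
  method-of-moments shapes per cluster and band, $A = 0.8I + 0.2/K$,
  uniform $\pi$. Clustering mirrors how the validation study constructs its
  ground truth, and lands close enough to the basin of attraction that EM
  converges in a handful of iterations on separable data.
* **Restarts**: 5 by default with consecutive sub-seeds; the best final
  log-likelihood wins and all restart log-likelihoods are reported.
* **Convergence**: relative log-likelihood change below `tol` ($10^{-6}$) or
  500 iterations. The trace is monotone up to arithmetic slack, and this is
  asserted by tests on every fitted object.
* **Empty-state guard**: if a state's total responsibility falls below
  $10^{-3}$, its shapes are carried over from the previous iterate instead of
  fitting to numerical noise.
* **Label convention**: after fitting, states are relabeled by ascending
  beta mean $a/(a+b)$ in the highest band, so "state K" is always the most
  gamma-dominant state across runs; the permutation is recorded. Viterbi ties
  are broken toward the lower state index.

## Post-fit statistics

* `exceedance_probability(a, b)` is $1 - F_{Beta}(0.5; a, b)$: the
  probability that a state's scaled power in a band exceeds the band median.
* `delta_probability()` integrates the density of $\Delta = X_j - X_k$ for
  two independent beta variables over $[-1, 0]$ by nested adaptive
  quadrature (outer absolute tolerance $10^{-4}$; the inner integral's
  piecewise limits follow the support of the joint density, and integrable
  endpoint singularities for shapes below 1 are handled by the adaptive
  rule on the open interval). Identical distributions give exactly 0.5, and
  $\Pr(\Delta_{jk} \le 0) + \Pr(\Delta_{kj} \le 0) = 1$.
* `ks_distance_beta()` has two modes: `"sampled"` (two-sample KS statistic
  from 100,000 draws per distribution) and `"exact"` (sup of the absolute
  CDF difference on a dense grid with local refinement). The exact mode is
  used wherever determinism matters, e.g. in the simulation study.
* `mean_state_duration()` is the geometric closed form $1/(1 - A_{kk})$
  windows. `subset_duration_statistics()` estimates duration and interval
  statistics for a union of states by simulating chains of length
  $N = 2000$ from $A$, $N_{MC} = 4000$ times, binarizing subset membership
  and averaging run lengths; replicate means are summarized by the median
  and central 95% interval. Two choices deserve note: the start state is
  drawn uniformly and a 100-window burn-in is discarded (reducing
  start-state bias), and runs touching either chain end are excluded as
  censored. Both choices matter little for chains 20× longer than the mean
  dwell but are stated because they are not forced by the definition.

## The simulation validation study

`run_simulation_study()` reproduces, at desk scale, the ground-truth recovery
experiment that justifies trusting the estimates:

1. `synthetic_seed_spectrogram()` builds a spectrogram whose windows are
   drawn from K labeled spectral profiles plus i.i.d. Gaussian dB noise per
   frequency bin. The default profiles elevate, for each state, a balanced
   cyclic subset of bands (band $h$ elevated in state $k$ iff
   $(h+k) \bmod K < \lceil K/2 \rceil$) by 8 dB over a −10 dB baseline with
   1.5 dB noise. The balanced codes ensure two things: any two states differ
   by the full gap in at least one band, and every band is elevated in
   roughly half the states, so each band's power sequence has a genuine
   interquartile spread and the logistic scaling stays well-conditioned.
2. `cluster_spectra()` carves the seed spectrogram into K clusters by seeded
   k-means on scaled band powers (10 restarts, re-seeded up to 10 times if a
   cluster empties) — deliberately ignoring temporal order.
3. `simulate_spectrogram()` draws a Markov path from $(\pi, A)$ — defaults:
   $\pi$ a point mass on state 1 and $A$ with 0.85 diagonal and the
   off-diagonal mass on the cyclic successor, mimicking sequentially
   alternating spectral states — and copies, per window, the spectrum of a
   uniformly resampled source window from the active cluster. Scaled
   observations are recomputed on the simulated sequence by the standard
   pipeline.
4. A K-state model is fitted (5 restarts) and Viterbi-decoded; estimated
   labels are aligned to the truth by the permutation maximizing the
   confusion-matrix diagonal (exhaustive search, which equals the Hungarian
   assignment for these K), and the study reports per replicate: path
   accuracy, the mean exact KS distance between true and fitted emissions
   (the "true" beta of a state-band is the MLE on the observations the true
   path assigns to that state), and the scaled L1 errors
   $\epsilon_A = \sum_{jk}|A_{jk}-\hat A_{jk}|/(2K)$ and
   $\epsilon_\pi = \sum_k|\pi_k-\hat\pi_k|/2$.

Study sizes — $K \in \{2,\dots,5\}$, 25 replicates per K, $M = 2000$
simulated windows, seed spectrograms of 1500 windows — were chosen so the
whole study completes in about a minute on one core while leaving each
replicate long enough to pin down the path and emissions essentially
exactly. At these sizes path accuracy is 1.0 in every replicate, the
emission KS distance is at numerical zero, and $\epsilon_\pi$ is at
floating-point zero (the generating $\pi$ is degenerate and the first-window
posterior saturates).

$\epsilon_A$ deserves a caveat: with saturated posteriors the EM estimate of
$A$ equals the empirical transition frequencies, whose error is pure Markov
sampling noise, $\mathbb{E}[\epsilon_A] \approx
0.8\sqrt{0.1275\,K/M} \approx 0.013$ for $K=5$ at $M = 2000$. This floor is a
property of the sequence length, not of the estimator: no method can estimate
transition probabilities better than the observed transition counts allow.
Driving the worst-case $\epsilon_A$ below 0.01 requires $M$ on the order of
$10^4$ windows (about 15–20 min of recording at the 0.1 s hop — the scale of
a real experimental session), at which point the error shrinks as
$\sqrt{1/M}$.

### What the synthetic generator does and does not emulate

The generator reproduces the features the model relies on: distinct
band-limited profiles, Markov switching, and observation noise. It does not
emulate 1/f background spectra, within-state band correlation, spectral
leakage between adjacent windows (simulated windows are resampled
independently), artifacts, or drifting state definitions. Passing the study
therefore demonstrates correct *estimation* under the model's own
assumptions — it does not by itself validate the model against real neural
data, where model order choice and artifact states require judgment.

## Known limitations

* Offline only: the scaling quartiles need the full recording.
* Single channel: no spatial modelling.
* K is user-chosen; no automatic model-order selection is provided.
* Geometric dwell times: strongly non-geometric durations would call for
  semi-Markov extensions.
* The EDF reader supports plain uncompressed 16-bit EDF (continuous
  recordings, no annotation channels).
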