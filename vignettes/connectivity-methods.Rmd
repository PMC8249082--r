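---
title: "Directed brain-heart-lung connectivity with gpdcnet: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed brain-heart-lung connectivity with gpdcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Concurrent EEG, ECG and whole-body plethysmography (Pleth) recordings
observe three organs of one tightly coupled physiological system.
Pairwise (bivariate) measures of association between two such signals are
confounded by the third: a common drive from the brain can masquerade as
a heart-lung connection.  `gpdcnet` therefore treats the recording as one
multivariate system and quantifies *effective directed* connectivity —
the direct, frequency-resolved inflow from one channel to another after
conditioning on all other channels — using multivariate autoregressive
(MVAR) modelling and the generalized partial directed coherence (GPDC).

# Model and measure

Within each short analysis window the demeaned channel vector
$x(t) \in \mathbb{R}^D$ is modelled as a stationary MVAR process of order
$p$:

$$x(t) = \sum_{r=1}^{p} A_r\, x(t-r) + e(t), \qquad
  \operatorname{Cov}(e) = \Sigma,$$

fitted by multivariate least squares on the lagged design matrix.  The
estimator is ordinary least squares rather than a lattice (Vieira-Morf
type) recursion: at the operating data-to-parameter ratio (more than
100 data points per coefficient, see below) both give equivalent
estimates, and OLS is deterministic, simple to validate against
explicitly formed normal equations, and exposes the regressor Gram
matrix that the asymptotic significance backend needs.  The residual
covariance uses the degrees-of-freedom corrected denominator
$n_{\mathrm{eff}} - pD$.

From the coefficient stack the spectral transfer structure is

$$\bar{A}(f) = I - \sum_{r=1}^{p} A_r\, e^{-i 2 \pi f r / f_s},$$

and the squared GPDC from channel $j$ to channel $i$ is

$$|\bar{\pi}_{ij}(f)|^2 =
  \frac{|\bar{A}_{ij}(f)|^2 / \sigma_i^2}
       {\sum_{k=1}^{D} |\bar{A}_{kj}(f)|^2 / \sigma_k^2},$$

with $\sigma_k^2$ the residual noise variances.  Two structural
properties follow directly and are enforced by tests: each column sums
to one over the receiving channel ($\sum_i |\bar\pi_{ij}(f)|^2 = 1$),
and the residual-variance weighting makes the measure invariant to
rescaling any single channel — essential when microvolt EEG, millivolt
ECG and pressure-derived Pleth share one model.  A structurally absent
coupling ($A_{ij,r} = 0$ for all $r$, $i \neq j$) gives exactly zero
GPDC at every frequency.

Matrix element $(i, j)$ always means flow *from column $j$ to row $i$*,
project-wide.  Diagonal entries are computed (they carry the column
normalization) but are never interpreted as inter-organ flow.

# Standard operating parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| window length | 10 | s | long enough for 100x data-to-parameter ratio, short enough for local stationarity |
| window overlap | 0 | s | consecutive, non-overlapping epochs |
| MVAR order $p$ | 7 | lags | band profiles converge for orders above 5 (see `order_sensitivity()`) |
| frequency grid | 1–200 | Hz, 1 Hz steps | full physiologically informative range below the 250 Hz Nyquist rate |
| significance level | 0.05 | — | strict per-value rule $p < \alpha$ |
| surrogates | 99 | — | p-value resolution 1/100 |
| band width | 10 | Hz | profile resolution |
| mains frequency | 60 | Hz | bands containing 60, 120, 180 Hz are excluded |
| smoothing half-width $k$ | 4 | windows | 9-point smooth = 90 s of raw data per point |

With the standard 6-channel, 500 Hz configuration each 10-s window
carries $5000 \times 6 = 30{,}000$ data points for the
$7 \times 6 \times 6 = 252$ MVAR coefficients, a ratio above 119;
`fit_mvar()` warns whenever a window drops below the 100x ratio.

Preprocessing mirrors a mixed-rate acquisition chain: channels above the
500 Hz target (e.g. 2 kHz ECG) are low-passed at 200 Hz with a 4th-order
Butterworth digital filter applied causally (forward only — no zero-phase
claim is made for the acquisition chain being emulated; `zero_phase =
TRUE` is available) and then decimated by the integer rate ratio.
Channels already at the target rate pass through unfiltered by default,
since only decimated channels need anti-alias protection; set
`filter_passthrough = TRUE` to filter everything identically.  Arbitrary
(non-integer) resampling is deliberately unsupported.  Trailing partial
windows are dropped, not padded: the MVAR fit needs full-length epochs.

# Significance: which GPDC values are real?

The masked quantity downstream is **ssGPDC**: a squared GPDC value that
passed a per-value test at strict $p < 0.05$.  Two backends exist:

**Circular-shift surrogates (default).**  Each of 99 surrogates rotates
every channel independently by a random offset of at least $p$ samples.
This destroys cross-channel lag alignment while exactly preserving each
channel's own autocorrelation sequence (up to the wrap-around), so the
surrogate ensemble samples the null of *no cross-channel coupling with
unchanged autospectra*.  The p-value is the standard rank statistic
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + S)$.  Two discreteness
facts matter and are deliberate: with $S = 99$ the attainable p-values
are $k/100$, so the strict rule $p < 0.05$ rejects iff $p \le 0.04$ and
the exact null rejection rate is 0.04, slightly conservative relative to
the nominal 0.05; and with fewer than 39 surrogates *nothing* can pass
at $\alpha = 0.05$.  Calibration checks in the test suite treat windows
as the independent units — all values inside a window share one model
fit and are strongly dependent — and verify that the empirical rejection
rate on independent white noise falls inside the 99% binomial interval
around $\alpha$ with $n$ equal to the number of windows.

**Asymptotic backend.**  For a stable model, the OLS coefficients of
source $j$ in equation $i$ are asymptotically Gaussian with covariance
$\sigma_i^2 [\hat\Gamma^{-1}]_{jj}/n_{\mathrm{eff}}$ built from the
lagged-regressor Gram matrix $\hat\Gamma$.  Under the null
$\bar A_{ij}(f) = 0$, $|\hat{\bar A}_{ij}(f)|^2$ is a two-component
chi-square quadratic form whose exact weights are the eigenvalues of the
$2 \times 2$ covariance of its real and imaginary parts; the p-value
uses a two-moment (Satterthwaite) chi-square approximation, which is
exact in the equal-weight and single-weight limits.  This backend is
roughly five times faster than surrogates but requires stability and
yields no p-value for diagonal entries (there is no zero-coupling null
for a channel on itself); it agrees with the surrogate mask on well over
90% of off-diagonal decisions in the synthetic testbed.

**No multiple-testing correction** is applied across frequencies,
channel pairs or windows: the mask is a raw per-value rule, which is the
convention for ssGPDC profile construction.  This inflates the
family-wise error rate by design; the per-band zero rule and the
pooling across thousands of values make the profiles robust to the
individual false positives, but any single masked value should not be
over-interpreted.  `stats::p.adjust()` can be applied to exported
p-value columns when a corrected view is wanted.

# Aggregation, comparison, dynamics

Organ-level pooling collects the multiset of all ssGPDC values over
{channel pairs of the ordered organ pair} x {grid frequencies in the
band} x {windows}.  Every value is one sample — values are *not*
averaged per window first.  This matches the convention of integrating
ssGPDC values across time per frequency band; the per-window averaging
alternative is available through `extract_band_timeseries()`, whose
per-window means are exactly that quantity.  Bands are half-open
$(low, high]$, so 60 Hz itself falls in the excluded $(50, 60]$ band;
the boundary convention is fixed and documented rather than inferable.
Empty pooled bands get mean 0 and SEM 0 with an explicit
`zero_assigned` flag (the zero rule); single-value bands report SEM 0
and `n = 1`.

Group differences use the two-sided Mann-Whitney-Wilcoxon rank-sum test:
exact enumeration when the smaller sample has at most 8 values without
ties, midrank normal approximation with tie correction otherwise, star
annotation `*` for $p<0.05$ and `**` for $p<0.001$.  Interactions with
an empty pool are reported as not-testable rather than dropped silently.
The most discriminative band of an interaction is the retained band with
the minimum rank-sum p-value; ties break toward the lower-frequency
band (a fixed, documented rule — ties are rare but must be
deterministic).

Time-resolved dynamics use the per-window in-band mean ssGPDC (0 when a
window has no significant in-band value, mirroring the zero rule; a
gap/`NA` option exists for sensitivity analysis), smoothed by a
9-point centered moving average whose window shrinks symmetrically at
the series edges — a choice that preserves constant series exactly and
keeps the first and last timestamps, at the cost of higher variance in
the first and last few points.  Group reference bands (mean ± SEM of
the pooled values at the selected band) provide the backdrop against
which peri-event excursions are read.

# The synthetic testbed

No public recordings accompany this analysis domain, so the package
ships a first-class generator.  Ground truth is itself a stable MVAR
process: each channel is an AR(2) resonator with poles at radius $r$
and angle $2\pi f_0/f_s$, and directed couplings are single
coefficients at chosen lags.  Because the generator satisfies the
model class exactly, recovery of the injected topology is a sharp test
of the estimation pipeline itself, uncontaminated by model mismatch.
That is also the generator's main limitation: real EEG/ECG/Pleth
signals are nonstationary, nonlinear, and contain sharp waveform
morphology (QRS complexes, breaths) that no low-order linear process
reproduces.  Passing the testbed therefore validates the *estimator and
inference chain*, not the linear model's adequacy for any particular
real recording.

Default node dynamics place the four EEG channels at 6–10 Hz cortical
rhythms, the ECG at an 11 Hz cardiac fundamental (murine heart rates
are near 660 beats/min) and the Pleth at a 3 Hz respiratory
oscillation, all with pole radius 0.85.  A near-unit-root resonator at
a low normalized frequency leaves very little stable coefficient
budget for cross-couplings, which is why the testbed's "strong"
couplings are 0.02 — the WT-like topology already has spectral radius
0.965.  The scenarios:

* `WT_LIKE` — strong bidirectional Brain–Heart (0.020/0.016 at lags
  1/2, both directions), moderate Brain→Lungs (0.010), weak
  Heart→Lungs (0.004);
* `KO_LIKE` — Brain–Heart weakened to 0.006/0.005, Brain→Lungs raised
  to 0.040, Heart→Lungs to 0.030;
* `KO_SEIZING` — as `KO_LIKE` with alternating 300-s epochs in which
  Brain→Lungs rises further to 0.060, simulated with state continuity
  across epoch boundaries and annotated as events.

These effect sizes were fixed once, before being frozen as defaults, so
that one hour per group (360 windows) separates the groups at
$p < 0.001$ on the full-spectrum pools with the correct sign pattern
(Brain–Heart reduced, Brain→Lungs elevated in the KO-like topology).
GPDC of a single-lag coupling peaks near the *source* channel's
resonance, because the column normalization divides by the source's own
transfer magnitude, which dips at its resonance — hence the test that a
unidirectional ECG→EEG coupling is detected near the cardiac frequency.

Simulation draws all innovations from R's seeded RNG, discards a
burn-in of $10p$ samples, and is bit-for-bit reproducible per seed.
Unstable coupling specifications are rejected at construction with the
offending spectral radius.

# Numerical and degenerate-input choices

* Singular designs (e.g. a constant channel after demeaning) are flagged
  fit failures; the window is excluded downstream and logged, never
  silently filled.
* Unstable fitted models are kept but flagged — the GPDC formula does
  not require stability — except in the asymptotic significance
  backend, which refuses them and points to the surrogate method.
* If more than 20% of a window's surrogate fits fail, the window is
  aborted and excluded.
* A numerically zero transfer column at some frequency yields NaN GPDC
  values for that column with a warning (it cannot occur for a fitted
  model with positive noise variances).
* Sample indices in messages are 0-based, as are window indices; window
  start times are half-open $[start, start + length)$ intervals.
* Text-format recordings are written with 17 significant digits so a
  write/read round-trip is bit-exact.

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated
data: 100 random stable models x 200 frequencies for the normalization
property; 18 rescaling configurations for scale invariance; 100–200
ten-second windows (6 channels, 99 surrogates) for type-I calibration
and directionality recovery; 50 replicates of $n = 5000$ for VAR
recovery; and one hour per group for the WT-like/KO-like contrast.
These sizes keep the complete run at desk scale while leaving every
binomial check adequately powered.

# Known limitations

* Linear, same-frequency coupling only: cross-frequency interactions
  (phase-amplitude nesting and the like) are invisible to MVAR + GPDC.
* The per-value $p<0.05$ mask is uncorrected (see above).
* Pooling treats every value as exchangeable; animal- or
  recording-level random effects are out of scope, and pooled p-values
  on tens of thousands of values become astronomically small — effect
  direction and magnitude, not the p-value itself, are the readable
  quantities at that scale.
* EDF support covers the common 16-bit continuous (EDF/EDF+C) layout;
  discontinuous EDF+D files are rejected.
* The asymptotic backend's Satterthwaite approximation is an
  approximation to a two-weight chi-square mixture; its tail error is
  small but nonzero, which is one reason the surrogate backend is the
  default.
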