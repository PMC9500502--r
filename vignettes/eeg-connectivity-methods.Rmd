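---
title: "Methods: MVAR connectivity, MCC graph metrics, and group comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MVAR connectivity, MCC graph metrics, and group comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`eegconn` implements a complete resting-state EEG functional-connectivity
analysis for two-group comparisons: directed coupling by the directed
transfer function (DTF) of a multivariate autoregressive (MVAR) model,
undirected lagged coupling by the imaginary part of coherency (iCoh),
minimum-connected-component (MCC) binarization of band-averaged
connectivity matrices, three global graph metrics, and nonparametric
group statistics. This vignette explains the models, the tunable
parameters, the synthetic-data generator that stands in for clinical
recordings, and the numerical choices made where the design was open.

## The connectivity model

### MVAR and the directed transfer function

A channels-by-samples recording $x_t \in \mathbb{R}^M$ is modelled as a
stable VAR($p$) process

$$x_t = \sum_{k=1}^{p} A_k\, x_{t-k} + e_t,\qquad e_t \sim \mathcal N(0, \Sigma),$$

fitted by multichannel least squares (`fit_var()`). The frequency-domain
transfer matrix is $H(f) = \bigl[I - \sum_k A_k e^{-i 2\pi f k / f_s}\bigr]^{-1}$
(`transfer_matrix()`), and the normalized DTF is

$$\gamma_{ij}(f) = \frac{|H_{ij}(f)|}{\sqrt{\sum_{k=1}^{M} |H_{ik}(f)|^2}},$$

the inflow from channel $j$ to channel $i$ as a fraction of all inflows to
$i$, so $\sum_j \gamma_{ij}^2(f) = 1$ for every target and frequency. DTF
reflects both direct and cascade (mediated) influence; it is not a partial
measure, and no partialized variants are provided.

The model order is selected by minimizing
$\mathrm{AIC}(p) = \ln\lvert\widehat\Sigma(p)\rvert + 2 p M^2 / \widehat T$
over a candidate range (`select_order()`), with ties broken toward the
smaller order. A fitted model is validated on three axes
(`validate_model()`): stability (companion spectral radius below 1),
residual whiteness (per-channel Ljung–Box portmanteau at $\alpha = 0.05$),
and consistency (the percentage of the data's auto-/cross-correlation
structure up to lag 20 reproduced by data simulated from the fitted model).

"Adaptive" estimation is approximated by sliding-window refits
(`windowed_fit()`, default 5 s windows with 50% overlap) with the
per-window DTF averaged; no Kalman-type recursion is attempted. On
stationary synthetic data the windowed and full-length estimates agree
within sampling error, and both paths are exposed.

### Cross-spectra and the imaginary part of coherency

Cross-spectral matrices are estimated by Welch averaging of
Hamming-tapered windowed Fourier cross-products (`cross_spectrum()`,
default 2 s windows, 50% overlap; on a 6-minute recording this yields
roughly 360 windows, keeping the small-sample coherence bias of order
$1/K$ negligible). Complex coherency is
$C_{ij}(f) = S_{ij}(f) / \sqrt{S_{ii}(f) S_{jj}(f)}$ and
$\mathrm{iCoh}_{ij}(f) = \mathrm{Im}\, C_{ij}(f)$. Because purely
instantaneous mixing (volume conduction) contributes only to the real
part, iCoh isolates lagged interactions; the package stores the signed
antisymmetric values and uses $|\mathrm{iCoh}|$ as the undirected edge
weight downstream.

### Bands and averaging

Connectivity is evaluated on a 0.5–45 Hz grid with 0.5 Hz spacing (the
narrowest band still spans seven bins) and averaged per band: delta
0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–45 Hz, plus a `total`
band covering 0.5–45 Hz. Bands are half-open $[lo, hi)$ with an inclusive
upper edge at 45 Hz, so the five sub-bands exactly partition the total
range and the total-band average equals the bin-weighted mean of the
sub-band averages. Band limits are conventional choices; none are fitted.

## From matrices to networks

Directed DTF band matrices are symmetrized by the pairwise maximum before
thresholding; diameter, efficiency and transitivity are undirected
notions, and the maximum preserves a strong influence in either
direction. Each band matrix is binarized by the MCC rule
(`mcc_binarize()`): the threshold is the *largest* cutoff $t$ at which
the graph $\{w_{ij} \ge t\}$ still spans all channels in one connected
component — equivalently the bottleneck weight of the maximum spanning
tree, which is how it is computed. Ties at the threshold are all
retained. This replaces any manually chosen proportional threshold with
a parameter-free rule, at the cost of letting the retained edge count
vary across subjects (the threshold and edge count are therefore
reported alongside the metrics).

On the binarized network three global metrics are computed with hop-count
shortest paths: diameter $D = \max_{ij} d_{ij}$, global efficiency
$E = \frac{1}{N(N-1)}\sum_{i \ne j} 1/d_{ij}$ (the average *inverse*
shortest path length — the formula, not the "average path length" gloss),
and transitivity $T = 3 \times \text{triangles} / \text{connected
triples}$. A graph with no connected triple has $T$ defined as 0 with a
warning. The implementations delegate to igraph; the test suite checks
them exactly against Floyd–Warshall and exhaustive triple-enumeration
oracles on hundreds of random graphs.

## Group statistics

For every (measure, band, metric) cell — 2 measures × 6 bands × 3 metrics
= 36 cells — the two groups are compared with a two-sided Wilcoxon
rank-sum test (`compare_groups()`): exact null distribution when the
pooled sample is at most 20 with no ties, otherwise the normal
approximation with tie and continuity corrections. Shapiro–Wilk normality
p-values are reported per cell but do not gate the rank-sum tests, and the
headline significance marks are uncorrected for multiplicity (a
Benjamini–Hochberg column is emitted alongside for honesty, but is not
used for the marks). A spectral contrast (`spectral_contrast()`) compares
the alpha-peak power (maximum channel-averaged Welch log-power in
8–13 Hz) and the mean gamma-band log-power between groups the same way.

## The synthetic cohort generator

No clinical recordings ship with the package; `make_cohort()` generates
two-group cohorts with fully known structure so that every downstream
stage is testable against ground truth. Each subject is built from:

* **alpha sources** — a small VAR whose diagonal blocks are AR(2)
  resonators at 10 Hz (≈2 Hz bandwidth) and whose off-diagonal lag-1
  coefficients implement directed couplings placed at the group's
  `alpha_coupling_density`;
* **gamma sources** — independent AR(2) resonators at 38 Hz (≈6 Hz
  bandwidth);
* **instantaneous mixing** — a random per-subject mixing matrix projects
  the sources to channels, emulating volume conduction (exactly the
  confound iCoh is designed to cancel);
* **1/f background noise** per channel, plus an optional 50 Hz line
  sinusoid.

Group structure enters through per-group multipliers on the alpha and
gamma source amplitudes and the alpha coupling density; a log-normal
per-subject jitter (sd 0.15) adds between-subject variability. The
defaults emulate a 32-channel, 512 Hz, 6-minute eyes-closed protocol with
a healthy-like group (alpha gain 1.0, gamma gain 1.0, density 0.1)
against a patient-like group with a damped alpha peak (0.6), elevated
gamma (1.6) and denser alpha coupling (0.4). The two gain contrasts
follow the qualitative direction the analysis is meant to detect; their
magnitudes, and the coupling densities, are free parameters chosen once
as plausible mesoscale effects — they are not calibrated to any clinical
dataset, and nothing in the package tunes them.

What the generator deliberately does **not** reproduce: anatomical
forward models (no BEM/dipole geometry), realistic artifact waveforms
beyond line noise, non-stationarity across the recording, and
heavy-tailed source distributions. Passing tests therefore demonstrate
correctness of the estimators under the model's own assumptions
(instantaneous mixing, Gaussian innovations, stationarity), not clinical
validity on real EEG.

## Preprocessing

The cleaning chain mirrors standard resting-state practice: a zero-phase
high-pass FIR at 0.5 Hz, sliding-window line-noise regression, ICA, and
back projection of the retained components.

The high-pass filter defaults to order 826. At that order and a 512 Hz
rate the Hamming transition band is about 2 Hz wide, so a directly
windowed high-pass would not even null DC at a 0.5 Hz cutoff; the filter
is therefore designed by spectral inversion of a unit-DC-gain
windowed-sinc low-pass, giving an exact DC null, ≈34 dB attenuation at
0.1 Hz and a passband flat to 1%. Deep (≥40 dB) attenuation immediately
below the cutoff is not achievable at this order — a genuine limitation
of the order-826 design, documented rather than hidden. The filter is
applied with group-delay compensation and `trim_edges()` drops one group
delay from each end so MVAR fitting never sees the edge transient.

ICA is a symmetric FastICA (logcosh contrast) on whitened data,
deterministic for a fixed seed, with as many components as channels
(fewer, with a warning, on rank-deficient data). Artifact components are
flagged by transparent rules (`flag_artifact_components()`): line-band
power ratio above 10 dB; a flat-or-rising log-log PSD slope over 25 Hz to
min(95, 0.95·Nyquist) Hz together with dominant high-frequency power
(muscle — the wide slope range is what separates broadband EMG from
narrowband gamma, which falls off again past its peak); low-frequency
dominance with frontal loading (ocular); excess kurtosis above 8
(spikes). These thresholds are configuration defaults with documented
rationale, **not** a reimplementation of any trained classifier; the
per-component feature record is kept so every rejection is auditable.

## Numerical and scaling choices

* `fit_var()` always removes channel means; variance normalization
  (`scale = TRUE`) is applied by the pipeline before connectivity
  estimation so DTF is invariant to per-channel gain, but is off by
  default in the low-level fitter so that raw simulation coefficients are
  recovered unchanged.
* The residual covariance uses the regression degrees of freedom
  ($T - pM$), and AIC uses $\widehat T$ = the number of regression rows.
* Replicate simulation studies in the tests and the acceptance script run
  at a reduced scale chosen to keep a full study tractable on one CPU:
  16 channels, 60 s at 128 Hz, a single full-length VAR(3) fit per
  subject, groups of 20 and 18. These sizes are the package's own
  trade-off between statistical resolution and runtime; the pipeline
  defaults remain the full-protocol values.
* Seeds thread through every random stage (cohort generation, ICA
  initialization, simulation), and identical configurations reproduce
  results bit-identically.

## Known limitations

* DTF is normalized, not partialized: strong common inputs can elevate
  pairwise values; the cascade property (1→2→3 implying apparent 1→3) is
  by design.
* MCC guarantees connectedness but not equal density across subjects;
  metric differences can partly reflect density differences.
* The rule-based IC classifier is a labelled-partition stand-in adequate
  for synthetic artifacts; real-data use should review its per-component
  feature records.
* Rank-sum p-values on small discrete metrics (diameter takes few values
  at 16–32 channels) are conservative under heavy ties.
* The generator's effect sizes are free parameters; detection rates
  measured on it say nothing about clinical effect sizes.
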