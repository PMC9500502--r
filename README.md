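# eegconn

Resting-state EEG functional connectivity and graph analysis for
two-group studies (e.g. patients vs healthy controls), in R.

Given multichannel eyes-closed recordings, `eegconn` estimates two
complementary coupling measures between every channel pair, reduces each
subject to a binary brain network per frequency band, and asks where the
groups differ:

* **DTF** — the normalized directed transfer function of a fitted
  multivariate autoregressive (MVAR) model,
  `γ_ij(f) = |H_ij(f)| / sqrt(Σ_k |H_ik(f)|²)` with
  `H(f) = [I − Σ_k A_k e^(−i2πfk/fs)]⁻¹`: the directed inflow from
  channel *j* to channel *i* as a fraction of all inflows to *i*. Model
  order by AIC (`ln|Σ̂(p)| + 2pM²/T̂`), with stability, residual-whiteness
  and consistency validation.
* **iCoh** — the imaginary part of complex coherency
  `Im[S_ij(f)/sqrt(S_ii S_jj)]` from Welch cross-spectra; instantaneous
  volume conduction contributes only to the real part, so iCoh isolates
  genuinely lagged interactions.

Band-averaged matrices (delta/theta/alpha/beta/gamma plus the full
0.5–45 Hz range) are binarized by **minimum-connected-component (MCC)**
thresholding — the largest cutoff that keeps all channels in one
connected component (the maximum-spanning-tree bottleneck) — and
summarized by three global graph metrics: diameter, global efficiency
`1/(N(N−1)) Σ 1/d_ij`, and transitivity `3·triangles/triples`. Groups are
compared per (measure, band, metric) cell with two-sided Wilcoxon
rank-sum tests (Shapiro–Wilk normality reported alongside), plus a
spectral contrast of alpha-peak and gamma-band power.

Because clinical recordings cannot be shipped, the package includes a
synthetic cohort generator (`make_cohort()`) with fully known ground
truth — coupled band-limited oscillators, instantaneous mixing, 1/f
noise — plus a preprocessing chain (zero-phase high-pass FIR, line-noise
removal, FastICA with rule-based artifact flagging, back projection).
See the methods vignette (`vignettes/eeg-connectivity-methods.Rmd`) for
the full model description and design rationale.

## Worked example

A small synthetic study — 8 + 8 subjects, 12 channels, 40 s at 128 Hz,
with the generator's default group contrasts (damped alpha peak, elevated
gamma, denser alpha coupling in the patient-like group):

```r
library(eegconn)
cfg <- default_config(
  cohort = list(n_subjects_per_group = c(8, 8), n_channels = 12, fs = 128,
                duration = 40, noise_seed = 11, mixing_matrix_seed = 12),
  preprocess = list(enabled = FALSE),
  mvar = list(p = 4, windowed = FALSE))
res <- run_pipeline(cfg)
print(res)
#> <pipeline_result> 192 metric rows, 36 comparison cells (9 significant at 0.05)

res$comparison[res$comparison$significant,
               c("measure", "band", "metric", "p_value", "direction")]
#>  measure  band            metric     p_value direction
#>      dtf theta          diameter 0.033648804   healthy
#>      dtf alpha          diameter 0.003005135   healthy
#>     icoh alpha          diameter 0.030296606   patient
#>     icoh  beta          diameter 0.015694295   healthy
#>      dtf total global_efficiency 0.049883450   patient
#>      dtf theta global_efficiency 0.037917638   patient
#>      dtf alpha global_efficiency 0.005351034   patient
#>     icoh total      transitivity 0.049883450   healthy
#>      dtf alpha      transitivity 0.039979603   patient

res$spectral[, c("feature", "p_value", "direction")]
#>        feature      p_value direction
#>  alpha_peak_db 0.0001554002   healthy
#>  gamma_mean_db 0.0069930070   patient
```

The alpha-band network cells carry the strongest effects — the patient
group's denser alpha coupling raises its global efficiency (direction
`patient`) and shortens its diameter relative to the healthy group — and
the spectral contrast recovers the generator-set alpha/gamma power
differences in the expected directions. `res$metrics` holds the tidy
per-subject table (subject, group, measure, band, diameter, efficiency,
transitivity, MCC threshold, edge count); with `out_dir` set, everything
is written as CSV/JSON next to the archived run configuration.

A thin CLI wraps the same pipeline:

```sh
Rscript inst/cli/eegconn-cli.R run-all --subjects 8 --channels 12 \
    --duration 40 --seed 11 --out results/demo
```

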