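# boldvar

Quantifies **intrinsic BOLD signal fluctuations** — acquired without any
maternal hyperoxia challenge — in the **placenta** and **fetal brain**, and
relates them to maternal risk factors (MRFs: pre-gravid obesity, diabetes,
hypertension) and fetal congenital heart disease (CHD).  It is aimed at
fetal-imaging groups who have 4D echo-planar BOLD series with manually drawn
volumes of interest and want a tested, deterministic pipeline from raw
frames to an inference table — plus synthetic phantoms and cohorts with
known ground truth, so every stage can be validated without clinical data.

## The two statistics

For a volume of interest (VOI) with voxel courses $x_{v,t}$:

* **Temporal variance** — fluctuation of the whole-organ signal.  With
  $m_t = \mathrm{mean}_v\, x_{v,t}$ and $\tilde m_t = m_t / \bar m$
  (unity-mean normalization, cancelling scanner gain):
  $\mathrm{TV} = \mathrm{sd}(\tilde m_t)$ (sample SD, $n-1$).
  A proxy for the cyclical maternal-inflow oxygenation cycle.
* **Spatial variance** — heterogeneity of fluctuation across the organ.
  Per voxel, the percent amplitude fluctuation
  $\mathrm{PAF}_v = \frac{100}{T}\sum_t |x_{v,t}-\mu_v| / \mu_v$; then
  $\mathrm{SV} = \mathrm{sd}_v(\mathrm{PAF}_v / \overline{\mathrm{PAF}})$.
  A proxy for perfusion differences across cotyledons.  Both statistics are
  invariant to global intensity rescaling.

Inference uses a **null-restricted wild bootstrap** (Rademacher multipliers,
valid under heteroskedastic errors) on designs
$[1,\,GA,\,\mathrm{MRF}]$ and $[1,\,GA,\,\mathrm{MRF},\,\mathrm{CHD},\,
\mathrm{MRF\times CHD}]$, one-sided in the "MRFs reduce variance" direction,
with Benjamini–Hochberg FDR across the four MRF predictors per
(tissue × metric × effect-type) block; CHD group comparisons use a
GA-adjusted two-sample Kolmogorov–Smirnov test, moment tests, and Welch t
tests.  See `vignette("intrinsic-bold-variance")` for the full methods
account.

## Worked example

```r
library(boldvar)

# 1. a phantom with known ground truth
spec <- phantom_spec(grid_shape = c(32L, 32L, 5L, 100L), inflow_amplitude = 0.1,
                     noise_sd = 1, motion_max_voxels = 1, seed = 42L)
ph <- generate_bold_phantom(spec)
ph$series
#> <bold_series> 32 x 32 x 5 voxels, 100 frames, TR 2.28 s

# 2. preprocess: motion-correct, denoise
mc <- motion_correct(ph$series)
clean <- denoise(mc$series, ph$masks$placenta, ph$masks$fluid)
cat(sprintf("mean NCC before/after correction: %.4f / %.4f\n",
            mc$qc$mean_ncc_before, mc$qc$mean_ncc_after))
#> mean NCC before/after correction: 0.8684 / 0.9533

# 3. metrics
variance_metrics(clean, ph$masks$placenta, tissue = "placenta")
#> <variance_metrics> placenta: TV = 0.06403, SV = 0.4142 (1070 voxels, 100 frames, 0 excluded)
cat(sprintf("ground-truth TV (noise-free): %.4f\n", ph$truth$true_tv))
#> ground-truth TV (noise-free): 0.0706

# 4. cohort statistics: 100 subjects, a true any-MRF effect of -0.5
co  <- generate_cohort(cohort_spec(n_subjects = 100L, beta_mrf = -0.5, seed = 7L))
bat <- mrf_battery(co, metrics = "tv_placenta", n_boot = 5000L, seed = 7L)
bat[bat$effect_type == "main", c("predictor", "coefficient", "p_one_sided", "p_fdr")]
#>     predictor coefficient p_one_sided  p_fdr
#>       any_mrf     -0.4597      0.0004 0.0008
#>      diabetes      0.0687      0.6785 0.6785
#>  hypertension     -0.1148      0.1648 0.2197
#>       obesity     -0.3328      0.0004 0.0008
```

Reading the output: the registration QC score (mean frame-to-frame NCC
against the reference) rises after correction; the measured TV (0.064) sits
slightly below the noise-free truth (0.071) because the temporal low-pass
filter attenuates the inflow sinusoid by a known factor (~0.92 at the
default FWHM).  In the battery, the imposed any-MRF effect (−0.5) is
recovered (−0.46) and FDR-significant; obesity — the most prevalent
component flag — inherits part of the signal, while diabetes (10%
prevalence) alone does not reach significance.  `run_pipeline(run_config(...))`
chains all of this (phantoms → preprocessing → metrics → battery) from one
seeded configuration and writes `cohort.csv`, `metrics.csv`, `stats.csv`,
`group_comparison.json`, `qc.json` and a log.

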