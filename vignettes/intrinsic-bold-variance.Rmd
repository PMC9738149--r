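---
title: "Spatiotemporal variance of intrinsic placental and fetal brain BOLD: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal variance of intrinsic placental and fetal brain BOLD: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

The placenta is a parallel oxygenator: tens of cotyledons, each a
semi-independent maternal-fetal perfusion unit, fed by cyclical inflow of
oxygenated maternal blood.  Echo-planar BOLD imaging acquired without any
maternal challenge ("intrinsic" BOLD) sees these perfusion cycles as slow
fluctuations of the T2*-weighted signal.  `boldvar` quantifies them with two
dimensionless statistics computed inside a volume of interest (VOI):

* **Temporal variance (TV).**  The VOI-average signal is computed per frame,
  the resulting course is divided by its own mean (unity-mean normalization,
  which cancels receiver gain and any other global scale factor), and TV is
  the sample standard deviation (denominator $n-1$) of the normalized
  course.  TV indexes the strength of the cyclical maternal-inflow
  oxygenation fluctuation.

* **Spatial variance (SV).**  For each VOI voxel the percent amplitude
  fluctuation (PAF) of its time course is computed; the PAF values are
  divided by their across-voxel mean; SV is the sample standard deviation of
  the normalized values across voxels.  SV indexes perfusion heterogeneity
  across cotyledons and is scale-independent by construction.

The PAF of a course $x_t$ with temporal mean $\mu > 0$ uses the
mean-absolute-deviation convention of the percent-amplitude-fluctuation
literature,

$$\mathrm{PAF} = \frac{100}{T}\sum_t \frac{|x_t - \mu|}{\mu},$$

because the originating description names the measure without printing a
formula.  An SD-based alternative ($100\,\mathrm{sd}(x)/\mu$) is available
behind `convention = "sd"`.  For a pure sinusoid of fractional amplitude
$a$ the two conventions give $100\,a\,2/\pi$ and $100\,a/\sqrt2$
respectively; the tests pin both.

Unity-mean normalization is strictly within-subject (each course divided by
its own mean).  A group-referenced rescaling would not be well defined per
subject and is not needed to remove scanner gain.

## Preprocessing

Fetal imaging moves.  The pipeline mirrors a typical placental BOLD
protocol:

1. **VOI propagation.**  The VOI drawn on frame 1 is copied to all frames.
   When the organ is not fully covered, `restrict_slices()` keeps the
   `n_slices = 5` consecutive axial slices with the largest in-mask voxel
   count (ties to the lowest index), mimicking the 5-slice window placed on
   the largest portion of the placenta.
2. **Motion correction.**  Inter-slice rigid registration: each axial slice
   of each frame is registered to the matching slice of the reference frame
   (frame 1, the segmentation frame) by maximizing normalized
   cross-correlation (NCC).  "Inter-slice" is read as per-slice 2D rigid
   registration rather than 3D volume registration: with 3 mm slices and
   ~5 mm in-plane voxels, through-plane coherent motion is the smaller
   error source and per-slice motion the dominant mode.  The search is a
   coarse grid (translations $\pm 5$ voxels step 1, rotations $\pm 10°$
   step 2°) followed by coordinate-wise golden-section refinement to
   0.05 voxel / 0.1°; NCC is non-convex, and grid-then-refine is robust at
   these ranges.  The identity transform is part of the search, so the
   corrected NCC can never fall below the uncorrected one.  Zero-variance
   slices pass through with an identity transform and a warning.
3. **Denoising.**  A per-voxel temporal Gaussian low-pass filter (default
   FWHM 3 frames, ~6.8 s at TR 2.28 s, i.e. well above the ~45 s inflow
   period but below thermal-noise frequencies; `0` disables), then the
   amniotic-fluid mean course (centred, unit variance) is regressed out of
   every VOI voxel.  Because the regressor is centred, voxel temporal means
   are preserved exactly.  The filter type/width and the choice of
   regression (rather than masking) for fluid control are configuration
   decisions, not claims about any specific historical pipeline.
4. **Series selection.**  Where repeated acquisitions exist,
   `select_series()` picks the series with the highest mean frame-to-frame
   NCC — a quantitative proxy for the manual "least observed motion" review,
   exposed as a QC score.

## Statistical battery

The stated scientific hypothesis is directional: maternal risk factors
(MRFs: pre-gravid obesity, grouped diabetes, grouped hypertension) *reduce*
spatiotemporal variance.  Accordingly:

* **Wild bootstrap regression.**  For each metric and each predictor in
  {any-MRF, diabetes, hypertension, obesity}, the main-effect design is
  $[1, \mathrm{GA}, \mathrm{MRF}]$ and the interaction design
  $[1, \mathrm{GA}, \mathrm{MRF}, \mathrm{CHD}, \mathrm{MRF \times CHD}]$.
  Inference uses a null-restricted wild bootstrap with Rademacher
  multipliers (5000 replicates by default), which is valid under
  heteroskedastic errors: the null model (target coefficient forced to 0) is
  fitted, responses $y^* = \hat y_0 + r_0 v$ with $v_i = \pm 1$ are formed,
  and the full model is refitted per replicate.  The one-sided p-value is
  $(1 + \#\{\beta^* \le \hat\beta\})/(B+1)$ for direction `"less"` (the
  default for every MRF and interaction test); the $+1$ convention avoids
  exactly-zero p-values.  Replicate refits are evaluated in closed form
  ($\beta^* = w^\top y^*$ with $w$ the target row of $(X^\top X)^{-1}
  X^\top$), which is algebraically identical to per-replicate OLS and is
  verified against an explicit refit loop in the tests.
* **FDR.**  Benjamini-Hochberg step-up across the four predictors within
  each (tissue × metric × effect-type) block, mirroring the standard
  main-effect/interaction table layout.  The family definition is a design
  choice; correcting across tissues as well is a defensible alternative and
  can be obtained by adjusting the pooled p-value columns directly.
* **Group comparison.**  Metrics are gestational-age-adjusted by *one
  pooled* regression on $[1, \mathrm{GA}]$ (per-group adjustment would
  remove the group difference under test), then CHD vs non-CHD residual
  distributions are compared by the two-sample Kolmogorov-Smirnov test
  (asymptotic p), their variances by the variance-ratio F-test, and their
  skewness and excess kurtosis by seeded permutation tests on the moment
  difference — an F-test is defined for variances only, so "a significance
  test per moment" is the operative reading.  Demographic summaries
  published as mean (SD, n) can be compared directly via `welch_t()`, which
  accepts summary triples as well as raw samples.
* **Degenerate designs.**  A constant predictor or rank-deficient design
  raises a classed error when the regression functions are called directly.
  The batch runner (`mrf_battery()`) keeps the full table shape instead:
  degenerate cells carry `NA` with the error message in a `note` column,
  and FDR is computed over the non-degenerate members of each family.  This
  matters in practice: with realistic prevalences (diabetes ~10%, CHD ~35%)
  a diabetes × CHD interaction column is frequently all-zero in small
  cohorts.

## The synthetic world

No public feto-placental BOLD cohort exists, so the package carries
first-class generators whose defaults state the simulated world once:

**Phantom** (`phantom_spec()`): TR 2.28 s and 100 frames match the
acquisition protocol; everything else is a free parameter chosen to be
physiologically plausible, since the source material gives no quantitative
amplitude or noise levels.  Baseline 100 (arbitrary units, background at
20%), inflow amplitude 0.1 (a ~7% TV, mid-range for reported placental
fluctuations), inflow period 45 s (slow utero-placental inflow cycling,
~5 cycles per acquisition), 12 cotyledon-like patches grown as Voronoi cells
of Poisson-placed seeds inside the placental ellipsoid, patch amplitude SD
0.03, per-patch static baseline contrast of 8% (cotyledons differ in blood
volume, which also gives slices the spatial texture any registration
algorithm needs), noise SD 1 (1% of baseline), sub-voxel motion
(±1 voxel, ±1°), and an amniotic-fluid compartment oscillating at half the
inflow amplitude with twice the period plus noise — so the
nuisance-regression stage has a real confound to remove.  Patch amplitudes
are renormalized so the realized volume-mean fractional amplitude equals
`inflow_amplitude` exactly: patch draws shape the *spatial* heterogeneity
(SV), while the volume-mean fluctuation (TV) is pinned to the requested
value.  Without this, the cotyledon lottery would inject ~9% CV of
between-subject TV noise that is not part of the stated cohort model.
Ground truth (injected transforms, per-patch amplitudes, analytic TV/SV of
the noise-free, motion-free signal) is computed from the discrete sinusoid
and the known amplitudes, independently of the metrics code.

**Cohort** (`cohort_spec()`): GA uniform on 27-42 weeks; independent
Bernoulli flags at prevalences matched to the study population (obesity 0.5,
hypertension 0.2, diabetes 0.1, CHD 0.35); target metric
$\beta_0 + \beta_{GA}\,GA + \beta_{MRF}\,MRF + \beta_{CHD}\,CHD +
\beta_{int}\,MRF{\times}CHD + \varepsilon$ with residual SD
$\sigma\max(1 + h\,z_{GA}, 0.1)$ — heteroskedastic by construction, because
the choice of a wild bootstrap is only testable on heteroskedastic data.
Defaults: $\beta_0 = 7$, $\beta_{GA} = 0.1$ (variance rises with GA as
placental blood volume flow grows), $\beta_{MRF} = -0.5$,
$\beta_{CHD} = \beta_{int} = 0$, $h = 0.5$, $\sigma = 0.3$.

**Units.**  Cohort metrics are on a percent scale (TV of 7 means a 7%
fluctuation; the pipeline multiplies measured TV/SV by 100).  Published
regression tables for these metrics print coefficients on an unstated
rescaled axis (values like −59); no attempt is made to match that scale,
but the percent scale makes an effect of −0.5 physically realizable, which
a unity-mean fraction (TV ≈ 0.07) would not be.

**End-to-end wiring.**  The synthetic pipeline inverts the discrete relation
$TV = a\,\mathrm{sd}(s)/(1 + a\,\bar s)$ to map each subject's model TV to a
phantom inflow amplitude (floored at TV 0.5% to keep amplitudes positive),
sets the patch spread to $0.3a$, and derives every per-subject and per-cell
seed deterministically from the master seed, so a rerun of the same
configuration is bit-identical.

**What a green test does not establish.**  The generator contains no MR
physics (no T2* decay, no dielectric standing-wave artifact), no fetal
cardiac or hiccup dynamics, no through-plane or non-rigid motion, no
spatially correlated noise, and its amplitude/noise levels are stated
choices rather than fits to any cohort.  Green acceptance tests certify the
pipeline's internal correctness and statistical calibration on this stated
world — not that the instrument recovers clinical effect sizes in vivo.

## Numerical choices

* Sample SD (denominator $n-1$) everywhere, consistent with the
  small-sample regression stage.
* Voxels with non-positive temporal mean violate the PAF precondition; they
  are excluded from the metrics and counted in a QC tally rather than
  poisoning the VOI statistics.
* An all-constant VOI (mean PAF 0) yields SV 0 with a warning; a constant
  VOI-average course yields TV 0.
* Slice-window ties break toward the lowest slice index; series-selection
  ties toward the lowest list index.
* Bilinear resampling with zero fill outside the field of view; frame 1 is
  untransformed by convention in both motion injection and correction.
* Rigid transforms rotate about the slice centre; the estimated correction
  is the (approximate) inverse of the injected motion, and
  `invert_rigid()` maps between the two parameterizations exactly.
* NIfTI-1 I/O is implemented directly (348-byte header, float32 on write,
  gzip via connection); no R NIfTI package is assumed.  Verified against an
  independent reader during development.

## Known limitations

* Per-slice 2D registration cannot recover through-plane motion; the
  generator does not produce it either, so this failure mode is untested by
  construction.
* The amniotic-fluid regression removes one global nuisance course;
  spatially varying fluid artifacts would require voxel-wise confound
  models.
* Zero-fill borders from large motions slightly depress NCC near the edge
  of the field of view; organs near the image border will register less
  accurately than the interior-placed phantom organs.
* The bootstrap p-value resolution is $1/(B+1)$; with the default
  $B = 5000$ the smallest attainable one-sided p is $2\times10^{-4}$.
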