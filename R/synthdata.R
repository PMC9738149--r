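# Synthetic data: 4D BOLD phantoms with known ground truth, and covariate
# cohorts with known effect sizes.
#
# The phantom emulates the features the downstream stages must cope with: a
# slow cyclical maternal-inflow component riding on a stationary baseline,
# cotyledon-like patches of heterogeneous amplitude inside the placenta, an
# independently fluctuating amniotic-fluid compartment, frame-to-frame rigid
# in-plane motion, and additive Gaussian noise.  It does not simulate MR
# physics (T2* decay, dielectric standing waves) or fetal cardiac dynamics.

#' Phantom specification
#'
#' Defaults describe a third-trimester acquisition: TR 2.28 s, 100 frames,
#' a ~7% peak inflow oscillation with a 45 s cycle, a dozen cotyledon
#' patches, ~1% thermal noise and sub-voxel motion.
#'
#' @param grid_shape integer vector (x, y, z, t); x >= 12, y >= 8, z >= 2,
#'   t >= 2.
#' @param tr_seconds repetition time (s).
#' @param baseline_intensity mean tissue intensity (arbitrary units).
#' @param inflow_amplitude fractional amplitude `a` of the cyclical
#'   maternal-inflow component (0 <= a < 1).
#' @param inflow_period_s period of the inflow cycle (s).
#' @param n_patches number of cotyledon-like amplitude patches (>= 0; 0 or 1
#'   gives a homogeneous placenta).
#' @param patch_amplitude_spread SD of per-patch fractional amplitudes around
#'   `inflow_amplitude`.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param motion_max_voxels per-slice translation bound (voxels).
#' @param motion_max_degrees per-slice rotation bound (degrees).
#' @param fluid_fraction approximate fraction of the grid assigned to the
#'   amniotic-fluid compartment, in [0, 1).
#' @param seed integer seed; identical seeds give bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 8L, 100L),
                         tr_seconds = 2.28,
                         baseline_intensity = 100,
                         inflow_amplitude = 0.1,
                         inflow_period_s = 45,
                         n_patches = 12L,
                         patch_amplitude_spread = 0.03,
                         noise_sd = 1,
                         motion_max_voxels = 1,
                         motion_max_degrees = 1,
                         fluid_fraction = 0.1,
                         seed = 1L) {
  chk_num(grid_shape, "grid_shape", len = 4L, lower = 1, integerish = TRUE)
  if (grid_shape[1] < 12 || grid_shape[2] < 8 || grid_shape[3] < 2) {
    abort2("field 'grid_shape' spatial dims must be at least 12 x 8 x 2",
           "boldvar_bad_field")
  }
  if (grid_shape[4] < 2) {
    abort2("field 'grid_shape' must have t >= 2", "boldvar_bad_field")
  }
  chk_num(tr_seconds, "tr_seconds", lower = 1e-6)
  chk_num(baseline_intensity, "baseline_intensity", lower = 1e-6)
  chk_num(inflow_amplitude, "inflow_amplitude", lower = 0, upper = 1 - 1e-9)
  chk_num(inflow_period_s, "inflow_period_s", lower = 1e-6)
  chk_num(n_patches, "n_patches", lower = 0, integerish = TRUE)
  chk_num(patch_amplitude_spread, "patch_amplitude_spread", lower = 0)
  chk_num(noise_sd, "noise_sd", lower = 0)
  chk_num(motion_max_voxels, "motion_max_voxels", lower = 0)
  chk_num(motion_max_degrees, "motion_max_degrees", lower = 0, upper = 45)
  chk_num(fluid_fraction, "fluid_fraction", lower = 0, upper = 1 - 1e-9)
  chk_num(seed, "seed", integerish = TRUE)
  structure(as.list(environment()), class = "phantom_spec")
}

# Deterministic disjoint tissue geometry on an (nx, ny, nz) grid: placental
# ellipsoid on the left, fetal-brain ellipsoid on the right, amniotic-fluid
# band between them sized by fluid_fraction.
phantom_masks <- function(nx, ny, nz, fluid_fraction) {
  u <- (seq_len(nx) - 0.5) / nx
  v <- (seq_len(ny) - 0.5) / ny
  w <- (seq_len(nz) - 0.5) / nz
  U <- array(rep(u, times = ny * nz), dim = c(nx, ny, nz))
  V <- array(rep(rep(v, each = nx), times = nz), dim = c(nx, ny, nz))
  W <- array(rep(w, each = nx * ny), dim = c(nx, ny, nz))

  placenta <- ((U - 0.32) / 0.22)^2 + ((V - 0.5) / 0.30)^2 <= 1
  brain <- ((U - 0.80) / 0.12)^2 + ((V - 0.5) / 0.20)^2 +
    ((W - 0.5) / 0.60)^2 <= 1
  fluid_hi <- min(0.56 + max(fluid_fraction, 1 / nx), 0.67)
  fluid <- U > 0.56 & U <= fluid_hi
  if (any(placenta & brain) || any(placenta & fluid) || any(brain & fluid)) {
    abort2("internal geometry error: phantom masks overlap",
           "boldvar_internal")
  }
  if (!any(placenta) || !any(brain) || !any(fluid)) {
    abort2("field 'grid_shape' too small to place disjoint tissue masks",
           "boldvar_bad_field")
  }
  list(placenta = placenta, brain = brain, fluid = fluid)
}

# Voronoi labelling of placenta voxels around Poisson-placed patch seeds.
assign_patches <- function(mask, n_patches) {
  idx <- which(mask, arr.ind = TRUE)
  if (n_patches <= 1L) return(rep(1L, nrow(idx)))
  k <- min(n_patches, nrow(idx))
  seeds <- idx[sample.int(nrow(idx), k), , drop = FALSE]
  d2 <- outer(idx[, 1], seeds[, 1], "-")^2 +
    outer(idx[, 2], seeds[, 2], "-")^2 +
    outer(idx[, 3], seeds[, 3], "-")^2
  max.col(-d2, ties.method = "first")
}

#' Generate a 4D BOLD phantom with analytic ground truth
#'
#' Voxel intensity in tissue is
#' `baseline * (1 + a_v * sin(2*pi*t*TR/period))` plus Gaussian noise, where
#' `a_v` is the (cotyledon-patch) amplitude at voxel v.  The fetal brain
#' carries a uniform-amplitude oscillation at a shorter period; the amniotic
#' fluid fluctuates with an independent low-frequency sinusoid so the
#' nuisance-regression stage has a real confound to remove.  Ground truth
#' holds the injected transforms, per-patch amplitudes, and the analytic
#' temporal/spatial variance of the noise-free, motion-free placental signal.
#'
#' @param spec a [phantom_spec()].
#' @return list with `series` ([bold_series()]), `masks` (named list of
#'   [voi_mask()]: placenta, brain, fluid), and `truth` (list with
#'   `true_transforms`, `true_patch_amplitudes`, `true_tv`, `true_sv`).
#' @export
generate_bold_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  d <- spec$grid_shape
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nt <- d[4]
  with_seed(spec$seed, {
    masks <- phantom_masks(nx, ny, nz, spec$fluid_fraction)
    tt <- seq_len(nt) - 1
    s_pl <- sin(2 * pi * tt * spec$tr_seconds / spec$inflow_period_s)
    s_br <- sin(2 * pi * tt * spec$tr_seconds /
                  (spec$inflow_period_s * 2 / 3) + 1)
    s_fl <- sin(2 * pi * tt * spec$tr_seconds /
                  (spec$inflow_period_s * 2) + 0.5)

    patch_of <- assign_patches(masks$placenta, spec$n_patches)
    n_patch_eff <- max(patch_of)
    patch_amp <- pmin(pmax(
      stats::rnorm(n_patch_eff, spec$inflow_amplitude,
                   spec$patch_amplitude_spread), 0), 0.95)
    if (spec$patch_amplitude_spread == 0 || n_patch_eff == 1L) {
      patch_amp <- rep(spec$inflow_amplitude, n_patch_eff)
    }
    amp_v <- patch_amp[patch_of]
    # static per-patch baseline contrast (cotyledons differ in blood volume,
    # so their mean T2*-weighted intensity differs); gives slices realistic
    # spatial texture without touching the fractional fluctuation amplitudes
    patch_base <- 1 + 0.08 * pmin(pmax(stats::rnorm(n_patch_eff), -2), 2)
    if (n_patch_eff == 1L) patch_base <- 1
    base_v <- patch_base[patch_of]
    # pin the realized volume-mean amplitude to the requested
    # inflow_amplitude: patch draws shape the across-voxel heterogeneity
    # (spatial variance), while the volume-mean fluctuation (temporal
    # variance) stays exactly the specified amplitude
    a_eff <- sum(base_v * amp_v) / sum(base_v)
    if (a_eff > 0 && spec$inflow_amplitude > 0) {
      patch_amp <- pmin(patch_amp * spec$inflow_amplitude / a_eff, 0.95)
      amp_v <- patch_amp[patch_of]
    }

    b <- spec$baseline_intensity
    D <- matrix(0.2 * b, nrow = nx * ny * nz, ncol = nt)
    D[which(masks$placenta), ] <- (b * base_v) * (1 + outer(amp_v, s_pl))
    D[which(masks$brain), ] <- rep(b * (1 + spec$inflow_amplitude * s_br),
                                   each = sum(masks$brain))
    D[which(masks$fluid), ] <- rep(b * (1 + 0.5 * spec$inflow_amplitude * s_fl),
                                   each = sum(masks$fluid))
    arr <- array(D, dim = c(nx, ny, nz, nt))

    # injected motion (frame 1 untransformed by convention)
    transforms <- NULL
    if (nt > 1 && (spec$motion_max_voxels > 0 || spec$motion_max_degrees > 0)) {
      grid <- expand.grid(slice = seq_len(nz), frame = 2:nt)
      transforms <- data.frame(
        frame = grid$frame, slice = grid$slice,
        dx = stats::runif(nrow(grid), -spec$motion_max_voxels,
                          spec$motion_max_voxels),
        dy = stats::runif(nrow(grid), -spec$motion_max_voxels,
                          spec$motion_max_voxels),
        theta = stats::runif(nrow(grid), -spec$motion_max_degrees,
                             spec$motion_max_degrees)
      )
      arr <- apply_motion(arr, transforms)
    }
    if (spec$noise_sd > 0) {
      arr <- arr + stats::rnorm(length(arr), 0, spec$noise_sd)
      arr[arr < 0] <- 0
    }

    # analytic (noise- and motion-free) ground truth on the placenta, from
    # the discrete sinusoid and known voxel amplitudes -- independent of the
    # metrics module
    s_bar <- mean(s_pl)
    a_bar <- mean(base_v * amp_v) / mean(base_v)  # baseline-weighted mean
    true_tv <- a_bar * stats::sd(s_pl) / (1 + a_bar * s_bar)
    M <- mean(abs(s_pl - s_bar))
    paf_v <- 100 * amp_v * M / (1 + amp_v * s_bar)
    true_sv <- if (mean(paf_v) == 0 || length(paf_v) < 2) 0 else
      stats::sd(paf_v / mean(paf_v))

    list(
      series = bold_series(arr, tr_seconds = spec$tr_seconds),
      masks = list(
        placenta = voi_mask(masks$placenta, "placenta"),
        brain = voi_mask(masks$brain, "brain"),
        fluid = voi_mask(masks$fluid, "fluid")
      ),
      truth = list(
        true_transforms = transforms,
        true_patch_amplitudes = patch_amp,
        true_tv = true_tv,
        true_sv = true_sv
      ),
      spec = spec
    )
  })
}

#' Cohort specification
#'
#' Describes a synthetic subject table: gestational age (GA) sampled
#' uniformly over `ga_range_weeks`, independent Bernoulli risk-factor and CHD
#' flags at the stated prevalences (matched to the study population:
#' obesity ~0.5, hypertension ~0.2, diabetes ~0.1, CHD ~1/3), and a linear
#' model on the target metric,
#' `metric = beta0 + beta_ga*GA + beta_mrf*MRF + beta_chd*CHD +
#'  beta_interaction*MRF*CHD + eps`,
#' where MRF is the any-risk-factor indicator and the residual SD grows with
#' standardized GA (`noise_sd * max(1 + hetero_scale * z(GA), 0.1)`), making
#' the data genuinely heteroskedastic.  Metrics are on the percent scale used
#' throughout (temporal variance of ~7 means a 7% fluctuation).
#'
#' @param n_subjects number of subjects (>= 4).
#' @param ga_range_weeks gestational-age window, within [27, 42] weeks.
#' @param prev_obesity,prev_hypertension,prev_diabetes,prev_chd prevalences
#'   in [0, 1].
#' @param beta0,beta_ga,beta_mrf,beta_chd,beta_interaction linear-model
#'   effects on the target metric.
#' @param hetero_scale residual-SD growth per SD of GA (>= 0).
#' @param noise_sd baseline residual SD.
#' @param metric target metric column name.
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 100L,
                        ga_range_weeks = c(27, 42),
                        prev_obesity = 0.5,
                        prev_hypertension = 0.2,
                        prev_diabetes = 0.1,
                        prev_chd = 0.35,
                        beta0 = 7,
                        beta_ga = 0.1,
                        beta_mrf = -0.5,
                        beta_chd = 0,
                        beta_interaction = 0,
                        hetero_scale = 0.5,
                        noise_sd = 0.3,
                        metric = "tv_placenta",
                        seed = 1L) {
  chk_num(n_subjects, "n_subjects", lower = 4, integerish = TRUE)
  chk_num(ga_range_weeks, "ga_range_weeks", len = 2L, lower = 27, upper = 42)
  if (ga_range_weeks[1] > ga_range_weeks[2]) {
    abort2("field 'ga_range_weeks' must be (low, high)", "boldvar_bad_field")
  }
  chk_num(prev_obesity, "prev_obesity", lower = 0, upper = 1)
  chk_num(prev_hypertension, "prev_hypertension", lower = 0, upper = 1)
  chk_num(prev_diabetes, "prev_diabetes", lower = 0, upper = 1)
  chk_num(prev_chd, "prev_chd", lower = 0, upper = 1)
  for (nm in c("beta0", "beta_ga", "beta_mrf", "beta_chd",
               "beta_interaction")) {
    chk_num(get(nm), nm)
  }
  chk_num(hetero_scale, "hetero_scale", lower = 0)
  chk_num(noise_sd, "noise_sd", lower = 0)
  stopifnot(is.character(metric), length(metric) == 1L)
  chk_num(seed, "seed", integerish = TRUE)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic subject table
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `subject_id`, `ga_weeks`, `chd`,
#'   `obesity`, `hypertension`, `diabetes`, `any_mrf`, `tv_placenta`,
#'   `sv_placenta`, `tv_brain`, `sv_brain`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  n <- spec$n_subjects
  with_seed(spec$seed, {
    ga <- stats::runif(n, spec$ga_range_weeks[1], spec$ga_range_weeks[2])
    obesity <- stats::rbinom(n, 1, spec$prev_obesity)
    hypertension <- stats::rbinom(n, 1, spec$prev_hypertension)
    diabetes <- stats::rbinom(n, 1, spec$prev_diabetes)
    chd <- stats::rbinom(n, 1, spec$prev_chd)
    any_mrf <- as.integer(obesity | hypertension | diabetes)

    zga <- if (stats::sd(ga) > 0) (ga - mean(ga)) / stats::sd(ga) else
      rep(0, n)
    sd_i <- spec$noise_sd * pmax(1 + spec$hetero_scale * zga, 0.1)
    eps <- stats::rnorm(n, 0, 1) * sd_i
    target <- spec$beta0 + spec$beta_ga * ga + spec$beta_mrf * any_mrf +
      spec$beta_chd * chd + spec$beta_interaction * any_mrf * chd + eps

    # null companion metrics: plausible baselines with a GA trend and
    # homoskedastic noise, no risk-factor effects
    null_metric <- function(b0, slope, sd0) {
      b0 + slope * (ga - 34) + stats::rnorm(n, 0, sd0)
    }
    out <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      ga_weeks = ga, chd = chd, obesity = obesity,
      hypertension = hypertension, diabetes = diabetes, any_mrf = any_mrf,
      tv_placenta = null_metric(7, 0.10, 0.5),
      sv_placenta = null_metric(40, 0.50, 3),
      tv_brain = null_metric(5, 0.05, 0.4),
      sv_brain = null_metric(35, 0.20, 3),
      stringsAsFactors = FALSE
    )
    if (!spec$metric %in% names(out)) {
      abort2(sprintf("field 'metric' unknown: %s", spec$metric),
             "boldvar_bad_field")
    }
    out[[spec$metric]] <- target
    out
  })
}
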