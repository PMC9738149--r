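# End-to-end orchestration: phantom/cohort generation (or real NIfTI input)
# -> preprocessing -> metrics -> statistics, with QC accounting and
# deterministic seeding.

#' Pipeline run configuration
#'
#' Exactly one of `synthetic` (a synthetic-cohort description) or `inputs`
#' (paths to real data) must be given.
#'
#' @param synthetic list with elements `cohort` (a [cohort_spec()] or
#'   argument list) and optionally `phantom` (argument list overriding
#'   [phantom_spec()] defaults for the per-subject phantoms).
#' @param inputs list with `manifest` (CSV path with columns `subject_id`,
#'   `bold`, `placenta`, `brain`, `fluid` pointing at NIfTI files) and
#'   `covariates` (CSV path with `subject_id`, `ga_weeks`, `chd`, `obesity`,
#'   `hypertension`, `diabetes`).
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed; every stochastic stage derives its seed
#'   from it.
#' @param n_boot wild-bootstrap replicates for the battery.
#' @param direction one-sided direction for the battery.
#' @param filter_fwhm_frames temporal filter width (frames, 0 = off).
#' @param fluid_regression logical, amniotic-fluid nuisance regression.
#' @param n_voi_slices placental VOI slice-window depth (see
#'   [restrict_slices()]).
#' @param motion_correction logical, run [motion_correct()].
#' @param registration list of registration bounds: `max_shift`,
#'   `max_theta`, `theta_step`.
#' @param paf_convention PAF convention, see [voxel_paf()].
#' @return object of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, inputs = NULL, out_dir = tempfile(),
                       seed, n_boot = 1000L, direction = "less",
                       filter_fwhm_frames = 3, fluid_regression = TRUE,
                       n_voi_slices = 5L, motion_correction = TRUE,
                       registration = list(max_shift = 5L, max_theta = 10,
                                           theta_step = 2),
                       paf_convention = "mad") {
  if (is.null(synthetic) == is.null(inputs)) {
    abort2("exactly one of 'synthetic' or 'inputs' must be supplied",
           "boldvar_bad_config")
  }
  if (missing(seed)) {
    abort2("a seed is mandatory when any stochastic stage is enabled",
           "boldvar_bad_config")
  }
  chk_num(seed, "seed", integerish = TRUE)
  chk_num(n_boot, "n_boot", lower = 100, integerish = TRUE)
  cfg <- structure(as.list(environment()), class = "run_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!is.null(cfg$inputs)) {
    for (f in c("manifest", "covariates")) {
      if (is.null(cfg$inputs[[f]]) || !file.exists(cfg$inputs[[f]])) {
        abort2(sprintf("input file missing: %s", cfg$inputs[[f]] %||% f),
               "boldvar_missing_file")
      }
    }
    man <- utils::read.csv(cfg$inputs$manifest, stringsAsFactors = FALSE)
    need <- c("subject_id", "bold", "placenta", "brain", "fluid")
    if (!all(need %in% names(man))) {
      abort2("manifest must have columns subject_id, bold, placenta, brain, fluid",
             "boldvar_bad_config")
    }
    for (col in c("bold", "placenta", "brain", "fluid")) {
      missing_files <- man[[col]][!file.exists(man[[col]])]
      if (length(missing_files) > 0) {
        abort2(sprintf("missing %s file: %s", col, missing_files[1]),
               "boldvar_missing_file")
      }
    }
  }
  if (!is.null(cfg$synthetic) && is.null(cfg$synthetic$cohort)) {
    abort2("synthetic config needs a 'cohort' element", "boldvar_bad_config")
  }
  invisible(TRUE)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[setdiff(names(cfg), "out_dir")]), f)
  unname(tools::md5sum(f))
}

# Fractional inflow amplitude reproducing a target (noise-free) temporal
# variance, in percent, given the discrete inflow sinusoid: inverts
# tv = a sd(s) / (1 + a mean(s)).
amplitude_for_tv <- function(tv_pct, s) {
  tv <- pmax(tv_pct, 0.5) / 100
  a <- tv / (stats::sd(s) - tv * mean(s))
  pmin(pmax(a, 0.001), 0.9)
}

preprocess_and_measure <- function(series, masks, cfg, log) {
  qc <- list()
  if (isTRUE(cfg$motion_correction)) {
    mc <- motion_correct(series, reference_frame = 1L,
                         max_shift = cfg$registration$max_shift,
                         max_theta = cfg$registration$max_theta,
                         theta_step = cfg$registration$theta_step)
    series <- mc$series
    qc$mean_ncc_before <- mc$qc$mean_ncc_before
    qc$mean_ncc_after <- mc$qc$mean_ncc_after
  }
  pl_mask <- restrict_slices(masks$placenta, cfg$n_voi_slices)
  series <- denoise(series, pl_mask, masks$fluid,
                    filter_fwhm_frames = cfg$filter_fwhm_frames,
                    fluid_regression = cfg$fluid_regression)
  pl <- variance_metrics(series, pl_mask, tissue = "placenta",
                         convention = cfg$paf_convention)
  br <- variance_metrics(series, masks$brain, tissue = "brain",
                         convention = cfg$paf_convention)
  qc$n_excluded_voxels <- pl$n_excluded_voxels + br$n_excluded_voxels
  qc$n_frames <- pl$n_frames
  list(placenta = pl, brain = br, qc = qc)
}

#' Run the full pipeline
#'
#' Stages run in order (simulate/load -> preprocess -> metrics -> stats);
#' every output carries the configuration hash and master seed, and a rerun
#' with the same configuration reproduces the metrics bit-exactly and the
#' statistics exactly.  Any stage error aborts with the stage name and
#' subject id; on abort the QC report on disk is flagged incomplete.
#'
#' @param cfg a [run_config()].
#' @return list with `cohort` (covariates + measured metrics), `stats`
#'   (the [mrf_battery()] table), `group` (per-metric [group_compare()]
#'   results), `qc`, and `paths` to the written files (`cohort.csv`,
#'   `metrics.csv`, `stats.csv`, `group_comparison.json`, `qc.json`,
#'   `log.txt`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  validate_config(cfg)  # fail fast before any computation
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "log.txt")
  log_lines <- character()
  log <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  hash <- config_hash(cfg)
  log("run start: config %s, seed %d", hash, cfg$seed)

  qc_path <- file.path(cfg$out_dir, "qc.json")
  stage <- "init"; subject <- NA_character_
  on_abort <- function(e) {
    jsonlite::write_json(
      list(status = "incomplete", stage = stage, subject = subject,
           config_hash = hash, seed = cfg$seed,
           error = conditionMessage(e)),
      qc_path, auto_unbox = TRUE)
    writeLines(c(log_lines, sprintf("ABORT in stage '%s' (subject %s): %s",
                                    stage, subject, conditionMessage(e))),
               log_path)
    abort2(sprintf("pipeline aborted in stage '%s' (subject %s): %s",
                   stage, subject, conditionMessage(e)),
           "boldvar_pipeline_error")
  }

  result <- tryCatch({
    if (!is.null(cfg$synthetic)) {
      stage <- "simulate"
      cohort_sp <- cfg$synthetic$cohort
      if (!inherits(cohort_sp, "cohort_spec")) {
        cohort_sp <- do.call(cohort_spec, cohort_sp)
      }
      cohort_sp$seed <- derive_seeds(cfg$seed, 1L)
      cohort <- generate_cohort(cohort_sp)
      target <- cohort[[cohort_sp$metric]]
      n <- nrow(cohort)
      subject_seeds <- derive_seeds(cfg$seed + 1L, n)
      phantom_args <- cfg$synthetic$phantom %||% list()

      # probe sinusoid for the amplitude inversion (depends only on the
      # phantom timing parameters)
      probe <- do.call(phantom_spec, phantom_args)
      tt <- seq_len(probe$grid_shape[4]) - 1
      s <- sin(2 * pi * tt * probe$tr_seconds / probe$inflow_period_s)

      log("simulate: %d subjects, grid %s", n,
          paste(probe$grid_shape, collapse = "x"))
      rows <- vector("list", n)
      qcs <- vector("list", n)
      for (i in seq_len(n)) {
        subject <- cohort$subject_id[i]
        stage <- "simulate"
        a_i <- amplitude_for_tv(target[i], s)
        args_i <- phantom_args
        args_i$inflow_amplitude <- a_i
        args_i$patch_amplitude_spread <- 0.3 * a_i
        args_i$seed <- subject_seeds[i]
        ph <- generate_bold_phantom(do.call(phantom_spec, args_i))
        stage <- "preprocess"
        meas <- preprocess_and_measure(ph$series, ph$masks, cfg, log)
        stage <- "metrics"
        rows[[i]] <- data.frame(
          subject_id = subject,
          tv_placenta = 100 * meas$placenta$temporal_variance,
          sv_placenta = 100 * meas$placenta$spatial_variance,
          tv_brain = 100 * meas$brain$temporal_variance,
          sv_brain = 100 * meas$brain$spatial_variance,
          n_voxels_placenta = meas$placenta$n_voxels,
          n_voxels_brain = meas$brain$n_voxels,
          n_frames = meas$placenta$n_frames,
          n_excluded_voxels = meas$qc$n_excluded_voxels,
          stringsAsFactors = FALSE)
        qcs[[i]] <- c(list(subject_id = subject), meas$qc)
      }
      subject <- NA_character_
      measured <- do.call(rbind, rows)
      covars <- cohort[c("subject_id", "ga_weeks", "chd", "obesity",
                         "hypertension", "diabetes", "any_mrf")]
      cohort_out <- merge(covars, measured, by = "subject_id", sort = FALSE)
    } else {
      stage <- "load"
      man <- utils::read.csv(cfg$inputs$manifest, stringsAsFactors = FALSE)
      covars <- utils::read.csv(cfg$inputs$covariates,
                                stringsAsFactors = FALSE)
      covars$any_mrf <- as.integer(covars$obesity | covars$hypertension |
                                     covars$diabetes)
      log("load: %d subjects from %s", nrow(man), cfg$inputs$manifest)
      rows <- vector("list", nrow(man))
      qcs <- vector("list", nrow(man))
      for (i in seq_len(nrow(man))) {
        subject <- man$subject_id[i]
        stage <- "load"
        nii <- read_nifti(man$bold[i])
        series <- bold_series(nii$data, voxel_size_mm = nii$voxel_size_mm,
                              tr_seconds = if (is.na(nii$tr_seconds) ||
                                               nii$tr_seconds <= 0) 2.28 else
                                nii$tr_seconds)
        masks <- list(
          placenta = voi_mask(read_nifti(man$placenta[i])$data > 0,
                              "placenta"),
          brain = voi_mask(read_nifti(man$brain[i])$data > 0, "brain"),
          fluid = voi_mask(read_nifti(man$fluid[i])$data > 0, "fluid"))
        stage <- "preprocess"
        meas <- preprocess_and_measure(series, masks, cfg, log)
        stage <- "metrics"
        rows[[i]] <- data.frame(
          subject_id = subject,
          tv_placenta = 100 * meas$placenta$temporal_variance,
          sv_placenta = 100 * meas$placenta$spatial_variance,
          tv_brain = 100 * meas$brain$temporal_variance,
          sv_brain = 100 * meas$brain$spatial_variance,
          n_voxels_placenta = meas$placenta$n_voxels,
          n_voxels_brain = meas$brain$n_voxels,
          n_frames = meas$placenta$n_frames,
          n_excluded_voxels = meas$qc$n_excluded_voxels,
          stringsAsFactors = FALSE)
        qcs[[i]] <- c(list(subject_id = subject), meas$qc)
      }
      subject <- NA_character_
      measured <- do.call(rbind, rows)
      cohort_out <- merge(covars, measured, by = "subject_id", sort = FALSE)
    }

    stage <- "stats"
    log("stats: wild bootstrap battery, B = %d", cfg$n_boot)
    battery <- mrf_battery(cohort_out, n_boot = cfg$n_boot,
                           seed = derive_seeds(cfg$seed + 2L, 1L),
                           direction = cfg$direction)
    group <- lapply(
      stats::setNames(nm = c("tv_placenta", "sv_placenta", "tv_brain",
                             "sv_brain")),
      function(m) group_compare(cohort_out, m, n_perm = 1000L,
                                seed = derive_seeds(cfg$seed + 3L, 1L)))

    stage <- "write"
    paths <- list(
      cohort = file.path(cfg$out_dir, "cohort.csv"),
      metrics = file.path(cfg$out_dir, "metrics.csv"),
      stats = file.path(cfg$out_dir, "stats.csv"),
      group = file.path(cfg$out_dir, "group_comparison.json"),
      qc = qc_path, log = log_path)
    utils::write.csv(cohort_out, paths$cohort, row.names = FALSE)
    utils::write.csv(measured, paths$metrics, row.names = FALSE)
    utils::write.csv(cbind(battery, config_hash = hash), paths$stats,
                     row.names = FALSE)
    jsonlite::write_json(group, paths$group, auto_unbox = TRUE, digits = NA)
    qc <- list(status = "complete", config_hash = hash, seed = cfg$seed,
               n_input_subjects = nrow(cohort_out),
               n_analyzed = nrow(cohort_out), n_dropped = 0L,
               subjects = qcs)
    jsonlite::write_json(qc, qc_path, auto_unbox = TRUE, digits = NA)
    log("run complete: %d subjects analyzed", nrow(cohort_out))
    writeLines(log_lines, log_path)
    list(cohort = cohort_out, stats = battery, group = group, qc = qc,
         paths = paths, config_hash = hash)
  }, error = function(e) {
    if (inherits(e, "boldvar_pipeline_error")) stop(e)
    on_abort(e)
  })
  invisible(result)
}

#' Pick the stillest of several repeated series
#'
#' Quantitative stand-in for choosing "the series with the least observed
#' motion" between repeated acquisitions: the series maximizing the mean
#' frame-to-frame NCC wins; ties go to the lowest index.
#'
#' @param series_list list of [bold_series()] or 4D arrays.
#' @return integer index into `series_list`.
#' @export
select_series <- function(series_list) {
  if (!is.list(series_list) || length(series_list) == 0) {
    abort2("series_list must be a non-empty list", "boldvar_bad_field")
  }
  scores <- vapply(series_list, qc_mean_ncc, numeric(1))
  which.max(scores)  # first index on ties
}
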