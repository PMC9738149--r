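# Preprocessing: VOI propagation, inter-slice rigid motion correction with a
# normalized cross-correlation cost, and denoising (temporal low-pass filter
# plus amniotic-fluid nuisance regression).

#' Propagate a first-frame VOI through time
#'
#' The VOI drawn on the first frame is copied unchanged to every frame.
#'
#' @param mask a [voi_mask()] or 3D binary array.
#' @param n_frames number of frames (>= 1).
#' @return 4D logical array (x, y, z, t), one identical mask per frame.
#' @export
propagate_voi <- function(mask, n_frames) {
  m <- as_mask_array(mask)
  chk_num(n_frames, "n_frames", lower = 1, integerish = TRUE)
  if (!any(m)) {
    abort2("VOI mask must contain at least one voxel", "boldvar_empty_mask")
  }
  array(m, dim = c(dim(m), n_frames))
}

#' Restrict a VOI to its densest consecutive axial slices
#'
#' Keeps the `n_slices` consecutive axial slices that maximize the in-mask
#' voxel count (ties broken toward the lowest slice index) and zeroes the
#' rest; used when the full organ is not covered and a fixed-depth window is
#' analyzed instead.
#'
#' @param mask a [voi_mask()] or 3D binary array.
#' @param n_slices window depth (>= 1); clamped to the grid depth with a
#'   warning when it exceeds it.
#' @return object of the same type as `mask`.
#' @export
restrict_slices <- function(mask, n_slices = 5L) {
  m <- as_mask_array(mask)
  chk_num(n_slices, "n_slices", lower = 1, integerish = TRUE)
  nz <- dim(m)[3]
  if (n_slices >= nz) {
    if (n_slices > nz) {
      warning(sprintf("n_slices = %d exceeds grid depth %d; clamped",
                      n_slices, nz))
    }
    return(mask)
  }
  counts <- apply(m, 3, sum)
  win <- vapply(seq_len(nz - n_slices + 1L),
                function(z0) sum(counts[z0:(z0 + n_slices - 1L)]),
                numeric(1))
  z0 <- which.max(win)  # which.max takes the first (lowest) index on ties
  keep <- z0:(z0 + n_slices - 1L)
  m[, , setdiff(seq_len(nz), keep)] <- FALSE
  if (inherits(mask, "voi_mask")) voi_mask(m, mask$label) else m
}

#' Normalized cross-correlation of two images
#'
#' `sum((a - mean(a)) * (b - mean(b))) / sqrt(sum((a - mean(a))^2) *
#' sum((b - mean(b))^2))`, in \[-1, 1\].
#'
#' @param image_a,image_b numeric arrays of equal shape with nonzero
#'   intensity variance.
#' @return scalar correlation.
#' @export
ncc <- function(image_a, image_b) {
  if (!identical(dim(image_a) %||% length(image_a),
                 dim(image_b) %||% length(image_b))) {
    abort2("image_a and image_b must have equal shapes", "boldvar_bad_field")
  }
  a <- as.numeric(image_a) - mean(image_a)
  b <- as.numeric(image_b) - mean(image_b)
  va <- sum(a * a); vb <- sum(b * b)
  if (va == 0) abort2("image_a has zero variance", "boldvar_zero_variance")
  if (vb == 0) abort2("image_b has zero variance", "boldvar_zero_variance")
  sum(a * b) / sqrt(va * vb)
}

#' Mean frame-to-frame NCC quality score
#'
#' Quantitative proxy for "least observed motion": the mean, over consecutive
#' frame pairs and axial slices, of the slicewise NCC.  Higher is stiller.
#'
#' @param series a [bold_series()] or 4D array.
#' @return scalar in \[-1, 1\] (NA if every slice is constant).
#' @export
qc_mean_ncc <- function(series) {
  arr <- as_series_array(series)
  d <- dim(arr)
  vals <- c()
  for (f in 2:d[4]) {
    for (z in seq_len(d[3])) {
      a <- arr[, , z, f - 1]; b <- arr[, , z, f]
      if (stats::sd(a) > 0 && stats::sd(b) > 0) {
        vals <- c(vals, ncc(a, b))
      }
    }
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

#' Inter-slice rigid motion correction
#'
#' For every frame other than the reference and every axial slice, estimates
#' the in-plane rigid transform (dx, dy, theta) maximizing the normalized
#' cross-correlation against the matching reference slice, then resamples the
#' slice under it (bilinear).  The search is a coarse grid (translations
#' step 1 voxel, rotations step `theta_step` degrees) followed by
#' golden-section refinement per parameter; the identity transform is part of
#' the search, so the corrected NCC never falls below the uncorrected NCC.
#' Slices with zero intensity variance pass through under the identity with a
#' warning.
#'
#' @param series a [bold_series()] or 4D array (t >= 2).
#' @param reference_frame frame registered against (default 1, the
#'   segmentation frame).
#' @param max_shift,max_theta search bounds (voxels, degrees).
#' @param theta_step coarse rotation step (degrees); 0 disables rotation.
#' @param shift_tol,theta_tol refinement tolerances.
#' @return list with `series` (corrected), `transforms` (data.frame `frame`,
#'   `slice`, `dx`, `dy`, `theta`, `ncc_before`, `ncc_after`) and `qc`
#'   (mean NCC against the reference before/after).
#' @export
motion_correct <- function(series, reference_frame = 1L, max_shift = 5L,
                           max_theta = 10, theta_step = 2,
                           shift_tol = 0.05, theta_tol = 0.1) {
  arr <- as_series_array(series)
  d <- dim(arr)
  chk_num(reference_frame, "reference_frame", lower = 1, upper = d[4],
          integerish = TRUE)
  out <- arr
  rows <- list()
  n_skipped <- 0L
  for (f in setdiff(seq_len(d[4]), reference_frame)) {
    for (z in seq_len(d[3])) {
      ref <- arr[, , z, reference_frame]
      mov <- arr[, , z, f]
      if (stats::sd(ref) == 0 || stats::sd(mov) == 0) {
        n_skipped <- n_skipped + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          frame = f, slice = z, dx = 0, dy = 0, theta = 0,
          ncc_before = NA_real_, ncc_after = NA_real_)
        next
      }
      fit <- cpp_register_slice(ref, mov, as.integer(max_shift), max_theta,
                                theta_step, shift_tol, theta_tol)
      out[, , z, f] <- cpp_resample_rigid(mov, fit[1], fit[2], fit[3])
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, slice = z, dx = fit[1], dy = fit[2], theta = fit[3],
        ncc_before = fit[5], ncc_after = fit[4])
    }
  }
  if (n_skipped > 0) {
    warning(sprintf("%d zero-variance slice(s) passed through unregistered",
                    n_skipped))
  }
  transforms <- do.call(rbind, rows)
  res <- if (inherits(series, "bold_series")) {
    bold_series(pmax(out, 0), series$voxel_size_mm, series$tr_seconds)
  } else {
    out
  }
  list(
    series = res,
    transforms = transforms,
    qc = list(mean_ncc_before = mean(transforms$ncc_before, na.rm = TRUE),
              mean_ncc_after = mean(transforms$ncc_after, na.rm = TRUE),
              n_zero_variance_slices = n_skipped)
  )
}

# Truncated, renormalized Gaussian smoothing matrix acting on the time axis.
gaussian_time_weights <- function(nt, fwhm_frames) {
  sigma <- fwhm_frames / (2 * sqrt(2 * log(2)))
  W <- exp(-(outer(seq_len(nt), seq_len(nt), "-"))^2 / (2 * sigma^2))
  W / rowSums(W)
}

#' Denoise a BOLD series
#'
#' Two sequential steps: (1) per-voxel temporal low-pass filtering with a
#' truncated Gaussian kernel (default FWHM 3 frames; 0 disables); (2) the
#' amniotic-fluid mean time course (centred, unit-variance) is regressed out
#' of every VOI voxel's time course.  The regressor is centred, so each
#' voxel's temporal mean is preserved and intensities keep their scale.  An
#' empty or constant fluid course skips step (2) with a warning.
#'
#' @param series a [bold_series()] or 4D array (t >= 3).
#' @param voi VOI whose voxels receive the nuisance regression.
#' @param fluid amniotic-fluid mask (disjoint from `voi`).
#' @param filter_fwhm_frames Gaussian FWHM in frames (0 = no filtering).
#' @param fluid_regression set `FALSE` to skip the nuisance regression.
#' @return denoised series, same type as the input.
#' @export
denoise <- function(series, voi, fluid, filter_fwhm_frames = 3,
                    fluid_regression = TRUE) {
  arr <- as_series_array(series)
  d <- dim(arr)
  if (d[4] < 3) abort2("denoise() needs t >= 3", "boldvar_bad_field")
  vm <- as_mask_array(voi)
  fm <- as_mask_array(fluid)
  check_same_grid(arr, vm); check_same_grid(arr, fm)
  if (any(vm & fm)) {
    abort2("VOI and fluid masks must be disjoint", "boldvar_bad_field")
  }
  chk_num(filter_fwhm_frames, "filter_fwhm_frames", lower = 0)

  D <- matrix(arr, nrow = prod(d[1:3]), ncol = d[4])
  if (filter_fwhm_frames > 0) {
    W <- gaussian_time_weights(d[4], filter_fwhm_frames)
    D <- D %*% t(W)
  }
  if (fluid_regression) {
    fidx <- which(fm)
    if (length(fidx) == 0) {
      warning("empty fluid mask: nuisance regression skipped")
    } else {
      f <- colMeans(D[fidx, , drop = FALSE])
      fc <- f - mean(f)
      if (stats::sd(fc) == 0) {
        warning("constant fluid course: nuisance regression skipped")
      } else {
        fs <- fc / stats::sd(fc)
        vidx <- which(vm)
        Y <- D[vidx, , drop = FALSE]
        beta <- (Y %*% fs) / sum(fs^2)
        D[vidx, ] <- Y - beta %*% t(fs)
      }
    }
  }
  out <- array(D, dim = d)
  if (inherits(series, "bold_series")) {
    bold_series(pmax(out, 0), series$voxel_size_mm, series$tr_seconds)
  } else {
    out
  }
}
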