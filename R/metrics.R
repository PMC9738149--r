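# The two summary statistics: temporal variance (TV) of the unity-mean
# normalized VOI-average signal, and spatial variance (SV) of mean-normalized
# per-voxel percent amplitude fluctuation (PAF).  Both are dimensionless and
# invariant to global intensity rescaling.

#' VOI-average signal time course
#'
#' Element t is the arithmetic mean of in-mask intensities of frame t.
#'
#' @param series a [bold_series()] or 4D array.
#' @param masks a 3D mask (applied to every frame) or a 4D per-frame mask
#'   stack from [propagate_voi()].
#' @return numeric vector of length `n_frames`.
#' @export
volume_mean_course <- function(series, masks) {
  arr <- as_series_array(series)
  d <- dim(arr)
  if (inherits(masks, "voi_mask") ||
      (is.array(masks) && length(dim(masks)) == 3L)) {
    masks <- propagate_voi(masks, d[4])
  }
  if (!is.array(masks) || length(dim(masks)) != 4L ||
      !identical(dim(masks)[1:3], d[1:3]) || dim(masks)[4] != d[4]) {
    abort2("masks must match the series grid, one mask per frame",
           "boldvar_bad_field")
  }
  vapply(seq_len(d[4]), function(f) {
    m <- masks[, , , f]
    if (!any(m)) {
      abort2(sprintf("empty mask at frame %d", f), "boldvar_empty_mask")
    }
    mean(arr[, , , f][m])
  }, numeric(1))
}

#' Normalize a time course to unity mean
#'
#' Divides by the temporal mean so the output has mean 1, removing arbitrary
#' scanner gain.  Within-subject only: each course is normalized to its own
#' mean.
#'
#' @param x numeric vector with positive mean.
#' @return `x / mean(x)`.
#' @export
normalize_unity_mean <- function(x) {
  if (!is.numeric(x) || length(x) < 1 || anyNA(x) || !all(is.finite(x))) {
    abort2("'x' must be a finite numeric vector", "boldvar_bad_field")
  }
  m <- mean(x)
  if (m <= 0) {
    abort2("cannot normalize a course with non-positive mean (corrupt or empty VOI)",
           "boldvar_nonpositive_mean")
  }
  x / m
}

#' Temporal variance of the VOI-average signal
#'
#' Sample standard deviation (denominator n-1) of the unity-mean normalized
#' VOI-average course.  A proxy for the cyclical maternal-inflow oxygenation
#' fluctuation.
#'
#' @inheritParams volume_mean_course
#' @return nonnegative scalar.
#' @export
temporal_variance <- function(series, masks) {
  course <- volume_mean_course(series, masks)
  if (length(course) < 2) {
    abort2("temporal variance needs at least 2 frames", "boldvar_bad_field")
  }
  stats::sd(normalize_unity_mean(course))
}

#' Percent amplitude fluctuation of one voxel time course
#'
#' Mean absolute deviation from the temporal mean, as a percentage of that
#' mean: `100 * mean(|x - mu|) / mu`.  The alternative SD-based convention
#' (`100 * sd(x) / mu`) is available via `convention = "sd"`.
#'
#' @param x numeric time course, length >= 2, positive mean.
#' @param convention `"mad"` (default) or `"sd"`.
#' @return nonnegative scalar (percent).
#' @export
voxel_paf <- function(x, convention = c("mad", "sd")) {
  convention <- match.arg(convention)
  if (length(x) < 2) abort2("PAF needs length >= 2", "boldvar_bad_field")
  mu <- mean(x)
  if (mu <= 0) {
    abort2("voxel course has non-positive mean", "boldvar_nonpositive_mean")
  }
  if (convention == "mad") 100 * mean(abs(x - mu)) / mu else
    100 * stats::sd(x) / mu
}

#' Per-voxel PAF map over a VOI
#'
#' Voxels with non-positive temporal mean violate the PAF precondition; they
#' are excluded and counted in the `n_excluded` attribute (a QC tally).
#'
#' @param series a [bold_series()] or 4D array.
#' @param mask a [voi_mask()] or 3D binary array.
#' @param convention PAF convention, see [voxel_paf()].
#' @return numeric vector of PAF values (percent) for the retained VOI
#'   voxels, with attribute `n_excluded`.
#' @export
paf_map <- function(series, mask, convention = c("mad", "sd")) {
  convention <- match.arg(convention)
  arr <- as_series_array(series)
  m <- as_mask_array(mask)
  check_same_grid(arr, m)
  d <- dim(arr)
  X <- matrix(arr, nrow = prod(d[1:3]), ncol = d[4])[which(m), , drop = FALSE]
  mu <- rowMeans(X)
  keep <- mu > 0
  X <- X[keep, , drop = FALSE]
  mu <- mu[keep]
  vals <- if (convention == "mad") {
    100 * rowMeans(abs(X - mu)) / mu
  } else {
    100 * apply(X, 1, stats::sd) / mu
  }
  structure(vals, n_excluded = sum(!keep))
}

#' Spatial variance of the PAF field
#'
#' Per-voxel PAF values are normalized by their across-voxel mean and the
#' sample standard deviation of the normalized values is returned; a proxy
#' for perfusion heterogeneity across cotyledons.  Scale-independent by
#' construction.  An all-constant VOI (mean PAF 0) returns 0 with a warning.
#'
#' @inheritParams paf_map
#' @return nonnegative scalar.
#' @export
spatial_variance <- function(series, mask, convention = c("mad", "sd")) {
  vals <- paf_map(series, mask, convention)
  if (length(vals) < 2) {
    abort2("spatial variance needs at least 2 valid voxels",
           "boldvar_bad_field")
  }
  m <- mean(vals)
  if (m == 0) {
    warning("mean PAF is zero (all-constant VOI); spatial variance set to 0")
    return(0)
  }
  stats::sd(vals / m)
}

#' Both variance metrics for one tissue
#'
#' @inheritParams paf_map
#' @param tissue tissue label recorded in the result.
#' @return object of class `variance_metrics`: list with
#'   `temporal_variance`, `spatial_variance`, `n_voxels`, `n_frames`,
#'   `n_excluded_voxels`, `tissue`.
#' @export
variance_metrics <- function(series, mask, tissue = "placenta",
                             convention = c("mad", "sd")) {
  convention <- match.arg(convention)
  arr <- as_series_array(series)
  m <- as_mask_array(mask)
  pm <- paf_map(arr, m, convention)
  structure(
    list(
      temporal_variance = temporal_variance(arr, m),
      spatial_variance = spatial_variance(arr, m, convention),
      n_voxels = sum(m),
      n_frames = dim(arr)[4],
      n_excluded_voxels = attr(pm, "n_excluded"),
      tissue = tissue
    ),
    class = "variance_metrics"
  )
}

#' @export
print.variance_metrics <- function(x, ...) {
  cat(sprintf(
    "<variance_metrics> %s: TV = %.4g, SV = %.4g (%d voxels, %d frames, %d excluded)\n",
    x$tissue, x$temporal_variance, x$spatial_variance, x$n_voxels,
    x$n_frames, x$n_excluded_voxels))
  invisible(x)
}
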