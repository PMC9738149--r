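# Rigid in-plane transforms shared by the phantom generator (motion
# injection) and the preprocessing stage (motion correction).
#
# A transform (dx, dy, theta) maps p to R_theta (p - c) + c + (dx, dy) with c
# the slice centre; resampling is inverse-mapped bilinear with zero fill.
# Translations are in voxels, theta in degrees (counter-clockwise in the
# x-y plane).

#' Resample a 2D slice under a rigid transform
#'
#' @param slice 2D numeric matrix.
#' @param dx,dy translation in voxels.
#' @param theta rotation in degrees about the slice centre.
#' @return resampled matrix of the same shape (bilinear, zero fill).
#' @export
rigid_resample <- function(slice, dx = 0, dy = 0, theta = 0) {
  if (!is.matrix(slice)) {
    abort2("'slice' must be a matrix", "boldvar_bad_field")
  }
  chk_num(dx, "dx"); chk_num(dy, "dy")
  chk_num(theta, "theta", lower = -45, upper = 45)
  cpp_resample_rigid(slice, dx, dy, theta)
}

#' Invert rigid transform parameters
#'
#' For T(p) = R_theta (p - c) + c + t the inverse is the transform with
#' angle -theta and translation -R_{-theta} t.  Useful for comparing an
#' estimated correction against injected ground-truth motion.
#'
#' @param dx,dy,theta transform parameters (vectorized).
#' @return data.frame with columns `dx`, `dy`, `theta`.
#' @export
invert_rigid <- function(dx, dy, theta) {
  th <- -theta * pi / 180
  data.frame(
    dx = -(cos(th) * dx - sin(th) * dy),
    dy = -(sin(th) * dx + cos(th) * dy),
    theta = -theta
  )
}

validate_transforms <- function(transforms, n_frames, n_slices) {
  need <- c("frame", "slice", "dx", "dy", "theta")
  if (!is.data.frame(transforms) || !all(need %in% names(transforms))) {
    abort2("transforms must be a data.frame with columns frame, slice, dx, dy, theta",
           "boldvar_bad_field")
  }
  want <- expand.grid(slice = seq_len(n_slices), frame = 2:n_frames)
  got <- transforms[order(transforms$frame, transforms$slice),
                    c("frame", "slice")]
  if (nrow(got) != nrow(want) ||
      !all(got$frame == want$frame) || !all(got$slice == want$slice)) {
    abort2(sprintf(
      "transform count mismatch: need one row per (frame 2..%d, slice 1..%d)",
      n_frames, n_slices), "boldvar_bad_field")
  }
  if (anyNA(transforms[need]) || !all(vapply(transforms[c("dx", "dy", "theta")],
                                             function(v) all(is.finite(v)),
                                             logical(1)))) {
    abort2("transform parameters must be finite", "boldvar_bad_field")
  }
  invisible(TRUE)
}

#' Apply per-frame, per-slice rigid motion to a BOLD series
#'
#' Injects known motion into a series (the corruption that motion correction
#' later removes).  Frame 1 is left untransformed by convention.
#'
#' @param series a [bold_series()] or 4D array.
#' @param transforms data.frame with columns `frame`, `slice`, `dx`, `dy`,
#'   `theta`; one row per (frame, slice) for frames 2..t.
#' @return a [bold_series()] with each slice resampled under its transform.
#' @export
apply_motion <- function(series, transforms) {
  arr <- as_series_array(series)
  d <- dim(arr)
  validate_transforms(transforms, d[4], d[3])
  if (max(abs(transforms$dx)) > d[1] || max(abs(transforms$dy)) > d[2]) {
    abort2("translations exceed the grid extent", "boldvar_bad_field")
  }
  out <- arr
  for (r in seq_len(nrow(transforms))) {
    f <- transforms$frame[r]; z <- transforms$slice[r]
    out[, , z, f] <- cpp_resample_rigid(arr[, , z, f], transforms$dx[r],
                                        transforms$dy[r], transforms$theta[r])
  }
  if (inherits(series, "bold_series")) {
    bold_series(out, series$voxel_size_mm, series$tr_seconds)
  } else {
    out
  }
}
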