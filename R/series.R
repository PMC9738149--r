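# Core containers: 4D BOLD series and binary volumes of interest.

#' BOLD time-series container
#'
#' Wraps a 4D intensity array (x, y, z, t) together with its voxel geometry
#' and repetition time.  Intensities are arbitrary scanner units; metrics
#' downstream are invariant to their absolute scale.
#'
#' @param data 4D numeric array (x, y, z, t), finite, nonnegative, t >= 2.
#' @param voxel_size_mm voxel edge lengths in mm (length 3, positive).
#' @param tr_seconds repetition time in seconds (positive).
#' @return an object of class `bold_series`.
#' @export
bold_series <- function(data, voxel_size_mm = c(4.7, 4.7, 3),
                        tr_seconds = 2.28) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    abort2("field 'data' must be a 4D array (x, y, z, t)", "boldvar_bad_field")
  }
  if (dim(data)[4] < 2L) {
    abort2("field 'data' must have t >= 2 frames", "boldvar_bad_field")
  }
  if (anyNA(data) || !all(is.finite(data))) {
    abort2("field 'data' must be finite", "boldvar_bad_field")
  }
  if (min(data) < 0) {
    abort2("field 'data' must be nonnegative on input", "boldvar_bad_field")
  }
  chk_num(voxel_size_mm, "voxel_size_mm", len = 3L, lower = 1e-6)
  chk_num(tr_seconds, "tr_seconds", lower = 1e-6)
  structure(
    list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
         tr_seconds = as.numeric(tr_seconds)),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d voxels, %d frames, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' Binary volume of interest
#'
#' @param data 3D logical (or 0/1) array on the series' spatial grid.
#' @param label one of `"placenta"`, `"brain"`, `"fluid"`.
#' @return an object of class `voi_mask`.
#' @export
voi_mask <- function(data, label = c("placenta", "brain", "fluid")) {
  label <- match.arg(label)
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort2("field 'data' must be a 3D array", "boldvar_bad_field")
  }
  data <- array(as.logical(data), dim = dim(data))
  if (anyNA(data)) abort2("field 'data' must be binary", "boldvar_bad_field")
  if (!any(data)) {
    abort2("VOI mask must contain at least one voxel", "boldvar_empty_mask")
  }
  structure(list(data = data, label = label), class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s, %d voxels on a %s grid\n", x$label,
              sum(x$data), paste(dim(x$data), collapse = " x ")))
  invisible(x)
}

# Internal coercions so operations accept either the classed containers or
# bare arrays.
as_series_array <- function(series) {
  if (inherits(series, "bold_series")) return(series$data)
  if (is.array(series) && length(dim(series)) == 4L) return(series)
  abort2("expected a bold_series or 4D array", "boldvar_bad_field")
}

as_mask_array <- function(mask) {
  if (inherits(mask, "voi_mask")) return(mask$data)
  if (is.array(mask) && length(dim(mask)) == 3L) {
    return(array(as.logical(mask), dim = dim(mask)))
  }
  abort2("expected a voi_mask or 3D array", "boldvar_bad_field")
}

check_same_grid <- function(series_arr, mask_arr) {
  if (!identical(dim(series_arr)[1:3], dim(mask_arr)[1:3])) {
    abort2("mask grid does not match the series' spatial grid",
           "boldvar_bad_field")
  }
  invisible(TRUE)
}
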