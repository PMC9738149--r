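# Independent reference implementations used as oracles.  These deliberately
# use naive explicit loops and textbook formulas, not the package's code
# paths.

# temporal variance: double-loop volume mean, unity-mean normalization,
# sample SD
naive_tv <- function(arr, mask) {
  nt <- dim(arr)[4]
  course <- numeric(nt)
  for (f in seq_len(nt)) {
    vals <- c()
    for (i in seq_len(dim(arr)[1])) {
      for (j in seq_len(dim(arr)[2])) {
        for (k in seq_len(dim(arr)[3])) {
          if (mask[i, j, k]) vals <- c(vals, arr[i, j, k, f])
        }
      }
    }
    course[f] <- mean(vals)
  }
  course <- course / mean(course)
  sqrt(sum((course - mean(course))^2) / (nt - 1))
}

# spatial variance: per-voxel mean-absolute-deviation percent fluctuation,
# mean-normalized, sample SD across voxels
naive_sv <- function(arr, mask) {
  pafs <- c()
  for (i in seq_len(dim(arr)[1])) {
    for (j in seq_len(dim(arr)[2])) {
      for (k in seq_len(dim(arr)[3])) {
        if (mask[i, j, k]) {
          x <- arr[i, j, k, ]
          mu <- mean(x)
          if (mu > 0) pafs <- c(pafs, 100 * mean(abs(x - mu)) / mu)
        }
      }
    }
  }
  p <- pafs / mean(pafs)
  sqrt(sum((p - mean(p))^2) / (length(p) - 1))
}

# exhaustive consecutive-window scan for restrict_slices
naive_best_window <- function(mask, n_slices) {
  counts <- apply(mask, 3, sum)
  nz <- length(counts)
  best <- -1; z0 <- 1
  for (s in seq_len(nz - n_slices + 1)) {
    tot <- sum(counts[s:(s + n_slices - 1)])
    if (tot > best) { best <- tot; z0 <- s }
  }
  z0:(z0 + n_slices - 1)
}

# OLS via explicit normal equations
naive_ols <- function(X, y) {
  solve(t(X) %*% X) %*% t(X) %*% y
}

# two-sample K-S D via explicit ECDF scan
naive_ks_D <- function(a, b) {
  g <- sort(unique(c(a, b)))
  max(abs(vapply(g, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# small noise-free, motion-free phantom spec used across tests
quiet_phantom <- function(grid = c(16L, 16L, 3L, 200L), a = 0.1,
                          tr = 1, period = 20, n_patches = 1L,
                          spread = 0, seed = 1L, noise = 0) {
  phantom_spec(grid_shape = grid, tr_seconds = tr, inflow_period_s = period,
               inflow_amplitude = a, n_patches = n_patches,
               patch_amplitude_spread = spread, noise_sd = noise,
               motion_max_voxels = 0, motion_max_degrees = 0, seed = seed)
}

# per-frame per-slice transform table covering frames 2..t
transform_grid <- function(n_frames, n_slices, dx = 0, dy = 0, theta = 0) {
  g <- expand.grid(slice = seq_len(n_slices), frame = 2:n_frames)
  data.frame(frame = g$frame, slice = g$slice, dx = dx, dy = dy,
             theta = theta)
}
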