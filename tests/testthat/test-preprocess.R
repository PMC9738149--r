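# VOI propagation, slice restriction, NCC, motion correction, denoising.

test_that("propagate_voi copies the frame-0 mask to every frame", {
  m <- array(FALSE, dim = c(5, 5, 2))
  m[1:5, 1, 1] <- TRUE; m[1:5, 2, 2] <- TRUE  # 10 voxels
  stack <- propagate_voi(m, 100L)
  expect_identical(dim(stack), c(5L, 5L, 2L, 100L))
  expect_equal(apply(stack, 4, sum), rep(10, 100))
  expect_identical(stack[, , , 57], m)

  expect_identical(propagate_voi(m, 1L)[, , , 1], m)
  full <- array(TRUE, dim = c(3, 3, 2))
  expect_true(all(propagate_voi(full, 4L)))
  expect_error(propagate_voi(array(FALSE, dim = c(3, 3, 2)), 5L),
               class = "boldvar_empty_mask")
})

test_that("restrict_slices matches an exhaustive window-scan oracle", {
  set.seed(42)
  for (rep in 1:20) {
    nz <- sample(6:12, 1)
    m <- array(runif(8 * 8 * nz) < 0.4, dim = c(8, 8, nz))
    m[, , sample(nz, 1)] <- TRUE  # guarantee non-empty
    n_slices <- sample(1:5, 1)
    if (n_slices >= nz) next
    out <- restrict_slices(m, n_slices)
    keep <- which(apply(out, 3, sum) > 0)
    oracle <- naive_best_window(m, n_slices)
    # all retained slices lie in the oracle window and match the input there
    expect_true(all(keep %in% oracle))
    expect_identical(out[, , oracle], m[, , oracle])
    expect_equal(sum(out), sum(m[, , oracle]))
  }
})

test_that("restrict_slices identity and clamping edge cases", {
  m <- array(FALSE, dim = c(4, 4, 6))
  m[, , 1:2] <- TRUE
  expect_identical(restrict_slices(m, 5L), m)  # mask smaller than window
  expect_warning(restrict_slices(m, 7L), "clamped")
  m2 <- array(FALSE, dim = c(4, 4, 6))
  m2[1:2, 1, 3] <- TRUE; m2[1, 1, 5] <- TRUE
  out <- restrict_slices(m2, 1L)
  expect_equal(which(apply(out, 3, sum) > 0), 3L)  # dominant slice only
})

test_that("ncc satisfies its defining identities", {
  set.seed(1)
  a <- matrix(rnorm(100, 10), 10, 10)
  expect_equal(ncc(a, a), 1)
  expect_equal(ncc(a, -2 * a + 7), -1)
  b <- matrix(rnorm(100, 10), 10, 10)
  expect_equal(ncc(a, b), ncc(b, a), tolerance = 1e-12)
  # independent noise fields, 10^4 voxels: |ncc| ~ 1/sqrt(n)
  x <- matrix(rnorm(1e4), 100, 100); y <- matrix(rnorm(1e4), 100, 100)
  expect_lt(abs(ncc(x, y)), 0.05)
  expect_error(ncc(matrix(5, 4, 4), b[1:4, 1:4]), "image_a")
  expect_error(ncc(b[1:4, 1:4], matrix(5, 4, 4)), "image_b")
  expect_error(ncc(a, b[1:5, 1:5]), "equal shapes")
})

test_that("motion_correct is near-identity on a motion-free phantom", {
  ph <- generate_bold_phantom(quiet_phantom(grid = c(16L, 16L, 3L, 6L),
                                            n_patches = 6L, spread = 0.03,
                                            noise = 0.5, seed = 11L))
  mc <- motion_correct(ph$series)
  expect_lt(max(abs(mc$transforms$dx)), 0.1)
  expect_lt(max(abs(mc$transforms$dy)), 0.1)
  expect_lt(max(abs(mc$transforms$theta)), 0.1)
})

test_that("motion_correct recovers injected translations and rotations", {
  ph <- generate_bold_phantom(quiet_phantom(grid = c(24L, 24L, 3L, 8L),
                                            n_patches = 10L, spread = 0.03,
                                            noise = 0.5, seed = 12L))
  d <- dim(ph$series$data)
  set.seed(13)
  g <- expand.grid(slice = seq_len(d[3]), frame = 2:d[4])
  inj <- data.frame(frame = g$frame, slice = g$slice,
                    dx = runif(nrow(g), -3, 3), dy = runif(nrow(g), -3, 3),
                    theta = runif(nrow(g), -8, 8))
  mov <- apply_motion(ph$series, inj)
  mc <- motion_correct(mov)
  est <- mc$transforms[order(mc$transforms$frame, mc$transforms$slice), ]
  inj <- inj[order(inj$frame, inj$slice), ]
  rec <- invert_rigid(est$dx, est$dy, est$theta)  # estimated motion
  expect_lt(mean(abs(rec$dx - inj$dx)), 0.5)
  expect_lt(mean(abs(rec$dy - inj$dy)), 0.5)
  expect_lt(mean(abs(rec$theta - inj$theta)), 1)
  # non-worsening guarantee
  expect_true(all(est$ncc_after >= est$ncc_before - 1e-12, na.rm = TRUE))
})

test_that("zero-variance slices pass through with identity and a warning", {
  arr <- array(runif(8 * 8 * 2 * 3, 50, 60), dim = c(8, 8, 2, 3))
  arr[, , 2, ] <- 7  # constant slice at every frame
  expect_warning(mc <- motion_correct(arr), "zero-variance")
  z2 <- mc$transforms[mc$transforms$slice == 2, ]
  expect_true(all(z2$dx == 0 & z2$dy == 0 & z2$theta == 0))
  expect_equal(mc$series[, , 2, ], arr[, , 2, ])
})

test_that("denoise removes the fluid signal and preserves means", {
  # a = 0: placental courses are constant, hence orthogonal to a fluid
  # regressor injected by hand
  ph <- generate_bold_phantom(quiet_phantom(grid = c(16L, 16L, 3L, 60L),
                                            a = 0, noise = 0, seed = 14L))
  arr <- ph$series$data
  pl <- ph$masks$placenta$data; fl <- ph$masks$fluid$data
  fluid_sig <- 100 * (1 + 0.05 * sin(2 * pi * (0:59) / 40 + 0.5))
  for (f in 1:60) {
    sl <- arr[, , , f]; sl[fl] <- fluid_sig[f]; arr[, , , f] <- sl
  }
  fl_course <- colMeans(matrix(arr, ncol = 60)[which(fl), ])
  fc <- fl_course - mean(fl_course)
  v <- which(pl)[1]
  ij <- arrayInd(v, dim(arr)[1:3])

  # orthogonal series + filter disabled: exact identity
  out0 <- denoise(arr, pl, fl, filter_fwhm_frames = 0)
  expect_equal(out0, arr, tolerance = 1e-10)

  # voxel course = clean sinusoid + c * fluid course, then denoise:
  # residual correlation with the fluid course is tiny
  contam <- arr
  contam[ij[1], ij[2], ij[3], ] <-
    100 * (1 + 0.1 * sin(2 * pi * (0:59) / 20)) + 3 * fc
  out <- denoise(contam, pl, fl, filter_fwhm_frames = 0)
  expect_lt(abs(cor(out[ij[1], ij[2], ij[3], ], fl_course)), 0.05)

  # mean re-addition contract: volume-mean intensity preserved within 1%
  vm_in <- mean(contam[propagate_voi(pl, 60)])
  vm_out <- mean(out[propagate_voi(pl, 60)])
  expect_lt(abs(vm_out - vm_in) / vm_in, 0.01)
})

test_that("temporal low-pass filtering shrinks white-noise variance", {
  set.seed(15)
  arr <- array(100 + rnorm(6 * 6 * 2 * 80), dim = c(6, 6, 2, 80))
  voi <- array(TRUE, dim = c(6, 6, 2))
  fl <- array(FALSE, dim = c(6, 6, 2))
  expect_warning(out <- denoise(arr, voi, fl, filter_fwhm_frames = 3),
                 "empty fluid mask")
  sd_in <- apply(matrix(arr, ncol = 80), 1, sd)
  sd_out <- apply(matrix(out, ncol = 80), 1, sd)
  expect_true(all(sd_out < sd_in))
})

test_that("motion inflates temporal variance and correction removes it", {
  ph <- generate_bold_phantom(quiet_phantom(grid = c(24L, 24L, 3L, 12L),
                                            n_patches = 10L, spread = 0.03,
                                            noise = 0.5, seed = 16L))
  d <- dim(ph$series$data)
  set.seed(17)
  g <- expand.grid(slice = seq_len(d[3]), frame = 2:d[4])
  inj <- data.frame(frame = g$frame, slice = g$slice,
                    dx = runif(nrow(g), -3, 3), dy = runif(nrow(g), -3, 3),
                    theta = runif(nrow(g), -6, 6))
  mov <- apply_motion(ph$series, inj)
  tv0 <- temporal_variance(ph$series, ph$masks$placenta)
  tv_corrupt <- temporal_variance(mov, ph$masks$placenta)
  tv_fixed <- temporal_variance(motion_correct(mov)$series,
                                ph$masks$placenta)
  expect_gt(tv_corrupt, 1.5 * tv0)
  expect_lt(abs(tv_fixed - tv0) / tv0, 0.10)
})
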