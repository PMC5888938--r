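test_that("Gaussian smoothing preserves constants, honours fwhm = 0, and has the right width", {
  aff <- diag(c(2, 2, 2, 1))
  run <- bold_run(array(7.5, c(8, 8, 8, 3)), tr = 2, affine = aff)
  sm <- smooth_volumes(run, 8)
  expect_equal(sm$data, run$data, tolerance = 1e-12)

  run2 <- bold_run(array(rnorm(8^3 * 3), c(8, 8, 8, 3)), tr = 2, affine = aff)
  expect_identical(smooth_volumes(run2, 0)$data, run2$data)

  # impulse response on a fine 1 mm grid matches a Gaussian with
  # sigma = 8 / (2 sqrt(2 log 2)) = 3.397 mm
  aff1 <- diag(c(1, 1, 1, 1))
  d <- array(0, c(31, 31, 31, 2)); d[16, 16, 16, 1] <- 1
  sm <- smooth_volumes(bold_run(d, 2, aff1), 8)
  sigma <- 8 / (2 * sqrt(2 * log(2)))
  prof <- sm$data[16:26, 16, 16, 1]
  expected <- sm$data[16, 16, 16, 1] * exp(-(0:10)^2 / (2 * sigma^2))
  # small edge-renormalization effects at the outer profile points
  expect_equal(prof, expected, tolerance = 0.01)

  # anisotropic voxels: width in voxels scales with 1/voxel size
  aff2 <- diag(c(1, 2, 1, 1))
  sm2 <- smooth_volumes(bold_run(d, 2, aff2), 8)
  # along y (2 mm voxels) the profile at k voxels equals the 1 mm profile
  # at 2k voxels
  expect_equal(sm2$data[16, 16 + 3, 16, 1] / sm2$data[16, 16, 16, 1],
               sm$data[16 + 6, 16, 16, 1] / sm$data[16, 16, 16, 1],
               tolerance = 0.01)
})

test_that("zero-phase band-pass has the contracted frequency response", {
  tr <- 2.23
  t <- (0:139) * tr
  s04 <- sin(2 * pi * 0.04 * t)
  s20 <- sin(2 * pi * 0.2 * t)
  gain04 <- sd(bandpass_butterworth(s04, tr)) / sd(s04)
  gain20 <- sd(bandpass_butterworth(s20, tr)) / sd(s20)
  expect_lt(abs(gain04 - 1), 0.05)       # passband within 5% of unity
  expect_lt(gain20, 0.10)                # >90% attenuation at 0.2 Hz

  # DC and very slow drift are removed
  slow <- sin(2 * pi * 0.002 * t) + 3
  expect_lt(sd(bandpass_butterworth(slow, tr)) / sd(slow), 0.1)

  # matrix input filters column-wise identically
  M <- cbind(s04, s20)
  F2 <- bandpass_butterworth(M, tr)
  expect_equal(F2[, 1], bandpass_butterworth(s04, tr))

  expect_error(bandpass_butterworth(s04, tr, band = c(0.05, 0.01)), "band edges")
  expect_error(bandpass_butterworth(s04, tr, band = c(0.01, 0.5)), "Nyquist")
})

test_that("denoising removes trends, confound copies, and centres every voxel", {
  set.seed(3)
  sp <- c(4, 4, 4); nt <- 80; tr <- 2.23
  wm <- array(FALSE, sp); wm[1, 1, 1] <- TRUE
  csf <- array(FALSE, sp); csf[4, 4, 4] <- TRUE
  motion <- matrix(rnorm(nt * 6, 0, 0.05), nt)

  # a pure linear trend vanishes
  d <- array(rep(seq_len(nt), each = prod(sp)) * 0.5, c(sp, nt))
  out <- denoise_run(bold_run(d, tr, diag(4)), motion, wm, csf)
  expect_lt(max(abs(out)), 1e-8)

  # a voxel equal to a motion regressor is fully regressed out
  d <- array(rnorm(prod(sp) * nt), c(sp, nt))
  d[2, 2, 2, ] <- motion[, 3] * 4 + 2
  out <- denoise_run(bold_run(d, tr, diag(4)), motion, wm, csf)
  vox <- matrix(out, ncol = prod(sp))[, (2 - 1) + (2 - 1) * 4 + (2 - 1) * 16 + 1]
  expect_lt(sd(vox), 1e-8 + 0.02 * sd(d[2, 2, 2, ]))
  expect_lt(max(abs(colMeans(out))), 1e-8)

  expect_error(denoise_run(bold_run(d, tr, diag(4)), motion[1:10, ], wm, csf),
               "volumes")
  expect_error(denoise_run(bold_run(d, tr, diag(4)), motion, array(FALSE, sp), csf),
               "non-empty")
})
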