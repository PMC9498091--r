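test_that("NIfTI round trip preserves values, spacing and mask payload", {
  set.seed(1)
  v <- as_volume(array(rnorm(8 * 7 * 6), c(8, 7, 6)),
                 spacing = c(0.9, 0.9, 3.0), modality = "CT")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  save_volume(v, f)
  v2 <- load_volume(f, "CT")
  expect_identical(v2$values, v$values)
  expect_equal(v2$spacing, c(0.9, 0.9, 3.0))
  expect_identical(v2$units, "HU")

  m <- as_mask(array(rep(c(0L, 1L), length.out = 8 * 7 * 6), c(8, 7, 6)),
               "L01", "liver", spacing = c(1.7, 1.7, 3))
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  save_mask(m, fm)
  hdr <- RNifti::niftiHeader(fm)
  expect_equal(hdr$bitpix, 8)  # uint8 payload
  m2 <- load_mask(fm, "L01", "liver")
  expect_identical(m2$values, m$values)
})

test_that("degenerate volumes are rejected", {
  expect_error(as_volume(matrix(0, 3, 3), c(1, 1, 1), "CT"), "3D")
  expect_error(as_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 1), "CT"),
               "finite")
  expect_error(as_volume(array(0, c(2, 2, 2)), c(1, 0, 1), "CT"),
               "positive")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(matrix(rnorm(16), 4, 4))
  RNifti::writeNifti(img, f)
  expect_error(load_volume(f, "CT"), "3D")
  expect_error(as_mask(array(0L, c(3, 3, 3)), "L", "lung", c(1, 1, 1)),
               "empty")
})

test_that("resampling preserves constants, ramps, and physical extent", {
  const <- as_volume(array(7, c(10, 12, 8)), c(2, 2, 2), "PET_MR")
  r <- resample_to_grid(const, c(1.3, 1.3, 1.3))
  expect_true(all(abs(r$values - 7) < 1e-12))
  expect_lt(max(abs(dim(r$values) * r$spacing -
                    dim(const$values) * const$spacing)), 1.3)

  expect_identical(resample_to_grid(const, c(2, 2, 2)), const)

  ramp_vals <- array(rep(seq(0, 19) * 2, times = 6 * 6), c(20, 6, 6))
  ramp <- as_volume(ramp_vals, c(1, 1, 1), "CT")
  half <- resample_to_grid(ramp, c(0.5, 1, 1))
  interior <- 3:36
  expect_equal(half$values[interior, 3, 3], (interior - 1) * 0.5 * 2,
               tolerance = 1e-6)

  m <- as_mask(array(as.integer(ramp_vals > 20), dim(ramp_vals)), "L",
               "bone", c(1, 1, 1))
  mr <- resample_to_grid(m, c(0.5, 1, 1))
  expect_true(all(mr$values %in% c(0L, 1L)))
  expect_error(resample_to_grid(ramp, c(0, 1, 1)), "positive")
})
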