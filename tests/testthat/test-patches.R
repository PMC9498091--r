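test_that("field-of-view crop has the right physical extent and padding", {
  v <- as_volume(array(rnorm(60 * 60 * 80), c(60, 60, 80)), c(2, 2, 2),
                 "PET_MR")
  blk <- lesion_fov_crop(v, center_mm = c(60, 60, 80),
                         fov_mm = c(132, 160, 250), grid_mm = 2)
  expect_equal(dim(blk), c(66, 80, 125))
  expect_equal(dim(blk) * 2, c(132, 160, 250))

  # corner centre: ~7/8 of the block is zero-padding (within the
  # one-voxel boundary layer of the volume faces)
  corner <- lesion_fov_crop(v, center_mm = c(0, 0, 0),
                            fov_mm = c(132, 160, 250), grid_mm = 2)
  expect_gte(mean(corner == 0), 7 / 8 - 0.02)
  expect_error(lesion_fov_crop(v, center_mm = c(-10, 0, 0)), "outside")

  const <- as_volume(array(3, c(40, 40, 40)), c(2, 2, 2), "PET_MR")
  cblk <- lesion_fov_crop(const, c(40, 40, 40), c(40, 40, 40), 2)
  expect_true(all(cblk == 3))

  # matched grids: crop is an exact sub-grid, not an interpolation
  # (block voxel j, 0-based, sits at centre + (j - 9) * 2 mm)
  sub <- lesion_fov_crop(v, c(60, 60, 80), c(40, 40, 40), 2)
  expect_equal(sub[11, 11, 11], v$values[32, 32, 42])
})

test_that("patch sampling is seeded, bounded, and exactly sized", {
  pos <- sample_patches(c(66, 80, 125), n = 384, seed = 3)
  expect_equal(nrow(pos), 384)
  expect_identical(pos, sample_patches(c(66, 80, 125), n = 384, seed = 3))

  big <- sample_patches(c(40, 50, 60), n = 10000, seed = 1)
  expect_true(all(big >= 1))
  expect_true(all(big[, 1] + 31 <= 40))
  expect_true(all(big[, 2] + 31 <= 50))
  expect_true(all(big[, 3] + 31 <= 60))
  expect_error(sample_patches(c(20, 40, 40), n = 5), "smaller")

  tiles <- tile_patches(c(66, 80, 125), stride = 16)
  expect_true(all(tiles[, 1] + 31 <= 66))
  expect_true(nrow(tiles) >= 8)
})

test_that("patch slicing yields co-indexed orientation triples", {
  patch <- array(seq_len(32^3), c(32, 32, 32))
  tr <- slice_patch(patch)
  expect_length(tr, 32)
  expect_equal(length(tr) * 3, 96)   # 96 2D slices per 3D patch
  expect_equal(dim(tr[[5]]$ax), c(32, 32))
  expect_equal(tr[[7]]$ax, patch[, , 7])
  expect_equal(tr[[7]]$cor, patch[, 7, ])
  expect_equal(tr[[7]]$sag, patch[7, , ])
  # stacking the axial slices reassembles the patch
  rebuilt <- array(0, c(32, 32, 32))
  for (i in 1:32) rebuilt[, , i] <- tr[[i]]$ax
  expect_identical(rebuilt, patch * 1)
  expect_error(slice_patch(array(0, c(16, 32, 32))), "cubic")
})

test_that("training-set patch arithmetic matches the study numbers", {
  n_slices <- length(slice_patch(array(0, c(32, 32, 32)))) * 3L
  expect_identical(36L * 384L * n_slices, 1327104L)
})

test_that("modality normalization maps onto the unit interval", {
  expect_equal(normalize_modality(c(0, 15, 30), "PET_MR"), c(0, 1, 1))
  expect_equal(normalize_modality(c(-200, 50, 300), "CT"), c(0, 0.5, 1))
  expect_equal(normalize_modality(c(0, 1500, 3000, 4000), "ADC"),
               c(0, 0.5, 1, 1))
  const <- matrix(5, 4, 4)
  out <- normalize_modality(const, "MR_VIBE",
                            stats = list(mean = 5, sd = 2))
  expect_true(all(out == 0.5))
  expect_error(normalize_modality(1, "XRAY"))
})
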