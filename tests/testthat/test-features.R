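test_that("lean body mass follows the sex-specific formula", {
  # frozen by direct evaluation of the formula
  expect_equal(compute_lbm("m", 80, 1.80), 61.73141, tolerance = 1e-6)
  expect_equal(compute_lbm("f", 60, 1.65), 39.28685, tolerance = 1e-6)
  # LBM < weight over a grid of adult physiques (males)
  for (w in seq(50, 140, by = 10)) for (h in seq(1.5, 2.05, by = 0.05)) {
    if (w / h^2 <= 12) next
    expect_lt(compute_lbm("m", w, h), w)
    expect_lt(compute_lbm("f", w, h), w)
  }
  expect_error(compute_lbm("m", -1, 1.8), "positive")
})

test_that("SUL conversion is a normalization identity and scales with dose", {
  act <- as_volume(array(500, c(4, 4, 4)), c(2, 2, 2), "PET_MR")
  sul <- to_sul(act, dose = 500 * 60, lbm = 60)
  expect_true(all(abs(sul$values - 1) < 1e-12))
  sul2 <- to_sul(act, dose = 2 * 500 * 60, lbm = 60)
  expect_true(all(abs(sul2$values - 0.5) < 1e-12))
  expect_error(to_sul(act, dose = 0, lbm = 60), "positive")
})

test_that("SULpeak matches an exhaustive sphere-mean search", {
  ph <- make_sphere_phantom(radius_mm = 12, value = 7)
  expect_equal(as.numeric(sul_peak(ph$volume, ph$mask)), 7)

  # single hot voxel: peak = best sphere mean, against brute force over
  # every voxel of the grid as candidate centre
  set.seed(42)
  dims <- c(24, 24, 24)
  arr <- array(1 + 0.1 * rnorm(prod(dims)), dims)
  arr[12, 12, 12] <- 10
  pet <- as_volume(arr, c(1.5, 1.5, 1.5), "PET_MR")
  mvals <- array(0L, dims); mvals[6:18, 6:18, 6:18] <- 1L
  mask <- as_mask(mvals, "L", "liver", c(1.5, 1.5, 1.5))

  offsets <- melrisk:::sphere_offsets(c(1.5, 1.5, 1.5), 6.2)
  brute <- -Inf
  cand <- which(mvals == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(cand))) {
    ctr <- cand[i, ]
    pts <- sweep(offsets, 2, ctr, "+")
    ok <- pts[, 1] >= 1 & pts[, 1] <= 24 & pts[, 2] >= 1 &
          pts[, 2] <= 24 & pts[, 3] >= 1 & pts[, 3] <= 24
    brute <- max(brute, mean(arr[pts[ok, , drop = FALSE]]))
  }
  expect_equal(as.numeric(sul_peak(pet, mask)), brute, tolerance = 1e-12)
  expect_lte(as.numeric(sul_peak(pet, mask)), max(arr))

  # mask smaller than the sphere support falls back to the mask mean
  tiny <- array(0L, dims); tiny[12, 12, 12:13] <- 1L
  tm <- as_mask(tiny, "L", "liver", c(1.5, 1.5, 1.5))
  val <- sul_peak(pet, tm)
  expect_true(isTRUE(attr(val, "fallback")))
  expect_equal(as.numeric(val), mean(arr[12, 12, 12:13]))
})

test_that("42% isocontour MTV matches sphere analytics and thresholds", {
  ph <- make_sphere_phantom(radius_mm = 10, value = 4, spacing = c(1, 1, 1))
  m <- mtv_isocontour(ph$volume, ph$mask)
  expect_equal(m$mtv_ml, 4 / 3 * pi * 1^3, tolerance = 0.05)
  expect_equal(tlg(ph$volume, m), m$mtv_ml * 4, tolerance = 1e-12)

  # two-level lesion: threshold 4.2 keeps only the 10-SUL voxels
  arr <- array(0, c(10, 10, 3)); arr[2:5, 2:5, 2] <- 10
  arr[6:8, 2:5, 2] <- 3
  mk <- array(0L, c(10, 10, 3)); mk[2:8, 2:5, 2] <- 1L
  pet <- as_volume(arr, c(1, 1, 1), "PET_MR")
  mask <- as_mask(mk, "L", "lung", c(1, 1, 1))
  r <- mtv_isocontour(pet, mask)
  expect_equal(r$threshold, 4.2)
  expect_equal(sum(r$submask), 16)
  expect_equal(tlg(pet, r), r$mtv_ml * 10)

  # fraction 0 keeps the whole connected mask
  r0 <- mtv_isocontour(pet, mask, fraction = 0)
  expect_equal(sum(r0$submask), sum(mk))

  # MTV non-increasing in fraction; bounded by the mask volume
  fr <- c(0, 0.2, 0.42, 0.6, 0.9)
  mtvs <- vapply(fr, function(f) mtv_isocontour(pet, mask, f)$mtv_ml,
                 numeric(1))
  expect_true(all(diff(mtvs) <= 1e-12))
  expect_lte(max(mtvs), sum(mk) * prod(c(1, 1, 1)) / 1000 + 1e-12)

  # all-zero PET inside the mask is degenerate
  z <- as_volume(array(0, c(10, 10, 3)), c(1, 1, 1), "PET_MR")
  expect_true(mtv_isocontour(z, mask)$degenerate)
})

test_that("axial diameter recovers sphere and ellipsoid extents", {
  ph <- make_sphere_phantom(radius_mm = 10, value = 1, spacing = c(1, 1, 1))
  expect_equal(lesion_diameter_axial(ph$mask), 20, tolerance = 1)

  # 30 x 20 x 10 mm ellipsoid, long axis in-plane
  dims <- c(40, 40, 20)
  g <- as.matrix(expand.grid(x = 1:40, y = 1:40, z = 1:20))
  inside <- ((g[, 1] - 20) / 15)^2 + ((g[, 2] - 20) / 10)^2 +
            ((g[, 3] - 10) / 5)^2 <= 1
  mv <- array(0L, dims); mv[g[inside, ]] <- 1L
  em <- as_mask(mv, "L", "soft tissue", c(1, 1, 1))
  expect_equal(lesion_diameter_axial(em), 30, tolerance = 1)

  single <- array(0L, c(5, 5, 5)); single[3, 3, 3] <- 1L
  sm <- as_mask(single, "L", "lung", c(1.7, 1.7, 3))
  expect_equal(lesion_diameter_axial(sm), 1.7)
})

test_that("small-lesion and brain rules suppress functional parameters", {
  r <- apply_small_lesion_rule(8, "lung")
  expect_equal(r$dm_mm, 5)
  expect_true(r$sub_cm)
  expect_false(r$measure_functional)

  r2 <- apply_small_lesion_rule(12, "lung")
  expect_equal(r2$dm_mm, 12)
  expect_true(r2$measure_functional)

  r3 <- apply_small_lesion_rule(25, "brain")
  expect_equal(r3$dm_mm, 25)
  expect_false(r3$measure_functional)
})

test_that("ADC ROI uses the eroded largest-diameter slice", {
  adc <- as_volume(array(900, c(12, 12, 5)), c(1, 1, 1), "ADC")
  mv <- array(0L, c(12, 12, 5)); mv[4:9, 4:9, 2:4] <- 1L
  mask <- as_mask(mv, "L", "liver", c(1, 1, 1))
  expect_equal(adc_mean_roi(adc, mask), 900)
  expect_true(is.na(adc_mean_roi(adc, mask, artifact_flag = TRUE)))

  # ring phantom: border 100, core 1000; erosion must keep only the core
  ring <- array(1500, c(12, 12, 3))
  ring[4:9, 4:9, 2] <- 100
  ring[5:8, 5:8, 2] <- 1000
  adc2 <- as_volume(ring, c(1, 1, 1), "ADC")
  mv2 <- array(0L, c(12, 12, 3)); mv2[4:9, 4:9, 2] <- 1L
  mask2 <- as_mask(mv2, "L", "liver", c(1, 1, 1))
  expect_equal(adc_mean_roi(adc2, mask2), 1000)
})

test_that("patient aggregation caps counts and sums tumor burden", {
  les <- data.frame(
    lesion_id = c("a", "b", "c"), organ_region = c("lung", "liver", "lung"),
    dm_mm = c(20, 30, 5), sub_cm = c(FALSE, FALSE, TRUE),
    sul_peak = c(4, 6, NA), adc_mean = c(800, 1000, NA),
    mtv_ml = c(1, 2, NA), tlg = c(5, 12, NA),
    functional_suppressed = c(FALSE, FALSE, TRUE))
  pf <- patient_feature_summary(les, n_found = 250)
  expect_equal(pf$n_lesions, 200L)
  expect_equal(pf$tmtv_ml, 3)
  expect_equal(pf$tlg_total, 17)
  expect_equal(pf$sul_range, 2)
  expect_equal(pf$adc_range, 200)
  expect_equal(pf$n_organ_regions, 2)
  expect_true(pf$organ_lung && pf$organ_liver)

  # sub-cm lesion contributed no functional values but counts for dm
  expect_equal(pf$dm_min, 5)

  single <- patient_feature_summary(les[1, ], n_found = 1)
  expect_equal(single$dm_range, 0)
  expect_equal(single$sul_range, 0)

  three <- data.frame(lesion_id = 1:3, organ_region = "lung",
                      dm_mm = 20, sub_cm = FALSE, sul_peak = 3,
                      adc_mean = NA, mtv_ml = c(1, 2, 3), tlg = 1,
                      functional_suppressed = FALSE)
  expect_equal(patient_feature_summary(three)$tmtv_ml, 6)
})

test_that("reference VOI ratios follow their definitions", {
  arr <- array(0.5, c(60, 60, 40))
  sp <- c(2, 2, 2)
  paint <- function(a, ctr, r, val) melrisk:::paint_sphere(a, sp, ctr, r, val)
  arr <- paint(arr, c(40, 60, 40), 16, 2.0)   # liver
  arr <- paint(arr, c(80, 60, 40), 14, 1.8)   # spleen
  pet <- as_volume(arr, sp, "PET_MR")
  s <- slr(pet, c(40, 60, 40), c(80, 60, 40))
  expect_equal(s$slr, 0.9, tolerance = 1e-9)
  expect_equal(nrow(s$sweep), 5)
  expect_equal(s$sweep$cutoff, c(1.1, 1.05, 1.0, 0.95, 0.9))
  expect_equal(s$sweep$elevated, rep(FALSE, 5))  # 0.9 is not above 0.9
  expect_error(slr(pet, c(0, 0, 0), c(80, 60, 40)), "outside")

  # BLR: vertebrae {1,1,4}, one excluded 1, liver 2 -> (1+1+4)/3 / 2 = 1
  arr2 <- array(0, c(60, 60, 40))
  arr2 <- paint(arr2, c(40, 60, 40), 16, 2.0)
  vc <- list(c(80, 20, 20), c(80, 50, 20), c(80, 80, 20), c(40, 20, 60))
  vals <- c(1, 1, 4, 1)
  for (i in 1:4) arr2 <- paint(arr2, vc[[i]], 10, vals[i])
  pet2 <- as_volume(arr2, sp, "PET_MR")
  expect_equal(blr(pet2, vc, c(FALSE, FALSE, FALSE, TRUE), c(40, 60, 40)),
               1, tolerance = 1e-9)
  expect_equal(blr(pet2, vc, c(FALSE, FALSE, FALSE, FALSE), c(40, 60, 40)),
               (1 + 1 + 4 + 1) / 4 / 2, tolerance = 1e-9)
  expect_true(is.na(blr(pet2, vc, rep(TRUE, 4), c(40, 60, 40))))
})

test_that("target lesion selection prefers uptake then size", {
  les <- data.frame(lesion_id = c("a", "b", "c"),
                    organ_region = c("lung", "liver", "bone"),
                    sul_peak = c(3, 8, 5), dm_mm = c(10, 20, 30))
  expect_equal(select_target_lesion(les), "b")

  tie <- data.frame(lesion_id = c("a", "b"), organ_region = "lung",
                    sul_peak = c(8.0, 7.9), dm_mm = c(20, 40))
  expect_equal(select_target_lesion(tie), "b")  # within 5%: largest wins

  brain <- data.frame(lesion_id = "a", organ_region = "brain",
                      sul_peak = NA_real_, dm_mm = 25)
  expect_error(select_target_lesion(brain), "eligible")
})
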