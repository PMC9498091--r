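#' Lean body mass (Janmahasatian formula)
#'
#' Sex-specific lean body mass used to normalize PET uptake:
#' males `9270 W / (6680 + 216 BMI)`, females `9270 W / (8780 + 244 BMI)`
#' with `BMI = W / H^2`.
#'
#' @param sex `"m"` or `"f"`.
#' @param weight_kg Body weight in kg (> 0).
#' @param height_m Body height in m (> 0).
#' @return Lean body mass in kg.
#' @export
compute_lbm <- function(sex, weight_kg, height_m) {
  sex <- match.arg(sex, c("m", "f"))
  if (!is.finite(weight_kg) || weight_kg <= 0 ||
      !is.finite(height_m) || height_m <= 0)
    stop("weight and height must be positive")
  bmi <- weight_kg / height_m^2
  if (sex == "m") 9270 * weight_kg / (6680 + 216 * bmi)
  else 9270 * weight_kg / (8780 + 244 * bmi)
}

#' Convert an activity-concentration volume to SUL
#'
#' `SUL(v) = C(v) / (dose / LBM)`; with the activity concentration in
#' Bq/mL, the injected dose in MBq and the lean body mass in kg, dose and
#' concentration must be expressed in consistent units (the caller is
#' responsible for decay correction).
#'
#' @param activity A `mel_volume` holding activity concentration.
#' @param dose Injected dose (> 0).
#' @param lbm Lean body mass in kg.
#' @param modality Modality tag of the returned SUL volume.
#' @return A `mel_volume` in SUL units.
#' @export
to_sul <- function(activity, dose, lbm, modality = "PET_MR") {
  stopifnot(inherits(activity, "mel_volume"))
  if (!is.finite(dose) || dose <= 0) stop("dose must be positive")
  if (!is.finite(lbm) || lbm <= 0) stop("lean body mass must be positive")
  as_volume(activity$values / (dose / lbm), spacing = activity$spacing,
            modality = modality, origin = activity$origin)
}

## Integer voxel offsets whose centre lies within a sphere of radius r_mm.
sphere_offsets <- function(spacing, radius_mm) {
  n <- floor(radius_mm / spacing)
  g <- expand.grid(dx = -n[1]:n[1], dy = -n[2]:n[2], dz = -n[3]:n[3])
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  as.matrix(g[d2 <= radius_mm^2, , drop = FALSE])
}

## Mean of `values` over a sphere around integer voxel coords (1-based,
## n x 3), clipped to the grid.
sphere_means <- function(values, centers, offsets) {
  d <- dim(values)
  sums <- numeric(nrow(centers))
  cnts <- numeric(nrow(centers))
  for (o in seq_len(nrow(offsets))) {
    x <- centers[, 1] + offsets[o, 1]
    y <- centers[, 2] + offsets[o, 2]
    z <- centers[, 3] + offsets[o, 3]
    ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
    if (any(ok)) {
      sums[ok] <- sums[ok] + values[cbind(x[ok], y[ok], z[ok])]
      cnts[ok] <- cnts[ok] + 1
    }
  }
  sums / pmax(cnts, 1)
}

#' Peak SUL of a lesion
#'
#' Mean SUL inside a 1 cm^3 sphere (radius 6.2 mm), with the sphere
#' centre placed on the mask voxel that maximizes the mean (EANM-style
#' peak). Spheres are clipped at the volume border. If the mask holds
#' fewer voxels than the sphere support, the value falls back to the
#' plain mean over the mask and is flagged via `attr(, "fallback")`.
#'
#' @param pet A `mel_volume` in SUL units.
#' @param mask A `mel_mask` on the same grid.
#' @param radius_mm Sphere radius; 6.2 mm gives a 1 cm^3 sphere.
#' @return Peak SUL (numeric scalar).
#' @export
sul_peak <- function(pet, mask, radius_mm = 6.2) {
  check_same_grid(pet, mask)
  vox <- which(mask$values == 1L, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("lesion mask is empty")
  offsets <- sphere_offsets(pet$spacing, radius_mm)
  if (nrow(vox) < nrow(offsets)) {
    out <- mean(pet$values[vox])
    attr(out, "fallback") <- TRUE
    return(out)
  }
  max(sphere_means(pet$values, vox, offsets))
}

check_same_grid <- function(vol, mask) {
  if (!all(dim(vol$values) == dim(mask$values)))
    stop("volume and mask grids differ in shape")
  if (!all(abs(vol$spacing - mask$spacing) < 1e-9))
    stop("volume and mask grids differ in spacing")
  invisible(TRUE)
}

## 26-connected component of `eligible` containing `seed` (1-based coords).
connected_component_26 <- function(eligible, seed) {
  d <- dim(eligible)
  visited <- array(FALSE, dim = d)
  lin <- function(m) (m[, 3] - 1L) * (d[1] * d[2]) + (m[, 2] - 1L) * d[1] + m[, 1]
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  frontier <- matrix(as.integer(seed), ncol = 3)
  visited[frontier] <- TRUE
  while (nrow(frontier) > 0) {
    cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o)
      cbind(frontier[, 1] + offs[o, 1], frontier[, 2] + offs[o, 2],
            frontier[, 3] + offs[o, 3])))
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
          cand[, 2] >= 1 & cand[, 2] <= d[2] &
          cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) break
    cand <- cand[!duplicated(lin(cand)), , drop = FALSE]
    keep <- eligible[cand] & !visited[cand]
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) break
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited
}

#' Metabolic tumor volume by fractional isocontour
#'
#' Thresholds the lesion at `fraction` times its maximum SUL and keeps the
#' voxels 26-connected to the maximum voxel. The default 42% isocontour is
#' the study definition of the MTV.
#'
#' @inheritParams sul_peak
#' @param fraction Isocontour fraction of the lesion maximum (default 0.42).
#' @return A list with `mtv_ml` (volume in mL), `submask` (binary array),
#'   `threshold`, `max_sul`, and `degenerate` (TRUE when the PET signal
#'   inside the mask is non-positive).
#' @export
mtv_isocontour <- function(pet, mask, fraction = 0.42) {
  check_same_grid(pet, mask)
  inmask <- mask$values == 1L
  if (!any(inmask)) stop("lesion mask is empty")
  vals <- pet$values[inmask]
  mx <- max(vals)
  if (mx <= 0) {
    return(list(mtv_ml = 0, submask = array(0L, dim(mask$values)),
                threshold = NA_real_, max_sul = mx, degenerate = TRUE))
  }
  thr <- fraction * mx
  eligible <- inmask & pet$values >= thr
  idx <- which(inmask & pet$values == mx, arr.ind = TRUE)
  comp <- connected_component_26(eligible, idx[1, ])
  submask <- array(as.integer(comp), dim = dim(mask$values))
  list(mtv_ml = sum(submask) * voxel_volume_ml(pet$spacing),
       submask = submask, threshold = thr, max_sul = mx, degenerate = FALSE)
}

#' Total lesion glycolysis
#'
#' `TLG = MTV (mL) x mean SUL inside the MTV submask`.
#'
#' @param pet A `mel_volume` in SUL units.
#' @param mtv Result of [mtv_isocontour()].
#' @return TLG (numeric scalar); 0 with `attr(, "degenerate")` when the
#'   submask is empty.
#' @export
tlg <- function(pet, mtv) {
  if (sum(mtv$submask) == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  mtv$mtv_ml * mean(pet$values[mtv$submask == 1L])
}

#' Longest axial in-plane diameter of a lesion
#'
#' Maximum over axial (z) slices of the largest pairwise physical distance
#' between in-plane mask voxel centres, widened by one in-plane voxel so
#' the value reports the physical extent rather than the centre-to-centre
#' distance (a single-voxel mask has the extent of one voxel).
#'
#' @param mask A `mel_mask`.
#' @return Diameter in mm (0 only degenerately; a single-voxel mask
#'   reports the in-plane extent of one voxel).
#' @export
lesion_diameter_axial <- function(mask) {
  vox <- which(mask$values == 1L, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("lesion mask is empty")
  sp <- mask$spacing
  best <- 0
  for (z in unique(vox[, 3])) {
    pts <- vox[vox[, 3] == z, 1:2, drop = FALSE]
    if (nrow(pts) == 1) {
      best <- max(best, max(sp[1:2]))
      next
    }
    pts <- unique(pts)
    xy <- cbind(pts[, 1] * sp[1], pts[, 2] * sp[2])
    if (nrow(xy) > 3) xy <- xy[grDevices::chull(xy), , drop = FALSE]
    dmax <- max(stats::dist(xy))
    ## voxel centres are dmax apart; add one in-plane voxel for the extent
    best <- max(best, dmax + min(sp[1:2]))
  }
  best
}

#' Small-lesion and brain-lesion measurement rule
#'
#' Lesions with a longest diameter below 10 mm have their diameter
#' recorded as 5 mm and no functional parameters measured (partial-volume
#' protection); brain lesions keep only the diameter.
#'
#' @param dm_mm Measured longest axial diameter (mm, > 0).
#' @param organ_region Organ region of the lesion.
#' @return A list with `dm_mm` (recorded diameter), `sub_cm`,
#'   `measure_functional` (SULpeak/MTV/TLG), and `measure_adc`.
#' @export
apply_small_lesion_rule <- function(dm_mm, organ_region) {
  organ_region <- match.arg(organ_region, ORGAN_REGIONS)
  if (!is.finite(dm_mm) || dm_mm <= 0) stop("diameter must be positive")
  sub_cm <- dm_mm < 10
  brain <- organ_region == "brain"
  list(dm_mm = if (sub_cm) 5 else dm_mm,
       sub_cm = sub_cm,
       measure_functional = !sub_cm && !brain,
       measure_adc = !sub_cm && !brain)
}

erode_slice_4n <- function(sl) {
  d <- dim(sl)
  p <- matrix(FALSE, d[1] + 2, d[2] + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1)] <- sl
  core <- p[2:(d[1] + 1), 2:(d[2] + 1)] &
          p[1:d[1], 2:(d[2] + 1)] & p[3:(d[1] + 2), 2:(d[2] + 1)] &
          p[2:(d[1] + 1), 1:d[2]] & p[2:(d[1] + 1), 3:(d[2] + 2)]
  core
}

#' Mean ADC over the largest-diameter slice of a lesion
#'
#' Operationalizes a free-hand ROI placed in the region of the largest
#' diameter while avoiding organ borders: the mask is restricted to its
#' largest-diameter axial slice and eroded in-plane by one voxel
#' (4-neighbourhood). If erosion empties the slice the un-eroded slice is
#' used and the result flagged (`attr(, "uneroded")`). When the lesion's
#' diffusion data are artifact-corrupted the value is missing.
#'
#' @param adc A `mel_volume` with ADC values (1e-6 mm^2/s).
#' @param mask A `mel_mask` on the same grid.
#' @param artifact_flag If `TRUE`, returns `NA` (ADC not acquired).
#' @return Mean ADC (numeric scalar) or `NA`.
#' @export
adc_mean_roi <- function(adc, mask, artifact_flag = mask$adc_artifact) {
  if (isTRUE(artifact_flag)) return(NA_real_)
  check_same_grid(adc, mask)
  vox <- which(mask$values == 1L, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("lesion mask is empty")
  sp <- mask$spacing
  ## largest in-plane extent picks the ROI slice
  zbest <- NULL; best <- -1
  for (z in unique(vox[, 3])) {
    pts <- unique(vox[vox[, 3] == z, 1:2, drop = FALSE])
    dm <- if (nrow(pts) == 1) 0 else
      max(stats::dist(cbind(pts[, 1] * sp[1], pts[, 2] * sp[2])))
    if (dm > best) { best <- dm; zbest <- z }
  }
  sl <- mask$values[, , zbest] == 1L
  core <- erode_slice_4n(sl)
  if (!any(core)) {
    out <- mean(adc$values[, , zbest][sl])
    attr(out, "uneroded") <- TRUE
    return(out)
  }
  mean(adc$values[, , zbest][core])
}

#' Extract the full feature set of one lesion
#'
#' Applies the measurement protocol to one lesion: axial diameter, the
#' small-lesion and brain rules, then SULpeak, 42%-isocontour MTV, TLG and
#' the ADC mean where functional measurement is allowed.
#'
#' @param pet SUL volume used for PET quantification.
#' @param adc ADC volume (or `NULL` when diffusion data are absent).
#' @param mask A `mel_mask` for the lesion.
#' @return A one-row `data.frame` with columns `lesion_id`, `organ_region`,
#'   `dm_mm`, `sub_cm`, `sul_peak`, `adc_mean`, `mtv_ml`, `tlg`,
#'   `functional_suppressed`.
#' @export
compute_lesion_features <- function(pet, adc, mask) {
  dm_raw <- lesion_diameter_axial(mask)
  rule <- apply_small_lesion_rule(dm_raw, mask$organ_region)
  sul <- mtvml <- tlgv <- adcm <- NA_real_
  if (rule$measure_functional) {
    sul <- as.numeric(sul_peak(pet, mask))
    m <- mtv_isocontour(pet, mask)
    mtvml <- m$mtv_ml
    tlgv <- as.numeric(tlg(pet, m))
    if (!is.null(adc) && rule$measure_adc)
      adcm <- as.numeric(adc_mean_roi(adc, mask))
  }
  data.frame(lesion_id = mask$lesion_id, organ_region = mask$organ_region,
             dm_mm = rule$dm_mm, sub_cm = rule$sub_cm, sul_peak = sul,
             adc_mean = adcm, mtv_ml = mtvml, tlg = tlgv,
             functional_suppressed = !rule$measure_functional,
             stringsAsFactors = FALSE)
}

rng_or_zero <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(c(mean = NA_real_, min = NA_real_,
                               max = NA_real_, range = NA_real_))
  c(mean = mean(x), min = min(x), max = max(x), range = max(x) - min(x))
}

#' Per-patient aggregation of lesion features
#'
#' Sums MTV and TLG into TMTV and total TLG, caps the lesion count at 200,
#' and computes mean/min/max/range summaries of diameter, SULpeak and ADC
#' mean over the lesions where each is defined.
#'
#' @param lesions A `data.frame` of per-lesion rows as returned by
#'   [compute_lesion_features()] (one or more rows).
#' @param n_found Number of lesions actually found (before the cap).
#' @param slr Optional spleen-liver ratio to carry along.
#' @param blr Optional bone-marrow-liver ratio.
#' @return A one-row `data.frame` of patient-level features.
#' @export
patient_feature_summary <- function(lesions, n_found = nrow(lesions),
                                    slr = NA_real_, blr = NA_real_) {
  if (nrow(lesions) == 0) stop("patient must have at least one lesion")
  if (all(!is.finite(lesions$dm_mm))) stop("no lesion with a defined diameter")
  dm <- rng_or_zero(lesions$dm_mm)
  su <- rng_or_zero(lesions$sul_peak)
  ad <- rng_or_zero(lesions$adc_mean)
  regions <- sort(unique(lesions$organ_region))
  out <- data.frame(
    n_lesions = min(as.integer(n_found), 200L),
    tmtv_ml = sum(lesions$mtv_ml[is.finite(lesions$mtv_ml)]),
    tlg_total = sum(lesions$tlg[is.finite(lesions$tlg)]),
    n_organ_regions = length(regions),
    organ_regions = paste(regions, collapse = ";"),
    dm_mean = dm["mean"], dm_min = dm["min"], dm_max = dm["max"],
    dm_range = dm["range"],
    sul_mean = su["mean"], sul_min = su["min"], sul_max = su["max"],
    sul_range = su["range"],
    adc_mean = ad["mean"], adc_min = ad["min"], adc_max = ad["max"],
    adc_range = ad["range"],
    slr = slr, blr = blr,
    stringsAsFactors = FALSE
  )
  for (r in ORGAN_REGIONS)
    out[[paste0("organ_", gsub(" ", "_", r))]] <- r %in% regions
  rownames(out) <- NULL
  out
}

voi_mean <- function(pet, center_mm, diameter_mm) {
  sp <- pet$spacing
  d <- dim(pet$values)
  ctr <- round((center_mm - pet$origin) / sp) + 1L
  offsets <- sphere_offsets(sp, diameter_mm / 2)
  x <- ctr[1] + offsets[, 1]; y <- ctr[2] + offsets[, 2]
  z <- ctr[3] + offsets[, 3]
  if (any(x < 1 | x > d[1] | y < 1 | y > d[2] | z < 1 | z > d[3]))
    stop("reference VOI extends outside the volume")
  mean(pet$values[cbind(x, y, z)])
}

#' Spleen-liver ratio with cutoff sweep
#'
#' `SLR = SULmean(spleen VOI) / SULmean(liver VOI)` with 2 cm spherical
#' reference VOIs, plus the elevated/normal classification at the cutoffs
#' 1.1 down to 0.9 in steps of 0.05.
#'
#' @param pet SUL volume.
#' @param liver_center,spleen_center Physical VOI centres (mm).
#' @param cutoffs Cutoff sweep (default `seq(1.1, 0.9, by = -0.05)`).
#' @return A list with `slr`, `liver_sul`, `spleen_sul` and a `sweep`
#'   data.frame (`cutoff`, `elevated`).
#' @export
slr <- function(pet, liver_center, spleen_center,
                cutoffs = seq(1.1, 0.9, by = -0.05)) {
  liver <- voi_mean(pet, liver_center, 20)
  spleen <- voi_mean(pet, spleen_center, 20)
  ratio <- spleen / liver
  list(slr = ratio, liver_sul = liver, spleen_sul = spleen,
       sweep = data.frame(cutoff = cutoffs, elevated = ratio > cutoffs))
}

#' Bone-marrow-liver ratio
#'
#' Mean SUL over up to four 1.5 cm VOIs in the L1-L4 vertebrae (excluded
#' vertebrae dropped), divided by the 2 cm liver-VOI mean. Missing when
#' every vertebra is excluded.
#'
#' @param pet SUL volume.
#' @param vertebra_centers List (length <= 4) of physical VOI centres.
#' @param exclusion_flags Logical vector: `TRUE` drops the vertebra.
#' @param liver_center Physical liver-VOI centre.
#' @return BLR (numeric scalar) or `NA` when no vertebra is eligible.
#' @export
blr <- function(pet, vertebra_centers, exclusion_flags, liver_center) {
  stopifnot(length(vertebra_centers) == length(exclusion_flags))
  keep <- !exclusion_flags
  if (!any(keep)) return(NA_real_)
  v <- vapply(vertebra_centers[keep], function(ctr) voi_mean(pet, ctr, 15),
              numeric(1))
  mean(v) / voi_mean(pet, liver_center, 20)
}

#' Select the target lesion of a patient
#'
#' The lesion with the highest tracer uptake (SULpeak) wins; lesions whose
#' SULpeak lies within a relative tolerance of the best are treated as
#' ties and the largest diameter decides. Brain lesions are excluded.
#'
#' @param lesions Per-lesion feature `data.frame`.
#' @param tie_tol Relative SULpeak tolerance treated as a tie (default 5%).
#' @return The `lesion_id` of the target lesion.
#' @export
select_target_lesion <- function(lesions, tie_tol = 0.05) {
  eligible <- lesions[lesions$organ_region != "brain" &
                      is.finite(lesions$sul_peak), , drop = FALSE]
  if (nrow(eligible) == 0)
    stop("no eligible lesion with a defined SULpeak")
  best <- max(eligible$sul_peak)
  tied <- eligible[eligible$sul_peak >= best * (1 - tie_tol), , drop = FALSE]
  tied$lesion_id[which.max(tied$dm_mm)]
}
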