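#' @keywords internal
#' @useDynLib melrisk, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

MODALITIES <- c("PET_CT", "CT", "PET_MR", "MR_VIBE", "ADC")

modality_units <- function(modality) {
  switch(modality,
    PET_CT = "SUL", PET_MR = "SUL",
    CT = "HU",
    MR_VIBE = "arbitrary",
    ADC = "1e-6 mm^2/s",
    stop("unknown modality: ", modality)
  )
}

#' Construct a 3D scalar volume
#'
#' A `mel_volume` couples a 3D array of voxel values with its voxel spacing
#' (mm), modality tag and physical units. Voxel indices are 0-based in
#' physical terms: the centre of voxel (0,0,0) sits at `origin`, and voxel
#' (i,j,k) at `origin + c(i,j,k) * spacing`. The axial plane is xy; z runs
#' head-foot.
#'
#' @param values Numeric 3D array.
#' @param spacing Numeric length-3, mm per voxel along x, y, z. All > 0.
#' @param modality One of `"PET_CT"`, `"CT"`, `"PET_MR"`, `"MR_VIBE"`, `"ADC"`.
#' @param origin Physical coordinate (mm) of voxel (0,0,0).
#' @return An object of class `mel_volume` with fields `values`, `spacing`,
#'   `modality`, `units`, `origin`.
#' @export
as_volume <- function(values, spacing, modality, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("volume values must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers")
  if (any(!is.finite(values)))
    stop("volume values must be finite")
  modality <- match.arg(modality, MODALITIES)
  structure(
    list(values = values, spacing = as.numeric(spacing), modality = modality,
         units = modality_units(modality), origin = as.numeric(origin)),
    class = "mel_volume"
  )
}

#' @export
print.mel_volume <- function(x, ...) {
  cat(sprintf("<mel_volume> %s [%s], %s voxels @ (%.2f, %.2f, %.2f) mm\n",
              x$modality, x$units, paste(dim(x$values), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Construct a binary lesion mask
#'
#' @param values Integer/logical 3D array (0/1), same grid as its reference
#'   volume. Must be nonempty.
#' @param lesion_id Identifier string.
#' @param organ_region One of the nine recorded organ regions.
#' @param spacing Voxel spacing in mm.
#' @param adc_artifact Whether the diffusion data over this lesion are
#'   corrupted by artifacts (the ADC mean is then not measured).
#' @return An object of class `mel_mask`.
#' @export
as_mask <- function(values, lesion_id, organ_region, spacing,
                    adc_artifact = FALSE) {
  organ_region <- match.arg(organ_region, ORGAN_REGIONS)
  v <- array(as.integer(values != 0), dim = dim(values))
  if (sum(v) == 0L) stop("lesion mask is empty")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers")
  structure(
    list(values = v, lesion_id = as.character(lesion_id),
         organ_region = organ_region, spacing = as.numeric(spacing),
         adc_artifact = isTRUE(adc_artifact)),
    class = "mel_mask"
  )
}

ORGAN_REGIONS <- c("lymph nodes", "soft tissue", "bone", "liver", "spleen",
                   "lung", "pleura", "brain", "other viscera")

#' Read a volume from a NIfTI file
#'
#' Spacing is taken from the file header; modality and units from the
#' argument.
#'
#' @param path Path to a readable `.nii` / `.nii.gz` file.
#' @param modality Modality tag assigned to the loaded volume.
#' @return A [as_volume()] object.
#' @export
load_volume <- function(path, modality) {
  if (!file.exists(path)) stop("cannot read volume file: ", path)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L)
    stop("expected a 3D image, got ", length(dim(vals)), "D: ", path)
  ## strip niftiImage attributes; undo the float32 rounding the header
  ## imposes on pixel dimensions (0.9 mm is stored as 0.89999998)
  as_volume(array(as.vector(vals), dim(vals)),
            spacing = signif(abs(RNifti::pixdim(img))[1:3], 6),
            modality = modality)
}

#' Write a volume to a NIfTI file
#'
#' Scalar volumes are stored as 64-bit float, so the round trip through
#' [load_volume()] is lossless; masks should be written with
#' [save_mask()] (8-bit integer payload).
#'
#' @param v A `mel_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
save_volume <- function(v, path) {
  stopifnot(inherits(v, "mel_volume"))
  if (any(!is.finite(v$values))) stop("volume values must be finite")
  img <- RNifti::asNifti(v$values)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a lesion mask to a NIfTI file (uint8 payload)
#'
#' @param m A `mel_mask`.
#' @param path Output path.
#' @export
save_mask <- function(m, path) {
  stopifnot(inherits(m, "mel_mask"))
  img <- RNifti::asNifti(m$values)
  RNifti::pixdim(img) <- m$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a lesion mask from a NIfTI file
#'
#' @param path Path to the mask file.
#' @inheritParams as_mask
#' @return A `mel_mask`.
#' @export
load_mask <- function(path, lesion_id, organ_region, adc_artifact = FALSE) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L) stop("expected a 3D mask: ", path)
  as_mask(array(as.vector(vals), dim(vals)), lesion_id, organ_region,
          spacing = signif(abs(RNifti::pixdim(img))[1:3], 6),
          adc_artifact = adc_artifact)
}

## Trilinear sampling of `values` (3D array) at fractional 0-based voxel
## coordinates given as an n x 3 matrix. Points outside the grid return
## `outside`. Used by resampling and the lesion field-of-view crop.
trilinear_sample <- function(values, frac_idx, outside = 0) {
  d <- dim(values)
  n <- nrow(frac_idx)
  out <- rep(as.numeric(outside), n)
  inside <- frac_idx[, 1] > -0.5 & frac_idx[, 1] < d[1] - 0.5 &
            frac_idx[, 2] > -0.5 & frac_idx[, 2] < d[2] - 0.5 &
            frac_idx[, 3] > -0.5 & frac_idx[, 3] < d[3] - 0.5
  if (!any(inside)) return(out)
  p <- frac_idx[inside, , drop = FALSE]
  ## clamp so the 8 corners stay in range (edge voxels extend half a voxel)
  p[, 1] <- pmin(pmax(p[, 1], 0), d[1] - 1)
  p[, 2] <- pmin(pmax(p[, 2], 0), d[2] - 1)
  p[, 3] <- pmin(pmax(p[, 3], 0), d[3] - 1)
  i0 <- pmin(floor(p), rep(d - 2L, each = nrow(p))) # lower corner, 0-based
  i0 <- pmax(i0, 0)
  f <- p - i0
  acc <- numeric(nrow(p))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    idx <- cbind(i0[, 1] + dx + 1L, i0[, 2] + dy + 1L, i0[, 3] + dz + 1L)
    acc <- acc + w * values[idx]
  }
  out[inside] <- acc
  out
}

nearest_sample <- function(values, frac_idx, outside = 0) {
  d <- dim(values)
  n <- nrow(frac_idx)
  out <- rep(as.numeric(outside), n)
  ri <- round(frac_idx)
  inside <- ri[, 1] >= 0 & ri[, 1] <= d[1] - 1 &
            ri[, 2] >= 0 & ri[, 2] <= d[2] - 1 &
            ri[, 3] >= 0 & ri[, 3] <= d[3] - 1
  if (any(inside)) {
    idx <- cbind(ri[inside, 1] + 1L, ri[inside, 2] + 1L, ri[inside, 3] + 1L)
    out[inside] <- values[idx]
  }
  out
}

#' Resample a volume or mask onto a new voxel spacing
#'
#' Scalar volumes are interpolated trilinearly, masks nearest-neighbour.
#' The grid size is chosen so the total physical extent is preserved to
#' within one voxel.
#'
#' @param v A `mel_volume` or `mel_mask`.
#' @param target_spacing New spacing (mm), length 3, all > 0.
#' @return An object of the same class on the new grid.
#' @export
resample_to_grid <- function(v, target_spacing) {
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("target_spacing must be three strictly positive numbers")
  is_mask <- inherits(v, "mel_mask")
  if (!is_mask && !inherits(v, "mel_volume")) stop("not a volume or mask")
  d <- dim(v$values)
  extent <- d * v$spacing
  nd <- pmax(1L, as.integer(round(extent / target_spacing)))
  if (all(abs(target_spacing - v$spacing) < 1e-12)) return(v)
  g <- expand.grid(x = seq_len(nd[1]) - 1L, y = seq_len(nd[2]) - 1L,
                   z = seq_len(nd[3]) - 1L)
  phys <- cbind(g$x * target_spacing[1], g$y * target_spacing[2],
                g$z * target_spacing[3])
  frac <- sweep(phys, 2, v$spacing, "/")
  vals <- if (is_mask) nearest_sample(v$values, frac) else
    trilinear_sample(v$values, frac)
  arr <- array(vals, dim = nd)
  if (is_mask) {
    out <- v
    out$values <- array(as.integer(arr != 0), dim = nd)
    out$spacing <- as.numeric(target_spacing)
    out
  } else {
    as_volume(arr, spacing = target_spacing, modality = v$modality,
              origin = v$origin)
  }
}

voxel_volume_ml <- function(spacing) prod(spacing) / 1000
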