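#' Crop the lesion field of view from co-registered volumes
#'
#' Extracts a block of fixed physical extent (default 132 x 160 x 250 mm,
#' LR x AP x HF) centred on a lesion, resampled to an isotropic working
#' grid; regions outside the source volume are zero-padded.
#'
#' @param volume A `mel_volume`.
#' @param center_mm Physical centre (mm) of the crop.
#' @param fov_mm Physical extent of the block (length 3, mm).
#' @param grid_mm Isotropic working-grid spacing (mm).
#' @return A 3D array of size `round(fov_mm / grid_mm)`.
#' @export
lesion_fov_crop <- function(volume, center_mm, fov_mm = c(132, 160, 250),
                            grid_mm = 2) {
  d <- dim(volume$values)
  hi <- volume$origin + (d - 1) * volume$spacing
  if (any(center_mm < volume$origin) || any(center_mm > hi))
    stop("crop centre lies outside the volume")
  nd <- pmax(1L, as.integer(round(fov_mm / grid_mm)))
  ## snap the crop lattice onto the source lattice: when the working grid
  ## matches the source spacing this makes the trilinear resampling exact
  ## instead of low-pass filtering fine texture by sub-voxel shifts
  center_mm <- volume$origin +
    round((center_mm - volume$origin) / volume$spacing) * volume$spacing
  g <- expand.grid(x = seq_len(nd[1]) - 1, y = seq_len(nd[2]) - 1,
                   z = seq_len(nd[3]) - 1)
  phys <- cbind(center_mm[1] + (g$x - floor((nd[1] - 1) / 2)) * grid_mm,
                center_mm[2] + (g$y - floor((nd[2] - 1) / 2)) * grid_mm,
                center_mm[3] + (g$z - floor((nd[3] - 1) / 2)) * grid_mm)
  frac <- sweep(sweep(phys, 2, volume$origin, "-"), 2, volume$spacing, "/")
  array(trilinear_sample(volume$values, frac, outside = 0), dim = nd)
}

#' Sample random 3D patch positions inside a block
#'
#' Draws `n` seeded uniform-random positions of `patch_vox`-cubed patches
#' fully inside the block.
#'
#' @param block_dim Dimensions of the field-of-view block (length 3).
#' @param n Number of patches (study default 384 per patient).
#' @param patch_vox Patch edge length in voxels.
#' @param seed RNG seed.
#' @return An `n x 3` matrix of 1-based start indices, with
#'   `attr(, "patch_vox")`.
#' @export
sample_patches <- function(block_dim, n = 384, patch_vox = 32, seed = 1) {
  if (any(block_dim < patch_vox))
    stop("field-of-view block is smaller than the patch size")
  maxoff <- block_dim - patch_vox
  pos <- withr::with_seed(seed, cbind(
    sample.int(maxoff[1] + 1L, n, replace = TRUE),
    sample.int(maxoff[2] + 1L, n, replace = TRUE),
    sample.int(maxoff[3] + 1L, n, replace = TRUE)))
  attr(pos, "patch_vox") <- as.integer(patch_vox)
  pos
}

#' Deterministic patch tiling of a block
#'
#' Regular grid of patch positions with a fixed stride, used for the
#' validation and test lesions where a deterministic, exhaustive cover is
#' preferable to random draws.
#'
#' @inheritParams sample_patches
#' @param stride Stride in voxels between patch starts.
#' @return Position matrix as in [sample_patches()].
#' @export
tile_patches <- function(block_dim, patch_vox = 32, stride = 16) {
  if (any(block_dim < patch_vox))
    stop("field-of-view block is smaller than the patch size")
  starts <- lapply(block_dim, function(d)
    unique(c(seq(1L, d - patch_vox + 1L, by = stride), d - patch_vox + 1L)))
  pos <- as.matrix(expand.grid(starts[[1]], starts[[2]], starts[[3]]))
  dimnames(pos) <- NULL
  attr(pos, "patch_vox") <- as.integer(patch_vox)
  pos
}

#' Slice a 3D patch into co-indexed orientation triples
#'
#' A cubic patch of edge `s` yields `s` axial + `s` coronal + `s`
#' sagittal 2D slices, grouped into `s` triples sharing the slice index.
#'
#' @param patch A cubic 3D array (edge `s`, study value 32).
#' @param triple_idx Which triples to return (default all `s`).
#' @return A list of triples; each triple is `list(ax, cor, sag)` of
#'   `s x s` matrices.
#' @export
slice_patch <- function(patch, triple_idx = seq_len(dim(patch)[1])) {
  d <- dim(patch)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("patch must be a cubic 3D array")
  lapply(triple_idx, function(i)
    list(ax = patch[, , i], cor = patch[, i, ], sag = patch[i, , ]))
}

#' Normalize a slice or block to the network input range
#'
#' PET: SUL clipped to \[0, 15\] then divided by 15. CT: HU windowed
#' \[-200, 300\] onto \[0, 1\]. VIBE: z-scored with per-volume statistics
#' then squashed by a sigmoid. ADC: divided by 3000 (1e-6 mm^2/s) and
#' clipped to \[0, 1\].
#'
#' @param x Numeric array/matrix of raw voxel values.
#' @param modality Modality tag.
#' @param stats For `MR_VIBE`: `list(mean, sd)` of the source volume.
#' @return Normalized values in \[0, 1\] (VIBE: (0, 1)).
#' @export
normalize_modality <- function(x, modality, stats = NULL) {
  modality <- match.arg(modality, MODALITIES)
  switch(modality,
    PET_CT = , PET_MR = pmin(pmax(x, 0), 15) / 15,
    CT = (pmin(pmax(x, -200), 300) + 200) / 500,
    ADC = pmin(pmax(x / 3000, 0), 1),
    MR_VIBE = {
      if (is.null(stats)) stats <- list(mean = mean(x), sd = stats::sd(x))
      s <- if (!is.finite(stats$sd) || stats$sd <= 0) 1 else stats$sd
      1 / (1 + exp(-(x - stats$mean) / s))
    })
}

MODALITY_PAIRS <- list(
  "PET_MR+VIBE" = c(pet = "PET_MR", anat = "MR_VIBE"),
  "PET_MR+ADC" = c(pet = "PET_MR", anat = "ADC"),
  "PET_CT+CT" = c(pet = "PET_CT", anat = "CT"))

pairs_for_subset <- function(subset) {
  switch(subset,
    both = names(MODALITY_PAIRS),
    `PET_CT+CT` = "PET_CT+CT",
    `PET_MR+MR` = c("PET_MR+VIBE", "PET_MR+ADC"),
    stop("unknown modality subset: ", subset))
}

## Build the stored 2D sample set of one lesion: normalized field-of-view
## blocks are sliced at the given positions/triples for every modality
## pair. Columns of the six slice matrices are samples.
build_sample_store <- function(blocks, positions, triple_idx, pairs,
                               patient_id, label, anthro_raw,
                               drop_adc = FALSE) {
  if (drop_adc) pairs <- setdiff(pairs, "PET_MR+ADC")
  if (length(pairs) == 0) stop("no modality pair left for lesion")
  s <- attr(positions, "patch_vox")
  n_samp <- nrow(positions) * length(triple_idx) * length(pairs)
  mats <- lapply(1:6, function(i) matrix(0, s * s, n_samp))
  names(mats) <- c("pet_ax", "pet_cor", "pet_sag",
                   "anat_ax", "anat_cor", "anat_sag")
  pair_tag <- character(n_samp)
  col <- 0L
  for (p in seq_len(nrow(positions))) {
    rng <- lapply(1:3, function(a) positions[p, a]:(positions[p, a] + s - 1L))
    sub <- lapply(blocks, function(b) b[rng[[1]], rng[[2]], rng[[3]]])
    for (pr in pairs) {
      mods <- MODALITY_PAIRS[[pr]]
      tr_pet <- slice_patch(sub[[mods["pet"]]], triple_idx)
      tr_anat <- slice_patch(sub[[mods["anat"]]], triple_idx)
      for (t in seq_along(triple_idx)) {
        col <- col + 1L
        mats$pet_ax[, col] <- tr_pet[[t]]$ax
        mats$pet_cor[, col] <- tr_pet[[t]]$cor
        mats$pet_sag[, col] <- tr_pet[[t]]$sag
        mats$anat_ax[, col] <- tr_anat[[t]]$ax
        mats$anat_cor[, col] <- tr_anat[[t]]$cor
        mats$anat_sag[, col] <- tr_anat[[t]]$sag
        pair_tag[col] <- pr
      }
    }
  }
  list(slices = mats, n = n_samp, patch_vox = s,
       patient = rep(patient_id, n_samp), pair = pair_tag,
       label = rep(label, n_samp),
       anthro = matrix(rep(anthro_raw, each = n_samp), n_samp, 3),
       lesion_key = NULL)
}

concat_stores <- function(stores) {
  list(slices = lapply(names(stores[[1]]$slices), function(nm)
         do.call(cbind, lapply(stores, function(s) s$slices[[nm]]))) |>
         stats::setNames(names(stores[[1]]$slices)),
       n = sum(vapply(stores, function(s) s$n, numeric(1))),
       patch_vox = stores[[1]]$patch_vox,
       patient = unlist(lapply(stores, function(s) s$patient)),
       pair = unlist(lapply(stores, function(s) s$pair)),
       label = unlist(lapply(stores, function(s) s$label)),
       anthro = do.call(rbind, lapply(stores, function(s) s$anthro)))
}

## Assemble the network batch for sample columns `idx` of a store.
make_batch <- function(store, idx, anthro_center, anthro_scale) {
  s <- store$patch_vox
  N <- length(idx)
  tomat <- function(m) matrix(as.vector(m[, idx, drop = FALSE]), ncol = 1)
  anth <- sweep(sweep(store$anthro[idx, , drop = FALSE], 2, anthro_center,
                      "-"), 2, anthro_scale, "/")
  list(pet = list(ax = tomat(store$slices$pet_ax),
                  cor = tomat(store$slices$pet_cor),
                  sag = tomat(store$slices$pet_sag)),
       anat = list(ax = tomat(store$slices$anat_ax),
                   cor = tomat(store$slices$anat_cor),
                   sag = tomat(store$slices$anat_sag)),
       anthro = anth,
       dims = list(H = s, W = s, N = N))
}
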