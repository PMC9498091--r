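# Programmatic phantoms shared across the suite.

# Uniform ellipsoid (default sphere) of given SUL on a zero background;
# voxel centres at 0-based index * spacing.
make_sphere_phantom <- function(radius_mm = 10, value = 4,
                                spacing = c(1, 1, 1),
                                dims = rep(round(4 * radius_mm /
                                                 min(spacing)) + 1L, 3),
                                background = 0, modality = "PET_MR") {
  arr <- array(background, dim = dims)
  ctr <- (dims - 1) / 2 * spacing
  g <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                             z = seq_len(dims[3])))
  phys <- sweep(g - 1, 2, spacing, "*")
  inside <- colSums((t(phys) - ctr)^2) <= radius_mm^2
  arr[g[inside, , drop = FALSE]] <- value
  list(volume = as_volume(arr, spacing, modality),
       mask = as_mask(array(as.integer(arr != background), dims),
                      "L01", "lung", spacing),
       center = ctr, inside = inside)
}

tiny_rendered_case <- function(seed = 5, n_patients = 3) {
  cfg <- sim_config(n_patients = n_patients, shape = c(40, 40, 48),
                    spacing = c(2, 2, 2), lesion_rate = 1,
                    dm_range_mm = c(16, 30), with_organs = FALSE,
                    seed = seed)
  simulate_cohort(cfg)
}

# brute-force product-limit estimator, independent of survival::survfit
brute_force_km <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    deaths <- sum(times == ut[i] & events)
    if (at_risk > 0) s <- s * (1 - deaths / at_risk)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}
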