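#' Configuration for the synthetic multimodal cohort
#'
#' Defines the study conditions the phantom generator emulates: grid and
#' spacing of the co-registered volumes, lesion geometry and uptake
#' ranges, the texture-heterogeneity contrast between risk classes, the
#' per-class ADC model, organ reference regions, and the outcome model
#' (exponential survival with a latent-aggressiveness hazard multiplier,
#' logistic response link, administrative censoring).
#'
#' @param n_patients Number of patients (>= 2).
#' @param shape Grid size in voxels (x, y, z).
#' @param spacing Voxel spacing in mm; the default matches whole-body MR
#'   resolution (1.7 x 1.7 x 3 mm).
#' @param lesion_rate Poisson mean of the per-patient lesion count
#'   (at least one lesion is always present).
#' @param dm_range_mm Lesion diameter range (long axial axis, mm).
#' @param aspect_range Range of the ellipsoid minor/major axis ratio
#'   (1, 1 gives spheres; narrow ranges give geometrically matched
#'   lesions for controlled planted-signal experiments).
#' @param sulmax_range Range of the lesion maximum SUL.
#' @param hetero_lo Texture amplitude of low-risk lesions, in (0, 1).
#' @param hetero_effect Additional texture amplitude of high-risk lesions.
#' @param adc_mean_low,adc_mean_high Class means of the lesion ADC
#'   (1e-6 mm^2/s) for low- and high-risk patients.
#' @param adc_spread_low,adc_spread_high Between-lesion SD of the lesion
#'   ADC means per class (drives the intraindividual ADC range marker).
#' @param adc_sd_voxel Within-lesion voxel SD of ADC.
#' @param baseline_hazard Exponential baseline hazard (per day).
#' @param beta Log hazard ratio per unit latent aggressiveness.
#' @param resp_gamma0,resp_gamma1 Logistic response link:
#'   `P(responder) = plogis(gamma0 - gamma1 * a)`.
#' @param censor_days Administrative censoring horizon (days).
#' @param outcome_mode `"stochastic"` draws outcomes from the hazard and
#'   response models; `"balanced"` alternates planted low/high labels and
#'   draws outcomes consistent with them (for planted-signal experiments).
#' @param with_organs Render liver/spleen/vertebra reference regions.
#' @param liver_sul,spleen_sul,vertebra_sul Organ uptake levels (SUL).
#' @param pet_background,ct_background,vibe_background,adc_background
#'   Background levels per modality.
#' @param ct_lesion,vibe_lesion Lesion levels in CT (HU) and VIBE (a.u.).
#' @param noise_sd Background noise SD applied to the PET volumes.
#' @param lesion_edge_mm Width of the smooth rim blending a lesion into
#'   the background (point-spread-function analogue; 0 gives hard
#'   binary edges).
#' @param p_female,age_mean,age_sd Demographics.
#' @param p_adc_artifact Probability that a lesion's DWI is
#'   artifact-corrupted (its ADC then missing).
#' @param p_vertebra_excluded Probability a vertebra is excluded from the
#'   bone-marrow reference (osteoarthritis/fracture analogue).
#' @param p_brain Probability a secondary lesion sits in the brain.
#' @param seed RNG seed; identical configs give identical cohorts.
#' @return A list of class `mel_sim_config`.
#' @export
sim_config <- function(n_patients = 37,
                       shape = c(96, 96, 160),
                       spacing = c(1.7, 1.7, 3.0),
                       lesion_rate = 3,
                       dm_range_mm = c(6, 45),
                       aspect_range = c(0.6, 1),
                       sulmax_range = c(2, 12),
                       hetero_lo = 0.05,
                       hetero_effect = 0.6,
                       adc_mean_low = 1100, adc_mean_high = 900,
                       adc_spread_low = 80, adc_spread_high = 420,
                       adc_sd_voxel = 60,
                       baseline_hazard = 1 / 900,
                       beta = 1.4,
                       resp_gamma0 = 0.5, resp_gamma1 = 2,
                       censor_days = 1800,
                       outcome_mode = c("stochastic", "balanced"),
                       with_organs = TRUE,
                       liver_sul = 2.0, spleen_sul = 1.8, vertebra_sul = 1.2,
                       pet_background = 0.4, ct_background = -100,
                       vibe_background = 80, adc_background = 1600,
                       ct_lesion = 40, vibe_lesion = 260,
                       noise_sd = 0.02,
                       lesion_edge_mm = 4,
                       p_female = 19 / 37, age_mean = 62, age_sd = 13,
                       p_adc_artifact = 0.05,
                       p_vertebra_excluded = 0.1,
                       p_brain = 0.05,
                       seed = 1) {
  cfg <- as.list(environment())
  cfg$outcome_mode <- match.arg(outcome_mode)
  if (cfg$n_patients < 2) stop("need at least 2 patients")
  if (any(cfg$spacing <= 0) || any(cfg$shape < 8))
    stop("invalid grid specification")
  if (cfg$hetero_lo < 0 || cfg$hetero_effect < 0 ||
      cfg$hetero_lo + cfg$hetero_effect >= 1)
    stop("heterogeneity amplitudes must be >= 0 with sum < 1")
  if (diff(cfg$dm_range_mm) < 0 || cfg$dm_range_mm[1] <= 0)
    stop("invalid diameter range")
  structure(cfg, class = "mel_sim_config")
}

## seeded multi-octave uniform noise in [0,1] over a small grid; the
## fine octave carries most weight so the texture is visible to local
## (3x3) filters
fractal_noise <- function(dims, scales = c(8, 4, 2),
                          weights = c(0.25, 0.5, 1)) {
  acc <- array(0, dim = dims)
  for (s in seq_along(scales)) {
    cd <- pmax(2L, ceiling(dims / scales[s]) + 1L)
    coarse <- array(stats::runif(prod(cd)), dim = cd)
    g <- expand.grid(x = seq_len(dims[1]) - 1, y = seq_len(dims[2]) - 1,
                     z = seq_len(dims[3]) - 1)
    frac <- cbind(g$x / scales[s], g$y / scales[s], g$z / scales[s])
    acc <- acc + weights[s] * array(trilinear_sample(coarse, frac), dim = dims)
  }
  rng <- range(acc)
  if (diff(rng) < 1e-12) return(array(0.5, dim = dims))
  (acc - rng[1]) / diff(rng)
}

sim_landmarks <- function(cfg) {
  extent <- cfg$shape * cfg$spacing
  list(
    liver = extent * c(0.32, 0.42, 0.55), liver_r = 30,
    spleen = extent * c(0.72, 0.42, 0.55), spleen_r = 20,
    vertebrae = lapply(c(0.42, 0.37, 0.32, 0.27),
                       function(f) extent * c(0.5, 0.72, f)),
    vertebra_r = 10,
    excluded = rep(FALSE, 4)
  )
}

sample_outcome <- function(cfg, a, planted_risk = NULL) {
  if (cfg$outcome_mode == "balanced") {
    if (planted_risk == "low") {
      os <- stats::runif(1, 600, cfg$censor_days)
      died <- stats::runif(1) < 0.3
      response <- sample(c("CR", "PR", "SD"), 1, prob = c(4, 8, 2))
    } else if (stats::runif(1) < 0.5) {
      os <- stats::runif(1, 60, 500); died <- TRUE
      response <- sample(RESPONSE_LEVELS, 1, prob = c(1, 1, 1, 5))
    } else {
      os <- stats::runif(1, 600, 1400)
      died <- stats::runif(1) < 0.5
      response <- "PD"
    }
  } else {
    ev <- stats::rexp(1, rate = cfg$baseline_hazard * exp(cfg$beta * a))
    died <- ev <= cfg$censor_days
    os <- min(ev, cfg$censor_days)
    responder <- stats::runif(1) <
      stats::plogis(cfg$resp_gamma0 - cfg$resp_gamma1 * a)
    response <- if (responder) sample(c("CR", "PR", "SD"), 1,
                                      prob = c(4, 8, 2)) else "PD"
  }
  list(os_days = max(1L, as.integer(round(os))), died = died,
       response = response)
}

sample_lesion_geometry <- function(cfg, k, lm, placed = list()) {
  extent <- cfg$shape * cfg$spacing
  regions <- setdiff(ORGAN_REGIONS, "brain")
  region <- if (k > 1 && stats::runif(1) < cfg$p_brain) "brain"
            else sample(regions, 1,
                        prob = c(20, 20, 12, 14, 5, 16, 3, 9) / 100)
  dm <- if (k == 1) stats::runif(1, max(12, cfg$dm_range_mm[1]),
                                 cfg$dm_range_mm[2])
        else stats::runif(1, cfg$dm_range_mm[1], cfg$dm_range_mm[2])
  rx <- dm / 2
  ry <- rx * stats::runif(1, cfg$aspect_range[1], cfg$aspect_range[2])
  rz <- rx * stats::runif(1, cfg$aspect_range[1], cfg$aspect_range[2])
  margin <- c(rx, ry, rz) + 4
  for (try in 1:60) {
    ctr <- stats::runif(3) * (extent - 2 * margin) + margin
    ok <- TRUE
    if (cfg$with_organs) {
      keepout <- function(p, r) sqrt(sum((ctr - p)^2)) > r + rx + 12
      ok <- keepout(lm$liver, lm$liver_r) && keepout(lm$spleen, lm$spleen_r)
      if (ok) for (v in lm$vertebrae) ok <- ok && keepout(v, lm$vertebra_r)
    }
    ## metastases are distinct: no overlap between lesions
    if (ok) for (pl in placed)
      ok <- ok && sqrt(sum((ctr - pl$center)^2)) >
        max(pl$radii) + rx + 4
    if (ok) return(list(region = region, dm = dm, center = ctr,
                        radii = c(rx, ry, rz)))
  }
  stop("could not place lesion inside the volume")
}

#' Simulate a synthetic multimodal cohort
#'
#' Draws a latent aggressiveness `a ~ Uniform(0,1)` per patient which
#' drives overall survival (exponential hazard multiplied by
#' `exp(beta * a)`), treatment response (logistic link) and, through the
#' resulting risk class, lesion texture heterogeneity and the ADC model.
#' Risk labels follow the OS > 548 days AND response rule.
#'
#' @param config A [sim_config()].
#' @param render If `TRUE`, voxel volumes are rendered for every case
#'   ([render_volumes()]); otherwise cases carry geometry only.
#' @return A list of class `mel_cohort_sim`: `cases` (list of
#'   `mel_case`), `cohort` (the cohort table), `config`.
#' @export
simulate_cohort <- function(config = sim_config(), render = TRUE) {
  cfg <- config
  cases <- withr::with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_patients), function(i) {
      a <- stats::runif(1)
      planted <- if (cfg$outcome_mode == "balanced")
        c("low", "high")[(i %% 2) + 1] else NULL
      out <- sample_outcome(cfg, a, planted)
      risk <- assign_risk(out$os_days, out$response)
      sex <- if (stats::runif(1) < cfg$p_female) "f" else "m"
      height <- stats::rnorm(1, 1.72, 0.09)
      weight <- stats::rnorm(1, 78, 14)
      rec <- data.frame(
        patient_id = sprintf("P%02d", i), sex = sex,
        age = round(min(95, max(18, stats::rnorm(1, cfg$age_mean,
                                                 cfg$age_sd)))),
        height = round(min(2.05, max(1.45, height)), 2),
        weight = round(min(140, max(45, weight)), 1),
        dose_mbq = round(stats::rnorm(1, 316, 13), 1),
        response = out$response, os_days = out$os_days, died = out$died,
        risk = risk, stringsAsFactors = FALSE)
      lm <- sim_landmarks(cfg)
      lm$excluded <- stats::runif(4) < cfg$p_vertebra_excluded
      n_les <- max(1L, stats::rpois(1, cfg$lesion_rate))
      placed <- list()
      lesions <- lapply(seq_len(n_les), function(k) {
        ## the first lesion must fit; later ones are dropped when no
        ## non-overlapping position exists in the phantom
        geo <- if (k == 1L) sample_lesion_geometry(cfg, k, lm, placed)
               else tryCatch(sample_lesion_geometry(cfg, k, lm, placed),
                             error = function(e) NULL)
        if (is.null(geo)) return(NULL)
        placed[[length(placed) + 1L]] <<- geo
        geo$adc_artifact <- stats::runif(1) < cfg$p_adc_artifact
        geo$sulmax <- stats::runif(1, cfg$sulmax_range[1],
                                   cfg$sulmax_range[2])
        adc_mu <- if (risk == "low") cfg$adc_mean_low else cfg$adc_mean_high
        adc_sp <- if (risk == "low") cfg$adc_spread_low else
          cfg$adc_spread_high
        geo$adc_lesion_mean <- max(200, stats::rnorm(1, adc_mu, adc_sp))
        geo
      })
      lesions <- Filter(Negate(is.null), lesions)
      structure(list(record = rec, a = a, risk = risk, lesions = lesions,
                     landmarks = lm, volumes = NULL, masks = NULL,
                     texture_seed = (cfg$seed * 10007 + i * 7919) %%
                       2147483647L),
                class = "mel_case")
    })
  })
  if (render) cases <- lapply(cases, render_volumes, config = cfg)
  cohort <- do.call(rbind, lapply(cases, function(cs) cs$record))
  class(cohort) <- c("mel_cohort", "data.frame")
  structure(list(cases = cases, cohort = cohort, config = cfg),
            class = "mel_cohort_sim")
}

#' @export
print.mel_cohort_sim <- function(x, ...) {
  cat(sprintf("<mel_cohort_sim> %d patients (%d low risk), %s\n",
              nrow(x$cohort), sum(x$cohort$risk == "low"),
              if (is.null(x$cases[[1]]$volumes)) "geometry only"
              else "rendered"))
  invisible(x)
}

paint_sphere <- function(arr, spacing, center, radius, value) {
  d <- dim(arr)
  lo <- pmax(1L, floor((center - radius) / spacing) + 1L)
  hi <- pmin(d, ceiling((center + radius) / spacing) + 1L)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  px <- (g$x - 1) * spacing[1]; py <- (g$y - 1) * spacing[2]
  pz <- (g$z - 1) * spacing[3]
  inside <- (px - center[1])^2 + (py - center[2])^2 + (pz - center[3])^2 <=
    radius^2
  arr[as.matrix(g[inside, ])] <- value
  arr
}

#' Render the multimodal volumes of one simulated case
#'
#' Lesions become ellipsoids carrying a seeded multi-octave texture field
#' `T` in \[0,1\]: PET voxels are `SULmax * (1 - h * T)` with `h` the
#' class heterogeneity amplitude; CT lesions sit at soft-tissue HU, VIBE
#' lesions are hyperintense, ADC voxels are drawn around the lesion's ADC
#' mean. Organ reference regions (liver, spleen, L1-L4) are rendered with
#' configurable uptake so SLR and BLR are computable. All five volumes
#' share one grid by construction.
#'
#' @param case A `mel_case` from [simulate_cohort()].
#' @param config The `mel_sim_config` used to create the case.
#' @return The case with `volumes` (named list of `mel_volume`) and
#'   `masks` (list of `mel_mask`) filled in.
#' @export
render_volumes <- function(case, config) {
  cfg <- config
  d <- cfg$shape; sp <- cfg$spacing
  withr::with_seed(case$texture_seed, {
    pet <- array(cfg$pet_background, dim = d) +
      array(stats::rnorm(prod(d), 0, cfg$noise_sd), dim = d)
    pet[pet < 0] <- 0
    ct <- array(cfg$ct_background, dim = d)
    vibe <- array(cfg$vibe_background, dim = d)
    adc <- array(cfg$adc_background, dim = d)
    lmk <- case$landmarks
    if (cfg$with_organs) {
      pet <- paint_sphere(pet, sp, lmk$liver, lmk$liver_r, cfg$liver_sul)
      pet <- paint_sphere(pet, sp, lmk$spleen, lmk$spleen_r, cfg$spleen_sul)
      for (v in lmk$vertebrae)
        pet <- paint_sphere(pet, sp, v, lmk$vertebra_r, cfg$vertebra_sul)
      ct <- paint_sphere(ct, sp, lmk$liver, lmk$liver_r, 55)
      ct <- paint_sphere(ct, sp, lmk$spleen, lmk$spleen_r, 50)
      for (v in lmk$vertebrae)
        ct <- paint_sphere(ct, sp, v, lmk$vertebra_r, 300)
    }
    h <- cfg$hetero_lo + cfg$hetero_effect * (case$risk == "high")
    masks <- vector("list", length(case$lesions))
    for (k in seq_along(case$lesions)) {
      geo <- case$lesions[[k]]
      lo <- pmax(1L, floor((geo$center - geo$radii) / sp) + 1L)
      hi <- pmin(d, ceiling((geo$center + geo$radii) / sp) + 1L)
      bd <- hi - lo + 1L
      g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
      px <- (g$x - 1) * sp[1]; py <- (g$y - 1) * sp[2]
      pz <- (g$z - 1) * sp[3]
      inside <- ((px - geo$center[1]) / geo$radii[1])^2 +
                ((py - geo$center[2]) / geo$radii[2])^2 +
                ((pz - geo$center[3]) / geo$radii[3])^2 <= 1
      rho2 <- ((px - geo$center[1]) / geo$radii[1])^2 +
              ((py - geo$center[2]) / geo$radii[2])^2 +
              ((pz - geo$center[3]) / geo$radii[3])^2
      idx <- as.matrix(g[inside, , drop = FALSE])
      tex <- fractal_noise(bd)
      tv <- tex[as.matrix(sweep(as.matrix(g[inside, , drop = FALSE]), 2,
                                lo - 1L, "-"))]
      ## smooth rim: blend the lesion into the background over
      ## lesion_edge_mm (PSF analogue), so edges are not the dominant
      ## high-frequency content
      wgt <- if (cfg$lesion_edge_mm > 0) {
        wl <- (1 - sqrt(rho2[inside])) * min(geo$radii) / cfg$lesion_edge_mm
        wl <- pmin(pmax(wl, 0), 1)
        wl * wl * (3 - 2 * wl)
      } else rep(1, sum(inside))
      ## the texture field modulates every modality with the class
      ## amplitude h, so the planted heterogeneity is multimodal
      blend <- function(bg_vals, lesion_vals)
        bg_vals * (1 - wgt) + lesion_vals * wgt
      ## centred texture: the class amplitude h changes the voxel spread
      ## but not the mean lesion uptake
      pet[idx] <- blend(pet[idx], geo$sulmax * (1 - h * (tv - 0.5)))
      ct[idx] <- blend(ct[idx], cfg$ct_lesion + 120 * h * (tv - 0.5))
      vibe[idx] <- blend(vibe[idx],
                         cfg$vibe_lesion * (1 + 0.8 * h * (tv - 0.5)))
      adc[idx] <- blend(adc[idx], geo$adc_lesion_mean +
                        cfg$adc_sd_voxel * stats::rnorm(sum(inside)))
      mv <- array(0L, dim = d); mv[idx] <- 1L
      masks[[k]] <- as_mask(mv, lesion_id = sprintf("L%02d", k),
                            organ_region = geo$region, spacing = sp,
                            adc_artifact = geo$adc_artifact)
    }
    pet_ct <- pet + array(stats::rnorm(prod(d), 0, cfg$noise_sd), dim = d)
    pet_ct[pet_ct < 0] <- 0
    case$volumes <- list(
      PET_CT = as_volume(pet_ct, sp, "PET_CT"),
      CT = as_volume(ct, sp, "CT"),
      PET_MR = as_volume(pet, sp, "PET_MR"),
      MR_VIBE = as_volume(vibe, sp, "MR_VIBE"),
      ADC = as_volume(adc, sp, "ADC"))
    case$masks <- masks
  })
  case
}

#' Export a simulated case to disk
#'
#' Writes `patients/<id>/<modality>.nii.gz`, the lesion masks, a
#' `lesions.csv` with the per-lesion labels and a `landmarks.json`.
#'
#' @param case A rendered `mel_case`.
#' @param directory Cohort output directory.
#' @export
export_case <- function(case, directory) {
  if (is.null(case$volumes)) stop("case has not been rendered")
  pdir <- file.path(directory, "patients", case$record$patient_id)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(case$volumes))
    save_volume(case$volumes[[m]], file.path(pdir, paste0(m, ".nii.gz")))
  for (k in seq_along(case$masks))
    save_mask(case$masks[[k]],
              file.path(pdir, sprintf("lesion_%02d.nii.gz", k)))
  les <- do.call(rbind, lapply(case$masks, function(m)
    data.frame(lesion_id = m$lesion_id, organ_region = m$organ_region,
               adc_artifact = m$adc_artifact, stringsAsFactors = FALSE)))
  utils::write.csv(les, file.path(pdir, "lesions.csv"), row.names = FALSE)
  lmk <- case$landmarks
  jsonlite::write_json(
    list(liver = lmk$liver, liver_r = lmk$liver_r, spleen = lmk$spleen,
         spleen_r = lmk$spleen_r, vertebrae = lmk$vertebrae,
         vertebra_r = lmk$vertebra_r, excluded = lmk$excluded),
    file.path(pdir, "landmarks.json"), digits = NA, auto_unbox = TRUE)
  invisible(pdir)
}

#' Export a whole simulated cohort
#'
#' @param sim A `mel_cohort_sim`.
#' @param directory Output directory; gets `cohort.csv` plus one
#'   subdirectory per patient.
#' @export
export_cohort <- function(sim, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (case in sim$cases) export_case(case, directory)
  save_cohort_table(sim$cohort, file.path(directory, "cohort.csv"))
  invisible(directory)
}

#' Load an exported case back from disk
#'
#' @param directory Cohort directory written by [export_cohort()].
#' @param patient_id Patient to load.
#' @return A `mel_case` with volumes, masks and landmarks (no latent
#'   variables; the record row comes from `cohort.csv`).
#' @export
load_case <- function(directory, patient_id) {
  pdir <- file.path(directory, "patients", patient_id)
  if (!dir.exists(pdir)) stop("no exported patient at ", pdir)
  vols <- lapply(stats::setNames(nm = MODALITIES), function(m)
    load_volume(file.path(pdir, paste0(m, ".nii.gz")), m))
  les <- utils::read.csv(file.path(pdir, "lesions.csv"),
                         stringsAsFactors = FALSE)
  masks <- lapply(seq_len(nrow(les)), function(k)
    load_mask(file.path(pdir, sprintf("lesion_%02d.nii.gz", k)),
              lesion_id = les$lesion_id[k],
              organ_region = les$organ_region[k],
              adc_artifact = les$adc_artifact[k]))
  lj <- jsonlite::read_json(file.path(pdir, "landmarks.json"),
                            simplifyVector = TRUE)
  lmk <- list(liver = lj$liver, liver_r = lj$liver_r, spleen = lj$spleen,
              spleen_r = lj$spleen_r,
              vertebrae = lapply(seq_len(nrow(lj$vertebrae)),
                                 function(i) lj$vertebrae[i, ]),
              vertebra_r = lj$vertebra_r, excluded = lj$excluded)
  cohort <- load_cohort_table(file.path(directory, "cohort.csv"))
  rec <- cohort[cohort$patient_id == patient_id, , drop = FALSE]
  structure(list(record = rec, a = NA_real_, risk = rec$risk,
                 lesions = NULL, landmarks = lmk, volumes = vols,
                 masks = masks, texture_seed = NA_integer_),
            class = "mel_case")
}

#' Simulate a patient-feature table without imaging
#'
#' Fast feature-level counterpart of the imaging generator, used for
#' statistical calibration of the marker screen: draws the marker battery
#' and outcomes directly. With `planted = "none"` every marker is
#' independent of outcome (null model); `"tmtv"` ties the hazard to
#' log-TMTV; `"adc_range"` widens the ADC range in high-risk patients.
#'
#' @param n Number of patients.
#' @param planted One of `"none"`, `"tmtv"`, `"adc_range"`.
#' @param hazard_beta Strength of the planted TMTV-hazard link.
#' @param seed RNG seed.
#' @return A list with `features` (data.frame) and `outcomes`
#'   (data.frame with `os_days`, `died`, `response`).
#' @export
simulate_features <- function(n = 60, planted = c("none", "tmtv",
                                                  "adc_range"),
                              hazard_beta = 1.2, seed = 1) {
  planted <- match.arg(planted)
  withr::with_seed(seed, {
    log_tmtv <- stats::rnorm(n, log(50), 1)
    haz <- (1 / 600) * exp(if (planted == "tmtv")
      hazard_beta * (log_tmtv - log(50)) else 0)
    ev <- stats::rexp(n, haz)
    died <- ev <= 1800
    os_days <- pmax(1, round(pmin(ev, 1800)))
    response <- ifelse(stats::runif(n) < 0.38,
                       sample(c("CR", "PR", "SD"), n, replace = TRUE,
                              prob = c(4, 8, 2)), "PD")
    risk <- assign_risk(os_days, response)
    adc_mu <- if (planted == "adc_range") log(300) + 0.9 * (risk == "high")
              else log(500)
    organ_p <- c(0.45, 0.45, 0.35, 0.40, 0.15, 0.45, 0.10, 0.25, 0.25)
    feats <- data.frame(
      tmtv_ml = exp(log_tmtv),
      tlg_total = exp(stats::rnorm(n, log(500), 1.2)),
      n_lesions = pmin(200, 1 + stats::rpois(n, 10)),
      n_organ_regions = 1 + stats::rbinom(n, 7, 0.3),
      dm_max = pmax(6, stats::rnorm(n, 40, 15)),
      sul_min = exp(stats::rnorm(n, log(1.5), 0.5)),
      adc_range = exp(stats::rnorm(n, adc_mu, 0.5)),
      slr_elevated = stats::runif(n) < 0.08,
      blr = stats::rnorm(n, 0.76, 0.19))
    for (i in seq_along(ORGAN_REGIONS))
      feats[[paste0("organ_", gsub(" ", "_", ORGAN_REGIONS[i]))]] <-
        stats::runif(n) < organ_p[i]
    list(features = feats,
         outcomes = data.frame(os_days = os_days, died = died,
                               response = response, risk = risk,
                               stringsAsFactors = FALSE))
  })
}
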