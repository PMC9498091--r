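test_that("identical configs give identical cohorts", {
  cfg <- sim_config(n_patients = 3, shape = c(32, 32, 32),
                    spacing = c(2, 2, 2), lesion_rate = 1,
                    with_organs = FALSE, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$cases[[2]]$volumes$PET_MR$values,
                   b$cases[[2]]$volumes$PET_MR$values)
  expect_identical(a$cases[[3]]$masks[[1]]$values,
                   b$cases[[3]]$masks[[1]]$values)
  expect_error(sim_config(n_patients = 1), "at least 2")
})

test_that("latent aggressiveness drives survival in the stated direction", {
  cfg <- sim_config(n_patients = 500, beta = 1.4, seed = 77)
  sim <- simulate_cohort(cfg, render = FALSE)
  a <- vapply(sim$cases, function(cs) cs$a, numeric(1))
  os <- sim$cohort$os_days
  top <- a >= quantile(a, 0.75); bot <- a <= quantile(a, 0.25)
  expect_lt(mean(os[top]), mean(os[bot]))

  # null model: no dependence of outcome on a
  cfg0 <- sim_config(n_patients = 500, beta = 0, resp_gamma1 = 0,
                     seed = 78)
  sim0 <- simulate_cohort(cfg0, render = FALSE)
  a0 <- vapply(sim0$cases, function(cs) cs$a, numeric(1))
  expect_lt(abs(cor(a0, sim0$cohort$os_days)), 0.1)
})

test_that("rendered lesions honour the texture and geometry model", {
  # no texture, no taper: lesion voxels are exactly SULmax
  cfg <- sim_config(n_patients = 2, shape = c(40, 40, 40),
                    spacing = c(2, 2, 2), lesion_rate = 1,
                    dm_range_mm = c(20, 24), hetero_lo = 0,
                    hetero_effect = 0, lesion_edge_mm = 0,
                    with_organs = FALSE, outcome_mode = "balanced",
                    seed = 4)
  sim <- simulate_cohort(cfg)
  cs <- sim$cases[[1]]
  lesion_vals <- cs$volumes$PET_MR$values[cs$masks[[1]]$values == 1L]
  expect_equal(max(abs(lesion_vals - cs$lesions[[1]]$sulmax)), 0)

  # diameter recovery within one in-plane voxel
  feats <- compute_lesion_features(cs$volumes$PET_MR, cs$volumes$ADC,
                                   cs$masks[[1]])
  expect_equal(feats$dm_mm, cs$lesions[[1]]$dm, tolerance = 2.01)
  # planted SULmax recovered within 10%
  expect_equal(feats$sul_peak, cs$lesions[[1]]$sulmax, tolerance = 0.1 *
               cs$lesions[[1]]$sulmax)

  # organ reference regions support the spleen-liver ratio
  cfgo <- sim_config(n_patients = 2, shape = c(72, 72, 72),
                     spacing = c(2, 2, 2), lesion_rate = 1,
                     dm_range_mm = c(14, 18), liver_sul = 2.0,
                     spleen_sul = 1.8, seed = 12)
  simo <- simulate_cohort(cfgo)
  cso <- simo$cases[[1]]
  s <- slr(cso$volumes$PET_MR, cso$landmarks$liver, cso$landmarks$spleen)
  expect_equal(s$slr, 0.9, tolerance = 0.02)
})

test_that("export and reload give identical downstream features", {
  sim <- tiny_rendered_case(seed = 6, n_patients = 2)
  dir <- withr::local_tempdir()
  export_cohort(sim, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  ids <- sim$cohort$patient_id
  expect_equal(length(list.files(file.path(dir, "patients"))), 2)
  # 5 scalar volumes per patient
  for (id in ids)
    expect_length(list.files(file.path(dir, "patients", id),
                             pattern = "^(PET_CT|CT|PET_MR|MR_VIBE|ADC)"),
                  5)
  reloaded <- load_case(dir, ids[1])
  orig <- case_patient_features(sim$cases[[1]])
  back <- case_patient_features(reloaded)
  expect_equal(back$patient$tmtv_ml, orig$patient$tmtv_ml,
               tolerance = 1e-9)
  expect_equal(back$patient$dm_max, orig$patient$dm_max)
  expect_equal(back$patient$slr, orig$patient$slr, tolerance = 1e-9)
})

test_that("feature-level generator plants the ADC-range class signal", {
  hits <- 0
  for (s in 1:10) {
    d <- simulate_features(n = 60, planted = "adc_range", seed = s)
    hi <- d$outcomes$risk == "high"
    if (sum(hi) >= 2 && sum(!hi) >= 2) {
      p <- welch_t_test(d$features$adc_range[hi],
                        d$features$adc_range[!hi])$p
      if (p < 0.05) hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})
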