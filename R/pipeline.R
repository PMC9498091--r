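#' Patient-level feature extraction for one case
#'
#' Runs the lesion measurement protocol over every mask of the case
#' (PET quantification on the PET/MR volume), aggregates to patient
#' level, and adds the spleen-liver and bone-marrow-liver reference
#' ratios from the case landmarks where they are computable.
#'
#' @param case A rendered or loaded `mel_case`.
#' @return A list with `lesions` (per-lesion data.frame) and `patient`
#'   (one-row data.frame including `slr`, `slr_elevated`, `blr`).
#' @export
case_patient_features <- function(case) {
  pet <- case$volumes$PET_MR
  adc <- case$volumes$ADC
  lesions <- do.call(rbind, lapply(case$masks, function(m)
    compute_lesion_features(pet, adc, m)))
  lesions <- cbind(patient_id = case$record$patient_id, lesions)
  lmk <- case$landmarks
  slr_val <- tryCatch(slr(pet, lmk$liver, lmk$spleen),
                      error = function(e) NULL)
  blr_val <- tryCatch(blr(pet, lmk$vertebrae, lmk$excluded, lmk$liver),
                      error = function(e) NA_real_)
  pat <- patient_feature_summary(lesions, n_found = nrow(lesions),
                                 slr = if (is.null(slr_val)) NA_real_
                                       else slr_val$slr,
                                 blr = blr_val)
  pat$slr_elevated <- if (is.null(slr_val)) NA else
    slr_val$sweep$elevated[slr_val$sweep$cutoff == 1.1]
  pat <- cbind(patient_id = case$record$patient_id, pat)
  list(lesions = lesions, patient = pat)
}

#' Feature tables for a whole cohort
#'
#' @param sim A rendered `mel_cohort_sim`, or a directory written by
#'   [export_cohort()] (cases are then re-loaded from disk).
#' @return A list with `lesion_features` and `patient_features`
#'   data.frames keyed by `patient_id`.
#' @export
extract_cohort_features <- function(sim) {
  cases <- if (is.character(sim)) {
    cohort <- load_cohort_table(file.path(sim, "cohort.csv"))
    lapply(cohort$patient_id, function(id) load_case(sim, id))
  } else sim$cases
  res <- lapply(cases, case_patient_features)
  list(lesion_features = do.call(rbind, lapply(res, `[[`, "lesions")),
       patient_features = do.call(rbind, lapply(res, `[[`, "patient")))
}

#' Summary report of the embedded study cohort
#'
#' Recomputes the headline cohort statistics from the embedded
#' 37-patient table: deaths, responder counts per category, arithmetic
#' mean OS of the deceased, sex counts, mean age, and the agreement of
#' the OS/response risk rule with the printed risk column.
#'
#' @return A list of named scalars.
#' @export
fixture_report <- function() {
  tab <- table1_fixture()
  responders <- tab$response %in% c("CR", "PR", "SD")
  derived <- assign_risk(tab$os_days, tab$response)
  list(
    n_patients = nrow(tab),
    deaths = sum(tab$died),
    responders = sum(responders),
    response_counts = as.list(table(factor(tab$response,
                                           levels = RESPONSE_LEVELS))),
    nonresponders = sum(!responders),
    females = sum(tab$sex == "f"),
    mean_age = mean(tab$age),
    mean_os_deceased = mean(tab$os_days[tab$died]),
    risk_agreement = sum(derived == tab$risk),
    n_low_risk = sum(tab$risk == "low")
  )
}

read_run_config <- function(config) {
  if (is.null(config)) return(list(sim = sim_config(),
                                   model = model_config()))
  raw <- if (is.character(config)) yaml::read_yaml(config) else config
  sim <- do.call(sim_config, raw$sim %||% list())
  model <- do.call(model_config, raw$model %||% list())
  list(sim = sim, model = model)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

PIPELINE_STAGES <- c("simulate", "features", "survival", "train-cnn",
                     "evaluate")

#' Run the analysis pipeline
#'
#' Orchestrates `simulate` (phantom cohort written to disk), `features`
#' (cases re-loaded from disk, feature CSVs written), `survival` (marker
#' screen and Kaplan-Meier exports), `train-cnn` (leave-one-patient-out
#' cross-validation, predictions CSV) and `evaluate` (confusion metrics
#' JSON from the predictions). Later stages fail with a dependency error
#' when their upstream artifacts are absent.
#'
#' @param outdir Output directory.
#' @param stages Subset of
#'   `c("simulate","features","survival","train-cnn","evaluate")`.
#' @param config `NULL` (defaults), a YAML file path, or a list with
#'   `sim` / `model` key lists passed to [sim_config()] /
#'   [model_config()].
#' @param seed Master seed applied to the simulation and the
#'   cross-validation.
#' @return A run-manifest list (config hash, seed, stages, artifact
#'   paths, timestamps), also written to `manifest.json`.
#' @export
run_pipeline <- function(outdir, stages = PIPELINE_STAGES, config = NULL,
                         seed = 1) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  cfg <- read_run_config(config)
  cfg$sim$seed <- seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cohort_dir <- file.path(outdir, "cohort")
  artifacts <- list()
  need <- function(path, stage, producer) {
    if (!file.exists(path))
      stop(sprintf("stage '%s' needs missing artifact %s (run '%s' first)",
                   stage, path, producer))
    path
  }
  if ("simulate" %in% stages) {
    sim <- simulate_cohort(cfg$sim, render = TRUE)
    export_cohort(sim, cohort_dir)
    artifacts$cohort <- file.path(cohort_dir, "cohort.csv")
  }
  if ("features" %in% stages) {
    need(file.path(cohort_dir, "cohort.csv"), "features", "simulate")
    fts <- extract_cohort_features(cohort_dir)
    utils::write.csv(fts$lesion_features,
                     file.path(outdir, "lesion_features.csv"),
                     row.names = FALSE)
    utils::write.csv(fts$patient_features,
                     file.path(outdir, "patient_features.csv"),
                     row.names = FALSE)
    artifacts$lesion_features <- file.path(outdir, "lesion_features.csv")
    artifacts$patient_features <- file.path(outdir, "patient_features.csv")
  }
  if ("survival" %in% stages) {
    pf <- need(file.path(outdir, "patient_features.csv"), "survival",
               "features")
    feats <- utils::read.csv(pf, stringsAsFactors = FALSE)
    cohort <- load_cohort_table(need(file.path(cohort_dir, "cohort.csv"),
                                     "survival", "simulate"))
    stopifnot(identical(feats$patient_id, cohort$patient_id))
    screen <- marker_screen(feats, cohort)
    utils::write.csv(screen, file.path(outdir, "marker_screen.csv"),
                     row.names = FALSE)
    km <- km_curve(cohort$os_days, cohort$died)
    utils::write.table(
      data.frame(time = km$time, survival = km$surv, at_risk = km$n_risk),
      file.path(outdir, "km_overall.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    artifacts$marker_screen <- file.path(outdir, "marker_screen.csv")
    artifacts$km_overall <- file.path(outdir, "km_overall.tsv")
  }
  if ("train-cnn" %in% stages) {
    need(file.path(cohort_dir, "cohort.csv"), "train-cnn", "simulate")
    sim <- simulate_cohort(cfg$sim, render = TRUE)
    cv <- loocv(sim, cfg$model, seed = seed)
    utils::write.csv(cv$predictions, file.path(outdir, "predictions.csv"),
                     row.names = FALSE)
    artifacts$predictions <- file.path(outdir, "predictions.csv")
  }
  if ("evaluate" %in% stages) {
    pr <- need(file.path(outdir, "predictions.csv"), "evaluate",
               "train-cnn")
    preds <- utils::read.csv(pr, stringsAsFactors = FALSE)
    metrics <- confusion_metrics(preds$label, preds$truth)
    jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts$metrics <- file.path(outdir, "metrics.json")
  }
  manifest <- list(
    config_hash = config_hash(cfg),
    master_seed = seed,
    package_version = as.character(utils::packageVersion("melrisk")),
    stages = stages,
    artifacts = artifacts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
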