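## Head warm-up: the branch features of every training sample are
## computed once (populating the batch-norm running statistics), and the
## dense fusion head alone is driven to a good operating point by many
## cheap full-batch Adam steps before end-to-end training begins. In
## short training schedules this replaces the hundreds of epochs the
## full-scale protocol would spend bringing the head into range.
head_warmup <- function(model, store, onehot_all, wts, ctr, scl) {
  cfg <- model$config
  feats <- matrix(0, store$n, 2L * cfg$widths[3])
  ## features are extracted per patient under the patient's own batch
  ## statistics, exactly as predictions are normalized later
  for (pid in unique(store$patient)) {
    idx <- which(store$patient == pid)
    b <- make_batch(store, idx, ctr, scl)
    pet <- branch_fwd(model$params, model$buffers, "pet", b$pet,
                      b$dims, cfg, training = "batch")
    anat <- branch_fwd(model$params, model$buffers, "anat", b$anat,
                       b$dims, cfg, training = "batch")
    feats[idx, ] <- cbind(pet$out, anat$out)
  }
  anth <- sweep(sweep(store$anthro, 2, ctr, "-"), 2, scl, "/")
  head_names <- grep("^head\\.", names(model$params), value = TRUE)
  hp <- model$params[head_names]
  st <- adam_init(hp)
  for (it in seq_len(cfg$head_warmup_steps)) {
    jit <- if (cfg$anthro_jitter > 0)
      anth + stats::rnorm(length(anth), 0, cfg$anthro_jitter) else anth
    X <- cbind(feats, jit)
    f1 <- dense_fwd(hp, "head.fc1", X)
    h1 <- relu_fwd(f1$out)
    f2 <- dense_fwd(hp, "head.fc2", h1$out)
    h2 <- relu_fwd(f2$out)
    f3 <- dense_fwd(hp, "head.fc3", h2$out)
    sm <- softmax_ce(f3$out, onehot_all, weights = wts)
    grads <- new.env(parent = emptyenv())
    dh2 <- dense_bwd(hp, grads, "head.fc3", sm$dZ, f3$cache)
    df2 <- relu_bwd(dh2, h2$cache)
    dh1 <- dense_bwd(hp, grads, "head.fc2", df2, f2$cache)
    df1 <- relu_bwd(dh1, h1$cache)
    dense_bwd(hp, grads, "head.fc1", df1, f1$cache)
    hp <- adam_step(hp, grads, st, cfg$head_warmup_lr %||% 0.05)
  }
  model$params[head_names] <- hp
  model
}

onehot_labels <- function(labels) {
  lv <- c("low", "high")
  m <- matrix(0, length(labels), 2)
  m[cbind(seq_along(labels), match(labels, lv))] <- 1
  m
}

#' Train the multistream network on a patch-sample set
#'
#' Minimizes the categorical cross-entropy with Adam over minibatches of
#' orientation slice triples. Initialization, shuffling and dropout are
#' seeded. Training and validation must not share lesions; the held-out
#' test patient of a cross-validation fold must never appear here at all.
#'
#' @param model A `mel_cnn` from [build_model()].
#' @param train_store Sample store of the training patients (from the
#'   internal patch assembly; see [loocv()]).
#' @param val_store Optional validation store (different lesions; may
#'   share patients with training, as the validation lesion is a second
#'   lesion of the same patients).
#' @param seed Training seed (shuffling, dropout).
#' @param verbose Print per-epoch losses.
#' @return The model with updated parameters plus `history` (data.frame
#'   of per-epoch train/validation loss) and the anthropometric
#'   standardization in `anthro_center` / `anthro_scale`.
#' @export
train_cnn <- function(model, train_store, val_store = NULL,
                      seed = model$config$seed, verbose = FALSE) {
  cfg <- model$config
  if (!is.null(val_store)) {
    tr_keys <- unique(paste(train_store$patient, train_store$lesion %||%
                            "", sep = "/"))
    va_keys <- unique(paste(val_store$patient, val_store$lesion %||% "x",
                            sep = "/"))
    if (length(intersect(tr_keys, va_keys)) > 0)
      stop("leakage: training and validation share a lesion")
  }
  ctr <- colMeans(train_store$anthro)
  scl <- apply(train_store$anthro, 2, stats::sd)
  scl[!is.finite(scl) | scl <= 0] <- 1
  onehot_all <- onehot_labels(train_store$label)
  ## inverse-frequency sample weights: leave-one-out folds are mildly
  ## class-imbalanced, which otherwise biases the prior of the net
  wts <- if (isTRUE(cfg$class_balance)) {
    tab <- table(train_store$label)
    as.numeric(sum(tab) / (length(tab) * tab[train_store$label]))
  } else rep(1, train_store$n)
  S <- train_store$n
  bs <- min(cfg$batch_size, S)
  hist_tr <- numeric(cfg$epochs); hist_va <- rep(NA_real_, cfg$epochs)
  withr::with_seed(seed, {
    st <- adam_init(model$params)
    if ((cfg$head_warmup_steps %||% 0) > 0)
      model <- head_warmup(model, train_store, onehot_all, wts, ctr, scl)
    by_patient <- isTRUE(cfg$batch_by_patient)
    for (ep in seq_len(cfg$epochs)) {
      batches <- if (by_patient) {
        ## one patient per minibatch: batch-norm statistics are then
        ## patient-wise during training, matching transductive inference
        pats <- sample(unique(train_store$patient))
        lapply(pats, function(p) which(train_store$patient == p))
      } else {
        perm <- sample.int(S)
        lapply(seq(1, S, by = bs), function(start)
          perm[start:min(start + bs - 1, S)])
      }
      losses <- numeric(0)
      for (idx in batches) {
        if (length(idx) < 2) next
        batch <- make_batch(train_store, idx, ctr, scl)
        if (cfg$anthro_jitter > 0)
          batch$anthro <- batch$anthro +
            stats::rnorm(length(batch$anthro), 0, cfg$anthro_jitter)
        out <- cnn_forward(model, batch, training = TRUE)
        sm <- softmax_ce(out$logits, onehot_all[idx, , drop = FALSE],
                         weights = wts[idx])
        grads <- cnn_backward(model, out$cache, sm$dZ)
        model$params <- adam_step(model$params, grads, st, cfg$lr,
                                  head_lr_mult = cfg$head_lr_mult %||% 1)
        losses <- c(losses, sm$loss)
      }
      hist_tr[ep] <- mean(losses)
      if (!is.null(val_store)) {
        pv <- predict_store(model, val_store, ctr, scl)
        hist_va[ep] <- -mean(log(pmax(ifelse(val_store$label == "low",
                                             pv[, 1], pv[, 2]), 1e-12)))
      }
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %s", ep, hist_tr[ep],
                        ifelse(is.na(hist_va[ep]), "-",
                               sprintf("%.4f", hist_va[ep]))))
    }
  })
  model$history <- data.frame(epoch = seq_len(cfg$epochs),
                              train_loss = hist_tr, val_loss = hist_va)
  model$anthro_center <- ctr
  model$anthro_scale <- scl
  model
}

## eval-mode softmax probabilities for every sample of a store
predict_store <- function(model, store, anthro_center = model$anthro_center,
                          anthro_scale = model$anthro_scale,
                          chunk = 256L) {
  mode <- if (identical(model$config$bn_inference, "running")) FALSE
          else "batch"
  probs <- matrix(0, store$n, 2)
  for (start in seq(1, store$n, by = chunk)) {
    idx <- start:min(start + chunk - 1, store$n)
    batch <- make_batch(store, idx, anthro_center, anthro_scale)
    probs[idx, ] <- cnn_forward(model, batch, training = mode)$prob
  }
  probs
}

#' Aggregate patch predictions into a patient-level risk call
#'
#' Mean softmax probability over all patch samples and modality pairs of
#' the patient's target lesion; the patient is called low risk when the
#' mean low-risk probability exceeds 0.5 (an exact tie goes to high
#' risk, the conservative call).
#'
#' @param model A trained `mel_cnn`.
#' @param store Sample store of the patient's target lesion.
#' @return A list with `prob_low` and `label`.
#' @export
predict_patient <- function(model, store) {
  if (store$n < 1) stop("no patch samples for patient")
  p <- predict_store(model, store)
  prob_low <- mean(p[, 1])
  list(prob_low = prob_low,
       label = if (prob_low > 0.5) "low" else "high")
}

#' Select the validation lesion of a patient
#'
#' The lesion with the second-highest SULpeak and a longest diameter of
#' at least 10 mm; lower-ranked lesions are tried when the second-ranked
#' one is too small. Falls back to the highest-uptake lesion (flagged via
#' `attr(, "fallback")`) when no other lesion qualifies.
#'
#' @param lesions Per-lesion feature `data.frame`.
#' @return The validation `lesion_id`.
#' @export
select_validation_lesion <- function(lesions) {
  eligible <- lesions[lesions$organ_region != "brain" &
                      is.finite(lesions$sul_peak), , drop = FALSE]
  if (nrow(eligible) == 0) stop("no eligible lesion")
  ranked <- eligible[order(-eligible$sul_peak), , drop = FALSE]
  cand <- ranked[-1, , drop = FALSE]
  cand <- cand[cand$dm_mm >= 10, , drop = FALSE]
  if (nrow(cand) > 0) return(cand$lesion_id[1])
  out <- ranked$lesion_id[1]
  attr(out, "fallback") <- TRUE
  out
}

mask_centroid_mm <- function(mask) {
  vox <- which(mask$values == 1L, arr.ind = TRUE)
  (colMeans(vox) - 1) * mask$spacing
}

## Per-patient preparation: lesion features, target/validation lesion,
## normalized field-of-view blocks and the three patch-sample stores.
prepare_patient <- function(case, cfg, master_seed, val_stride = 16L,
                            with_val = TRUE) {
  pet <- case$volumes$PET_MR
  adc <- case$volumes$ADC
  feats <- do.call(rbind, lapply(case$masks, function(m)
    compute_lesion_features(pet, adc, m)))
  target_id <- select_target_lesion(feats)
  val_id <- as.character(select_validation_lesion(feats))
  tmask <- case$masks[[which(vapply(case$masks, function(m) m$lesion_id,
                                    character(1)) == target_id)]]
  vmask <- case$masks[[which(vapply(case$masks, function(m) m$lesion_id,
                                    character(1)) == val_id)]]
  pairs0 <- pairs_for_subset(cfg$modality_subset)
  needed <- unique(unlist(MODALITY_PAIRS[pairs0]))
  vibe_stats <- if ("MR_VIBE" %in% needed)
    list(mean = mean(case$volumes$MR_VIBE$values),
         sd = stats::sd(case$volumes$MR_VIBE$values)) else NULL
  crop_blocks <- function(center) {
    lapply(stats::setNames(nm = needed), function(m) {
      blk <- lesion_fov_crop(case$volumes[[m]], center, cfg$fov_mm,
                             cfg$grid_mm)
      normalize_modality(blk, m,
                         stats = if (m == "MR_VIBE") vibe_stats else NULL)
    })
  }
  t_blocks <- crop_blocks(mask_centroid_mm(tmask))
  v_blocks <- if (with_val) crop_blocks(mask_centroid_mm(vmask)) else NULL
  pid <- case$record$patient_id
  pat_seed <- (master_seed * 131071 +
               sum(utf8ToInt(pid)) * 7919) %% 2147483647
  ## interior slice triples: edge slices of a patch rarely intersect the
  ## lesion, so a reduced triple count samples central positions
  triple_idx <- if (cfg$triples_per_patch >= cfg$patch_vox)
    seq_len(cfg$patch_vox)
  else unique(round(seq(1, cfg$patch_vox,
                        length.out = cfg$triples_per_patch + 2L))
              )[2:(cfg$triples_per_patch + 1L)]
  pairs <- pairs_for_subset(cfg$modality_subset)
  dm_target <- feats$dm_mm[feats$lesion_id == target_id]
  anthro <- c(case$record$height, case$record$weight, dm_target)
  label <- case$record$risk
  train_pos <- sample_patches(dim(t_blocks[[1]]), n = cfg$n_patches,
                              patch_vox = cfg$patch_vox, seed = pat_seed)
  tile_pos <- tile_patches(dim(t_blocks[[1]]), patch_vox = cfg$patch_vox,
                           stride = val_stride)
  mk <- function(blocks, pos, mask, lesion) {
    st <- build_sample_store(blocks, pos, triple_idx, pairs, pid, label,
                             anthro, drop_adc = mask$adc_artifact)
    st$lesion <- rep(lesion, st$n)
    st
  }
  val <- NULL
  if (with_val) {
    vtile_pos <- tile_patches(dim(v_blocks[[1]]),
                              patch_vox = cfg$patch_vox,
                              stride = val_stride)
    val <- mk(v_blocks, vtile_pos, vmask, val_id)
  }
  list(patient_id = pid, label = label, features = feats,
       target_lesion = target_id, val_lesion = val_id,
       train = mk(t_blocks, train_pos, tmask, target_id),
       val = val,
       test = mk(t_blocks, tile_pos, tmask, target_id))
}

#' Confusion-matrix metrics for risk predictions
#'
#' The positive class is low risk: TP counts correctly predicted
#' low-risk patients. Rates with a zero denominator are reported `NA`.
#'
#' @param predicted,truth Character vectors of `"low"` / `"high"` labels.
#' @return A list with `tp`, `tn`, `fp`, `fn`, `sensitivity`,
#'   `specificity`, `ppv`, `accuracy`.
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("prediction and label lengths differ")
  if (any(!c(predicted, truth) %in% c("low", "high")))
    stop("labels must be 'low' or 'high'")
  tp <- sum(predicted == "low" & truth == "low")
  tn <- sum(predicted == "high" & truth == "high")
  fp <- sum(predicted == "low" & truth == "high")
  fn <- sum(predicted == "high" & truth == "low")
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       ppv = rate(tp, tp + fp),
       accuracy = rate(tp + tn, tp + tn + fp + fn))
}

#' Leave-one-patient-out cross-validation of the risk network
#'
#' One fold per patient: the network is trained from scratch on the
#' remaining patients' target lesions (seeded random patches), monitored
#' on their validation lesions, and tested on the held-out patient's
#' target lesion (deterministic patch tiling). Every fold asserts
#' structurally that the held-out patient contributes no training or
#' validation sample.
#'
#' @param sim A rendered `mel_cohort_sim` (or a list with `cases`).
#' @param config A [model_config()].
#' @param seed Master seed fanned out to per-fold initialization and
#'   per-patient patch sampling.
#' @param use_validation Monitor validation loss per epoch (slower).
#' @param permute_labels Permute risk labels across patients before
#'   training (null-signal calibration mode).
#' @param verbose Print fold progress.
#' @return A list of class `mel_loocv`: `predictions` (data.frame with
#'   `patient_id`, `truth`, `prob_low`, `label`, `fold`), `metrics`
#'   ([confusion_metrics()]), `config`, `seed`.
#' @export
loocv <- function(sim, config = model_config(), seed = 1,
                  use_validation = FALSE, permute_labels = FALSE,
                  verbose = FALSE) {
  cases <- sim$cases
  if (length(cases) < 3) stop("need at least 3 patients for cross-validation")
  prep <- lapply(cases, prepare_patient, cfg = config, master_seed = seed,
                 with_val = use_validation)
  if (permute_labels) {
    labs <- vapply(prep, function(p) p$label, character(1))
    newlabs <- withr::with_seed(seed + 555, sample(labs))
    for (i in seq_along(prep)) {
      prep[[i]]$label <- newlabs[i]
      for (part in c("train", "val", "test"))
        if (!is.null(prep[[i]][[part]]))
          prep[[i]][[part]]$label <- rep(newlabs[i],
                                         prep[[i]][[part]]$n)
    }
  }
  ids <- vapply(prep, function(p) p$patient_id, character(1))
  preds <- vector("list", length(prep))
  for (f in seq_along(prep)) {
    train_stores <- prep[-f]
    tr <- concat_stores(lapply(train_stores, function(p) p$train))
    tr$lesion <- unlist(lapply(train_stores, function(p) p$train$lesion))
    if (ids[f] %in% tr$patient)
      stop("leakage: held-out patient present in training samples")
    va <- NULL
    if (use_validation) {
      va <- concat_stores(lapply(train_stores, function(p) p$val))
      va$lesion <- unlist(lapply(train_stores, function(p) p$val$lesion))
      if (ids[f] %in% va$patient)
        stop("leakage: held-out patient present in validation samples")
    }
    fold_cfg <- config
    fold_cfg$seed <- (seed * 1000 + f) %% 2147483647
    model <- build_model(fold_cfg)
    model <- train_cnn(model, tr, va, seed = fold_cfg$seed)
    pp <- predict_patient(model, prep[[f]]$test)
    preds[[f]] <- data.frame(patient_id = ids[f], truth = prep[[f]]$label,
                             prob_low = pp$prob_low, label = pp$label,
                             fold = f, stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("fold %d/%d: %s -> %s (p_low %.2f)", f, length(prep),
                      prep[[f]]$label, pp$label, pp$prob_low))
  }
  predictions <- do.call(rbind, preds)
  structure(list(predictions = predictions,
                 metrics = confusion_metrics(predictions$label,
                                             predictions$truth),
                 config = config, seed = seed),
            class = "mel_loocv")
}

#' @export
print.mel_loocv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<mel_loocv> %d folds: accuracy %.3f, sensitivity %s,",
                     " specificity %s, ppv %s\n"),
              nrow(x$predictions), m$accuracy,
              format(round(m$sensitivity, 3)),
              format(round(m$specificity, 3)),
              format(round(m$ppv, 3))))
  invisible(x)
}

#' Modality-ablation study
#'
#' Reruns the leave-one-patient-out cross-validation on each requested
#' modality subset (joint input, PET/CT only, PET/MR only) and collects
#' the per-subset confusion metrics.
#'
#' @param sim A rendered `mel_cohort_sim`.
#' @param config Base [model_config()]; its `modality_subset` is
#'   overridden per run.
#' @param subsets Subsets to evaluate.
#' @param seed Master seed (shared across subsets).
#' @return A list with `metrics` (data.frame, one row per subset) and
#'   `runs` (named list of `mel_loocv` objects).
#' @export
modality_ablation <- function(sim, config = model_config(),
                              subsets = c("both", "PET_CT+CT",
                                          "PET_MR+MR"),
                              seed = 1) {
  subsets <- match.arg(subsets, several.ok = TRUE)
  runs <- lapply(subsets, function(su) {
    cfg <- config
    cfg$modality_subset <- su
    loocv(sim, cfg, seed = seed)
  })
  names(runs) <- subsets
  metrics <- do.call(rbind, lapply(subsets, function(su) {
    m <- runs[[su]]$metrics
    data.frame(subset = su, tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn,
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, accuracy = m$accuracy,
               stringsAsFactors = FALSE)
  }))
  list(metrics = metrics, runs = runs)
}
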