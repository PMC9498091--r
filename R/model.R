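#' Configuration of the multistream risk network
#'
#' Defaults are the frozen study-scale configuration: per-orientation
#' squeeze-and-excitation extractors with 8 channels, wide-residual
#' trunks with channel schedule 48/96/192, a 96/48/2 dense head, Adam
#' with learning rate 5e-4, batch size 32, 150 epochs and 384 training
#' patches per patient. Smaller values of the width/epoch/patch knobs
#' give desk-scale variants of the same topology.
#'
#' @param extractor_channels Channels of the extractor convolutions.
#' @param se_reduction Reduction factor of the channel-attention
#'   bottleneck.
#' @param widths Wide-residual channel schedule (three strictly
#'   increasing widths).
#' @param dense Dense-head widths (three layers; last must be 2).
#' @param dropout Dropout rate inside the wide-residual blocks.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param n_patches 3D training patches sampled per patient.
#' @param triples_per_patch Orientation slice triples used per 3D patch
#'   (up to 32).
#' @param patch_vox Patch edge length in voxels (32).
#' @param grid_mm Isotropic working-grid spacing of the lesion
#'   field-of-view crop (mm).
#' @param fov_mm Physical lesion field of view (LR x AP x HF, mm).
#' @param modality_subset `"both"`, `"PET_CT+CT"` or `"PET_MR+MR"`.
#' @param bn_momentum Running-statistics momentum of batch norm.
#' @param bn_inference Batch-norm statistics used at prediction time:
#'   `"batch"` normalizes with the statistics of the presented patient's
#'   own patch samples (transductive inference, robust when running
#'   statistics are estimated from few updates), `"running"` uses the
#'   exponential running statistics.
#' @param anthro_jitter SD of Gaussian noise added to the standardized
#'   anthropometric inputs during training (augmentation guarding
#'   against patient-identity memorization in small cohorts; 0 disables).
#' @param class_balance Weight samples by inverse class frequency in the
#'   training loss (leave-one-out folds are mildly imbalanced).
#' @param head_lr_mult Learning-rate multiplier of the dense fusion head
#'   (discriminative fine-tuning; useful in very short training runs).
#' @param head_warmup_steps Full-batch head-only optimization steps on
#'   cached branch features before end-to-end training (0 disables).
#'   Short schedules use this to bring the fusion head to its operating
#'   point at negligible cost.
#' @param head_warmup_lr Adam learning rate of the warm-up phase.
#' @param batch_by_patient Build each end-to-end minibatch from a single
#'   patient's samples so that training-time batch-norm statistics are
#'   patient-wise, consistent with `bn_inference = "batch"`.
#' @param seed Seed for weight initialization and patch sampling fan-out.
#' @return A list of class `mel_model_config`.
#' @export
model_config <- function(extractor_channels = 8,
                         se_reduction = 2,
                         widths = c(48, 96, 192),
                         dense = c(96, 48, 2),
                         dropout = 0.1,
                         lr = 5e-4,
                         batch_size = 32,
                         epochs = 150,
                         n_patches = 384,
                         triples_per_patch = 32,
                         patch_vox = 32,
                         grid_mm = 2,
                         fov_mm = c(132, 160, 250),
                         modality_subset = c("both", "PET_CT+CT",
                                             "PET_MR+MR"),
                         bn_momentum = 0.7,
                         bn_inference = c("batch", "running"),
                         anthro_jitter = 0,
                         class_balance = TRUE,
                         head_lr_mult = 1,
                         head_warmup_steps = 0,
                         head_warmup_lr = 0.05,
                         batch_by_patient = FALSE,
                         seed = 1) {
  cfg <- as.list(environment())
  cfg$modality_subset <- match.arg(modality_subset)
  cfg$bn_inference <- match.arg(bn_inference)
  if (length(cfg$widths) != 3 || any(diff(cfg$widths) <= 0))
    stop("widths must be three strictly increasing channel counts")
  if (length(cfg$dense) != 3 || cfg$dense[3] != 2)
    stop("dense head must have three layers ending in width 2")
  if (cfg$triples_per_patch < 1 || cfg$triples_per_patch > cfg$patch_vox)
    stop("triples_per_patch must lie in [1, patch_vox]")
  structure(cfg, class = "mel_model_config")
}

BRANCHES <- c("pet", "anat")
ORIENTATIONS <- c("ax", "cor", "sag")

init_se_block <- function(params, pre, cin, c, r) {
  params <- init_conv(params, paste0(pre, ".conv1"), cin, c)
  params <- init_bn(params, paste0(pre, ".bn1"), c)
  params <- init_conv(params, paste0(pre, ".conv2"), c, c)
  params <- init_bn(params, paste0(pre, ".bn2"), c)
  params <- init_dense(params, paste0(pre, ".att1"), c, max(1L, c %/% r))
  params <- init_dense(params, paste0(pre, ".att2"), max(1L, c %/% r), c)
  params
}

#' Build the multistream network
#'
#' Two branches (PET; anatomical MR/CT). Each branch runs three parallel
#' per-orientation feature extractors of two sequential
#' squeeze-and-excitation blocks, concatenates the orientation feature
#' maps, and processes them through three wide residual blocks with
#' increasing channel counts followed by global average pooling. The
#' pooled branch features are merged with three standardized
#' anthropometric scalars (height, weight, target-lesion diameter) and
#' classified by a three-layer dense head with softmax over two risk
#' classes.
#'
#' @param config A [model_config()].
#' @return An object of class `mel_cnn` with `params` (named parameter
#'   list), `buffers` (batch-norm running statistics), `config`,
#'   `n_parameters` and a parameter `breakdown`.
#' @export
build_model <- function(config = model_config()) {
  cfg <- config
  c <- cfg$extractor_channels
  params <- withr::with_seed(cfg$seed, {
    p <- list()
    for (br in BRANCHES) {
      for (o in ORIENTATIONS) {
        pre <- paste(br, o, sep = ".")
        p <- init_se_block(p, paste0(pre, ".se1"), 1L, c, cfg$se_reduction)
        p <- init_se_block(p, paste0(pre, ".se2"), c, c, cfg$se_reduction)
      }
      cin <- 3L * c
      for (k in 1:3) {
        w <- cfg$widths[k]
        pre <- paste0(br, ".wrb", k)
        p <- init_conv(p, paste0(pre, ".convA"), cin, w)
        p <- init_bn(p, paste0(pre, ".bnA"), w)
        p <- init_conv(p, paste0(pre, ".convB"), w, w)
        p <- init_conv(p, paste0(pre, ".convR"), cin, w)
        p <- init_bn(p, paste0(pre, ".bnM"), w)
        cin <- w
      }
    }
    fin <- 2L * cfg$widths[3] + 3L
    p <- init_dense(p, "head.fc1", fin, cfg$dense[1])
    p <- init_dense(p, "head.fc2", cfg$dense[1], cfg$dense[2])
    p <- init_dense(p, "head.fc3", cfg$dense[2], cfg$dense[3])
    p
  })
  n_par <- sum(vapply(params, length, integer(1)))
  is_conv <- grepl("\\.conv", names(params))
  is_dense <- grepl("\\.(fc|att)", names(params))
  breakdown <- c(
    conv = sum(vapply(params[is_conv], length, integer(1))),
    dense = sum(vapply(params[is_dense], length, integer(1))),
    bn = sum(vapply(params[!is_conv & !is_dense], length, integer(1))))
  structure(list(params = params, buffers = new.env(parent = emptyenv()),
                 config = cfg, n_parameters = n_par,
                 breakdown = breakdown),
            class = "mel_cnn")
}

#' @export
print.mel_cnn <- function(x, ...) {
  cat(sprintf(paste0("<mel_cnn> %s trainable parameters ",
                     "(conv %s, dense %s, bn %s)\n"),
              format(x$n_parameters, big.mark = ","),
              format(x$breakdown["conv"], big.mark = ","),
              format(x$breakdown["dense"], big.mark = ","),
              format(x$breakdown["bn"], big.mark = ",")))
  cat(sprintf("  widths %s, dense head %s, extractor channels %d\n",
              paste(x$config$widths, collapse = "/"),
              paste(x$config$dense, collapse = "/"),
              x$config$extractor_channels))
  invisible(x)
}

se_fwd <- function(params, buffers, pre, X, dims, training, momentum) {
  cv1 <- conv_fwd(params, paste0(pre, ".conv1"), X, dims)
  b1 <- bnrelu_fwd(params, buffers, paste0(pre, ".bn1"), cv1$out,
                   training, momentum)
  cv2 <- conv_fwd(params, paste0(pre, ".conv2"), b1$out, dims)
  b2 <- bnrelu_fwd(params, buffers, paste0(pre, ".bn2"), cv2$out,
                   training, momentum)
  U <- b2$out
  gp <- gap_fwd(U, dims)
  f1 <- dense_fwd(params, paste0(pre, ".att1"), gp$out)
  a1 <- relu_fwd(f1$out)
  f2 <- dense_fwd(params, paste0(pre, ".att2"), a1$out)
  gate <- 1 / (1 + exp(-f2$out))
  Y <- U * gate[gp$cache$g, , drop = FALSE]
  list(out = Y, cache = list(cv1 = cv1, b1 = b1, cv2 = cv2, b2 = b2,
                             U = U, gp = gp, f1 = f1, a1 = a1, f2 = f2,
                             gate = gate))
}

se_bwd <- function(params, grads, pre, dY, cache,
                   need_input_grad = TRUE) {
  g <- cache$gp$cache$g
  dU <- dY * cache$gate[g, , drop = FALSE]
  dgate <- rowsum(dY * cache$U, g)
  dz2 <- dgate * cache$gate * (1 - cache$gate)
  da1 <- dense_bwd(params, grads, paste0(pre, ".att2"), dz2,
                   cache$f2$cache)
  dz1 <- relu_bwd(da1, cache$a1$cache)
  ds <- dense_bwd(params, grads, paste0(pre, ".att1"), dz1,
                  cache$f1$cache)
  dU <- dU + gap_bwd(ds, cache$gp$cache)
  dcv2 <- bnrelu_bwd(params, grads, paste0(pre, ".bn2"), dU,
                     cache$b2$cache)
  db1 <- conv_bwd(params, grads, paste0(pre, ".conv2"), dcv2,
                  cache$cv2$cache)
  dcv1 <- bnrelu_bwd(params, grads, paste0(pre, ".bn1"), db1,
                     cache$b1$cache)
  conv_bwd(params, grads, paste0(pre, ".conv1"), dcv1, cache$cv1$cache,
           need_dx = need_input_grad)
}

wrb_fwd <- function(params, buffers, pre, X, dims, training, dropout,
                    momentum) {
  cvA <- conv_fwd(params, paste0(pre, ".convA"), X, dims)
  bA <- bnrelu_fwd(params, buffers, paste0(pre, ".bnA"), cvA$out,
                   training, momentum)
  dp <- dropout_fwd(bA$out, dropout, training)
  cvB <- conv_fwd(params, paste0(pre, ".convB"), dp$out, dims)
  cvR <- conv_fwd(params, paste0(pre, ".convR"), X, dims)
  M <- cvB$out + cvR$out
  bM <- bnrelu_fwd(params, buffers, paste0(pre, ".bnM"), M, training,
                   momentum)
  list(out = bM$out, cache = list(cvA = cvA, bA = bA, dp = dp, cvB = cvB,
                                  cvR = cvR, bM = bM))
}

wrb_bwd <- function(params, grads, pre, dY, cache) {
  dM <- bnrelu_bwd(params, grads, paste0(pre, ".bnM"), dY,
                   cache$bM$cache)
  dX <- conv_bwd(params, grads, paste0(pre, ".convR"), dM,
                 cache$cvR$cache)
  ddp <- conv_bwd(params, grads, paste0(pre, ".convB"), dM,
                  cache$cvB$cache)
  drA <- dropout_bwd(ddp, cache$dp$cache)
  dcvA <- bnrelu_bwd(params, grads, paste0(pre, ".bnA"), drA,
                     cache$bA$cache)
  dX + conv_bwd(params, grads, paste0(pre, ".convA"), dcvA,
                cache$cvA$cache)
}

branch_fwd <- function(params, buffers, br, slices, dims, cfg, training) {
  mom <- cfg$bn_momentum
  ex <- lapply(ORIENTATIONS, function(o) {
    pre <- paste(br, o, sep = ".")
    s1 <- se_fwd(params, buffers, paste0(pre, ".se1"), slices[[o]], dims,
                 training, mom)
    s2 <- se_fwd(params, buffers, paste0(pre, ".se2"), s1$out, dims,
                 training, mom)
    list(s1 = s1, s2 = s2)
  })
  names(ex) <- ORIENTATIONS
  X <- do.call(cbind, lapply(ex, function(e) e$s2$out))
  wr <- vector("list", 3L)
  for (k in 1:3) {
    wr[[k]] <- wrb_fwd(params, buffers, paste0(br, ".wrb", k), X, dims,
                       training, cfg$dropout, mom)
    X <- wr[[k]]$out
  }
  gp <- gap_fwd(X, dims)
  list(out = gp$out, cache = list(ex = ex, wr = wr, gp = gp))
}

branch_bwd <- function(params, grads, br, dY, cache, cfg) {
  dX <- gap_bwd(dY, cache$gp$cache)
  for (k in 3:1)
    dX <- wrb_bwd(params, grads, paste0(br, ".wrb", k), dX,
                  cache$wr[[k]]$cache)
  c0 <- cfg$extractor_channels
  for (i in seq_along(ORIENTATIONS)) {
    o <- ORIENTATIONS[i]
    pre <- paste(br, o, sep = ".")
    dblock <- dX[, ((i - 1L) * c0 + 1L):(i * c0), drop = FALSE]
    d1 <- se_bwd(params, grads, paste0(pre, ".se2"), dblock,
                 cache$ex[[o]]$s2$cache)
    se_bwd(params, grads, paste0(pre, ".se1"), d1, cache$ex[[o]]$s1$cache,
           need_input_grad = FALSE)
  }
  invisible(NULL)
}

#' Forward pass of the multistream network
#'
#' @param model A `mel_cnn`.
#' @param batch A list with `pet` and `anat` (each a named list of
#'   `ax`/`cor`/`sag` activation matrices of shape `(H*W*N) x 1`),
#'   `anthro` (`N x 3` standardized scalars) and `dims`
#'   (`list(H, W, N)`).
#' @param training `TRUE` (training mode: batch statistics, buffers
#'   updated, dropout active), `"batch"` (inference with batch
#'   statistics of the presented samples, buffers untouched) or `FALSE`
#'   (inference with running statistics).
#' @return A list with `prob` (`N x 2` softmax output, columns low/high),
#'   `logits`, and `cache` (when `training`).
#' @export
cnn_forward <- function(model, batch, training = FALSE) {
  params <- model$params; buffers <- model$buffers; cfg <- model$config
  dims <- batch$dims
  pet <- branch_fwd(params, buffers, "pet", batch$pet, dims, cfg, training)
  anat <- branch_fwd(params, buffers, "anat", batch$anat, dims, cfg,
                     training)
  feats <- cbind(pet$out, anat$out, batch$anthro)
  f1 <- dense_fwd(params, "head.fc1", feats)
  h1 <- relu_fwd(f1$out)
  f2 <- dense_fwd(params, "head.fc2", h1$out)
  h2 <- relu_fwd(f2$out)
  f3 <- dense_fwd(params, "head.fc3", h2$out)
  list(prob = softmax(f3$out), logits = f3$out,
       cache = if (isTRUE(training))
         list(pet = pet, anat = anat, f1 = f1, h1 = h1, f2 = f2,
              h2 = h2, f3 = f3, dims = dims) else NULL)
}

cnn_backward <- function(model, cache, dZ) {
  params <- model$params
  grads <- new.env(parent = emptyenv())
  dh2 <- dense_bwd(params, grads, "head.fc3", dZ, cache$f3$cache)
  df2 <- relu_bwd(dh2, cache$h2$cache)
  dh1 <- dense_bwd(params, grads, "head.fc2", df2, cache$f2$cache)
  df1 <- relu_bwd(dh1, cache$h1$cache)
  dfeats <- dense_bwd(params, grads, "head.fc1", df1, cache$f1$cache)
  w3 <- model$config$widths[3]
  branch_bwd(params, grads, "pet", dfeats[, 1:w3, drop = FALSE],
             cache$pet$cache, model$config)
  branch_bwd(params, grads, "anat",
             dfeats[, (w3 + 1):(2 * w3), drop = FALSE],
             cache$anat$cache, model$config)
  as.list(grads)
}
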