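## Minimal CPU neural-network engine.
##
## Activations live as matrices of shape (H*W*N) x C: rows iterate h
## fastest, then w, then sample n; columns are channels. 3x3
## same-padding convolutions and the fused batch-norm + ReLU run in
## compiled code (src/conv.cpp); everything else is plain matrix
## algebra. Every layer has an explicit backward pass; gradients are
## accumulated into an environment keyed by parameter name.

`%||%` <- function(a, b) if (is.null(a)) b else a

## broadcast a length-C vector across M rows without sweep()'s aperm
row_bc <- function(v, M) matrix(v, M, length(v), byrow = TRUE)

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

init_conv <- function(params, name, cin, cout) {
  params[[paste0(name, ".W")]] <- he_init(9L * cin, cout, 9L * cin)
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

init_dense <- function(params, name, fin, fout) {
  params[[paste0(name, ".W")]] <- he_init(fin, fout, fin)
  params[[paste0(name, ".b")]] <- numeric(fout)
  params
}

init_bn <- function(params, name, c) {
  params[[paste0(name, ".gamma")]] <- rep(1, c)
  params[[paste0(name, ".beta")]] <- rep(0, c)
  params
}

conv_fwd <- function(params, name, X, dims) {
  res <- cpp_conv_fwd(X, params[[paste0(name, ".W")]],
                      params[[paste0(name, ".b")]],
                      dims$H, dims$W, dims$N)
  list(out = res$Y, cache = list(Xcol = res$Xcol, dims = dims))
}

conv_bwd <- function(params, grads, name, dY, cache, need_dx = TRUE) {
  res <- cpp_conv_bwd(cache$Xcol, params[[paste0(name, ".W")]], dY,
                      cache$dims$H, cache$dims$W, cache$dims$N, need_dx)
  nm_w <- paste0(name, ".W"); nm_b <- paste0(name, ".b")
  grads[[nm_w]] <- (grads[[nm_w]] %||% 0) + res$dW
  grads[[nm_b]] <- (grads[[nm_b]] %||% 0) + as.numeric(res$db)
  res$dX
}

## fused batch norm + ReLU (every conv-side batch norm feeds a ReLU).
## `training` may be TRUE (batch statistics, running buffers updated),
## "batch" (batch statistics without touching the buffers; transductive
## inference over one patient's samples) or FALSE (running statistics).
bnrelu_fwd <- function(params, buffers, name, X, training, momentum = 0.7,
                       eps = 1e-5) {
  g <- params[[paste0(name, ".gamma")]]
  b <- params[[paste0(name, ".beta")]]
  if (isTRUE(training) || identical(training, "batch")) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    if (isTRUE(training)) {
      rn <- paste0(name, ".rmean"); rv <- paste0(name, ".rvar")
      if (is.null(buffers[[rn]])) {
        buffers[[rn]] <- mu; buffers[[rv]] <- v
      } else {
        buffers[[rn]] <- momentum * buffers[[rn]] + (1 - momentum) * mu
        buffers[[rv]] <- momentum * buffers[[rv]] + (1 - momentum) * v
      }
    }
  } else {
    mu <- buffers[[paste0(name, ".rmean")]] %||% numeric(ncol(X))
    v <- buffers[[paste0(name, ".rvar")]] %||% rep(1, ncol(X))
  }
  invstd <- 1 / sqrt(v + eps)
  res <- cpp_bnrelu_fwd(X, g, b, mu, invstd)
  list(out = res$Y, cache = list(xhat = res$xhat, invstd = invstd, g = g,
                                 out = res$Y, training = isTRUE(training)))
}

bnrelu_bwd <- function(params, grads, name, dY, cache) {
  dY <- dY * (cache$out > 0)
  nm_g <- paste0(name, ".gamma"); nm_b <- paste0(name, ".beta")
  grads[[nm_g]] <- (grads[[nm_g]] %||% 0) + colSums(dY * cache$xhat)
  grads[[nm_b]] <- (grads[[nm_b]] %||% 0) + colSums(dY)
  M <- nrow(dY)
  dxhat <- dY * row_bc(cache$g, M)
  if (!cache$training)
    return(dxhat * row_bc(cache$invstd, M))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- dxhat - row_bc(s1 / M, M) - cache$xhat * row_bc(s2 / M, M)
  dX * row_bc(cache$invstd, M)
}

relu_fwd <- function(X) {
  Y <- X; Y[Y < 0] <- 0
  list(out = Y, cache = X > 0)
}

relu_bwd <- function(dY, cache) dY * cache

dropout_fwd <- function(X, rate, training) {
  if (!isTRUE(training) || rate <= 0) return(list(out = X, cache = NULL))
  keep <- matrix(stats::runif(length(X)) >= rate, nrow(X), ncol(X))
  list(out = X * keep / (1 - rate), cache = list(keep = keep, rate = rate))
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache)) return(dY)
  dY * cache$keep / (1 - cache$rate)
}

gap_fwd <- function(X, dims) {
  g <- rep(seq_len(dims$N), each = dims$H * dims$W)
  list(out = rowsum(X, g) / (dims$H * dims$W), cache = list(g = g,
       hw = dims$H * dims$W))
}

gap_bwd <- function(dY, cache) dY[cache$g, , drop = FALSE] / cache$hw

dense_fwd <- function(params, name, X) {
  W <- params[[paste0(name, ".W")]]
  Y <- X %*% W
  Y <- Y + row_bc(params[[paste0(name, ".b")]], nrow(Y))
  list(out = Y, cache = list(X = X))
}

dense_bwd <- function(params, grads, name, dY, cache) {
  nm_w <- paste0(name, ".W"); nm_b <- paste0(name, ".b")
  grads[[nm_w]] <- (grads[[nm_w]] %||% 0) + crossprod(cache$X, dY)
  grads[[nm_b]] <- (grads[[nm_b]] %||% 0) + colSums(dY)
  dY %*% t(params[[nm_w]])
}

softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

## categorical cross-entropy with integrated softmax gradient; optional
## per-sample weights (e.g. inverse class frequency)
softmax_ce <- function(Z, onehot, weights = NULL) {
  P <- softmax(Z)
  ll <- rowSums(onehot * log(pmax(P, 1e-12)))
  if (is.null(weights)) {
    loss <- -mean(ll)
    dZ <- (P - onehot) / nrow(Z)
  } else {
    w <- weights / sum(weights)
    loss <- -sum(w * ll)
    dZ <- (P - onehot) * w
  }
  list(loss = loss, prob = P, dZ = dZ)
}

adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, head_lr_mult = 1) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    lr_nm <- if (head_lr_mult != 1 && startsWith(nm, "head."))
      lr * head_lr_mult else lr
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr_nm * mhat / (sqrt(vhat) + eps)
  }
  params
}
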