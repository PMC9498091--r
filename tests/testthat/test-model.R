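test_that("the study-scale network has ~1.8 million parameters", {
  m <- build_model(model_config())
  expect_gt(m$n_parameters, 1.8e6 * 0.9)
  expect_lt(m$n_parameters, 1.8e6 * 1.1)
  # deterministic across seeds: the count depends only on topology
  m2 <- build_model(model_config(seed = 2026))
  expect_identical(m$n_parameters, m2$n_parameters)
  expect_identical(m$breakdown, m2$breakdown)
})

test_that("doubling conv widths roughly quadruples conv parameters", {
  base <- build_model(model_config(extractor_channels = 4,
                                   widths = c(8, 16, 32),
                                   dense = c(16, 8, 2)))
  dbl <- build_model(model_config(extractor_channels = 8,
                                  widths = c(16, 32, 64),
                                  dense = c(16, 8, 2)))
  ratio <- dbl$breakdown["conv"] / base$breakdown["conv"]
  expect_gt(ratio, 3.4)
  expect_lt(ratio, 4.2)
})

test_that("invalid configurations are rejected", {
  expect_error(model_config(widths = c(96, 48, 192)), "increasing")
  expect_error(model_config(dense = c(96, 48, 3)), "width 2")
  expect_error(model_config(triples_per_patch = 0), "triples")
})

test_that("softmax outputs are probabilities for random inputs", {
  cfg <- model_config(extractor_channels = 2, widths = c(3, 4, 5),
                      dense = c(8, 4, 2), seed = 3)
  m <- build_model(cfg)
  set.seed(8)
  N <- 4L
  sl <- function() matrix(rnorm(32 * 32 * N), ncol = 1)
  batch <- list(pet = list(ax = sl(), cor = sl(), sag = sl()),
                anat = list(ax = sl(), cor = sl(), sag = sl()),
                anthro = matrix(rnorm(3 * N), N, 3),
                dims = list(H = 32L, W = 32L, N = N))
  out <- cnn_forward(m, batch, training = FALSE)
  expect_equal(dim(out$prob), c(N, 2L))
  expect_equal(unname(rowSums(out$prob)), rep(1, N), tolerance = 1e-6)
  expect_true(all(out$prob >= 0))
})

test_that("analytic gradients agree with finite differences", {
  cfg <- model_config(extractor_channels = 2, widths = c(3, 4, 5),
                      dense = c(6, 4, 2), dropout = 0,
                      class_balance = FALSE, seed = 42)
  m <- build_model(cfg)
  set.seed(7)
  N <- 3L; H <- W <- 6L
  sl <- function() matrix(rnorm(H * W * N), ncol = 1)
  batch <- list(pet = list(ax = sl(), cor = sl(), sag = sl()),
                anat = list(ax = sl(), cor = sl(), sag = sl()),
                anthro = matrix(rnorm(3 * N), N, 3),
                dims = list(H = H, W = W, N = N))
  onehot <- diag(2)[c(1, 2, 1), ]
  loss_fn <- function(mm) {
    out <- cnn_forward(mm, batch, training = TRUE)
    melrisk:::softmax_ce(out$logits, onehot)$loss
  }
  out <- cnn_forward(m, batch, training = TRUE)
  sm <- melrisk:::softmax_ce(out$logits, onehot)
  grads <- melrisk:::cnn_backward(m, out$cache, sm$dZ)
  set.seed(99)
  for (nm in sample(names(m$params), 12)) {
    p <- m$params[[nm]]
    i <- sample(length(p), 1)
    eps <- 1e-5
    mp <- m; mp$buffers <- new.env(); mp$params[[nm]][i] <- p[i] + eps
    mn <- m; mn$buffers <- new.env(); mn$params[[nm]][i] <- p[i] - eps
    num <- (loss_fn(mp) - loss_fn(mn)) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
  }
})
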