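test_that("forward shape propagation reproduces the published activation sizes", {
  shapes <- model_shapes(input_size = 224L)
  expect_equal(
    shapes$activation,
    c("224x224x3", "112x112x64", "56x56x64", "56x56x64", "56x56x64",
      "28x28x128", "28x28x128", "28x28x256", "1x1x256", "2")
  )
  # and the actual tensors agree with the table, not just the arithmetic
  set.seed(1)
  m <- build_model()
  x <- array(runif(224 * 224 * 3), c(224, 224, 3, 1))
  fw <- mlgleason:::cnn_forward(m, x, cache = TRUE)
  expect_equal(dim(fw$cache$b1$y), c(112L, 112L, 64L, 1L))
  expect_equal(dim(fw$cache$o2), c(56L, 56L, 64L, 1L))
  expect_equal(dim(fw$cache$o3), c(28L, 28L, 128L, 1L))
  expect_equal(dim(fw$cache$o4), c(28L, 28L, 256L, 1L))
  expect_equal(dim(fw$cache$g), c(256L, 1L))
  expect_equal(dim(fw$logits), c(2L, 1L))
})

test_that("pretrained init without a cached weight file errors with fallback advice", {
  expect_error(build_model(init = "pretrained"), "random")
})

test_that("weighted cross-entropy matches closed forms", {
  set.seed(2)
  logits <- matrix(rnorm(8), 2, 4)
  y <- c(1L, 2L, 2L, 1L)
  # uniform weights reduce to the plain mean cross-entropy
  p <- apply(logits, 2, function(z) exp(z - max(z)) / sum(exp(z - max(z))))
  plain <- mean(-log(p[cbind(y, 1:4)]))
  expect_equal(weighted_cross_entropy(logits, y, c(1, 1)), plain)
  # confidently correct logits give near-zero loss
  expect_lt(weighted_cross_entropy(matrix(c(20, 0), 2, 1), 1L, c(1, 1)), 1e-8)
  # two-sample batch with weights (2, 1): hand-computed weighted mean
  l2 <- matrix(c(1, 0, 0.2, 0.9), 2, 2)
  y2 <- c(1L, 2L)
  w <- c(2, 1)
  p2 <- apply(l2, 2, function(z) exp(z) / sum(exp(z)))
  hand <- (2 * -log(p2[1, 1]) + 1 * -log(p2[2, 2])) / 3
  expect_equal(weighted_cross_entropy(l2, y2, w), hand)
  expect_error(weighted_cross_entropy(matrix(c(NaN, 1), 2, 1), 1L, c(1, 1)), "finite")
})

test_that("inverse-frequency class weights follow n/(2*n_c)", {
  expect_equal(default_class_weights(c(1, 1, 2, 2)), c(1, 1))
  expect_equal(default_class_weights(rep(c(1, 2), c(90, 10))), c(100 / 180, 100 / 20))
  expect_error(default_class_weights(rep(1, 5)), "both classes")
})

test_that("learning-rate schedule: 0.1 drops every 15 epochs, 10x head", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 1), 1e-3)
  expect_equal(lr_at_epoch(cfg, 15), 1e-3)
  expect_equal(lr_at_epoch(cfg, 16), 1e-4)
  expect_equal(lr_at_epoch(cfg, 31), 1e-5)
  expect_equal(lr_at_epoch(cfg, 1, "head"), 1e-2)
  expect_equal(lr_at_epoch(cfg, 16, "head"), 1e-3)
})

test_that("early stopping fires after patience consecutive rises and never earlier", {
  # strictly rising from epoch 2: 8 rises complete at epoch 9
  expect_equal(early_stop_epoch(1:20, patience = 8), 9L)
  expect_equal(early_stop_epoch(c(3, 2, 1, 2, 3, 4), patience = 3), 6L)
  expect_true(is.na(early_stop_epoch(rep(1, 30), patience = 8))) # flat never triggers
  set.seed(12)
  for (i in 1:50) {
    trace <- cumsum(rnorm(30))
    e <- early_stop_epoch(trace, patience = 5)
    if (!is.na(e)) {
      expect_gte(e, 6) # patience + 1
      expect_true(all(diff(trace[(e - 5):e]) > 0))
    }
  }
})

test_that("network gradients match central finite differences", {
  set.seed(42)
  m <- build_model()
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- c(1L, 2L)
  w <- c(1.3, 0.7)
  loss_fn <- function(model) {
    fw <- mlgleason:::cnn_forward(model, x, training = TRUE)
    weighted_cross_entropy(fw$logits, y, w)
  }
  fw <- mlgleason:::cnn_forward(m, x, training = TRUE, cache = TRUE)
  ce <- weighted_cross_entropy(fw$logits, y, w, gradient = TRUE)
  gr <- mlgleason:::cnn_backward(m, fw$cache, ce$dlogits)
  fp <- mlgleason:::flatten_model_params(m)
  set.seed(7)
  h <- 1e-4
  for (nm in sample(names(gr), 10)) {
    for (i in sample(length(fp[[nm]]), min(2L, length(fp[[nm]])))) {
      fpp <- fp; fpp[[nm]][i] <- fpp[[nm]][i] + h
      fpm <- fp; fpm[[nm]][i] <- fpm[[nm]][i] - h
      fd <- (loss_fn(mlgleason:::unflatten_model_params(m, fpp)) -
               loss_fn(mlgleason:::unflatten_model_params(m, fpm))) / (2 * h)
      an <- gr[[nm]][i]
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), 1e-4)
    }
  }
})

test_that("one optimizer step with uniform weights and no L2 is a plain Adam/CE step", {
  set.seed(5)
  params <- list(fc_w = matrix(rnorm(6), 2, 3), fc_b = rnorm(2))
  grads <- list(fc_w = matrix(rnorm(6), 2, 3), fc_b = rnorm(2))
  st <- mlgleason:::adam_init(params)
  out <- mlgleason:::adam_step(params, grads, st, function(p) 1e-3, l2 = 0)
  # textbook Adam with bias correction at t = 1
  for (nm in names(params)) {
    mhat <- (0.1 * grads[[nm]]) / (1 - 0.9)
    vhat <- (0.001 * grads[[nm]]^2) / (1 - 0.999)
    expect_equal(out$params[[nm]], params[[nm]] - 1e-3 * mhat / (sqrt(vhat) + 1e-8))
  }
  # with L2, conv/fc weight gradients gain l2 * w, biases do not
  out2 <- mlgleason:::adam_step(params, grads, mlgleason:::adam_init(params),
                                function(p) 1e-3, l2 = 0.5)
  g2 <- grads$fc_w + 0.5 * params$fc_w
  mhat <- (0.1 * g2) / (1 - 0.9)
  vhat <- (0.001 * g2^2) / (1 - 0.999)
  expect_equal(out2$params$fc_w, params$fc_w - 1e-3 * mhat / (sqrt(vhat) + 1e-8))
  expect_equal(out2$params$fc_b, out$params$fc_b)
})

test_that("training is deterministic given the seed and records a consistent history", {
  d <- toy_binary_data(24, size = 16L, seed = 31)
  v <- toy_binary_data(8, size = 16L, seed = 32)
  cfg <- train_config(max_epochs = 2L, batch_size = 8L, input_size = 16L,
                      augment = TRUE, seed = 77L)
  f1 <- train_binary_cnn(d$x, d$y, v$x, v$y, cfg)
  f2 <- train_binary_cnn(d$x, d$y, v$x, v$y, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params$fc_w, f2$model$params$fc_w)
  expect_equal(nrow(f1$history), 2L)
  expect_equal(f1$stop_reason, "max_epochs")
  expect_error(train_binary_cnn(d$x, rep(1L, 24), v$x, v$y, cfg), "positive")
})

test_that("a short run separates the two-colour toy problem", {
  d <- toy_binary_data(48, size = 16L, seed = 41)
  v <- toy_binary_data(24, size = 16L, seed = 42)
  cfg <- train_config(max_epochs = 5L, batch_size = 8L, input_size = 16L,
                      augment = FALSE, seed = 9L)
  fit <- train_binary_cnn(d$x, d$y, v$x, v$y, cfg)
  best <- fit$history$val_f1[which.min(fit$history$val_loss)]
  expect_gte(max(fit$history$val_f1), 0.9)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$epochs, fit$stop_epoch)
})
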