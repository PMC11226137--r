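#' Architecture of the truncated-ResNet18 binary classifier
#'
#' The one-vs-all sub-classifier is a ResNet18 cut down to fight overfitting
#' on small histopathology datasets: the entire `conv5` stage and the second
#' half of the `conv4` stage are removed, so global average pooling is
#' connected directly to the output of the first `conv4` block's ReLU. The
#' layer stack is:
#'
#' * Conv1 7x7, 64, stride 2 + BN + ReLU + 2x2 max-pool
#' * residual block 2: Conv2a/Conv2b 3x3, 64, stride 1 (identity skip)
#' * residual block 3: Conv3a (stride 2)/Conv3b 3x3, 128 (1x1 projection skip)
#' * truncated block 4: Conv4a 3x3, 256, stride 1 with its 1x1 projection
#'   skip, through the block ReLU
#' * global average pooling (256 features), fully connected to 2 logits,
#'   softmax
#'
#' The network is fully convolutional up to the pooling, so any input side
#' >= 16 works; 224 reproduces the published activation sizes.
#'
#' @return An `architecture_spec` list describing the layer stack.
#' @export
architecture_spec <- function() {
  structure(
    list(
      conv1 = list(k = 7L, out = 64L, stride = 2L, pad = 3L),
      conv2 = list(k = 3L, out = 64L, stride = 1L),
      conv3 = list(k = 3L, out = 128L, stride = 2L),
      conv4 = list(k = 3L, out = 256L, stride = 1L),
      n_classes = 2L
    ),
    class = "architecture_spec"
  )
}

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))), c(kh, kw, cin, cout))
}

new_bn <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c), state = list(mean = rep(0, c), var = rep(1, c)))
}

#' Build a binary grading CNN
#'
#' Instantiates the [architecture_spec()] network. `init = "random"` uses He
#' initialization for convolutions and a small random head.
#' `init = "pretrained"` copies backbone weights from a cached weight file
#' (an RDS holding a named list of conv weight arrays and BN parameters in
#' this package's layout); without such a file it errors and instructs the
#' fallback, since ImageNet weights cannot be fetched at build time.
#'
#' @param spec An [architecture_spec()].
#' @param init `"random"` or `"pretrained"`.
#' @param pretrained_path RDS file with backbone weights (for
#'   `init = "pretrained"`).
#' @return A `gleason_cnn` model object.
#' @export
build_model <- function(spec = architecture_spec(), init = c("random", "pretrained"),
                        pretrained_path = NULL) {
  init <- match.arg(init)
  p <- list()
  p$conv1_w <- he_init(7, 7, 3, 64)
  p$conv2a_w <- he_init(3, 3, 64, 64)
  p$conv2b_w <- he_init(3, 3, 64, 64)
  p$conv3a_w <- he_init(3, 3, 64, 128)
  p$conv3b_w <- he_init(3, 3, 128, 128)
  p$proj3_w <- he_init(1, 1, 64, 128)
  p$conv4a_w <- he_init(3, 3, 128, 256)
  p$proj4_w <- he_init(1, 1, 128, 256)
  p$fc_w <- matrix(rnorm(2 * 256, sd = sqrt(1 / 256)), 2, 256)
  p$fc_b <- rep(0, 2)
  bn <- list(
    bn1 = new_bn(64), bn2a = new_bn(64), bn2b = new_bn(64),
    bn3a = new_bn(128), bn3b = new_bn(128), bnp3 = new_bn(128),
    bn4a = new_bn(256), bnp4 = new_bn(256)
  )
  model <- structure(list(spec = spec, params = p, bn = bn), class = "gleason_cnn")
  if (init == "pretrained") {
    if (is.null(pretrained_path) || !file.exists(pretrained_path %||% "")) {
      abort(paste0(
        "pretrained backbone weights are not available (no cached weight file ",
        "was supplied); pass pretrained_path = <rds of backbone weights>, or ",
        "use init = \"random\""
      ))
    }
    w <- readRDS(pretrained_path)
    for (nm in intersect(names(w), names(p))) model$params[[nm]] <- w[[nm]]
    if (!is.null(w$bn)) {
      for (nm in intersect(names(w$bn), names(bn))) model$bn[[nm]] <- w$bn[[nm]]
    }
  }
  model
}

#' @export
print.gleason_cnn <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L)) +
    sum(vapply(x$bn, function(b) length(b$gamma) * 2L, 0L))
  cat("<gleason_cnn> truncated ResNet18 binary classifier,",
      format(np, big.mark = ","), "parameters\n")
  invisible(x)
}

# Forward pass. Returns logits (2 x N); with cache = TRUE also every
# intermediate needed for backprop and Grad-CAM. Training mode uses batch
# BN statistics and updates the running ones (returned via $model).
cnn_forward <- function(model, x, training = FALSE, cache = FALSE) {
  p <- model$params
  bn <- model$bn
  run_bn <- function(name, z) {
    r <- bn_forward(z, bn[[name]]$gamma, bn[[name]]$beta, bn[[name]]$state, training)
    bn[[name]]$state <<- r$state
    r
  }
  c1 <- conv_forward(x, p$conv1_w, 2, 3)
  b1 <- run_bn("bn1", c1)
  r1 <- relu_forward(b1$y)
  pool <- maxpool_forward(r1)
  # block 2 (identity skip)
  c2a <- conv_forward(pool$y, p$conv2a_w, 1, 1)
  b2a <- run_bn("bn2a", c2a)
  r2a <- relu_forward(b2a$y)
  c2b <- conv_forward(r2a, p$conv2b_w, 1, 1)
  b2b <- run_bn("bn2b", c2b)
  o2 <- relu_forward(pool$y + b2b$y)
  # block 3 (stride-2 transition, projection skip)
  c3a <- conv_forward(o2, p$conv3a_w, 2, 1)
  b3a <- run_bn("bn3a", c3a)
  r3a <- relu_forward(b3a$y)
  c3b <- conv_forward(r3a, p$conv3b_w, 1, 1)
  b3b <- run_bn("bn3b", c3b)
  s3 <- conv_forward(o2, p$proj3_w, 2, 0)
  bp3 <- run_bn("bnp3", s3)
  o3 <- relu_forward(bp3$y + b3b$y)
  # truncated block 4: single conv through the block ReLU
  c4a <- conv_forward(o3, p$conv4a_w, 1, 1)
  b4a <- run_bn("bn4a", c4a)
  s4 <- conv_forward(o3, p$proj4_w, 1, 0)
  bp4 <- run_bn("bnp4", s4)
  o4 <- relu_forward(bp4$y + b4a$y)
  g <- gap_forward(o4)
  logits <- fc_forward(g, p$fc_w, p$fc_b)
  model$bn <- bn
  out <- list(logits = logits, model = model)
  if (cache) {
    out$cache <- list(
      x = x, b1 = b1, r1 = r1, pool = pool,
      c2a_in = pool$y, b2a = b2a, r2a = r2a, b2b = b2b, o2 = o2,
      b3a = b3a, r3a = r3a, b3b = b3b, bp3 = bp3, o3 = o3,
      b4a = b4a, bp4 = bp4, o4 = o4, g = g
    )
  }
  out
}

# Manual backprop mirroring cnn_forward. Returns gradients named like params.
cnn_backward <- function(model, cache, dlogits) {
  p <- model$params
  gr <- list()
  fcb <- fc_backward(dlogits, cache$g, p$fc_w)
  gr$fc_w <- fcb$dw; gr$fc_b <- fcb$db
  do4 <- gap_backward(fcb$dx, dim(cache$o4))
  do4 <- relu_backward(do4, cache$o4)
  # block 4
  b4 <- bn_backward(do4, cache$b4a$cache)
  gr$bn4a_g <- b4$dgamma; gr$bn4a_b <- b4$dbeta
  cb4 <- conv_backward(cache$o3, p$conv4a_w, b4$dx, 1, 1)
  gr$conv4a_w <- cb4$dw
  bp4 <- bn_backward(do4, cache$bp4$cache)
  gr$bnp4_g <- bp4$dgamma; gr$bnp4_b <- bp4$dbeta
  sp4 <- conv_backward(cache$o3, p$proj4_w, bp4$dx, 1, 0)
  gr$proj4_w <- sp4$dw
  do3 <- cb4$dx + sp4$dx
  do3 <- relu_backward(do3, cache$o3)
  # block 3
  b3b <- bn_backward(do3, cache$b3b$cache)
  gr$bn3b_g <- b3b$dgamma; gr$bn3b_b <- b3b$dbeta
  cb3b <- conv_backward(cache$r3a, p$conv3b_w, b3b$dx, 1, 1)
  gr$conv3b_w <- cb3b$dw
  dr3a <- relu_backward(cb3b$dx, cache$r3a)
  b3a <- bn_backward(dr3a, cache$b3a$cache)
  gr$bn3a_g <- b3a$dgamma; gr$bn3a_b <- b3a$dbeta
  cb3a <- conv_backward(cache$o2, p$conv3a_w, b3a$dx, 2, 1)
  gr$conv3a_w <- cb3a$dw
  bp3 <- bn_backward(do3, cache$bp3$cache)
  gr$bnp3_g <- bp3$dgamma; gr$bnp3_b <- bp3$dbeta
  sp3 <- conv_backward(cache$o2, p$proj3_w, bp3$dx, 2, 0)
  gr$proj3_w <- sp3$dw
  do2 <- cb3a$dx + sp3$dx
  do2 <- relu_backward(do2, cache$o2)
  # block 2
  b2b <- bn_backward(do2, cache$b2b$cache)
  gr$bn2b_g <- b2b$dgamma; gr$bn2b_b <- b2b$dbeta
  cb2b <- conv_backward(cache$r2a, p$conv2b_w, b2b$dx, 1, 1)
  gr$conv2b_w <- cb2b$dw
  dr2a <- relu_backward(cb2b$dx, cache$r2a)
  b2a <- bn_backward(dr2a, cache$b2a$cache)
  gr$bn2a_g <- b2a$dgamma; gr$bn2a_b <- b2a$dbeta
  cb2a <- conv_backward(cache$c2a_in, p$conv2a_w, b2a$dx, 1, 1)
  gr$conv2a_w <- cb2a$dw
  dpool <- do2 + cb2a$dx
  dr1 <- maxpool_backward(dpool, cache$pool, dim(cache$r1))
  dr1 <- relu_backward(dr1, cache$r1)
  b1 <- bn_backward(dr1, cache$b1$cache)
  gr$bn1_g <- b1$dgamma; gr$bn1_b <- b1$dbeta
  cb1 <- conv_backward(cache$x, p$conv1_w, b1$dx, 2, 3)
  gr$conv1_w <- cb1$dw
  gr
}

#' Activation shapes of the network
#'
#' Propagates an input of the given side through the layer stack and reports
#' every activation size, matching the published table row for row (for a
#' 224-pixel input: 112x112x64 after Conv1, 56x56x64 through block 2,
#' 28x28x128 through block 3, 1x1x256 after global average pooling, and 2
#' output logits).
#'
#' @param spec An [architecture_spec()].
#' @param input_size Input side in pixels (default 224).
#' @return Tibble with columns `layer` and `activation` (e.g. `"112x112x64"`).
#' @export
model_shapes <- function(spec = architecture_spec(), input_size = 224L) {
  s <- as.integer(input_size)
  conv_out <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L
  a1 <- conv_out(s, 7L, 2L, 3L)
  ap <- a1 %/% 2L
  a3 <- conv_out(ap, 3L, 2L, 1L)
  fmt <- function(n, c) sprintf("%dx%dx%d", n, n, c)
  tibble::tibble(
    layer = c("input", "conv1", "maxpool", "conv2a", "conv2b", "conv3a",
              "conv3b", "conv4a", "gap", "fc"),
    activation = c(
      fmt(s, 3L), fmt(a1, 64L), fmt(ap, 64L), fmt(ap, 64L), fmt(ap, 64L),
      fmt(a3, 128L), fmt(a3, 128L), fmt(a3, 256L), "1x1x256", "2"
    )
  )
}

# run the network in inference mode on an (H,W,3,N) batch, in minibatches,
# returning positive-class softmax scores; a plain function stands in for a
# model (useful for oracles in tests and score-mode slide maps)
model_scores <- function(model, x, batch_size = 32L) {
  if (is.function(model)) return(model(x))
  n <- dim(x)[4]
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    logits <- cnn_forward(model, x[, , , ix, drop = FALSE], training = FALSE)$logits
    out[ix] <- softmax_cols(logits)[2L, ]
  }
  out
}
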