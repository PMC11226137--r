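# Layer primitives over the compiled kernels. Activations are (H, W, C, N)
# numeric arrays; every forward returns what its backward needs.

conv_forward <- function(x, w, stride, pad) {
  cpp_conv2d_forward(x, w, as.integer(stride), as.integer(pad))
}

conv_backward <- function(x, w, dy, stride, pad) {
  cpp_conv2d_backward(x, w, dy, as.integer(stride), as.integer(pad))
}

relu_forward <- function(x) {
  y <- pmax(x, 0)
  dim(y) <- dim(x)
  y
}

relu_backward <- function(dy, y) dy * (y > 0)

maxpool_forward <- function(x) cpp_maxpool2_forward(x)

maxpool_backward <- function(dy, pool, xdim) cpp_maxpool2_backward(dy, pool$idx, as.integer(xdim))

# per-channel batch normalization over (H, W, N); biased variance
bn_forward <- function(x, gamma, beta, state, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (training) {
    xm <- matrix(x, nrow = hw)
    mu_cn <- colMeans(xm); dim(mu_cn) <- c(C, N)
    mu <- rowMeans(mu_cn)
    m2_cn <- colMeans(xm^2); dim(m2_cn) <- c(C, N)
    v <- rowMeans(m2_cn) - mu^2
    v <- pmax(v, 0)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- (x - rep(mu, each = hw)) * rep(inv_sd, each = hw)
  y <- xhat * rep(gamma, each = hw) + rep(beta, each = hw)
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma, hw = hw, C = C, N = N),
       state = state)
}

bn_backward <- function(dy, cache) {
  hw <- cache$hw; C <- cache$C; N <- cache$N
  m <- hw * N
  xhat <- cache$xhat
  ch_sum <- function(a) {
    s_cn <- colSums(matrix(a, nrow = hw)); dim(s_cn) <- c(C, N)
    rowSums(s_cn)
  }
  dgamma <- ch_sum(dy * xhat)
  dbeta <- ch_sum(dy)
  dxhat <- dy * rep(cache$gamma, each = hw)
  s1 <- ch_sum(dxhat)
  s2 <- ch_sum(dxhat * xhat)
  dx <- (dxhat - rep(s1 / m, each = hw) - xhat * rep(s2 / m, each = hw)) *
    rep(cache$inv_sd, each = hw)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

gap_forward <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  y <- colMeans(matrix(x, nrow = hw))
  dim(y) <- c(d[3], d[4])
  y
}

gap_backward <- function(dy, xdim) {
  hw <- xdim[1] * xdim[2]
  dx <- rep(as.vector(dy) / hw, each = hw)
  dim(dx) <- xdim
  dx
}

fc_forward <- function(x, w, b) w %*% x + b

fc_backward <- function(dy, x, w) {
  list(dx = t(w) %*% dy, dw = dy %*% t(x), db = rowSums(dy))
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}
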