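# Minimal CPU neural-network core: tensors are (H, W, C) arrays, parameters
# are flat named lists of arrays, and every layer provides an explicit
# forward (returning output + cache) and backward (returning input gradient
# + parameter gradients). Convolutions run as im2col + BLAS matrix products.

## ---- convolution -----------------------------------------------------

conv_init <- function(k, c_in, c_out, gain = sqrt(2)) {
  w <- matrix(stats::rnorm(k * k * c_in * c_out, 0,
                           gain / sqrt(k * k * c_in)),
              k * k * c_in, c_out)
  attr(w, "k") <- k
  attr(w, "c_in") <- c_in
  list(w = w, b = numeric(c_out))
}

im2col <- function(x, k, pad) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  P <- array(0, c(H + 2L * pad, W + 2L * pad, C))
  P[pad + seq_len(H), pad + seq_len(W), ] <- x
  Xc <- matrix(0, H * W, k * k * C)
  o <- 0L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    block <- P[di + seq_len(H), dj + seq_len(W), , drop = FALSE]
    Xc[, o * C + seq_len(C)] <- matrix(block, H * W, C)
    o <- o + 1L
  }
  Xc
}

conv_forward <- function(x, par, pad = NULL) {
  k <- attr(par$w, "k")
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  d <- dim(x)
  Xc <- im2col(x, k, pad)
  y <- Xc %*% par$w
  y <- sweep(y, 2L, par$b, `+`)
  list(y = array(y, c(d[1L], d[2L], ncol(par$w))),
       cache = list(Xc = Xc, dim_in = d, k = k, pad = pad))
}

conv_backward <- function(dy, par, cache) {
  d <- cache$dim_in
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  k <- cache$k; pad <- cache$pad
  dym <- matrix(dy, H * W, ncol(par$w))
  dw <- crossprod(cache$Xc, dym)
  attr(dw, "k") <- k
  attr(dw, "c_in") <- C
  db <- colSums(dym)
  dXc <- dym %*% t(par$w)
  dP <- array(0, c(H + 2L * pad, W + 2L * pad, C))
  o <- 0L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    dP[di + seq_len(H), dj + seq_len(W), ] <-
      dP[di + seq_len(H), dj + seq_len(W), , drop = FALSE] +
      array(dXc[, o * C + seq_len(C)], c(H, W, C))
    o <- o + 1L
  }
  list(dx = dP[pad + seq_len(H), pad + seq_len(W), , drop = FALSE],
       dpar = list(w = dw, b = db))
}

## ---- pooling / upsampling --------------------------------------------

maxpool2_forward <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1L], 2L); re <- ro + 1L
  co <- seq(1L, d[2L], 2L); ce <- co + 1L
  a <- list(x[ro, co, , drop = FALSE], x[re, co, , drop = FALSE],
            x[ro, ce, , drop = FALSE], x[re, ce, , drop = FALSE])
  m <- pmax(a[[1L]], a[[2L]], a[[3L]], a[[4L]])
  ## deterministic tie-break: first view in fixed scan order wins
  m1 <- a[[1L]] == m
  m2 <- (a[[2L]] == m) & !m1
  m3 <- (a[[3L]] == m) & !m1 & !m2
  m4 <- !(m1 | m2 | m3)
  list(y = m, cache = list(masks = list(m1, m2, m3, m4), dim_in = d))
}

maxpool2_backward <- function(dy, cache) {
  d <- cache$dim_in
  dx <- array(0, d)
  ro <- seq(1L, d[1L], 2L); re <- ro + 1L
  co <- seq(1L, d[2L], 2L); ce <- co + 1L
  ms <- cache$masks
  dx[ro, co, ] <- dy * ms[[1L]]
  dx[re, co, ] <- dy * ms[[2L]]
  dx[ro, ce, ] <- dy * ms[[3L]]
  dx[re, ce, ] <- dy * ms[[4L]]
  dx
}

upsample2_forward <- function(x) {
  d <- dim(x)
  y <- array(0, c(2L * d[1L], 2L * d[2L], d[3L]))
  ro <- seq(1L, 2L * d[1L], 2L); re <- ro + 1L
  co <- seq(1L, 2L * d[2L], 2L); ce <- co + 1L
  y[ro, co, ] <- x; y[re, co, ] <- x; y[ro, ce, ] <- x; y[re, ce, ] <- x
  list(y = y, cache = d)
}

upsample2_backward <- function(dy, cache) {
  d <- cache
  ro <- seq(1L, 2L * d[1L], 2L); re <- ro + 1L
  co <- seq(1L, 2L * d[2L], 2L); ce <- co + 1L
  dy[ro, co, , drop = FALSE] + dy[re, co, , drop = FALSE] +
    dy[ro, ce, , drop = FALSE] + dy[re, ce, , drop = FALSE]
}

avgpool2_forward <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1L], 2L); re <- ro + 1L
  co <- seq(1L, d[2L], 2L); ce <- co + 1L
  y <- (x[ro, co, , drop = FALSE] + x[re, co, , drop = FALSE] +
        x[ro, ce, , drop = FALSE] + x[re, ce, , drop = FALSE]) / 4
  list(y = y, cache = d)
}

avgpool2_backward <- function(dy, cache) {
  d <- cache
  dx <- array(0, d)
  ro <- seq(1L, d[1L], 2L); re <- ro + 1L
  co <- seq(1L, d[2L], 2L); ce <- co + 1L
  q <- dy / 4
  dx[ro, co, ] <- q; dx[re, co, ] <- q; dx[ro, ce, ] <- q; dx[re, ce, ] <- q
  dx
}

## ---- activations -----------------------------------------------------

relu_forward <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_backward <- function(dy, cache) dy * cache

lrelu_forward <- function(x, slope = 0.2)
  list(y = ifelse(x > 0, x, slope * x), cache = list(pos = x > 0, s = slope))
lrelu_backward <- function(dy, cache)
  dy * ifelse(cache$pos, 1, cache$s)

## trainable linear unit: per-channel learnable slopes on both branches
tlu_init <- function(c_out, neg = 0.25, pos = 1)
  list(sn = rep(neg, c_out), sp = rep(pos, c_out))

tlu_forward <- function(x, par) {
  d <- dim(x)
  sn <- array(rep(par$sn, each = d[1L] * d[2L]), d)
  sp <- array(rep(par$sp, each = d[1L] * d[2L]), d)
  pos <- x >= 0
  list(y = ifelse(pos, sp * x, sn * x),
       cache = list(x = x, pos = pos, sn = sn, sp = sp, dim = d))
}

tlu_backward <- function(dy, cache) {
  d <- cache$dim
  dx <- dy * ifelse(cache$pos, cache$sp, cache$sn)
  px <- dy * cache$x
  per_ch <- function(a) colSums(matrix(a, d[1L] * d[2L], d[3L]))
  list(dx = dx,
       dpar = list(sn = per_ch(px * !cache$pos),
                   sp = per_ch(px * cache$pos)))
}

## ---- dense -----------------------------------------------------------

dense_init <- function(n_in, n_out, gain = sqrt(2)) {
  list(w = matrix(stats::rnorm(n_in * n_out, 0, gain / sqrt(n_in)),
                  n_in, n_out),
       b = numeric(n_out))
}

dense_forward <- function(x, par)
  list(y = drop(x %*% par$w) + par$b, cache = x)

dense_backward <- function(dy, par, cache) {
  list(dx = drop(par$w %*% dy),
       dpar = list(w = outer(cache, dy), b = dy))
}

## ---- softmax over the channel axis -----------------------------------

softmax_channels <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, d[1L] * d[2L], d[3L])
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  array(e / rowSums(e), d)
}

## gradient of logits given gradient on the softmax output
softmax_channels_backward <- function(dp, p) {
  d <- dim(p)
  pm <- matrix(p, d[1L] * d[2L], d[3L])
  dm <- matrix(dp, d[1L] * d[2L], d[3L])
  array(pm * (dm - rowSums(dm * pm)), d)
}

## cross-entropy on integer targets in 0:(K-1); returns loss and dlogits
softmax_ce <- function(logits, target) {
  d <- dim(logits)
  K <- d[3L]
  p <- softmax_channels(logits)
  pm <- matrix(p, d[1L] * d[2L], K)
  idx <- cbind(seq_len(d[1L] * d[2L]), as.integer(target) + 1L)
  eps <- 1e-12
  loss <- -mean(log(pm[idx] + eps))
  onehot <- matrix(0, d[1L] * d[2L], K)
  onehot[idx] <- 1
  dlogits <- array((pm - onehot) / (d[1L] * d[2L]), d)
  list(loss = loss, dlogits = dlogits, p = p)
}

## ---- parameter containers and Adam -----------------------------------

## parameters live in flat named lists whose elements are lists of arrays
## (e.g. params$enc1_conv1$w); these helpers walk that structure.

param_map <- function(params, f) {
  out <- params
  for (nm in names(params)) out[[nm]] <- lapply(params[[nm]], f)
  out
}

param_zero_like <- function(params)
  param_map(params, function(a) {
    z <- a
    z[] <- 0
    z
  })

param_add <- function(a, b) {
  for (nm in names(b)) for (el in names(b[[nm]]))
    a[[nm]][[el]] <- a[[nm]][[el]] + b[[nm]][[el]]
  a
}

adam_init <- function(params)
  list(m = param_zero_like(params), v = param_zero_like(params), t = 0L)

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) for (el in names(grads[[nm]])) {
    g <- grads[[nm]][[el]]
    state$m[[nm]][[el]] <- beta1 * state$m[[nm]][[el]] + (1 - beta1) * g
    state$v[[nm]][[el]] <- beta2 * state$v[[nm]][[el]] + (1 - beta2) * g^2
    params[[nm]][[el]] <- params[[nm]][[el]] -
      lr * (state$m[[nm]][[el]] / bc1) /
        (sqrt(state$v[[nm]][[el]] / bc2) + eps)
  }
  list(params = params, state = state)
}
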