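#' Numerically stabilized softmax
#'
#' Maps activations \eqn{a_n} to class probabilities
#' \eqn{p_n = e^{a_n} / \sum_{n'} e^{a_{n'}}}, subtracting the maximum
#' activation before exponentiation so the result is invariant to adding a
#' constant and never overflows. Accepts a vector (one activation per
#' class) or an (H, W, K) array (softmax over the last axis).
#'
#' @param a numeric vector or 3D array of activations; must be finite.
#' @return probabilities of the same shape, summing to 1 over classes.
#' @examples
#' softmax(c(0, 0, 0, 0))        # uniform 0.25
#' softmax(c(log(2), 0, 0, 0))   # 0.4 0.2 0.2 0.2
#' @export
softmax <- function(a) {
  if (any(is.na(a)) || any(!is.finite(a)))
    stop("softmax requires finite activations")
  if (is.array(a) && length(dim(a)) == 3L) return(softmax_channels(a))
  e <- exp(a - max(a))
  e / sum(e)
}

#' Trainable linear unit (two-slope piecewise-linear activation)
#'
#' \eqn{f(x) = s_+ x} for \eqn{x \ge 0} and \eqn{s_- x} otherwise. The
#' slopes are the learnable parameters inside the network bottleneck; this
#' standalone form evaluates the activation at fixed slopes. With
#' `slopes = c(0, 1)` it is the rectifier; with `slopes = c(1, 1)` the
#' identity.
#'
#' @param x numeric input (any shape).
#' @param slopes numeric length 2: (negative-branch, positive-branch).
#' @return numeric of the same shape.
#' @export
tlu <- function(x, slopes = c(0.25, 1)) {
  if (any(!is.finite(x))) stop("tlu requires finite input")
  ifelse(x >= 0, slopes[2L] * x, slopes[1L] * x)
}

#' Specification of the modified U-net
#'
#' Defaults mirror the published architecture: 512x512 input, 64 feature
#' channels in the first block, four encoder and four decoder blocks around
#' one densely connected bottleneck (nine blocks in total), 2x2 max-pooling
#' with stride 2, channel count doubling per encoder block and halving per
#' decoder block, ReLU activations everywhere except the bottleneck
#' (trainable linear units) and the 4-channel softmax output. Decoder
#' upsampling is nearest-neighbour followed by convolution; skip merging is
#' channel concatenation. `input_size` can be reduced (any multiple of
#' `2^n_encoder_blocks`) for CPU-scale experiments.
#'
#' @param input_size square input side, divisible by `2^n_encoder_blocks`.
#' @param base_channels feature channels in the first encoder block.
#' @param n_encoder_blocks,n_decoder_blocks encoder/decoder depth.
#' @param dense_layers number of densely connected bottleneck convolutions.
#' @param growth channels added by each dense bottleneck layer (default
#'   `base_channels`).
#' @param n_classes output channels (default 4: background, mitochondria,
#'   myofibrils, Z-disc).
#' @return object of class `UNetSpec`.
#' @export
unet_spec <- function(input_size = 512L, base_channels = 64L,
                      n_encoder_blocks = 4L, n_decoder_blocks = 4L,
                      dense_layers = 4L, growth = base_channels,
                      n_classes = 4L) {
  if (n_encoder_blocks != n_decoder_blocks)
    stop("encoder and decoder must have the same number of blocks")
  if (input_size %% (2^n_encoder_blocks) != 0L)
    stop(sprintf("input_size must be divisible by 2^%d", n_encoder_blocks))
  structure(list(input_size = as.integer(input_size),
                 base_channels = as.integer(base_channels),
                 n_encoder_blocks = as.integer(n_encoder_blocks),
                 n_decoder_blocks = as.integer(n_decoder_blocks),
                 dense_layers = as.integer(dense_layers),
                 growth = as.integer(growth),
                 n_classes = as.integer(n_classes)),
            class = "UNetSpec")
}

#' Build (initialize) the modified U-net
#'
#' Allocates all weights for the given [unet_spec()]. The returned network
#' is introspectable: `net$blocks` lists every block with its role and
#' output channels, and `unet_n_blocks()` returns the total block count
#' (`n_encoder + 1 + n_decoder`).
#'
#' @param spec a [unet_spec()].
#' @param seed RNG seed for weight initialization.
#' @return object of class `UNet`.
#' @export
build_unet <- function(spec = unet_spec(), seed = 0L) {
  if (!inherits(spec, "UNetSpec")) stop("spec must be a UNetSpec")
  with_seed(seed, {
    B <- spec$n_encoder_blocks
    base <- spec$base_channels
    params <- list()
    blocks <- list()
    for (b in seq_len(B)) {
      c_in <- if (b == 1L) 1L else as.integer(base * 2^(b - 2))
      c_out <- as.integer(base * 2^(b - 1))
      params[[sprintf("enc%d_conv1", b)]] <- conv_init(3L, c_in, c_out)
      params[[sprintf("enc%d_conv2", b)]] <- conv_init(3L, c_out, c_out)
      blocks[[length(blocks) + 1L]] <-
        list(role = "encoder", index = b, channels = c_out)
    }
    cb <- as.integer(base * 2^(B - 1))
    for (l in seq_len(spec$dense_layers)) {
      c_in <- cb + (l - 1L) * spec$growth
      params[[sprintf("bott_dense%d", l)]] <-
        conv_init(3L, c_in, spec$growth)
      params[[sprintf("bott_tlu%d", l)]] <- tlu_init(spec$growth)
    }
    c_bott <- as.integer(base * 2^B)
    params[["bott_trans"]] <-
      conv_init(1L, cb + spec$dense_layers * spec$growth, c_bott)
    blocks[[length(blocks) + 1L]] <-
      list(role = "bottleneck", index = 1L, channels = c_bott)
    for (b in seq_len(B)) {
      c_in <- as.integer(base * 2^(B - b + 1))
      c_mid <- c_in %/% 2L
      params[[sprintf("dec%d_up", b)]] <- conv_init(3L, c_in, c_mid)
      params[[sprintf("dec%d_conv1", b)]] <- conv_init(3L, 2L * c_mid, c_mid)
      params[[sprintf("dec%d_conv2", b)]] <- conv_init(3L, c_mid, c_mid)
      blocks[[length(blocks) + 1L]] <-
        list(role = "decoder", index = b, channels = c_mid)
    }
    params[["out"]] <- conv_init(1L, base, spec$n_classes, gain = 1)
    structure(list(spec = spec, params = params, blocks = blocks),
              class = "UNet")
  })
}

#' Total number of blocks in a U-net
#' @param net a `UNet`.
#' @return integer block count (encoders + bottleneck + decoders).
#' @export
unet_n_blocks <- function(net) length(net$blocks)

#' @export
print.UNet <- function(x, ...) {
  cat(sprintf("<UNet> %d blocks, input %dx%d, %d classes\n",
              unet_n_blocks(x), x$spec$input_size, x$spec$input_size,
              x$spec$n_classes))
  for (b in x$blocks)
    cat(sprintf("  %-10s %d: %d channels\n", b$role, b$index, b$channels))
  invisible(x)
}

## full forward pass; x is an (H, W) matrix of intensities in [0, 1]
unet_forward <- function(net, x, with_cache = FALSE) {
  spec <- net$spec
  p <- net$params
  B <- spec$n_encoder_blocks
  h <- array(x - 0.5, c(nrow(x), ncol(x), 1L))
  caches <- list()
  skips <- list()
  for (b in seq_len(B)) {
    c1 <- conv_forward(h, p[[sprintf("enc%d_conv1", b)]])
    r1 <- relu_forward(c1$y)
    c2 <- conv_forward(r1$y, p[[sprintf("enc%d_conv2", b)]])
    r2 <- relu_forward(c2$y)
    skips[[b]] <- r2$y
    pl <- maxpool2_forward(r2$y)
    h <- pl$y
    caches[[sprintf("enc%d", b)]] <- list(c1 = c1$cache, r1 = r1$cache,
                                          c2 = c2$cache, r2 = r2$cache,
                                          pool = pl$cache)
  }
  dense_caches <- list()
  for (l in seq_len(spec$dense_layers)) {
    cv <- conv_forward(h, p[[sprintf("bott_dense%d", l)]])
    tl <- tlu_forward(cv$y, p[[sprintf("bott_tlu%d", l)]])
    dense_caches[[l]] <- list(conv = cv$cache, tlu = tl$cache,
                              c_in = dim(h)[3L])
    ## dense connectivity: concatenate the new features onto the input
    hh <- array(0, dim(h) + c(0L, 0L, spec$growth))
    hh[, , seq_len(dim(h)[3L])] <- h
    hh[, , dim(h)[3L] + seq_len(spec$growth)] <- tl$y
    h <- hh
  }
  tr <- conv_forward(h, p[["bott_trans"]])
  rt <- relu_forward(tr$y)
  h <- rt$y
  caches[["bott"]] <- list(dense = dense_caches, trans = tr$cache,
                           rtrans = rt$cache)
  for (b in seq_len(B)) {
    up <- upsample2_forward(h)
    cu <- conv_forward(up$y, p[[sprintf("dec%d_up", b)]])
    ru <- relu_forward(cu$y)
    skip <- skips[[B - b + 1L]]
    cat_in <- array(0, dim(ru$y) + c(0L, 0L, dim(skip)[3L]))
    cat_in[, , seq_len(dim(ru$y)[3L])] <- ru$y
    cat_in[, , dim(ru$y)[3L] + seq_len(dim(skip)[3L])] <- skip
    c1 <- conv_forward(cat_in, p[[sprintf("dec%d_conv1", b)]])
    r1 <- relu_forward(c1$y)
    c2 <- conv_forward(r1$y, p[[sprintf("dec%d_conv2", b)]])
    r2 <- relu_forward(c2$y)
    h <- r2$y
    caches[[sprintf("dec%d", b)]] <- list(up = up$cache, cu = cu$cache,
                                          ru = ru$cache, c1 = c1$cache,
                                          r1 = r1$cache, c2 = c2$cache,
                                          r2 = r2$cache,
                                          n_mid = dim(ru$y)[3L])
  }
  out <- conv_forward(h, p[["out"]])
  caches[["out"]] <- out$cache
  res <- list(logits = out$y, prob = softmax_channels(out$y))
  if (with_cache) res$cache <- caches
  res
}

## backward pass from dlogits; returns gradient list mirroring net$params
unet_backward <- function(net, caches, dlogits) {
  spec <- net$spec
  p <- net$params
  B <- spec$n_encoder_blocks
  grads <- list()
  bo <- conv_backward(dlogits, p[["out"]], caches[["out"]])
  grads[["out"]] <- bo$dpar
  dh <- bo$dx
  dskips <- vector("list", B)
  for (b in rev(seq_len(B))) {
    cc <- caches[[sprintf("dec%d", b)]]
    dr2 <- relu_backward(dh, cc$r2)
    b2 <- conv_backward(dr2, p[[sprintf("dec%d_conv2", b)]], cc$c2)
    grads[[sprintf("dec%d_conv2", b)]] <- b2$dpar
    dr1 <- relu_backward(b2$dx, cc$r1)
    b1 <- conv_backward(dr1, p[[sprintf("dec%d_conv1", b)]], cc$c1)
    grads[[sprintf("dec%d_conv1", b)]] <- b1$dpar
    n_mid <- cc$n_mid
    dcat <- b1$dx
    dru <- dcat[, , seq_len(n_mid), drop = FALSE]
    dskips[[B - b + 1L]] <-
      dcat[, , n_mid + seq_len(dim(dcat)[3L] - n_mid), drop = FALSE]
    dcu <- relu_backward(dru, cc$ru)
    bu <- conv_backward(dcu, p[[sprintf("dec%d_up", b)]], cc$cu)
    grads[[sprintf("dec%d_up", b)]] <- bu$dpar
    dh <- upsample2_backward(bu$dx, cc$up)
  }
  cb <- caches[["bott"]]
  dtr <- relu_backward(dh, cb$rtrans)
  bt <- conv_backward(dtr, p[["bott_trans"]], cb$trans)
  grads[["bott_trans"]] <- bt$dpar
  dh <- bt$dx
  for (l in rev(seq_len(spec$dense_layers))) {
    dc <- cb$dense[[l]]
    c_in <- dc$c_in
    dprev <- dh[, , seq_len(c_in), drop = FALSE]
    dnew <- dh[, , c_in + seq_len(spec$growth), drop = FALSE]
    btl <- tlu_backward(dnew, dc$tlu)
    grads[[sprintf("bott_tlu%d", l)]] <- btl$dpar
    bcv <- conv_backward(btl$dx, p[[sprintf("bott_dense%d", l)]], dc$conv)
    grads[[sprintf("bott_dense%d", l)]] <- bcv$dpar
    dh <- dprev + bcv$dx
  }
  for (b in rev(seq_len(B))) {
    cc <- caches[[sprintf("enc%d", b)]]
    dpool <- maxpool2_backward(dh, cc$pool)
    dpool <- dpool + dskips[[b]]
    dr2 <- relu_backward(dpool, cc$r2)
    b2 <- conv_backward(dr2, p[[sprintf("enc%d_conv2", b)]], cc$c2)
    grads[[sprintf("enc%d_conv2", b)]] <- b2$dpar
    dr1 <- relu_backward(b2$dx, cc$r1)
    b1 <- conv_backward(dr1, p[[sprintf("enc%d_conv1", b)]], cc$c1)
    grads[[sprintf("enc%d_conv1", b)]] <- b1$dpar
    dh <- b1$dx
  }
  grads
}

#' Training configuration for the U-net
#'
#' The loss is categorical cross-entropy over the softmax output — the
#' canonical pairing for a multi-class probability map — optimized with
#' Adam. Validation loss is evaluated every epoch; the returned checkpoint
#' is the epoch with the best validation loss, and training stops early
#' after `patience` epochs without improvement.
#'
#' @param epochs maximum epochs.
#' @param batch_size gradient-accumulation batch size.
#' @param lr Adam learning rate.
#' @param seed RNG seed governing shuffling (weights are seeded in
#'   [build_unet()]).
#' @param patience early-stopping patience in epochs (`Inf` disables).
#' @return object of class `TrainConfig`.
#' @export
train_config <- function(epochs = 30L, batch_size = 4L, lr = 1e-3,
                         seed = 0L, patience = Inf) {
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch size must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, seed = as.integer(seed), patience = patience),
            class = "TrainConfig")
}

#' Train the U-net on annotated patches
#'
#' @param net a [build_unet()] network.
#' @param data list with `train` and `val`, each a list of samples; a
#'   sample is `list(x = intensity matrix in [0,1], y = integer label
#'   matrix)` (see [patch_dataset()]).
#' @param cfg a [train_config()].
#' @return list with `net` (the checkpoint with best validation loss) and
#'   `history` (data.frame of per-epoch train/val loss).
#' @export
train_unet <- function(net, data, cfg = train_config()) {
  if (length(data$train) == 0L) stop("empty training split")
  if (length(data$val) == 0L) stop("empty validation split")
  with_seed(cfg$seed, {
    state <- adam_init(net$params)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    best <- list(loss = Inf, params = net$params, epoch = 0L)
    stale <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(data$train))
      tr_loss <- 0
      i <- 1L
      while (i <= length(ord)) {
        take <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
        acc <- NULL
        for (s in take) {
          smp <- data$train[[s]]
          fw <- unet_forward(net, smp$x, with_cache = TRUE)
          ce <- softmax_ce(fw$logits, smp$y)
          if (!is.finite(ce$loss))
            stop(sprintf("divergent (non-finite) loss at epoch %d", ep))
          tr_loss <- tr_loss + ce$loss
          g <- unet_backward(net, fw$cache, ce$dlogits)
          acc <- if (is.null(acc)) g else param_add(acc, g)
        }
        acc <- param_map(acc, function(a) a / length(take))
        if (cfg$lr > 0) {
          upd <- adam_step(net$params, acc, state, lr = cfg$lr)
          net$params <- upd$params
          state <- upd$state
        }
        i <- i + cfg$batch_size
      }
      tr_loss <- tr_loss / length(ord)
      val_loss <- mean(vapply(data$val, function(smp) {
        fw <- unet_forward(net, smp$x)
        softmax_ce(fw$logits, smp$y)$loss
      }, numeric(1)))
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss,
                                     val_loss = val_loss))
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = net$params, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$patience) break
      }
    }
    net$params <- best$params
    list(net = net, history = hist, best_epoch = best$epoch,
         best_val_loss = best$loss)
  })
}

#' Segment a volume with a trained U-net
#'
#' Applies the network slice by slice. Slices larger than the network tile
#' are covered with overlapping tiles whose class probabilities are
#' averaged before the argmax; slices smaller than the tile require a
#' padding policy (`pad = "reflect"`), otherwise an error is raised.
#'
#' @param net trained `UNet`.
#' @param volume `IntensityVolume` or 3D array.
#' @param tile tile side (default: the network input size).
#' @param overlap tile overlap in pixels (default tile/4).
#' @param pad `NULL` (error on small inputs) or `"reflect"`.
#' @return list with `labels` (`LabelVolume`) and `prob` (4D array
#'   z × H × W × K of class probabilities).
#' @export
predict_volume <- function(net, volume, tile = NULL, overlap = NULL,
                           pad = NULL) {
  arr <- vol_data(volume)
  vs <- vol_voxel_size(volume)
  tile <- as.integer(tile %||% net$spec$input_size)
  overlap <- as.integer(overlap %||% max(tile %/% 4L, 0L))
  d <- dim(arr)
  H <- d[2L]; W <- d[3L]
  padded <- FALSE
  if (H < tile || W < tile) {
    if (is.null(pad))
      stop("volume slices are smaller than the tile and no padding policy was given")
    padded <- TRUE
    H0 <- H; W0 <- W
  }
  K <- net$spec$n_classes
  prob <- array(0, c(d[1L], H, W, K))
  for (z in seq_len(d[1L])) {
    sl <- arr[z, , ]
    if (padded) sl <- reflect_pad(sl, tile)
    hh <- nrow(sl); ww <- ncol(sl)
    acc <- array(0, c(hh, ww, K))
    cnt <- matrix(0, hh, ww)
    step <- max(tile - overlap, 1L)
    ys <- unique(c(seq(1L, max(hh - tile + 1L, 1L), by = step),
                   hh - tile + 1L))
    xs <- unique(c(seq(1L, max(ww - tile + 1L, 1L), by = step),
                   ww - tile + 1L))
    for (y0 in ys) for (x0 in xs) {
      piece <- sl[y0:(y0 + tile - 1L), x0:(x0 + tile - 1L)]
      pr <- unet_forward(net, piece)$prob
      acc[y0:(y0 + tile - 1L), x0:(x0 + tile - 1L), ] <-
        acc[y0:(y0 + tile - 1L), x0:(x0 + tile - 1L), , drop = FALSE] + pr
      cnt[y0:(y0 + tile - 1L), x0:(x0 + tile - 1L)] <-
        cnt[y0:(y0 + tile - 1L), x0:(x0 + tile - 1L)] + 1
    }
    acc <- acc / array(cnt, dim(acc))
    if (padded) acc <- acc[seq_len(H), seq_len(W), , drop = FALSE]
    prob[z, , , ] <- acc
  }
  lab <- apply(prob, c(1, 2, 3), which.max) - 1L
  list(labels = label_volume(array(as.integer(lab), d), vs), prob = prob)
}

reflect_pad <- function(m, target) {
  while (nrow(m) < target) {
    need <- min(target - nrow(m), nrow(m))
    m <- rbind(m, m[nrow(m):(nrow(m) - need + 1L), , drop = FALSE])
  }
  while (ncol(m) < target) {
    need <- min(target - ncol(m), ncol(m))
    m <- cbind(m, m[, ncol(m):(ncol(m) - need + 1L), drop = FALSE])
  }
  m
}

#' Build a patch training set from a phantom
#'
#' Extracts matching intensity/label patches at the footprints returned by
#' [extract_patches()] and partitions them by a [make_split()] fold.
#'
#' @param phantom a `PhantomVolume`.
#' @param footprints footprint table from [extract_patches()].
#' @param split one `DatasetSplit` (ids index footprint rows).
#' @return list with `train`, `val`, `test` lists of
#'   `list(x = intensity, y = labels)` samples.
#' @export
patch_dataset <- function(phantom, footprints, split) {
  get <- function(ids) lapply(ids, function(i) {
    fp <- footprints[i, , drop = FALSE]
    attr(fp, "patch_size") <- attr(footprints, "patch_size")
    list(x = crop_patch(phantom$intensity, fp),
         y = crop_patch(phantom$labels, fp))
  })
  list(train = get(split$train), val = get(split$val), test = get(split$test))
}
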