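test_that("softmax reproduces closed forms and the unstabilized formula", {
  expect_equal(softmax(c(0, 0, 0, 0)), rep(0.25, 4))
  expect_equal(softmax(c(log(2), 0, 0, 0)), c(0.4, 0.2, 0.2, 0.2))
  set.seed(8)
  for (i in 1:25) {
    a <- rnorm(4, sd = 3)
    naive <- exp(a) / sum(exp(a))          # direct formula, no stabilization
    expect_equal(softmax(a), naive, tolerance = 1e-9)
    expect_equal(softmax(a + 7.3), softmax(a), tolerance = 1e-12)
    expect_equal(sum(softmax(a)), 1, tolerance = 1e-12)
  }
  expect_error(softmax(c(NaN, 1)), "finite")
})

test_that("the trainable linear unit hits its rectifier and identity limits", {
  expect_identical(tlu(-3, c(0, 1)), 0)
  expect_identical(tlu(-3, c(1, 1)), -3)
  expect_identical(tlu(-4, c(0.25, 1)), -1)
  expect_identical(tlu(5, c(0.25, 1)), 5)
  expect_error(tlu(Inf), "finite")
})

test_that("the default architecture has 9 blocks, 64 base channels, 4 outputs", {
  net <- build_unet(unet_spec(), seed = 1)
  expect_identical(unet_n_blocks(net), 9L)
  roles <- vapply(net$blocks, `[[`, character(1), "role")
  expect_identical(sum(roles == "encoder"), 4L)
  expect_identical(sum(roles == "decoder"), 4L)
  expect_identical(sum(roles == "bottleneck"), 1L)
  expect_identical(net$blocks[[1]]$channels, 64L)
  ## channels double along the encoder, halve along the decoder
  enc_ch <- vapply(net$blocks[roles == "encoder"], `[[`, integer(1), "channels")
  expect_identical(enc_ch, as.integer(64 * 2^(0:3)))
  dec_ch <- vapply(net$blocks[roles == "decoder"], `[[`, integer(1), "channels")
  expect_identical(dec_ch, as.integer(1024L / 2L^(1:4)))
  ## output convolution has n_classes = 4 channels
  expect_identical(ncol(net$params$out$w), 4L)
  expect_error(unet_spec(input_size = 100), "divisible")
})

test_that("forward pass normalizes probabilities and halves spatial size per pool", {
  spec <- unet_spec(input_size = 64, base_channels = 2, n_encoder_blocks = 4,
                    n_decoder_blocks = 4, dense_layers = 1, growth = 2)
  net <- build_unet(spec, seed = 2)
  fw <- cardioEM:::unet_forward(net, matrix(0, 64, 64), with_cache = TRUE)
  expect_identical(dim(fw$prob), c(64L, 64L, 4L))
  expect_lt(max(abs(apply(fw$prob, c(1, 2), sum) - 1)), 1e-6)
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  ## after 4 pools of a 64px input the bottleneck works on a 4x4 grid
  expect_identical(fw$cache$bott$trans$dim_in[1:2], c(4L, 4L))
})

test_that("training is deterministic, monotone under lr 0, and errors on empty splits", {
  ph <- generate_phantom(training_phantom_config(21, c(8L, 96L, 96L), mito_count = 0L))
  fp <- extract_patches(ph$intensity, 32, 8, seed = 1)
  ds <- patch_dataset(ph, fp, make_split(1:8, c(6, 2, 0), seed = 1)[[1]])
  spec <- unet_spec(input_size = 32, base_channels = 4, n_encoder_blocks = 2,
                    n_decoder_blocks = 2, dense_layers = 1, growth = 4)
  net <- build_unet(spec, seed = 5)
  cfg <- train_config(epochs = 2, batch_size = 3, seed = 9)
  r1 <- train_unet(net, ds, cfg)
  r2 <- train_unet(net, ds, cfg)
  expect_identical(r1$history, r2$history)
  ## zero learning rate: parameters untouched, loss constant across epochs
  r0 <- train_unet(net, ds, train_config(epochs = 3, lr = 0, seed = 9))
  expect_identical(r0$net$params, net$params)
  expect_equal(diff(r0$history$val_loss), rep(0, 2), tolerance = 1e-12)
  expect_error(train_unet(net, list(train = list(), val = ds$val), cfg),
               "empty")
})

test_that("validation loss decreases over a short training run", {
  ph <- generate_phantom(training_phantom_config(22, c(10L, 128L, 128L), mito_count = 12L,
                                              mito_semiaxes_um = c(0.12, 0.1, 0.1)))
  fp <- extract_patches(ph$intensity, 64, 12, seed = 2)
  ds <- patch_dataset(ph, fp, make_split(1:12, c(9, 3, 0), seed = 2)[[1]])
  spec <- unet_spec(input_size = 64, base_channels = 8, n_encoder_blocks = 2,
                    n_decoder_blocks = 2, dense_layers = 2, growth = 8)
  res <- train_unet(build_unet(spec, seed = 0), ds,
                    train_config(epochs = 6, batch_size = 4, seed = 0))
  expect_lt(tail(res$history$val_loss, 1), res$history$val_loss[1])
  expect_lt(res$best_val_loss, res$history$val_loss[1])
})

test_that("prediction is deterministic, tiles correctly, and handles padding", {
  spec <- unet_spec(input_size = 32, base_channels = 4, n_encoder_blocks = 2,
                    n_decoder_blocks = 2, dense_layers = 1, growth = 4)
  net <- build_unet(spec, seed = 3)
  vol <- intensity_volume(array(runif(2 * 48 * 48), c(2, 48, 48)))
  p1 <- predict_volume(net, vol, tile = 32, overlap = 8)
  p2 <- predict_volume(net, vol, tile = 32, overlap = 8)
  expect_identical(p1$labels$data, p2$labels$data)
  expect_identical(dim(p1$labels$data), c(2L, 48L, 48L))
  expect_true(all(p1$labels$data %in% 0:3))
  ## probabilities stay normalized after overlap averaging
  expect_lt(max(abs(apply(p1$prob, c(1, 2, 3), sum) - 1)), 1e-6)
  ## a network with all-zero weights emits equal logits -> one uniform label
  net0 <- net
  net0$params <- cardioEM:::param_map(net0$params, function(a) { a[] <- 0; a })
  u <- predict_volume(net0, vol, tile = 32, overlap = 8)
  expect_identical(unique(as.vector(u$labels$data)), 0L)
  ## small slices: error without a padding policy, reflect pad otherwise
  small <- intensity_volume(array(runif(1 * 20 * 20), c(1, 20, 20)))
  expect_error(predict_volume(net, small, tile = 32), "padding")
  ps <- predict_volume(net, small, tile = 32, pad = "reflect")
  expect_identical(dim(ps$labels$data), c(1L, 20L, 20L))
})

test_that("joint 4-class training makes Z-disc segmentation at least as good as binary", {
  ## the Z-disc class occupies ~1% of voxels; plain binary training tends to
  ## collapse to the majority class, while joint multi-class training can
  ## still learn it. Compare Z-disc Jaccard at a fixed budget over 3 seeds.
  zdisc_jaccard <- function(seed, binary) {
    cfg <- phantom_config(shape_voxels = c(24L, 192L, 192L),
                          voxel_size_um = 0.04, mito_count = 25L,
                          mito_semiaxes_um = c(0.22, 0.18, 0.18),
                          myofibril_fill_fraction = 0.3, seed = 100 + seed)
    ph <- generate_phantom(cfg)
    fp <- extract_patches(ph$intensity, 64, 16, seed = seed)
    ds <- patch_dataset(ph, fp, make_split(1:16, c(12, 2, 2), seed = seed)[[1]])
    if (binary)
      ds <- lapply(ds, function(part)
        lapply(part, function(s) { s$y <- (s$y == 3L) * 1L; s }))
    spec <- unet_spec(input_size = 64, base_channels = 8,
                      n_encoder_blocks = 2, n_decoder_blocks = 2,
                      dense_layers = 2, growth = 8,
                      n_classes = if (binary) 2L else 4L)
    res <- train_unet(build_unet(spec, seed = seed), ds,
                      train_config(epochs = 12, batch_size = 4, seed = seed))
    test_slice <- vol_data(ph$intensity)[24, , , drop = FALSE]
    truth <- vol_data(ph$labels)[24, , ] == 3L
    pred <- predict_volume(res$net, test_slice, tile = 64, overlap = 16)
    predz <- pred$labels$data[1, , ] == (if (binary) 1L else 3L)
    uni <- sum(predz | truth)
    if (uni == 0) 1 else sum(predz & truth) / uni
  }
  diffs <- vapply(1:3, function(s)
    zdisc_jaccard(s, binary = FALSE) - zdisc_jaccard(s, binary = TRUE),
    numeric(1))
  expect_gte(median(diffs), 0)
})
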