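test_that("activation functions follow their closed forms", {
  expect_equal(relu(-1), 0)
  expect_equal(relu(2), 2)
  expect_equal(relu(0), 0)
  expect_equal(sigmoid(0), 0.5)
  expect_gt(sigmoid(30), 1 - 1e-10)
  x <- seq(-4, 4, by = 0.5)
  expect_equal(sigmoid(-x), 1 - sigmoid(x))
})

test_that("model configuration enforces the divisibility constraint", {
  expect_error(unet_config(depth = 5, input_shape = c(200L, 360L)),
               "not divisible by 16")
  cfg <- unet_config(depth = 5, init_channels = 64)
  expect_equal(femaug:::unet_channels(cfg), c(64, 128, 256, 512, 1024))
})

test_that("analytic gradients match finite differences off the ReLU kinks", {
  set.seed(42)
  cfg <- unet_config(depth = 2L, init_channels = 2L, input_shape = c(8L, 8L))
  p <- jittered_weights(cfg)
  x <- matrix(runif(64), 8, 8)
  y <- random_mask(8, 8)
  fw <- femaug:::unet_forward
  cache <- fw(p, cfg, x, with_cache = TRUE)
  g <- femaug:::unet_backward(p, cfg, cache, y)
  eps <- 1e-6
  for (nm in names(p)) {
    idx <- if (length(p[[nm]]) <= 4) seq_along(p[[nm]]) else
      sample(length(p[[nm]]), 6)
    for (i in idx) {
      p2 <- p
      p2[[nm]][i] <- p2[[nm]][i] + eps
      l1 <- femaug:::bce_loss(fw(p2, cfg, x)$logits, y)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      l0 <- femaug:::bce_loss(fw(p2, cfg, x)$logits, y)
      num <- (l1 - l0) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]),
                1e-4 * max(1, abs(num)) + 1e-7)
    }
  }
})

test_that("forward pass keeps shape and maps an all-zero image to 0.5", {
  set.seed(5)
  cfg <- unet_config(depth = 5L, init_channels = 4L, input_shape = c(32L, 48L))
  p <- build_unet(cfg)   # zero biases
  pr <- plogis(femaug:::unet_forward(p, cfg, matrix(0, 32, 48))$logits)
  expect_equal(dim(pr), c(32L, 48L))
  expect_true(all(pr == 0.5))
  # channel doubling with halved resolution down the contraction path
  cache <- femaug:::unet_forward(p, cfg, matrix(runif(32 * 48), 32, 48),
                                 with_cache = TRUE)
  dims <- t(vapply(cache$enc, function(e) dim(e$h2), integer(3)))
  expect_equal(dims[, 3], c(4L, 8L, 16L, 32L, 64L))
  expect_equal(dims[, 1], c(32L, 16L, 8L, 4L, 2L))
})

test_that("padding centers, crops overhang, and un-pads exactly", {
  img <- matrix(runif(200 * 361), 200, 361)
  pad <- pad_to_model_input(img, shape = c(208L, 352L))
  expect_equal(dim(pad), c(208L, 352L))
  sml <- matrix(runif(30 * 33), 30, 33)
  pad2 <- pad_to_model_input(sml)
  expect_equal(dim(pad2), c(32L, 48L))
  back <- unpad_image(pad2, attr(pad2, "pad_offsets"))
  expect_equal(back, sml)
  same <- pad_to_model_input(matrix(1, 32, 48))
  expect_true(all(same == 1))
})

test_that("scan-level splits have floor sizes with remainder to train", {
  s <- split_dataset(sprintf("s%03d", 1:120), seed = 7)
  expect_equal(lengths(s)[c("train", "val", "test")],
               c(train = 72L, val = 24L, test = 24L))
  s10 <- split_dataset(letters[1:10], seed = 7)
  expect_equal(unname(lengths(s10)), c(6L, 2L, 2L))
  expect_setequal(unlist(s10), letters[1:10])
  expect_identical(split_dataset(letters[1:10], seed = 7), s10)
  expect_false(identical(split_dataset(letters[1:10], seed = 8), s10))
  expect_error(split_dataset(letters[1:2]), "at least 3")
  expect_error(split_dataset(letters[1:10], ratios = c(50, 20, 20)), "sum")
})

test_that("training is seed-deterministic and reduces the loss", {
  set.seed(1)
  cfg <- unet_config(depth = 3L, init_channels = 4L, input_shape = c(16L, 16L))
  xs <- lapply(1:3, function(i) {
    y <- matrix(0, 16, 16); y[5:12, 5:12] <- 1
    list(x = y * 0.8 + matrix(runif(256, 0, 0.1), 16, 16), y = y)
  })
  ctrl <- train_control(max_epochs = 12L, patience = 11L, batch_size = 2L,
                        seed = 3L)
  f1 <- fit_unet(xs, xs, config = cfg, control = ctrl)
  f2 <- fit_unet(xs, xs, config = cfg, control = ctrl)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_lt(tail(f1$history$loss, 1), f1$history$loss[1])
  # early stopping halts within patience epochs of the best epoch
  ctrl2 <- train_control(max_epochs = 40L, patience = 3L, seed = 3L)
  f3 <- fit_unet(xs, xs, config = cfg, control = ctrl2)
  expect_lte(nrow(f3$history), f3$best_epoch + 3L)
})

test_that("prediction thresholds at 0.5 with ties going to foreground", {
  cfg <- unet_config(depth = 2L, init_channels = 2L, input_shape = c(8L, 8L))
  set.seed(2)
  p <- build_unet(cfg)
  p$out_W[] <- 0; p$out_b <- 0   # logits identically 0 -> probability 0.5
  model <- structure(list(params = p, config = cfg), class = "unet")
  m <- predict(model, matrix(runif(64), 8, 8), type = "mask")
  expect_true(all(m == 1))
  expect_error(predict(model, matrix(0, 9, 8)), "divisible")
  # predict_mask un-pads to the source geometry
  img <- pad_to_model_input(matrix(runif(30), 5, 6))
  msk <- predict_mask(model, img)
  expect_equal(dim(msk), c(5L, 6L))
})
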