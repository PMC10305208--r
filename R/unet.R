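#' Rectified linear unit
#'
#' `relu(x) = max(0, x)`, applied elementwise; the hidden activation of
#' the U-Net.
#' @param x Numeric vector/array.
#' @return Same shape as `x`.
#' @export
relu <- function(x) {
  stopifnot(all(is.finite(x)))
  pmax(x, 0)
}

#' Logistic sigmoid
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`; the output activation mapping logits
#' to foreground probabilities.
#' @param x Numeric vector/array.
#' @return Values in (0, 1), same shape as `x`.
#' @export
sigmoid <- function(x) {
  stopifnot(all(is.finite(x)))
  stats::plogis(x)
}

#' U-Net architecture configuration
#'
#' A five-level encoder-decoder: each contraction level applies two 3x3
#' same-padding convolutions with ReLU and a 2x2 max pool (halving the
#' resolution and doubling the channels), the expansion path mirrors it
#' with 3x3 stride-2 transposed convolutions and skip concatenations, and
#' a final 1x1 convolution with a sigmoid produces one foreground
#' probability per pixel. Input height and width must be divisible by
#' `2^(depth - 1)` (16 for depth 5).
#'
#' @param depth Number of resolution levels (default 5).
#' @param init_channels Channels of the first level (default 64; the
#'   desk-scale profile uses 16).
#' @param input_shape Default model input `c(rows, cols)`; the reference
#'   geometry is `c(208, 352)`.
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(depth = 5L, init_channels = 64L,
                        input_shape = c(208L, 352L)) {
  stopifnot(depth >= 2L, init_channels >= 1L)
  div <- 2^(depth - 1)
  if (any(input_shape %% div != 0))
    stop(sprintf("input shape %dx%d not divisible by %d (depth %d)",
                 input_shape[1L], input_shape[2L], div, depth))
  structure(list(depth = as.integer(depth),
                 init_channels = as.integer(init_channels),
                 input_shape = as.integer(input_shape)),
            class = "unet_config")
}

unet_channels <- function(cfg) cfg$init_channels * 2^(seq_len(cfg$depth) - 1L)

he_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Initialize U-Net weights
#'
#' Creates the learnable state (convolution kernels and biases) with
#' fan-in-scaled Gaussian initialization, drawn from the current RNG state
#' (seed it, or let [fit_unet()] do so).
#'
#' @param cfg A [unet_config()].
#' @return Object of class `unet_weights`: a named flat list of arrays.
#' @export
build_unet <- function(cfg = unet_config()) {
  ch <- unet_channels(cfg)
  d <- cfg$depth
  p <- list()
  for (l in seq_len(d)) {
    cin <- if (l == 1L) 1L else ch[l - 1L]
    p[[paste0("enc", l, "_c1W")]] <- he_mat(9 * cin, ch[l], 9 * cin)
    p[[paste0("enc", l, "_c1b")]] <- numeric(ch[l])
    p[[paste0("enc", l, "_c2W")]] <- he_mat(9 * ch[l], ch[l], 9 * ch[l])
    p[[paste0("enc", l, "_c2b")]] <- numeric(ch[l])
  }
  for (l in seq_len(d - 1L)) {       # decoder level l outputs ch[l]
    p[[paste0("dec", l, "_upW")]] <- he_mat(ch[l + 1L], 9 * ch[l], 9 * ch[l + 1L])
    p[[paste0("dec", l, "_upb")]] <- numeric(ch[l])
    p[[paste0("dec", l, "_c1W")]] <- he_mat(9 * 2 * ch[l], ch[l], 9 * 2 * ch[l])
    p[[paste0("dec", l, "_c1b")]] <- numeric(ch[l])
    p[[paste0("dec", l, "_c2W")]] <- he_mat(9 * ch[l], ch[l], 9 * ch[l])
    p[[paste0("dec", l, "_c2b")]] <- numeric(ch[l])
  }
  p[["out_W"]] <- he_mat(ch[1L], 1L, ch[1L])
  p[["out_b"]] <- 0
  structure(p, class = "unet_weights", config = cfg)
}

as_cube <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  x
}

conv_block_fw <- function(p, pre, x) {
  h1 <- .conv3_forward(x, p[[paste0(pre, "_c1W")]], p[[paste0(pre, "_c1b")]])
  h1[h1 < 0] <- 0
  h2 <- .conv3_forward(h1, p[[paste0(pre, "_c2W")]], p[[paste0(pre, "_c2b")]])
  h2[h2 < 0] <- 0
  list(x = x, h1 = h1, h2 = h2)
}

conv_block_bw <- function(p, pre, cache, g, grads) {
  g <- g * (cache$h2 > 0)
  b2 <- .conv3_backward(cache$h1, p[[paste0(pre, "_c2W")]], g)
  grads[[paste0(pre, "_c2W")]] <- grads[[paste0(pre, "_c2W")]] + b2$gW
  grads[[paste0(pre, "_c2b")]] <- grads[[paste0(pre, "_c2b")]] + as.numeric(b2$gb)
  g1 <- b2$gx * (cache$h1 > 0)
  b1 <- .conv3_backward(cache$x, p[[paste0(pre, "_c1W")]], g1)
  grads[[paste0(pre, "_c1W")]] <- grads[[paste0(pre, "_c1W")]] + b1$gW
  grads[[paste0(pre, "_c1b")]] <- grads[[paste0(pre, "_c1b")]] + as.numeric(b1$gb)
  list(gx = b1$gx, grads = grads)
}

unet_forward <- function(p, cfg, x, with_cache = FALSE) {
  d <- cfg$depth
  x <- as_cube(x)
  enc <- vector("list", d); pool_idx <- vector("list", d - 1L)
  a <- x
  for (l in seq_len(d)) {
    enc[[l]] <- conv_block_fw(p, paste0("enc", l), a)
    if (l < d) {
      mp <- .maxpool2_forward(enc[[l]]$h2)
      pool_idx[[l]] <- mp$idx
      a <- mp$out
    }
  }
  dec <- vector("list", d - 1L); up <- vector("list", d - 1L)
  dcur <- enc[[d]]$h2
  for (l in rev(seq_len(d - 1L))) {
    u <- .upconv2_forward(dcur, p[[paste0("dec", l, "_upW")]],
                          p[[paste0("dec", l, "_upb")]])
    u[u < 0] <- 0
    up[[l]] <- u
    skip <- enc[[l]]$h2
    cat_lu <- array(c(skip, u), dim = c(dim(u)[1:2], dim(skip)[3] + dim(u)[3]))
    dec[[l]] <- conv_block_fw(p, paste0("dec", l), cat_lu)
    dcur <- dec[[l]]$h2
  }
  H <- dim(dcur)[1L]; W <- dim(dcur)[2L]; C <- dim(dcur)[3L]
  A <- dcur; dim(A) <- c(H * W, C)
  z <- A %*% p[["out_W"]] + p[["out_b"]]
  dim(z) <- c(H, W)
  if (!with_cache) return(list(logits = z))
  list(logits = z, enc = enc, pool_idx = pool_idx, up = up, dec = dec,
       A = A, shape = c(H, W, C))
}

bce_loss <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

unet_backward <- function(p, cfg, cache, y) {
  d <- cfg$depth
  z <- cache$logits
  n <- length(z)
  gz <- (stats::plogis(z) - y) / n
  grads <- lapply(p, function(w) w * 0)
  # output head
  H <- cache$shape[1L]; W <- cache$shape[2L]; C <- cache$shape[3L]
  gzv <- matrix(gz, H * W, 1L)
  grads[["out_W"]] <- grads[["out_W"]] + crossprod(cache$A, gzv)
  grads[["out_b"]] <- grads[["out_b"]] + sum(gzv)
  g <- array(gzv %*% t(p[["out_W"]]), dim = c(H, W, C))
  # decoder, top level down to the bottom
  for (l in seq_len(d - 1L)) {
    bb <- conv_block_bw(p, paste0("dec", l), cache$dec[[l]], g, grads)
    grads <- bb$grads
    ch_skip <- dim(cache$enc[[l]]$h2)[3L]
    gcat <- bb$gx
    gskip <- gcat[, , seq_len(ch_skip), drop = FALSE]
    gu <- gcat[, , ch_skip + seq_len(dim(cache$up[[l]])[3L]), drop = FALSE]
    cache$enc[[l]]$gskip <- gskip
    gu <- gu * (cache$up[[l]] > 0)
    dinput <- if (l == d - 1L) cache$enc[[d]]$h2 else cache$dec[[l + 1L]]$h2
    ub <- .upconv2_backward(dinput, p[[paste0("dec", l, "_upW")]], gu)
    grads[[paste0("dec", l, "_upW")]] <- grads[[paste0("dec", l, "_upW")]] + ub$gW
    grads[[paste0("dec", l, "_upb")]] <- grads[[paste0("dec", l, "_upb")]] + as.numeric(ub$gb)
    g <- ub$gx
  }
  # encoder, bottom up
  genc <- g                        # gradient at enc[[d]]$h2
  for (l in rev(seq_len(d))) {
    if (l < d) {
      hw <- dim(cache$enc[[l]]$h2)
      gpool <- .maxpool2_backward(cache$pool_idx[[l]], genc, hw[1L], hw[2L])
      genc <- gpool + cache$enc[[l]]$gskip
    }
    bb <- conv_block_bw(p, paste0("enc", l), cache$enc[[l]], genc, grads)
    grads <- bb$grads
    genc <- bb$gx
  }
  grads
}

#' Training control parameters
#'
#' Training minimizes pixelwise binary cross-entropy with the Adam
#' optimizer; early stopping monitors validation IoU and restores the
#' weights of the best-validation epoch. Reference settings: learning
#' rate 0.001, up to 5000 epochs, patience 50.
#'
#' @param lr Learning rate (alpha) for Adam.
#' @param max_epochs Maximum number of epochs.
#' @param patience Consecutive epochs without validation-IoU improvement
#'   before stopping; must be smaller than `max_epochs`.
#' @param batch_size Mini-batch size (gradients averaged over the batch).
#' @param seed Integer seed controlling weight initialization and
#'   shuffling.
#' @param stop_iou Optional early target: stop as soon as validation IoU
#'   reaches this value.
#' @param verbose Print one line per epoch.
#' @return Object of class `train_control`.
#' @export
train_control <- function(lr = 0.001, max_epochs = 5000L, patience = 50L,
                          batch_size = 2L, seed = 1L, stop_iou = NULL,
                          verbose = FALSE) {
  stopifnot(lr > 0, patience < max_epochs, batch_size >= 1L)
  structure(list(lr = lr, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), stop_iou = stop_iou,
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

check_sample_shapes <- function(samples, cfg, what) {
  div <- 2^(cfg$depth - 1)
  for (s in samples) {
    d <- dim(s$x)
    if (any(d %% div != 0))
      stop(sprintf("%s image shape %dx%d not divisible by %d; pad first",
                   what, d[1L], d[2L], div))
    if (!identical(dim(s$y), d)) stop(what, " mask/image shape mismatch")
  }
}

#' Fit the U-Net segmentation model
#'
#' Optimizes the binary cross-entropy between predicted foreground
#' probabilities and ground-truth masks with Adam, evaluating IoU on the
#' validation set after every epoch. Training stops at `max_epochs`, when
#' validation IoU has not improved for `patience` consecutive epochs, or
#' when `stop_iou` is reached; the returned model carries the weights of
#' the best-validation epoch. With a fixed `seed` the whole run is
#' reproducible.
#'
#' @param train List of samples, each `list(x = , y = )` with `x` a
#'   grayscale matrix scaled to `[0, 1]` and `y` a binary mask of the same
#'   shape (see [prepare_samples()]).
#' @param val Validation samples in the same format; defaults to `train`
#'   when omitted.
#' @param config A [unet_config()].
#' @param control A [train_control()].
#' @return Object of class `unet` with elements `params`, `config`,
#'   `control`, `history` (data frame: epoch, loss, val_iou),
#'   `best_epoch`.
#' @seealso [predict.unet()], [predict_mask()]
#' @export
fit_unet <- function(train, val = NULL, config = unet_config(),
                     control = train_control()) {
  if (length(train) == 0L) stop("empty training set")
  if (is.null(val)) val <- train
  if (length(val) == 0L) stop("empty validation set")
  check_sample_shapes(train, config, "train")
  check_sample_shapes(val, config, "validation")

  set.seed(control$seed)
  p <- build_unet(config)
  m <- lapply(p, function(w) w * 0)
  v <- lapply(p, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; tstep <- 0

  best_iou <- -Inf; best_p <- p; best_epoch <- 0L; wait <- 0L
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_iou = numeric())

  for (epoch in seq_len(control$max_epochs)) {
    ord <- sample(length(train))
    losses <- numeric(0)
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + control$batch_size - 1L, length(ord))]
      i <- i + control$batch_size
      grads <- NULL
      for (k in batch) {
        s <- train[[k]]
        cache <- unet_forward(p, config, s$x, with_cache = TRUE)
        loss <- bce_loss(cache$logits, s$y)
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d (sample %d): aborting",
                       epoch, k))
        losses <- c(losses, loss)
        g <- unet_backward(p, config, cache, s$y)
        grads <- if (is.null(grads)) g else mapply(`+`, grads, g,
                                                   SIMPLIFY = FALSE)
      }
      nb <- length(batch)
      tstep <- tstep + 1
      for (nm in names(p)) {
        gk <- grads[[nm]] / nb
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gk
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gk^2
        mhat <- m[[nm]] / (1 - b1^tstep)
        vhat <- v[[nm]] / (1 - b2^tstep)
        p[[nm]] <- p[[nm]] - control$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val_iou <- mean(vapply(val, function(s) {
      pr <- unet_forward(p, config, s$x)$logits
      iou((stats::plogis(pr) >= 0.5) * 1, s$y)
    }, numeric(1)))
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = mean(losses),
                                         val_iou = val_iou))
    if (control$verbose)
      message(sprintf("epoch %4d  loss %.5f  val IoU %.4f",
                      epoch, mean(losses), val_iou))
    if (val_iou > best_iou) {
      best_iou <- val_iou; best_p <- p; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (!is.null(control$stop_iou) && best_iou >= control$stop_iou) break
    if (wait >= control$patience) break
  }

  structure(list(params = best_p, config = config, control = control,
                 history = history, best_epoch = best_epoch,
                 best_val_iou = best_iou),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  ch <- unet_channels(x$config)
  cat(sprintf("U-Net segmentation model (%d levels, channels %s)\n",
              x$config$depth, paste(ch, collapse = "-")))
  cat(sprintf("trained %d epochs; best epoch %d, validation IoU %.4f\n",
              nrow(x$history), x$best_epoch, x$best_val_iou))
  invisible(x)
}

#' @export
summary.unet <- function(object, ...) {
  npar <- sum(vapply(object$params, length, 1L))
  cat(sprintf("U-Net: depth %d, initial channels %d, %s parameters\n",
              object$config$depth, object$config$init_channels,
              format(npar, big.mark = ",")))
  cat(sprintf("training: lr %g, batch %d, seed %d\n", object$control$lr,
              object$control$batch_size, object$control$seed))
  cat(sprintf("epochs run %d; best epoch %d (val IoU %.4f); final loss %.5f\n",
              nrow(object$history), object$best_epoch, object$best_val_iou,
              utils::tail(object$history$loss, 1L)))
  invisible(object)
}

#' @export
coef.unet <- function(object, ...) object$params

#' @export
plot.unet <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "training BCE loss", ...)
  graphics::plot(x$history$epoch, x$history$val_iou, type = "l",
                 xlab = "epoch", ylab = "validation IoU", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Predict foreground probabilities or masks
#'
#' @param object A fitted [fit_unet()] model.
#' @param newdata A grayscale matrix in `[0, 1]` (shape divisible by
#'   `2^(depth-1)`), or a list of such matrices / samples.
#' @param type `"prob"` for the probability map, `"mask"` for the
#'   thresholded binary mask.
#' @param threshold Probability threshold; pixels at or above it are
#'   foreground (ties go to foreground).
#' @param ... Unused.
#' @return Matrix (or list of matrices) matching the input shape.
#' @export
predict.unet <- function(object, newdata, type = c("prob", "mask"),
                         threshold = 0.5, ...) {
  type <- match.arg(type)
  one <- function(img) {
    if (is.list(img)) img <- img$x
    d <- dim(img)
    div <- 2^(object$config$depth - 1)
    if (any(d %% div != 0))
      stop(sprintf("image shape %dx%d not divisible by %d", d[1L], d[2L], div))
    pr <- stats::plogis(unet_forward(object$params, object$config, img)$logits)
    if (type == "mask") (pr >= threshold) * 1 else pr
  }
  if (is.list(newdata) && !is.matrix(newdata)) lapply(newdata, one)
  else one(newdata)
}

#' Predict a binary mask and restore the source geometry
#'
#' Thresholds the model's probability map (probability >= `threshold` is
#' foreground) and, when the image came from [pad_to_model_input()],
#' un-pads the mask back to the source slice shape.
#'
#' @param model A fitted `unet` object.
#' @param image Padded model input (matrix in `[0, 1]`), typically from
#'   [pad_to_model_input()].
#' @param threshold Probability threshold (default 0.5).
#' @return Binary mask matrix in the source geometry when padding offsets
#'   are attached, otherwise in the model geometry.
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  mask <- predict(model, image, type = "mask", threshold = threshold)
  off <- attr(image, "pad_offsets")
  if (!is.null(off)) mask <- unpad_image(mask, off)
  mask
}

#' Center pad (or crop) an image to the model input shape
#'
#' Pads with zeros up to the target shape, centering the source; when a
#' source dimension exceeds the target (the reference crops are 360 x 200
#' while the model input is 352 x 208), the overhang is center-cropped.
#' The placement offsets are attached so predictions can be mapped back to
#' the source geometry with [unpad_image()].
#'
#' @param image Numeric matrix.
#' @param shape Target `c(rows, cols)`; default: each dimension rounded up
#'   to the next multiple of 16 (depth-5 divisibility).
#' @return Matrix of the target shape with attribute `pad_offsets`.
#' @export
pad_to_model_input <- function(image, shape = NULL) {
  stopifnot(is.matrix(image))
  d <- dim(image)
  if (is.null(shape)) shape <- as.integer(16 * ceiling(d / 16))
  r0 <- floor((shape[1L] - d[1L]) / 2)   # target row of source row 1, minus 1
  c0 <- floor((shape[2L] - d[2L]) / 2)
  out <- matrix(0, shape[1L], shape[2L])
  tr <- intersect(seq_len(shape[1L]), seq_len(d[1L]) + r0)
  tc <- intersect(seq_len(shape[2L]), seq_len(d[2L]) + c0)
  out[tr, tc] <- image[tr - r0, tc - c0]
  attr(out, "pad_offsets") <- list(orig = d, r0 = r0, c0 = c0)
  out
}

#' Undo [pad_to_model_input()]
#'
#' Maps a model-geometry image back onto the source geometry; regions that
#' were cropped away by the padding stage are restored as 0 (background).
#'
#' @param image Matrix in the model geometry.
#' @param offsets The `pad_offsets` attribute recorded when padding.
#' @return Matrix of the original shape.
#' @export
unpad_image <- function(image, offsets) {
  d <- offsets$orig
  out <- matrix(0, d[1L], d[2L])
  tr <- intersect(seq_len(nrow(image)), seq_len(d[1L]) + offsets$r0)
  tc <- intersect(seq_len(ncol(image)), seq_len(d[2L]) + offsets$c0)
  out[tr - offsets$r0, tc - offsets$c0] <- image[tr, tc]
  out
}

#' Convert a built category to model-ready samples
#'
#' Scales images to `[0, 1]`, equalizes image/mask widths (the attribute
#' column position is background in the mask), and center-pads both to a
#' common model input shape with shared offsets.
#'
#' @param dataset A `femaug_dataset` from [build_category()].
#' @param shape Target model input `c(rows, cols)`; default: maximum slice
#'   shape rounded up to the next multiple of 16.
#' @return List of samples `list(x, y, scan, z, posture)`; `x` carries the
#'   `pad_offsets` attribute.
#' @export
prepare_samples <- function(dataset, shape = NULL) {
  if (is.null(shape)) {
    dims <- vapply(dataset, function(s) dim(s$image), integer(2))
    shape <- as.integer(16 * ceiling(c(max(dims[1, ]), max(dims[2, ])) / 16))
  }
  lapply(dataset, function(s) {
    msk <- s$mask
    extra <- ncol(s$image) - ncol(msk)
    if (extra > 0) msk <- cbind(msk, matrix(0, nrow(msk), extra))
    x <- pad_to_model_input(s$image / 255, shape)
    y <- pad_to_model_input(msk, shape)
    attr(y, "pad_offsets") <- attr(x, "pad_offsets")
    list(x = x, y = y, scan = s$scan, z = s$z, posture = s$posture)
  })
}

#' Split scan ids into train/validation/test sets
#'
#' Scan-level split (no slice leakage): sizes are `floor(n * ratio)` with
#' the remainder assigned to the training set; 120 scans at 60:20:20 give
#' 72/24/24.
#'
#' @param scan_ids Vector of scan identifiers.
#' @param ratios Percentages summing to 100 (default `c(60, 20, 20)`).
#' @param seed Integer seed for the shuffle.
#' @return List with `train`, `val`, `test`.
#' @export
split_dataset <- function(scan_ids, ratios = c(60, 20, 20), seed = 1L) {
  if (length(scan_ids) < 3L) stop("need at least 3 scans to split")
  if (!isTRUE(all.equal(sum(ratios), 100))) stop("ratios must sum to 100")
  n <- length(scan_ids)
  sizes <- floor(n * ratios / 100)
  sizes[1L] <- sizes[1L] + (n - sum(sizes))   # remainder to train
  set.seed(seed)
  perm <- sample(scan_ids)
  list(train = perm[seq_len(sizes[1L])],
       val = perm[sizes[1L] + seq_len(sizes[2L])],
       test = perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])])
}
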