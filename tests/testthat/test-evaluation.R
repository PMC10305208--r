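test_that("DSC and IoU follow their set definitions", {
  A <- matrix(c(1, 1, 0, 0), 2); B <- matrix(c(1, 0, 1, 0), 2)
  expect_equal(dsc(A, B), 0.5)     # |A|=|B|=2, overlap 1
  expect_equal(iou(A, B), 1 / 3)
  expect_equal(dsc(A, A), 1)
  expect_equal(iou(A, A), 1)
  Z <- matrix(0, 2, 2)
  expect_equal(dsc(A, 1 - A), 0)   # disjoint non-empty
  expect_equal(iou(A, 1 - A), 0)
  expect_equal(dsc(Z, Z), 1)       # both-empty convention
  expect_equal(iou(Z, Z), 1)
  expect_error(dsc(A, matrix(0, 3, 2)), "shape mismatch")
  expect_error(iou(A, matrix(2, 2, 2)), "binary")
})

test_that("IoU = DSC/(2-DSC) and IoU <= DSC hold pairwise", {
  set.seed(31)
  for (k in 1:200) {
    A <- random_mask(5, 5); B <- random_mask(5, 5)
    d <- dsc(A, B); j <- iou(A, B)
    expect_equal(j, d / (2 - d))
    expect_lte(j, d)
    # set-enumeration oracle
    sa <- which(A == 1); sb <- which(B == 1)
    uni <- length(union(sa, sb))
    expect_equal(j, if (uni == 0) 1 else length(intersect(sa, sb)) / uni)
  }
})

test_that("volumes assemble in order and slice back losslessly", {
  m <- random_mask(4, 6)
  vol <- assemble_volume(list(m, m, m))
  expect_equal(dim(vol), c(3L, 4L, 6L))
  for (k in 1:3) expect_equal(vol[k, , ], m)
  masks <- lapply(1:5, function(i) random_mask(4, 4))
  vol2 <- assemble_volume(masks)
  expect_equal(sum(vol2), sum(vapply(masks, sum, 1)))
  for (k in 1:5) expect_equal(vol2[k, , ], masks[[k]])
  expect_error(assemble_volume(list(m, random_mask(3, 3))), "inconsistent")
})

test_that("six-view renders respect symmetry and degenerate inputs", {
  vol <- array(0, dim = c(10, 10, 10))
  vol[4:7, 4:7, 4:7] <- 1   # centered cube
  v <- render_views(vol)
  expect_named(v, c("front", "rear", "left", "right", "top", "bottom"))
  expect_equal(v$front, v$rear[, rev(seq_len(ncol(v$rear)))])
  expect_equal(v$left, v$right[, rev(seq_len(ncol(v$right)))])
  expect_message(bv <- render_views(array(0, dim = c(4, 4, 4))), "empty")
  expect_true(all(vapply(bv, sum, 1) == 0))
  one <- array(0, dim = c(6, 6, 6)); one[3, 4, 5] <- 1
  sv <- render_views(one)
  for (vn in names(sv)) expect_equal(sum(sv[[vn]] > 0), 1)
})

test_that("the spectral angle has its closed-form values and invariances", {
  expect_equal(sam(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(sam(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(sam(c(1, 0), c(1, 1)), acos(1 / sqrt(2)))
  t <- runif(16); r <- runif(16)
  expect_equal(sam(3.7 * t, r), sam(t, r))
  expect_equal(sam(t, r), sam(r, t))
  expect_error(sam(c(0, 0), c(1, 1)), "zero vector")
  expect_error(sam(1:3, 1:4), "length")
})

test_that("global SSIM is 1 on identity, symmetric, and collapses on
           disjoint constants", {
  x <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  expect_equal(ssim(x, x), 1)
  y <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  expect_equal(ssim(x, y), ssim(y, x))
  # constant 0 vs constant 255: luminance term ~ c1/(255^2 + c1)
  v <- ssim(matrix(0, 4, 4), matrix(255, 4, 4))
  expect_equal(v, (0.01 * 255)^2 / (255^2 + (0.01 * 255)^2))
  expect_lt(v, 0.001)
  expect_error(ssim(x, matrix(0, 4, 4)), "shape")
})

test_that("run evaluation aggregates per-scan scores and view metrics", {
  set.seed(33)
  gts <- list(a = array(rbinom(4 * 6 * 6, 1, 0.3), c(4, 6, 6)),
              b = array(rbinom(4 * 6 * 6, 1, 0.3), c(4, 6, 6)))
  rep1 <- evaluate_run(gts, gts)
  expect_equal(rep1$per_scan$dsc, c(1, 1))
  expect_equal(rep1$mean_dsc, 1)
  expect_equal(rep1$mean_iou, 1)
  expect_true(all(rep1$view_metrics$sam == 0))
  expect_true(all(rep1$view_metrics$ssim == 1))
  expect_equal(nrow(rep1$per_scan), 2L)
  preds <- lapply(gts, function(v) { v[1, , ] <- 0; v })
  rep2 <- evaluate_run(preds, gts, views = FALSE)
  expect_equal(rep2$mean_dsc, mean(rep2$per_scan$dsc))
  expect_error(evaluate_run(preds[1], gts), "unpaired")
  # per-slice mode averages slice scores
  rep3 <- evaluate_run(preds, gts, views = FALSE, per_slice = TRUE)
  manual <- mean(vapply(1:4, function(k)
    dsc(gts$a[k, , ], preds$a[k, , ]), numeric(1)))
  expect_equal(rep3$per_scan$dsc[rep3$per_scan$scan == "a"], manual)
})
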