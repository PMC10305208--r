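test_that("projection profiles equal hand-computed scaled sums", {
  img <- rbind(c(100, 0), c(100, 100))
  expect_equal(vertical_projection(img), c(2, 1))
  expect_equal(horizontal_projection(img), c(1, 2))
  expect_equal(vertical_projection(matrix(0, 3, 4)), rep(0, 4))
  expect_equal(vertical_projection(matrix(50), Sc = 100), 0.5)
  expect_error(vertical_projection(matrix(numeric(0), 0, 0)), "empty")
})

test_that("projections match a per-element loop oracle and conserve mass", {
  set.seed(21)
  for (k in 1:10) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    v <- numeric(8); h <- numeric(8)
    for (j in 1:8) for (i in 1:8) {
      v[j] <- v[j] + img[i, j] / 100
      h[i] <- h[i] + img[i, j] / 100
    }
    expect_equal(vertical_projection(img), v)
    expect_equal(horizontal_projection(img), h)
    expect_equal(sum(v), sum(img) / 100)
    expect_equal(sum(h), sum(img) / 100)
    expect_equal(horizontal_projection(img), vertical_projection(t(img)))
  }
})

test_that("threshold extents are tight first/last crossings", {
  expect_equal(threshold_extent(c(0, 6, 7, 0, 5, 0), 5), c(lo = 2, hi = 5))
  expect_null(threshold_extent(c(1, 2, 3), 10))
  expect_equal(threshold_extent(rep(4, 7), 4), c(lo = 1, hi = 7))
})

test_that("a single bright cuboid is localized to its exact extents", {
  vol <- array(0, dim = c(64, 96, 96))
  vol[11:30, 21:50, 31:70] <- 1000
  box <- scan_bounding_box(vol)   # clinical thresholds 50/5
  expect_equal(unname(box$z), c(11, 30))
  expect_equal(unname(box$y), c(21, 50))
  expect_equal(unname(box$x), c(31, 70))
  # brute-force voxel oracle
  idx <- which(vol >= 499, arr.ind = TRUE)
  expect_equal(unname(box$z), range(idx[, 1]))
  expect_equal(unname(box$y), range(idx[, 2]))
  expect_equal(unname(box$x), range(idx[, 3]))
})

test_that("two disjoint blobs produce a spanning box", {
  vol <- array(0, dim = c(32, 64, 64))
  vol[9:24, 25:40, 11:22] <- 1000
  vol[9:24, 25:40, 43:54] <- 1000
  box <- scan_bounding_box(vol, thresholds = c(axial = 2, coronal = 5,
                                               sagittal = 5))
  expect_equal(unname(box$x), c(11, 54))
})

test_that("an empty volume raises the not-found error", {
  expect_error(scan_bounding_box(array(0, dim = c(8, 16, 16))),
               "target structure not found")
})

test_that("localization is deterministic and covers the phantom masks", {
  prof <- desk_profile()
  for (s in c(2, 9, 17)) {
    scan <- make_scan(s, posture = if (s %% 2) "supine" else "prone")
    box2 <- scan_bounding_box(scan$volume, thresholds = prof$thresholds)
    expect_identical(scan$box, box2)
    combined <- scan$mask | scan$right_mask
    expect_gte(coverage_fraction(scan$box, combined), 0.99)
    expect_equal(coverage_fraction(scan$box, combined, dilate = 2L), 1)
  }
})

test_that("bounding boxes serialize to 0-based JSON", {
  scan <- make_scan(4)
  f <- tempfile(fileext = ".json")
  write_bbox_json(scan$box, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$x$lo, scan$box$x[["lo"]] - 1)
  expect_equal(j$z$hi, scan$box$z[["hi"]] - 1)
})
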