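test_that("attribute schemes carry the documented coefficients", {
  small <- attribute_scheme("small")
  expect_equal(posture_coefficient(small, "supine"), 1)
  expect_equal(posture_coefficient(small, "prone"), 2)
  expect_equal(posture_coefficient(attribute_scheme("large"), "supine"), 5)
  expect_equal(posture_coefficient(attribute_scheme("large"), "prone"), 10)
  expect_equal(posture_coefficient(attribute_scheme("excessive"), "supine"), 10)
  expect_equal(posture_coefficient(attribute_scheme("excessive"), "prone"), 20)
  for (nm in c("small", "large", "excessive")) {
    sc <- attribute_scheme(nm)
    expect_gt(sc$prone, sc$supine)
    expect_gt(sc$supine, 0)
  }
  expect_error(posture_coefficient(small, "standing"), "posture")
  expect_error(attribute_scheme("huge"))
})

test_that("dataset categories cross cropping with the three schemes", {
  expect_false(dataset_category("F-I")$cropped)
  expect_null(dataset_category("F-I")$scheme)
  expect_true(dataset_category("F-II")$cropped)
  expect_null(dataset_category("F-II")$scheme)
  expect_equal(dataset_category("F-IV")$scheme$name, "large")
  expect_true(dataset_category("F-V")$cropped)
  expect_equal(dataset_category("F-V")$scheme$name, "excessive")
  expect_false(dataset_category("F-VII")$cropped)
  expect_equal(dataset_category("F-VII")$scheme$name, "large")
  expect_error(dataset_category("F-IX"), "unknown")
  expect_length(category_ids(), 8L)
})

test_that("crops are fixed-size, centered, and padded at the field edge", {
  box <- structure(list(x = c(lo = 200, hi = 300), y = c(lo = 220, hi = 280),
                        z = c(lo = 1, hi = 10)), class = "bbox3d")
  slice <- matrix(runif(512 * 512), 512, 512)
  out <- crop_slice(slice, box, "axial")
  expect_equal(dim(out), c(200L, 360L))
  expect_error(crop_slice(slice, box, "oblique"), "unknown plane")
  # box centered near the corner: output keeps its size, padded with zeros
  corner <- structure(list(x = c(lo = 1, hi = 20), y = c(lo = 1, hi = 20),
                           z = c(lo = 1, hi = 10)), class = "bbox3d")
  out2 <- crop_slice(slice, corner, "axial")
  expect_equal(dim(out2), c(200L, 360L))
  expect_true(all(out2[, 1:100] == 0))
  const <- crop_slice(matrix(7, 512, 512), box, "axial")
  expect_true(all(const == 7))
})

test_that("the attribute column appends without touching the pixels", {
  img <- matrix(as.numeric(sample(0:255, 12)), 3, 4)
  aug <- append_attribute_column(img, 5)
  expect_equal(dim(aug), c(3L, 5L))
  expect_true(all(aug[, 5] == 5))
  expect_identical(aug[, 1:4], img)
  expect_identical(append_attribute_column(img, 0)[, 5], rep(0, 3))
  expect_error(append_attribute_column(img, 300), "8-bit")
  expect_error(append_attribute_column(img, -1), "8-bit")
})

test_that("built categories honor cropping, augmentation, and posture", {
  prof <- desk_profile()
  scans <- list(make_scan(31, "supine"), make_scan(32, "prone"))
  f2 <- build_category(scans, "F-II", crop_sizes = prof$crop_sizes,
                       slices_per_scan = 2L)
  f4 <- build_category(scans, "F-IV", crop_sizes = prof$crop_sizes,
                       slices_per_scan = 2L)
  expect_equal(length(f2), length(f4))
  for (k in seq_along(f4)) {
    expect_equal(ncol(f4[[k]]$image), ncol(f2[[k]]$image) + 1L)
    expect_identical(f4[[k]]$image[, seq_len(ncol(f2[[k]]$image))],
                     f2[[k]]$image)
    coef <- if (f4[[k]]$posture == "prone") 10 else 5
    expect_true(all(f4[[k]]$image[, ncol(f4[[k]]$image)] == coef))
    # the appended column alone identifies the posture
    expect_equal(unique(f4[[k]]$image[, ncol(f4[[k]]$image)]) > 5,
                 f4[[k]]$posture == "prone")
  }
  # F-I emits plain contrast-windowed slices
  f1 <- build_category(scans[1], "F-I", slices_per_scan = 2L)
  z <- f1[[1]]$z
  expect_identical(f1[[1]]$image,
                   window_normalize(scans[[1]]$volume[z, , ],
                                    contrast_window()))
  # missing posture label fails only for augmented categories
  anon <- scans[1]
  anon[[1]]$posture <- NULL
  expect_error(build_category(anon, "F-IV", crop_sizes = prof$crop_sizes),
               "posture")
  expect_no_error(build_category(anon, "F-II", crop_sizes = prof$crop_sizes,
                                 slices_per_scan = 2L))
})

test_that("category construction is deterministic and masks stay aligned", {
  prof <- desk_profile()
  scans <- list(make_scan(33, "prone"))
  a <- build_category(scans, "F-IV", crop_sizes = prof$crop_sizes,
                      slices_per_scan = 3L)
  b <- build_category(scans, "F-IV", crop_sizes = prof$crop_sizes,
                      slices_per_scan = 3L)
  expect_identical(a, b)
  for (s in a) {
    expect_equal(ncol(s$image), ncol(s$mask) + 1L)  # masks get no column
    expect_equal(nrow(s$image), nrow(s$mask))
    expect_true(all(s$mask %in% c(0, 1)))
  }
  smp <- prepare_samples(a)
  for (s in smp) {
    expect_identical(dim(s$x), dim(s$y))
    expect_equal(dim(s$x)[1] %% 16, 0)
    expect_equal(dim(s$x)[2] %% 16, 0)
  }
})

test_that("categories round-trip through PNG on disk", {
  prof <- desk_profile()
  scans <- list(make_scan(34, "supine"))
  ds <- build_category(scans, "F-III", crop_sizes = prof$crop_sizes,
                       slices_per_scan = 1L)
  dir <- file.path(tempdir(), "cat-f3")
  write_category_png(ds, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$category, "F-III")
  img <- read_gray_png(file.path(dir, "scan034", "axial",
                                 sprintf("%04d.png", ds[[1]]$z)))
  expect_equal(img, unname(ds[[1]]$image))
})
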