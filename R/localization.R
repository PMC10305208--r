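#' Histogram projection profiles of a grayscale slice
#'
#' The vertical projection of an image sums each column and divides by the
#' scaling constant `Sc`; the horizontal projection does the same per row.
#' Bright bone pixels dominate the sums on bone-windowed slices, so the
#' threshold crossings of the profiles bracket the femur pair.
#'
#' @param image Numeric matrix (grayscale slice, rows x columns).
#' @param Sc Positive scaling divisor; default 100.
#' @return Numeric vector: one value per column (`vertical_projection`) or
#'   per row (`horizontal_projection`).
#' @examples
#' vertical_projection(rbind(c(100, 0), c(100, 100)))    # 2, 1
#' horizontal_projection(rbind(c(100, 0), c(100, 100)))  # 1, 2
#' @export
vertical_projection <- function(image, Sc = 100) {
  stopifnot(Sc > 0)
  if (!is.matrix(image) || length(image) == 0L) stop("empty image")
  colSums(image) / Sc
}

#' @rdname vertical_projection
#' @export
horizontal_projection <- function(image, Sc = 100) {
  stopifnot(Sc > 0)
  if (!is.matrix(image) || length(image) == 0L) stop("empty image")
  rowSums(image) / Sc
}

#' First/last threshold crossing of a projection profile
#'
#' Returns the first and last indices at which the profile is at or above
#' the threshold; `NULL` when no element qualifies (absence is a value,
#' not an error).
#'
#' @param profile Numeric vector of projection values.
#' @param threshold Non-negative scalar, in the units of the scaled profile.
#' @return `c(lo = , hi = )` (1-based, inclusive) or `NULL`.
#' @examples
#' threshold_extent(c(0, 6, 7, 0, 5, 0), 5)  # lo = 2, hi = 5
#' @export
threshold_extent <- function(profile, threshold) {
  stopifnot(threshold >= 0)
  qualifying <- which(profile >= threshold)
  if (length(qualifying) == 0L) return(NULL)
  c(lo = min(qualifying), hi = max(qualifying))
}

#' Per-plane projection thresholds
#'
#' The clinical reference thresholds are 50 for axial-plane profiles and 5
#' for coronal and sagittal ones (applied to Sc-scaled profiles of
#' bone-windowed 512 x 512 slices). Profile sums scale with the amount of
#' cortical bone a profile line crosses, so desk-scale phantoms use
#' thresholds stated in equivalent cortical-bone pixels instead (see
#' [desk_profile()]).
#'
#' @return Named numeric vector `c(axial = , coronal = , sagittal = )`.
#' @export
localization_thresholds <- function() {
  c(axial = 50, coronal = 5, sagittal = 5)
}

plane_extents <- function(img, thr, Sc) {
  v <- threshold_extent(vertical_projection(img, Sc), thr)   # columns
  h <- threshold_extent(horizontal_projection(img, Sc), thr) # rows
  if (is.null(v) || is.null(h)) return(NULL)
  list(cols = v, rows = h)
}

mean_extent <- function(lo_values, hi_values) {
  c(lo = floor(mean(lo_values)), hi = ceiling(mean(hi_values)))
}

#' Bounding box of the femur pair by histogram projection
#'
#' Every axial, coronal, and sagittal slice of the volume is bone-windowed
#' to 8-bit grayscale and reduced to its vertical/horizontal projection
#' profiles; per slice, the tight first/last threshold crossings give a
#' candidate extent, and per axis the candidate `lo` values are averaged
#' (floored) and the `hi` values averaged (ceiled) over all contributing
#' slices. Each axis is seen by exactly two of the three planes; the two
#' plane-level means are merged by covering union (smallest `lo`, largest
#' `hi`), since every plane yields a conservative estimate and the box
#' must cover the organ for cropping. Slices in which either profile never
#' reaches the threshold contribute nothing.
#'
#' @param volume 3D HU array indexed `[z, y, x]`.
#' @param bone_window A [window_spec()]; default the 300/400 bone window.
#' @param thresholds Named vector as from [localization_thresholds()].
#' @param Sc Projection scaling divisor (default 100).
#' @return Object of class `bbox3d`: list with elements `x`, `y`, `z`,
#'   each `c(lo = , hi = )` in 1-based voxel indices.
#' @export
scan_bounding_box <- function(volume, bone_window = femaug::bone_window(),
                              thresholds = localization_thresholds(),
                              Sc = 100) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L || any(d == 0L)) stop("volume non-empty 3D array required")
  gray <- window_volume(volume, bone_window)
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]

  acc <- list(x = list(), y = list(), z = list())
  push <- function(axis, ext) {
    acc[[axis]][[length(acc[[axis]]) + 1L]] <<- ext
  }
  # axial plane: rows = y, cols = x
  for (k in seq_len(nz)) {
    e <- plane_extents(gray[k, , , drop = TRUE], thresholds[["axial"]], Sc)
    if (!is.null(e)) { push("x", e$cols); push("y", e$rows) }
  }
  # coronal plane: rows = z, cols = x
  for (k in seq_len(ny)) {
    e <- plane_extents(gray[, k, , drop = TRUE], thresholds[["coronal"]], Sc)
    if (!is.null(e)) { push("x2", e$cols); push("z", e$rows) }
  }
  # sagittal plane: rows = z, cols = y
  for (k in seq_len(nx)) {
    e <- plane_extents(gray[, , k, drop = TRUE], thresholds[["sagittal"]], Sc)
    if (!is.null(e)) { push("y2", e$cols); push("z2", e$rows) }
  }

  if (all(vapply(acc, length, 1L) == 0L))
    stop("target structure not found: no slice reaches the projection threshold")

  axis_extent <- function(primary, secondary, n) {
    planes <- list()
    for (nm in c(primary, secondary)) {
      exts <- acc[[nm]]
      if (is.null(exts) || length(exts) == 0L) next
      lo <- vapply(exts, `[[`, 1, "lo")
      hi <- vapply(exts, `[[`, 1, "hi")
      planes[[length(planes) + 1L]] <- mean_extent(lo, hi)
    }
    if (length(planes) == 0L)
      stop("target structure not found: no qualifying slice for an axis")
    # covering union of the plane-level means
    lo <- min(vapply(planes, `[[`, 1, "lo"))
    hi <- max(vapply(planes, `[[`, 1, "hi"))
    c(lo = max(1, lo), hi = min(n, hi))
  }

  box <- structure(list(x = axis_extent("x", "x2", nx),
                        y = axis_extent("y", "y2", ny),
                        z = axis_extent("z", "z2", nz)),
                   class = "bbox3d")
  box
}

#' @export
print.bbox3d <- function(x, ...) {
  cat(sprintf("bounding box (1-based voxel indices): x [%d, %d], y [%d, %d], z [%d, %d]\n",
              x$x[["lo"]], x$x[["hi"]], x$y[["lo"]], x$y[["hi"]],
              x$z[["lo"]], x$z[["hi"]]))
  invisible(x)
}

#' Write a bounding box as JSON (0-based indices)
#'
#' @param box A `bbox3d`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bbox_json <- function(box, path) {
  stopifnot(inherits(box, "bbox3d"))
  zero <- lapply(box[c("x", "y", "z")],
                 function(e) list(lo = unname(e[["lo"]]) - 1L,
                                  hi = unname(e[["hi"]]) - 1L))
  jsonlite::write_json(zero, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
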