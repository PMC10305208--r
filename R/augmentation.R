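#' Posture attribute schemes
#'
#' A scheme assigns a constant 8-bit coefficient to each lying posture:
#' small = (1 supine, 2 prone), large = (5, 10), excessive = (10, 20).
#' The prone coefficient is always the larger one, because the prone
#' posture is the special case that displaces the femur pair.
#'
#' @param name One of `"small"`, `"large"`, `"excessive"`.
#' @return List with `name`, `supine`, `prone`.
#' @examples
#' attribute_scheme("large")  # supine 5, prone 10
#' @export
attribute_scheme <- function(name = c("small", "large", "excessive")) {
  name <- match.arg(name)
  coefs <- switch(name,
                  small     = c(supine = 1, prone = 2),
                  large     = c(supine = 5, prone = 10),
                  excessive = c(supine = 10, prone = 20))
  list(name = name, supine = unname(coefs[["supine"]]),
       prone = unname(coefs[["prone"]]))
}

#' Attribute coefficient for a posture
#'
#' @param scheme An [attribute_scheme()].
#' @param posture `"supine"` or `"prone"`.
#' @return The scheme's coefficient for the posture.
#' @examples
#' posture_coefficient(attribute_scheme("small"), "supine")  # 1
#' @export
posture_coefficient <- function(scheme, posture) {
  if (!is.list(scheme) || !all(c("supine", "prone") %in% names(scheme)))
    stop("invalid attribute scheme")
  if (!is.character(posture) || length(posture) != 1L ||
      !posture %in% c("supine", "prone"))
    stop("unknown posture label: ", paste(posture, collapse = ", "))
  scheme[[posture]]
}

#' Dataset categories F-I to F-VIII
#'
#' The eight input-dataset categories cross two factors: cropping to the
#' femur bounding box, and posture-attribute augmentation at one of three
#' coefficient scales. F-I = uncropped/none, F-II = cropped/none,
#' F-III/IV/V = cropped + small/large/excessive,
#' F-VI/VII/VIII = uncropped + small/large/excessive.
#'
#' @param id Category id, e.g. `"F-IV"`.
#' @return List with `id`, `cropped` (logical), `scheme` (or `NULL`).
#' @export
dataset_category <- function(id) {
  defs <- list(
    "F-I"    = list(cropped = FALSE, scheme = NULL),
    "F-II"   = list(cropped = TRUE,  scheme = NULL),
    "F-III"  = list(cropped = TRUE,  scheme = "small"),
    "F-IV"   = list(cropped = TRUE,  scheme = "large"),
    "F-V"    = list(cropped = TRUE,  scheme = "excessive"),
    "F-VI"   = list(cropped = FALSE, scheme = "small"),
    "F-VII"  = list(cropped = FALSE, scheme = "large"),
    "F-VIII" = list(cropped = FALSE, scheme = "excessive"))
  if (!id %in% names(defs)) stop("unknown dataset category: ", id)
  d <- defs[[id]]
  list(id = id, cropped = d$cropped,
       scheme = if (is.null(d$scheme)) NULL else attribute_scheme(d$scheme))
}

#' All eight category ids, in order
#' @return Character vector `F-I` ... `F-VIII`.
#' @export
category_ids <- function() {
  c("F-I", "F-II", "F-III", "F-IV", "F-V", "F-VI", "F-VII", "F-VIII")
}

#' Fixed per-plane crop sizes
#'
#' Crop windows are fixed-size per plane (rows x columns): the reference
#' sizes are axial 200 x 360, coronal 110 x 360, sagittal 110 x 200. For
#' smaller (phantom) geometries pass scaled sizes.
#'
#' @return Named list of `c(rows, cols)` per plane.
#' @export
crop_sizes_reference <- function() {
  list(axial = c(200L, 360L), coronal = c(110L, 360L), sagittal = c(110L, 200L))
}

box_plane_center <- function(box, plane) {
  mid <- function(e) (e[["lo"]] + e[["hi"]]) / 2
  switch(plane,
         axial    = c(row = mid(box$y), col = mid(box$x)),
         coronal  = c(row = mid(box$z), col = mid(box$x)),
         sagittal = c(row = mid(box$z), col = mid(box$y)),
         stop("unknown plane: ", plane))
}

#' Crop a slice to the fixed per-plane window centered on the bounding box
#'
#' The fixed window (see [crop_sizes_reference()]) is centered on the
#' bounding-box center in the slice's plane; pixels falling outside the
#' slice are padded with `pad_value`. No resampling is performed.
#'
#' @param slice Grayscale matrix (rows x columns, plane orientation:
#'   axial = y rows / x cols, coronal = z/x, sagittal = z/y).
#' @param box A `bbox3d` from [scan_bounding_box()].
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param sizes Per-plane crop sizes, named list of `c(rows, cols)`.
#' @param pad_value Fill value outside the slice (default 0, the grayscale
#'   floor).
#' @return Matrix of exactly the per-plane fixed size.
#' @export
crop_slice <- function(slice, box, plane,
                       sizes = crop_sizes_reference(), pad_value = 0) {
  if (!plane %in% c("axial", "coronal", "sagittal"))
    stop("unknown plane: ", plane)
  sz <- sizes[[plane]]
  ctr <- box_plane_center(box, plane)
  r0 <- floor(ctr[["row"]]) - floor(sz[1L] / 2) + 1L
  c0 <- floor(ctr[["col"]]) - floor(sz[2L] / 2) + 1L
  out <- matrix(pad_value, sz[1L], sz[2L])
  rr <- r0:(r0 + sz[1L] - 1L)
  cc <- c0:(c0 + sz[2L] - 1L)
  rin <- which(rr >= 1L & rr <= nrow(slice))
  cin <- which(cc >= 1L & cc <= ncol(slice))
  if (length(rin) && length(cin))
    out[rin, cin] <- slice[rr[rin], cc[cin]]
  out
}

#' Append the posture attribute column to a slice
#'
#' Adds one constant column holding the attribute coefficient as the new
#' last column; the original pixels are untouched. The coefficient is
#' written in raw 8-bit grayscale units.
#'
#' @param slice Grayscale matrix.
#' @param coefficient Scalar in `[0, 255]`.
#' @return Matrix one column wider than `slice`.
#' @examples
#' append_attribute_column(matrix(0, 3, 4), 5)
#' @export
append_attribute_column <- function(slice, coefficient) {
  stopifnot(is.matrix(slice))
  if (!is.numeric(coefficient) || length(coefficient) != 1L ||
      coefficient < 0 || coefficient > 255)
    stop("attribute coefficient outside the 8-bit range [0, 255]: ",
         coefficient)
  cbind(slice, coefficient, deparse.level = 0)
}

select_axial_slices <- function(box, nz, slices_per_scan = NULL) {
  zr <- box$z[["lo"]]:box$z[["hi"]]
  if (is.null(slices_per_scan) || slices_per_scan >= length(zr)) return(zr)
  unique(round(seq(box$z[["lo"]], box$z[["hi"]],
                   length.out = slices_per_scan)))
}

#' Build one dataset category from preprocessed scans
#'
#' For every scan, the contrast-windowed axial slices are (optionally)
#' cropped to the fixed-size window centered on the scan's bounding box,
#' (optionally) augmented with the posture attribute column, and paired
#' with identically cropped ground-truth masks. Masks never receive an
#' attribute column; the attribute position is background for the model.
#'
#' @param scans List of scans; each scan is a list with elements `id`,
#'   `volume` (HU array `[z, y, x]`), `mask` (binary array, same shape),
#'   `posture` (`"supine"`/`"prone"`), and `box` (a `bbox3d`; required when
#'   the category crops or when `slices_per_scan` is used to sample slices
#'   inside the located z-extent).
#' @param category A [dataset_category()] or category id string.
#' @param window Contrast window for the model input (default
#'   [contrast_window()]).
#' @param crop_sizes Per-plane fixed sizes (default
#'   [crop_sizes_reference()]).
#' @param slices_per_scan Number of axial slices sampled evenly inside the
#'   scan's located z-extent; `NULL` (default) emits every slice in that
#'   extent.
#' @return List of class `femaug_dataset`: one element per emitted slice
#'   with `scan`, `z`, `posture`, `image` (grayscale matrix, possibly one
#'   column wider than the mask), `mask` (binary matrix).
#' @export
build_category <- function(scans, category,
                           window = contrast_window(),
                           crop_sizes = crop_sizes_reference(),
                           slices_per_scan = NULL) {
  if (is.character(category)) category <- dataset_category(category)
  out <- list()
  for (scan in scans) {
    if (!is.null(category$scheme) && is.null(scan$posture))
      stop("missing posture label for scan ", scan$id,
           " in augmented category ", category$id)
    nz <- dim(scan$volume)[1L]
    zs <- if (!is.null(scan$box)) {
      select_axial_slices(scan$box, nz, slices_per_scan)
    } else if (category$cropped) {
      stop("category ", category$id, " requires a bounding box for scan ",
           scan$id)
    } else seq_len(nz)
    coef <- if (is.null(category$scheme)) NULL else
      posture_coefficient(category$scheme, scan$posture)
    for (z in zs) {
      img <- window_normalize(scan$volume[z, , , drop = TRUE], window)
      msk <- scan$mask[z, , , drop = TRUE] * 1
      if (category$cropped) {
        img <- crop_slice(img, scan$box, "axial", crop_sizes)
        msk <- crop_slice(msk, scan$box, "axial", crop_sizes, pad_value = 0)
      }
      if (!is.null(coef)) img <- append_attribute_column(img, coef)
      out[[length(out) + 1L]] <- list(scan = scan$id, z = z,
                                      posture = scan$posture,
                                      image = img, mask = msk)
    }
  }
  structure(out, class = c("femaug_dataset", "list"),
            category = category$id)
}

#' Write a built category to disk as 8-bit PNG pairs
#'
#' Layout: `<dir>/<scan>/axial/<index>.png` plus `<index>_mask.png`, with a
#' `manifest.json` recording scan ids, postures and slice indices.
#'
#' @param dataset A `femaug_dataset` from [build_category()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_category_png <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(category = attr(dataset, "category"), slices = list())
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    d <- file.path(dir, s$scan, "axial")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    png::writePNG(s$image / 255, file.path(d, sprintf("%04d.png", s$z)))
    png::writePNG(s$mask, file.path(d, sprintf("%04d_mask.png", s$z)))
    manifest$slices[[i]] <- list(scan = s$scan, z = s$z, posture = s$posture)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
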