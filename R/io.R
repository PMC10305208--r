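#' Read a CT volume in Hounsfield units
#'
#' Reads either a NIfTI file (values assumed to already be HU) or a
#' directory of 16-bit grayscale PNG slices (sorted by file name; stored
#' integers are converted to HU with `HU = stored + intercept`, the common
#' unsigned-PNG convention).
#'
#' @param path A `.nii`/`.nii.gz` file or a directory of PNG slices.
#' @param posture Optional posture label (`"supine"`/`"prone"`) attached
#'   to the volume.
#' @param intercept HU intercept for PNG stacks (default -1024).
#' @param scale Full-scale integer value of the PNG stack (default 65535
#'   for 16-bit slices; use 255 for 8-bit stacks).
#' @return List with `volume` (HU array `[z, y, x]`), `spacing` (mm, when
#'   known) and `posture`.
#' @export
read_hu_volume <- function(path, posture = NULL, intercept = -1024,
                           scale = 65535) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    files <- files[!grepl("_mask\\.png$", files)]
    if (length(files) == 0L) stop("no PNG slices found in ", path)
    slices <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m <- m[, , 1L]   # grayscale channel
      m * scale + intercept
    })
    vol <- assemble_hu(slices)
    return(list(volume = vol, spacing = NULL, posture = posture))
  }
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  spacing <- tryCatch(rev(RNifti::pixdim(img)), error = function(e) NULL)
  list(volume = aperm(a, c(3, 2, 1)), spacing = spacing, posture = posture)
}

assemble_hu <- function(slices) {
  d <- dim(slices[[1L]])
  vol <- array(0, dim = c(length(slices), d))
  for (k in seq_along(slices)) vol[k, , ] <- slices[[k]]
  vol
}

#' Write an 8-bit grayscale PNG
#'
#' @param image Matrix of integers in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly. Round-trips losslessly through
#'   [read_gray_png()].
#' @export
write_gray_png <- function(image, path) {
  stopifnot(all(image >= 0 & image <= 255))
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG back to 0..255 integers
#'
#' @param path PNG path.
#' @return Matrix of integers in `[0, 255]`.
#' @export
read_gray_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  round(m * 255)
}
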