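#' Hounsfield window specification
#'
#' A CT display window maps the Hounsfield-unit (HU) range centered at the
#' window level `WL` with width `WW` onto a grayscale range
#' `[ymin, ymax]`; HU outside the window saturate at the range ends.
#' The package uses two windows throughout: the bone window
#' (WL = 300 HU, WW = 400 HU) for femur localization and the soft-tissue
#' contrast window (WL = 120 HU, WW = 336 HU) for the images fed to the
#' segmentation model.
#'
#' @param WL Window level (midpoint of the displayed HU range), in HU.
#' @param WW Window width, in HU; must be >= 1.
#' @param ymin,ymax Output grayscale floor and ceiling. Defaults 0 and 255
#'   (8-bit PNG export).
#' @return An object of class `window_spec`.
#' @examples
#' bone_window()
#' window_spec(WL = 120, WW = 336)
#' @export
window_spec <- function(WL, WW, ymin = 0, ymax = 255) {
  stopifnot(is.numeric(WL), length(WL) == 1L, is.finite(WL),
            is.numeric(WW), length(WW) == 1L, is.finite(WW))
  if (WW < 1) stop("degenerate window: WW must be >= 1, got ", WW)
  if (!(ymin < ymax)) stop("ymin must be strictly less than ymax")
  if (ymin < 0 || ymax > 255)
    stop("[ymin, ymax] must be representable in 8 bits for PNG export")
  structure(list(WL = WL, WW = WW, ymin = ymin, ymax = ymax),
            class = "window_spec")
}

#' @rdname window_spec
#' @export
bone_window <- function() window_spec(WL = 300, WW = 400)

#' @rdname window_spec
#' @export
contrast_window <- function() window_spec(WL = 120, WW = 336)

#' @export
print.window_spec <- function(x, ...) {
  b <- compute_window_bounds(x)
  cat(sprintf("CT window: WL = %g HU, WW = %g HU -> saturation [%g, %g] HU, output [%g, %g]\n",
              x$WL, x$WW, b[["HUmin"]], b[["HUmax"]], x$ymin, x$ymax))
  invisible(x)
}

#' Saturation bounds of a CT window
#'
#' Computes the HU values at which the linear window map saturates:
#' `HUmin = WL - 0.5 - (WW - 1)/2` and `HUmax = WL - 0.5 + (WW - 1)/2`.
#' Inputs at or below `HUmin` map to `ymin`, inputs at or above `HUmax`
#' map to `ymax`. For the bone window (WL = 300, WW = 400) the bounds are
#' 100 and 499 HU.
#'
#' @param window A [window_spec()].
#' @return Named numeric vector `c(HUmin = , HUmax = )`.
#' @examples
#' compute_window_bounds(bone_window())  # 100, 499
#' @export
compute_window_bounds <- function(window) {
  window <- as_window_spec(window)
  half <- (window$WW - 1) / 2
  c(HUmin = window$WL - 0.5 - half, HUmax = window$WL - 0.5 + half)
}

as_window_spec <- function(window) {
  if (inherits(window, "window_spec")) return(window)
  if (is.list(window) && all(c("WL", "WW") %in% names(window)))
    return(window_spec(window$WL, window$WW,
                       ymin = if (is.null(window$ymin)) 0 else window$ymin,
                       ymax = if (is.null(window$ymax)) 255 else window$ymax))
  stop("not a window spec")
}

#' Window-level and normalize a CT slice to integer grayscale
#'
#' Applies the linear window map
#' `y = ((x - (WL - 0.5)) / (WW - 1) + 0.5) * (ymax - ymin) + ymin`
#' to every pixel, clips to `[ymin, ymax]`, and quantizes by rounding half
#' up. The map is monotone non-decreasing; HU at or below `HUmin` give
#' `ymin` and HU at or above `HUmax` give `ymax`.
#'
#' @param slice Numeric matrix of HU values (rows x columns). All values
#'   must be finite.
#' @param window A [window_spec()].
#' @return Integer-valued matrix of the same shape, in `[ymin, ymax]`.
#' @examples
#' window_normalize(matrix(c(100, 299.5, 499), 1), bone_window())
#' @export
window_normalize <- function(slice, window) {
  window <- as_window_spec(window)
  if (!is.matrix(slice)) slice <- as.matrix(slice)
  bad <- which(!is.finite(slice))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(slice))
    stop(sprintf("non-finite HU value at slice element [%d, %d]",
                 ij[1L], ij[2L]))
  }
  y <- ((slice - (window$WL - 0.5)) / (window$WW - 1) + 0.5) *
    (window$ymax - window$ymin) + window$ymin
  y <- pmin(pmax(y, window$ymin), window$ymax)
  out <- floor(y + 0.5)          # round half up, ties away from ymin
  storage.mode(out) <- "double"
  dim(out) <- dim(slice)
  out
}

#' Window-level every axial slice of a volume
#'
#' Convenience wrapper that applies [window_normalize()] to a full
#' `nz x ny x nx` HU array.
#'
#' @param volume 3D numeric array of HU values, indexed `[z, y, x]`.
#' @param window A [window_spec()].
#' @return Array of the same shape with grayscale values.
#' @export
window_volume <- function(volume, window) {
  stopifnot(length(dim(volume)) == 3L)
  window <- as_window_spec(window)
  if (any(!is.finite(volume))) stop("non-finite HU value in volume")
  y <- ((volume - (window$WL - 0.5)) / (window$WW - 1) + 0.5) *
    (window$ymax - window$ymin) + window$ymin
  y <- pmin(pmax(y, window$ymin), window$ymax)
  floor(y + 0.5)
}
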