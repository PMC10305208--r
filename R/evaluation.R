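#' Dice similarity coefficient of two binary masks
#'
#' `DSC(A, B) = 2 |A intersect B| / (|A| + |B|)`, where A is the
#' ground-truth region and B the prediction. When both masks are empty the
#' score is defined as 1 (perfect agreement on "nothing").
#'
#' @param A,B Binary arrays (0/1) of identical shape.
#' @return Fraction in `[0, 1]`.
#' @examples
#' dsc(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))  # 0.5
#' @export
dsc <- function(A, B) {
  check_mask_pair(A, B)
  sa <- sum(A); sb <- sum(B)
  if (sa + sb == 0) return(1)
  2 * sum(A * B) / (sa + sb)
}

#' Intersection over union (Jaccard index) of two binary masks
#'
#' `IoU(A, B) = |A intersect B| / |A union B|`; 1 when both masks are
#' empty. For any single pair, `IoU = DSC / (2 - DSC)`.
#'
#' @inheritParams dsc
#' @return Fraction in `[0, 1]`.
#' @examples
#' iou(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))  # 1/3
#' @export
iou <- function(A, B) {
  check_mask_pair(A, B)
  inter <- sum(A * B)
  uni <- sum(A) + sum(B) - inter
  if (uni == 0) return(1)
  inter / uni
}

check_mask_pair <- function(A, B) {
  if (!identical(dim2(A), dim2(B)))
    stop("mask shape mismatch: ", paste(dim2(A), collapse = "x"), " vs ",
         paste(dim2(B), collapse = "x"))
  if (any(A != 0 & A != 1) || any(B != 0 & B != 1))
    stop("masks must be strictly binary")
  invisible(TRUE)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Stack per-slice masks into a 3D volume
#'
#' @param masks List of equally-shaped binary matrices, in slice order;
#'   slice `k` lands at depth `k`.
#' @return 3D binary array `[z, y, x]`.
#' @export
assemble_volume <- function(masks) {
  stopifnot(length(masks) >= 1L)
  d <- dim(masks[[1L]])
  for (m in masks) if (!identical(dim(m), d))
    stop("inconsistent slice shapes in mask stack")
  vol <- array(0, dim = c(length(masks), d))
  for (k in seq_along(masks)) vol[k, , ] <- masks[[k]]
  vol
}

shade_depth <- function(first_hit, extent) {
  # first-hit depth (1 = nearest) mapped linearly to grayscale; no hit -> 0
  out <- matrix(0, nrow(first_hit), ncol(first_hit))
  hit <- is.finite(first_hit)
  if (extent > 1) {
    out[hit] <- round(255 * (extent - first_hit[hit] + 1) / extent)
  } else out[hit] <- 255
  out
}

first_hit_along <- function(vol, margin, reverse = FALSE) {
  # margin: 1 = along z, 2 = along y, 3 = along x; returns matrix of the
  # other two dims (in their natural order) of 1-based first-hit depths.
  d <- dim(vol)
  n <- d[margin]
  ord <- if (reverse) n:1 else seq_len(n)
  keep <- setdiff(1:3, margin)
  fh <- matrix(Inf, d[keep[1L]], d[keep[2L]])
  for (step in seq_along(ord)) {
    sl <- switch(margin,
                 vol[ord[step], , , drop = TRUE],
                 vol[, ord[step], , drop = TRUE],
                 vol[, , ord[step], drop = TRUE])
    new_hit <- sl > 0 & !is.finite(fh)
    fh[new_hit] <- step
  }
  fh
}

#' Orthographic depth-shaded views of a binary volume
#'
#' Renders the mask surface from the six axis-aligned directions (front,
#' left, rear, right, top, bottom): along each ray the first occupied
#' voxel's depth is mapped linearly to grayscale (nearest = 255). Opposite
#' views are produced as seen from the respective side, i.e. mirrored.
#' An empty volume renders as six blank images (with a message).
#'
#' @param volume 3D binary array `[z, y, x]`; front looks along +y, left
#'   along +x, top along +z.
#' @return Named list of six grayscale matrices.
#' @export
render_views <- function(volume) {
  stopifnot(length(dim(volume)) == 3L)
  if (sum(volume) == 0) message("render_views: empty volume, blank views")
  d <- dim(volume)
  flip_cols <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  views <- list(
    front  = shade_depth(first_hit_along(volume, 2L), d[2L]),            # z x x
    rear   = flip_cols(shade_depth(first_hit_along(volume, 2L, TRUE), d[2L])),
    left   = shade_depth(first_hit_along(volume, 3L), d[3L]),            # z x y
    right  = flip_cols(shade_depth(first_hit_along(volume, 3L, TRUE), d[3L])),
    top    = shade_depth(first_hit_along(volume, 1L), d[1L]),            # y x x
    bottom = flip_cols(shade_depth(first_hit_along(volume, 1L, TRUE), d[1L])))
  views
}

#' Spectral angle between two images
#'
#' The angle `acos(<t, r> / (||t|| ||r||))` between the flattened intensity
#' vectors of the two images, in radians; 0 means identical direction. The
#' angle is invariant to positive rescaling of either image.
#'
#' @param t,r Numeric arrays/vectors of identical length (prediction and
#'   reference); neither may be all zero.
#' @return Angle in radians, in `[0, pi]`.
#' @examples
#' sam(c(1, 0), c(1, 1))  # pi/4
#' @export
sam <- function(t, r) {
  t <- as.numeric(t); r <- as.numeric(r)
  if (length(t) != length(r)) stop("length mismatch")
  nt <- sqrt(sum(t^2)); nr <- sqrt(sum(r^2))
  if (nt == 0 || nr == 0) stop("undefined angle: zero vector")
  if (identical(t, r)) return(0)   # avoid 1-ulp acos noise on identity
  acos(pmin(1, pmax(-1, sum(t * r) / (nt * nr))))
}

#' Global structural similarity index of two grayscale images
#'
#' `SSIM(x, y) = (2 mu_x mu_y + c1)(2 sigma_xy + c2) /
#' ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))` with the standard
#' stabilizers `c1 = (k1 L)^2`, `c2 = (k2 L)^2`, computed from global
#' (whole-image) statistics. Identical images score 1.
#'
#' @param x,y Numeric matrices of identical shape.
#' @param L Dynamic range (default 255 for 8-bit grayscale).
#' @param k1,k2 Stabilizer constants (defaults 0.01 and 0.03).
#' @return Score in `[-1, 1]`.
#' @export
ssim <- function(x, y, L = 255, k1 = 0.01, k2 = 0.03) {
  if (!identical(dim2(x), dim2(y))) stop("shape mismatch")
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Score a set of predicted scans against ground truth
#'
#' Computes per-scan volume DSC and IoU (the default; a per-slice mode
#' averages over slices instead), cohort means, and per-view SAM/SSIM
#' between the six orthographic renders of each predicted and ground-truth
#' volume.
#'
#' @param predictions Named list of predicted binary volumes (or lists of
#'   slice masks, which are assembled).
#' @param ground_truths Named list of ground-truth volumes, same names.
#' @param views Compute the six-view SAM/SSIM comparison (default TRUE).
#' @param per_slice Average per-slice DSC/IoU instead of per-volume.
#' @param render_mode `"shaded"` renders depth-shaded surfaces,
#'   `"silhouette"` binary silhouettes (scaled to 0/255).
#' @return List of class `femaug_report`: `per_scan` data frame,
#'   `mean_dsc`, `mean_iou`, and (optionally) `view_metrics` data frame.
#' @export
evaluate_run <- function(predictions, ground_truths, views = TRUE,
                         per_slice = FALSE,
                         render_mode = c("shaded", "silhouette")) {
  render_mode <- match.arg(render_mode)
  ids <- names(ground_truths)
  if (is.null(ids) || !setequal(names(predictions), ids))
    stop("unpaired scans: prediction and ground-truth names differ")
  as_vol <- function(v) if (is.list(v)) assemble_volume(v) else v
  rows <- list(); vrows <- list()
  for (id in ids) {
    pv <- as_vol(predictions[[id]]); gv <- as_vol(ground_truths[[id]])
    if (per_slice) {
      nz <- dim(gv)[1L]
      ds <- mean(vapply(seq_len(nz), function(k) dsc(gv[k, , ], pv[k, , ]),
                        numeric(1)))
      jc <- mean(vapply(seq_len(nz), function(k) iou(gv[k, , ], pv[k, , ]),
                        numeric(1)))
    } else {
      ds <- dsc(gv, pv); jc <- iou(gv, pv)
    }
    rows[[id]] <- data.frame(scan = id, dsc = ds, iou = jc,
                             stringsAsFactors = FALSE)
    if (views) {
      rp <- suppressMessages(render_views(pv))
      rg <- suppressMessages(render_views(gv))
      if (render_mode == "silhouette") {
        rp <- lapply(rp, function(m) (m > 0) * 255)
        rg <- lapply(rg, function(m) (m > 0) * 255)
      }
      for (vn in names(rp)) {
        both_empty <- sum(rp[[vn]]) == 0 && sum(rg[[vn]]) == 0
        vrows[[paste(id, vn)]] <- data.frame(
          scan = id, view = vn,
          sam = if (both_empty) 0 else sam(rp[[vn]], rg[[vn]]),
          ssim = ssim(rp[[vn]], rg[[vn]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  per_scan <- do.call(rbind, rows)
  rownames(per_scan) <- NULL
  out <- list(per_scan = per_scan,
              mean_dsc = mean(per_scan$dsc), mean_iou = mean(per_scan$iou))
  if (views) {
    out$view_metrics <- do.call(rbind, unname(vrows))
  }
  structure(out, class = "femaug_report")
}

#' @export
print.femaug_report <- function(x, ...) {
  cat(sprintf("segmentation report: %d scans, mean DSC %.4f, mean IoU %.4f\n",
              nrow(x$per_scan), x$mean_dsc, x$mean_iou))
  if (!is.null(x$view_metrics))
    cat(sprintf("views: SAM %.3f-%.3f rad, SSIM %.3f-%.3f\n",
                min(x$view_metrics$sam), max(x$view_metrics$sam),
                min(x$view_metrics$ssim), max(x$view_metrics$ssim)))
  invisible(x)
}

#' Write an evaluation report as JSON and CSV
#'
#' @param report A `femaug_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_scan, file.path(dir, "per_scan.csv"),
                   row.names = FALSE)
  if (!is.null(report$view_metrics))
    utils::write.csv(report$view_metrics, file.path(dir, "view_metrics.csv"),
                     row.names = FALSE)
  jsonlite::write_json(list(mean_dsc = report$mean_dsc,
                            mean_iou = report$mean_iou),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
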