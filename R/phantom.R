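#' Configuration for a lower-abdomen CT phantom
#'
#' The phantom is geometric, not anatomical: a soft-tissue background with
#' two mirrored high-attenuation femur-like composites, each a vertical
#' cylindrical shaft topped by a spherical head (displaced medially and
#' anteriorly) and a lateral ellipsoidal greater trochanter. Supine scans
#' place the heads anteriorly with the left femur on the image right;
#' prone scans mirror the volume antero-posteriorly and left-right (a
#' prone patient is flipped on the couch), and jitter the pose. Cortical
#' bone attenuation sits inside the bone window so the composites are
#' localizable by histogram projection.
#'
#' @param shape Volume shape `c(nz, ny, nx)` in voxels.
#' @param soft_hu Soft-tissue background HU range (low, high).
#' @param bone_hu Bone HU range (low, high); must start at or above the
#'   bone-window floor so phantoms are localizable.
#' @param posture `"supine"` or `"prone"`.
#' @param noise_sd Additive Gaussian HU noise standard deviation.
#' @param spacing Voxel spacing in mm `c(z, y, x)`; default `c(3, 1, 1)`
#'   (3 mm slice thickness).
#' @param shaft_radius,head_radius,troch_radii,lateral_sep Geometry in
#'   voxels; defaults are fractions of the geometry (shaft radius 0.09 of
#'   the in-plane extent, head radius equal to the shaft radius,
#'   trochanter semi-axes matching the shaft in-plane and 0.08 x nz
#'   axially, lateral separation 0.44 of the in-plane extent). Head and
#'   trochanter are clamped radially to the shaft radius so the composite
#'   keeps uniform per-slice extents (see the methods vignette).
#' @param jitter Maximum absolute voxel jitter applied per scan to the
#'   femur pose (prone and cohort variation).
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64L, 128L, 128L),
                           soft_hu = c(20, 80),
                           bone_hu = c(300, 1200),
                           posture = "supine",
                           noise_sd = 15,
                           spacing = c(3, 1, 1),
                           shaft_radius = NULL,
                           head_radius = NULL,
                           troch_radii = NULL,
                           lateral_sep = NULL,
                           jitter = 2L) {
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  if (!posture %in% c("supine", "prone")) stop("posture must be supine or prone")
  if (bone_hu[1L] < 300)
    stop("bone HU floor below the bone window: phantom would not localize")
  s <- min(shape[2L], shape[3L])
  rs <- if (is.null(shaft_radius)) 0.09 * s else shaft_radius
  cfg <- list(shape = as.integer(shape), soft_hu = soft_hu, bone_hu = bone_hu,
              posture = posture, noise_sd = noise_sd, spacing = spacing,
              shaft_radius = rs,
              head_radius = if (is.null(head_radius)) rs else head_radius,
              troch_radii = if (is.null(troch_radii))
                c(rs, rs, 0.08 * shape[1L]) else troch_radii,
              lateral_sep = if (is.null(lateral_sep)) 0.44 * s else lateral_sep,
              jitter = jitter)
  needed <- cfg$lateral_sep / 2 +
    max(cfg$head_radius, cfg$troch_radii[1L]) + jitter
  if (needed > s / 2 - 1)
    stop("femur geometry exceeds the volume: reduce radii or separation")
  structure(cfg, class = "phantom_config")
}

# Analytic femur composite: parameter list for one side, in supine frame.
# Head and trochanter sit concentric on the shaft axis, radially inscribed
# in the shaft, so per-slice projection extents are uniform along the
# shaft: localized protrusions would create grazing slices whose short
# extents drag the averaged bounding-box coordinates inside the organ.
femur_geometry <- function(cfg, side, dx = 0, dy = 0, scale = 1) {
  nz <- cfg$shape[1L]; ny <- cfg$shape[2L]; nx <- cfg$shape[3L]
  sgn <- if (side == "left") 1 else -1   # supine: patient left = image right
  cx <- (nx + 1) / 2 + sgn * cfg$lateral_sep / 2 + dx
  cy <- 0.55 * ny + dy                   # slightly posterior of center
  rs <- cfg$shaft_radius * scale
  rh <- min(cfg$head_radius, cfg$shaft_radius) * scale
  z0 <- max(1, round(0.15 * nz)); z1 <- min(nz, round(0.92 * nz))
  list(
    shaft = list(cx = cx, cy = cy, r = rs, z0 = z0, z1 = z1),
    head  = list(cx = cx, cy = cy, cz = z1 - rh, r = rh),  # proximal dome
    troch = list(cx = cx, cy = cy, cz = round(0.35 * nz),
                 rx = min(cfg$troch_radii[1L], rs),
                 ry = min(cfg$troch_radii[2L], rs),
                 rz = cfg$troch_radii[3L]))
}

# Voxelize one composite on the [z, y, x] grid (vectorized inclusion tests).
voxelize_femur <- function(geom, shape) {
  nz <- shape[1L]; ny <- shape[2L]; nx <- shape[3L]
  z <- seq_len(nz); y <- seq_len(ny); x <- seq_len(nx)
  Z <- array(rep(z, times = ny * nx), dim = shape)
  Y <- array(rep(rep(y, each = nz), times = nx), dim = shape)
  X <- array(rep(x, each = nz * ny), dim = shape)
  g <- geom$shaft
  m <- ((X - g$cx)^2 + (Y - g$cy)^2 <= g$r^2) & (Z >= g$z0) & (Z <= g$z1)
  h <- geom$head
  m <- m | ((X - h$cx)^2 + (Y - h$cy)^2 + ((Z - h$cz) * 1)^2 <= h$r^2)
  t <- geom$troch
  m <- m | (((X - t$cx) / t$rx)^2 + ((Y - t$cy) / t$ry)^2 +
              ((Z - t$cz) / t$rz)^2 <= 1)
  m
}

#' Generate one CT phantom with ground-truth femur masks
#'
#' Builds the HU volume (soft-tissue background plus two bone composites
#' and additive Gaussian noise) together with exact binary masks of the
#' left and right composites. The prone posture mirrors the supine
#' geometry antero-posteriorly and left-right before jitter, so the image
#' side on which the left femur appears depends on the posture.
#'
#' @param cfg A [phantom_config()].
#' @param seed Integer seed; the same seed reproduces the phantom exactly.
#' @return List with `volume` (HU array `[z, y, x]`), `left_mask`,
#'   `right_mask` (binary arrays), `posture`, `spacing`, and `geometry`
#'   (the analytic parameters used).
#' @export
generate_phantom <- function(cfg = phantom_config(), seed = 1L) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(seed)
  shape <- cfg$shape
  nz <- shape[1L]; ny <- shape[2L]; nx <- shape[3L]

  j <- cfg$jitter
  dx <- sample(-j:j, 1L); dy <- sample(-j:j, 1L)
  scale <- stats::runif(1L, 0.9, 1.1)
  geomL <- femur_geometry(cfg, "left", dx, dy, scale)
  geomR <- femur_geometry(cfg, "right", dx, dy, scale)
  left <- voxelize_femur(geomL, shape)
  right <- voxelize_femur(geomR, shape)

  soft_base <- stats::runif(1L, cfg$soft_hu[1L] + 10, cfg$soft_hu[2L] - 10)
  soft <- soft_base + (cfg$soft_hu[2L] - cfg$soft_hu[1L]) / 4 *
    sin(outer(seq_len(ny) / ny * 2 * pi, seq_len(nx) / nx * 2 * pi, "+"))
  vol <- array(rep(soft, each = nz), dim = shape)
  bone_hu <- stats::runif(1L, cfg$bone_hu[1L] + 200, cfg$bone_hu[2L] - 200)
  vol[left | right] <- bone_hu
  vol <- vol + array(stats::rnorm(prod(shape), 0, cfg$noise_sd), dim = shape)

  if (cfg$posture == "prone") {   # flipped on the couch: mirror y and x
    vol <- vol[, ny:1, nx:1, drop = FALSE]
    left <- left[, ny:1, nx:1, drop = FALSE]
    right <- right[, ny:1, nx:1, drop = FALSE]
  }
  list(volume = vol, left_mask = left, right_mask = right,
       posture = cfg$posture, spacing = cfg$spacing,
       geometry = list(left = geomL, right = geomR, scale = scale,
                       bone_hu = bone_hu))
}

#' Generate a phantom cohort with a manifest
#'
#' Draws `n` phantoms with randomized pose jitter and posture labels;
#' exactly `round(n * prone_fraction)` scans are prone, assigned to a
#' seeded random subset. Per-phantom seeds are drawn once from the cohort
#' seed, so the cohort is fully reproducible.
#'
#' @param n Number of scans (>= 3).
#' @param prone_fraction Fraction of prone scans in `[0, 1]`.
#' @param base_cfg A [phantom_config()] used for every scan.
#' @param seed Cohort seed.
#' @return List with `scans` (each: `id`, `volume`, `mask` = left mask,
#'   `right_mask`, `posture`) and `manifest` (data frame of id, posture,
#'   seed).
#' @export
generate_cohort <- function(n, prone_fraction = 0.5,
                            base_cfg = phantom_config(), seed = 1L) {
  if (n < 3) stop("cohort needs at least 3 scans")
  if (prone_fraction < 0 || prone_fraction > 1)
    stop("prone_fraction outside [0, 1]")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  n_prone <- round(n * prone_fraction)
  prone_idx <- sample.int(n, n_prone)
  postures <- rep("supine", n)
  postures[prone_idx] <- "prone"

  scans <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- base_cfg
    cfg_i$posture <- postures[i]
    ph <- generate_phantom(cfg_i, seed = seeds[i])
    scans[[i]] <- list(id = sprintf("scan%03d", i), volume = ph$volume,
                       mask = ph$left_mask, right_mask = ph$right_mask,
                       posture = ph$posture)
  }
  manifest <- data.frame(id = vapply(scans, `[[`, "", "id"),
                         posture = postures, seed = seeds,
                         stringsAsFactors = FALSE)
  list(scans = scans, manifest = manifest)
}

#' Write a phantom to disk (NIfTI volume + mask, 8-bit preview PNGs)
#'
#' @param phantom Output of [generate_phantom()].
#' @param dir Output directory.
#' @param id Scan id used in file names.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir, id = "scan001") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(aperm(phantom$volume, c(3, 2, 1)),
                     file.path(dir, paste0(id, ".nii.gz")))
  RNifti::writeNifti(aperm(phantom$left_mask * 1L, c(3, 2, 1)),
                     file.path(dir, paste0(id, "_mask.nii.gz")))
  mid <- ceiling(dim(phantom$volume)[1L] / 2)
  png::writePNG(window_normalize(phantom$volume[mid, , ], bone_window()) / 255,
                file.path(dir, paste0(id, "_axial_bone.png")))
  invisible(dir)
}
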