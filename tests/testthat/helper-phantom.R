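# Shared fixtures: all synthetic, generated in code at test time.

# Fraction of mask voxels inside a bounding box, optionally dilated.
coverage_fraction <- function(box, mask, dilate = 0L) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(1)
  mean(idx[, 1] >= box$z[["lo"]] - dilate & idx[, 1] <= box$z[["hi"]] + dilate &
       idx[, 2] >= box$y[["lo"]] - dilate & idx[, 2] <= box$y[["hi"]] + dilate &
       idx[, 3] >= box$x[["lo"]] - dilate & idx[, 3] <= box$x[["hi"]] + dilate)
}

# One desk-scale scan with its located bounding box.
make_scan <- function(seed, posture = "supine", profile = desk_profile()) {
  cfg <- profile$phantom
  cfg$posture <- posture
  ph <- generate_phantom(cfg, seed = seed)
  box <- scan_bounding_box(ph$volume, thresholds = profile$thresholds)
  list(id = sprintf("scan%03d", seed), volume = ph$volume,
       mask = ph$left_mask, right_mask = ph$right_mask,
       posture = ph$posture, box = box, phantom = ph)
}

# Tiny U-Net weights with biases nudged off zero so finite differences
# never sit on a ReLU kink.
jittered_weights <- function(cfg) {
  p <- build_unet(cfg)
  for (nm in names(p))
    if (grepl("b$", nm))
      p[[nm]] <- p[[nm]] + stats::runif(length(p[[nm]]), 0.01, 0.05)
  p
}

random_mask <- function(nr, nc, p = 0.4) {
  matrix(stats::rbinom(nr * nc, 1, p), nr, nc)
}
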