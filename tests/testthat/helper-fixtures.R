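# fixtures are built in code; no binary data anywhere

# a template frame with selected points moved, as a 68 x 2 matrix
frame_with <- function(...) {
  pts <- neutral_template()$points
  mods <- list(...)
  for (id in names(mods)) pts[as.integer(id), ] <- mods[[id]]
  pts
}

random_frame_points <- function() {
  matrix(runif(136, 0, 640), ncol = 2)
}

# a tiny track from explicit eyebrow/lid y-positions on side A (fps 30)
track_from_y <- function(eyebrow_y, lid_y = rep(120, length(eyebrow_y))) {
  coords <- matrix(1, nrow = length(eyebrow_y), ncol = 136)
  coords[, 2 * 20] <- eyebrow_y
  coords[, 2 * 38] <- lid_y
  suppressWarnings(landmark_track(coords, fps = 30))
}

# a bare feature_series for direct kinematics tests
series_of <- function(values, feature = "FOREHEAD", side = "A", unit = "mm") {
  structure(list(feature = feature, side = side, values = values, unit = unit),
            class = "feature_series")
}

mm_scale <- function(t = 1) scale_calibration(t)
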