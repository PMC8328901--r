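#' @title 68-point facial landmark model
#' @description
#' The landmark model follows the common 68-point facial annotation scheme
#' (jaw 1-17, eyebrows 18-27, nose 28-36, eyes 37-48, mouth 49-68) in image
#' coordinates: x grows rightward, y grows downward, units are pixels.
#' Point ids are 1-based everywhere in the public interface.
#' @name landmark-model
NULL

FEATURES <- c("FOREHEAD", "MOUTH")
SIDES <- c("A", "B")
EXPRESSIONS <- c("FROWN", "SMILE")
HB_GRADES <- c("II", "III", "IV", "V")

#' Validate raw landmark coordinates into a landmark frame
#'
#' A frame is well-formed iff it holds exactly 68 finite planar points.
#'
#' @param raw_points a 68 x 2 numeric matrix (columns x, y), or a length-136
#'   numeric vector ordered `x1, y1, ..., x68, y68`.
#' @param frame_index 0-based ordinal of the frame within its track.
#' @param time_s timestamp in seconds.
#' @return an object of class `landmark_frame` with fields `frame_index`,
#'   `time_s` and `points` (a 68 x 2 matrix).
#' @examples
#' f <- validate_frame(matrix(0, 68, 2))
#' @export
validate_frame <- function(raw_points, frame_index = 0L, time_s = 0) {
  if (is.numeric(raw_points) && is.null(dim(raw_points))) {
    if (length(raw_points) %% 2 != 0) {
      stop(sprintf("malformed frame: odd coordinate count %d", length(raw_points)))
    }
    raw_points <- matrix(raw_points, ncol = 2, byrow = TRUE)
  }
  raw_points <- as.matrix(raw_points)
  if (nrow(raw_points) != 68 || ncol(raw_points) != 2) {
    stop(sprintf("malformed frame: expected 68 points, got %d", nrow(raw_points)))
  }
  storage.mode(raw_points) <- "double"
  bad <- which(!is.finite(raw_points[, 1]) | !is.finite(raw_points[, 2]))
  if (length(bad) > 0) {
    stop(sprintf("malformed frame: non-finite coordinate at point %s",
                 paste(bad, collapse = ", ")))
  }
  dimnames(raw_points) <- list(NULL, c("x", "y"))
  structure(
    list(frame_index = as.integer(frame_index), time_s = as.numeric(time_s),
         points = raw_points),
    class = "landmark_frame"
  )
}

#' Map of scored landmark ids for the two hemifaces
#'
#' Sides are labelled geometrically (`A`, `B`); which one is healthy is
#' resolved only through the track's `affected_side` metadata, never from the
#' landmark data itself. The defaults are the scored points of the 68-point
#' scheme: eyebrow 20/25, upper eyelid rim 38/45, lower eyelid rim 42/47,
#' mouth corner 49/55, shared mouth centre 63. The lower-eyelid ids are kept
#' for completeness of the model but take no part in scoring.
#'
#' @param a named list of point ids for side A: `eyebrow`, `upper_lid`,
#'   `lower_lid`, `corner`.
#' @param b same for side B.
#' @param center shared mouth-centre point id.
#' @return an object of class `side_point_map`.
#' @export
side_point_map <- function(a = list(eyebrow = 20L, upper_lid = 38L, lower_lid = 42L, corner = 49L),
                           b = list(eyebrow = 25L, upper_lid = 45L, lower_lid = 47L, corner = 55L),
                           center = 63L) {
  need <- c("eyebrow", "upper_lid", "lower_lid", "corner")
  for (side in list(a, b)) {
    if (!all(need %in% names(side))) {
      stop("side map must name ids: ", paste(need, collapse = ", "))
    }
  }
  ids_a <- unlist(a[need]); ids_b <- unlist(b[need]); center <- as.integer(center)
  all_ids <- c(ids_a, ids_b, center)
  if (any(all_ids < 1L | all_ids > 68L)) stop("point ids must be in 1..68")
  if (length(intersect(ids_a, ids_b)) > 0) stop("side id sets must be disjoint")
  if (center %in% c(ids_a, ids_b)) stop("mouth-centre id must belong to neither side")
  structure(list(A = lapply(a[need], as.integer),
                 B = lapply(b[need], as.integer),
                 center = center),
            class = "side_point_map")
}

#' Assemble validated frames into a landmark track
#'
#' @param frames list of `landmark_frame` objects, or a numeric matrix with
#'   one row per frame and 136 columns `x1, y1, ..., x68, y68`.
#' @param fps frames per second.
#' @param subject_id subject identifier.
#' @param affected_side one of `"A"`, `"B"`, `"none"`.
#' @param hb_label optional clinical label in `II, III, IV, V, normal`.
#' @param frame_index,time_s used when `frames` is a matrix; defaults are
#'   0-based consecutive frames at `1/fps` spacing.
#' @return an object of class `landmark_track`: coordinate matrix `coords`
#'   (n x 136), integer `frame`, numeric `time_s`, plus the metadata fields.
#' @export
landmark_track <- function(frames, fps, subject_id = "anon",
                           affected_side = c("none", "A", "B"),
                           hb_label = NULL, frame_index = NULL, time_s = NULL) {
  affected_side <- match.arg(affected_side)
  if (!is.null(hb_label)) {
    hb_label <- match.arg(hb_label, c(HB_GRADES, "normal"))
  }
  if (is.list(frames)) {
    frames <- lapply(frames, function(f) {
      if (!inherits(f, "landmark_frame")) stop("frames must be landmark_frame objects")
      f
    })
    coords <- do.call(rbind, lapply(frames, function(f) as.vector(t(f$points))))
    frame_index <- vapply(frames, `[[`, integer(1), "frame_index")
    time_s <- vapply(frames, `[[`, numeric(1), "time_s")
  } else {
    coords <- as.matrix(frames)
    if (ncol(coords) != 136) {
      stop(sprintf("coordinate matrix must have 136 columns, got %d", ncol(coords)))
    }
    n <- nrow(coords)
    if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
    if (is.null(time_s)) time_s <- frame_index / fps
  }
  frame_index <- as.integer(frame_index)
  if (any(diff(frame_index) <= 0)) stop("frame_index must be strictly increasing")
  if (any(diff(time_s) < 0)) stop("time_s must be non-decreasing")
  if (!all(is.finite(coords))) {
    bad <- which(!apply(is.finite(coords), 1, all))[1]
    stop(sprintf("non-finite coordinate in frame %d", frame_index[bad]))
  }
  duration <- if (length(time_s) > 1) max(time_s) - min(time_s) else 0
  if (duration > 0 && (duration < 15 || duration > 20)) {
    warning(sprintf("track duration %.1f s is outside the typical 15-20 s protocol", duration))
  }
  structure(
    list(coords = coords, frame = frame_index, time_s = as.numeric(time_s),
         fps = as.numeric(fps), subject_id = subject_id,
         affected_side = affected_side, hb_label = hb_label),
    class = "landmark_track"
  )
}

#' @export
print.landmark_track <- function(x, ...) {
  cat(sprintf("<landmark_track> subject %s: %d frames @ %g fps (%.1f s), affected side %s%s\n",
              x$subject_id, nrow(x$coords), x$fps,
              if (nrow(x$coords) > 1) diff(range(x$time_s)) else 0,
              x$affected_side,
              if (is.null(x$hb_label)) "" else paste0(", HB ", x$hb_label)))
  invisible(x)
}

n_frames <- function(track) nrow(track$coords)

#' Extract one frame from a track
#'
#' @param track a `landmark_track`.
#' @param i 1-based row position within the track.
#' @return a `landmark_frame`.
#' @export
track_frame <- function(track, i) {
  validate_frame(matrix(track$coords[i, ], ncol = 2, byrow = TRUE),
                 frame_index = track$frame[i], time_s = track$time_s[i])
}

point_xy <- function(frame, id) frame$points[id, ]

#' Per-side feature distance of one frame
#'
#' The two scored features are axis-projected distances, matching the planes
#' in which the movements are assessed: the forehead feature is the vertical
#' (y) separation between the eyebrow point and the upper-eyelid point of one
#' side; the mouth feature is the horizontal (x) separation between that
#' side's mouth corner and the shared mouth centre. `method = "euclidean"`
#' switches to the full planar distance.
#'
#' @param frame a `landmark_frame`.
#' @param feature `"FOREHEAD"` or `"MOUTH"`.
#' @param side `"A"` or `"B"`.
#' @param map a [side_point_map()].
#' @param scale a [scale_calibration()] or `NULL` to stay in pixels.
#' @param method `"projected"` (default) or `"euclidean"`.
#' @return non-negative distance in mm (px if `scale` is `NULL`).
#' @export
feature_distance <- function(frame, feature = c("FOREHEAD", "MOUTH"),
                             side = c("A", "B"), map = side_point_map(),
                             scale = NULL,
                             method = c("projected", "euclidean")) {
  feature <- match.arg(feature)
  side <- match.arg(side)
  method <- match.arg(method)
  ids <- map[[side]]
  if (feature == "FOREHEAD") {
    p <- point_xy(frame, ids$eyebrow); q <- point_xy(frame, ids$upper_lid)
    d <- if (method == "projected") abs(p["y"] - q["y"]) else sqrt(sum((p - q)^2))
  } else {
    p <- point_xy(frame, ids$corner); q <- point_xy(frame, map$center)
    d <- if (method == "projected") abs(p["x"] - q["x"]) else sqrt(sum((p - q)^2))
  }
  t_mm <- if (is.null(scale)) 1 else scale$t
  unname(d * t_mm)
}
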