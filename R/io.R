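#' @title File formats and the detector adapter
#' @description
#' Trajectory CSV (`frame,time_s,x1,y1,...,x68,y68`, '#' comments, 0-based
#' frames), windows JSON (0-based half-open frame intervals), report JSON,
#' and the pluggable per-frame landmark-detector adapter for video input.
#' @name io
NULL

TRACK_HEADER <- c("frame", "time_s",
                  paste0(rep(c("x", "y"), 68), rep(1:68, each = 2)))

#' Write a landmark track to trajectory CSV
#'
#' Coordinates are written with 17 significant digits so that a read
#' round-trips the track exactly; subject metadata travels in '#' comment
#' lines.
#'
#' @param track a [landmark_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# subject_id: %s", track$subject_id),
               sprintf("# fps: %.17g", track$fps),
               sprintf("# affected_side: %s", track$affected_side),
               sprintf("# hb_label: %s",
                       if (is.null(track$hb_label)) "NA" else track$hb_label),
               paste(TRACK_HEADER, collapse = ",")), con)
  rows <- vapply(seq_len(nrow(track$coords)), function(i) {
    paste(c(track$frame[i], sprintf("%.17g", track$time_s[i]),
            sprintf("%.17g", track$coords[i, ])), collapse = ",")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' Read a trajectory CSV into a landmark track
#'
#' Metadata can come from '#' comment lines written by [write_track_csv()]
#' or be supplied/overridden through the arguments. Structural problems
#' (wrong column count, non-numeric cells, non-monotone frame indices) are
#' reported with the offending line number.
#'
#' @param path trajectory CSV file.
#' @param subject_id,affected_side,hb_label,fps optional overrides; `fps`
#'   falls back to the median frame-to-frame time step.
#' @return a [landmark_track()].
#' @export
read_track_csv <- function(path, subject_id = NULL, affected_side = NULL,
                           hb_label = NULL, fps = NULL) {
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  meta <- function(key) {
    m <- grep(sprintf("^# %s:", key), comments, value = TRUE)
    if (length(m) == 0) return(NULL)
    v <- trimws(sub(sprintf("^# %s:", key), "", m[1]))
    if (identical(v, "NA")) NULL else v
  }
  body_at <- which(!grepl("^#", lines))
  if (length(body_at) < 2) stop("trajectory file has no data rows")
  header <- strsplit(lines[body_at[1]], ",", fixed = TRUE)[[1]]
  if (length(header) != 138) {
    stop(sprintf("line %d: expected 138 columns (frame,time_s + 136 coordinates), got %d",
                 body_at[1], length(header)))
  }
  if (!identical(header, TRACK_HEADER)) {
    stop(sprintf("line %d: header does not match frame,time_s,x1,y1,...,x68,y68",
                 body_at[1]))
  }
  data_lines <- body_at[-1]
  cells <- strsplit(lines[data_lines], ",", fixed = TRUE)
  nc <- lengths(cells)
  if (any(nc != 138)) {
    i <- which(nc != 138)[1]
    stop(sprintf("line %d: expected 138 columns, got %d", data_lines[i], nc[i]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(cells))),
              ncol = 138, byrow = TRUE)
  if (anyNA(m)) {
    i <- which(apply(is.na(m), 1, any))[1]
    stop(sprintf("line %d: non-numeric cell", data_lines[i]))
  }
  frame <- as.integer(m[, 1])
  if (any(diff(frame) <= 0)) {
    i <- which(diff(frame) <= 0)[1] + 1L
    stop(sprintf("line %d: frame index not strictly increasing (duplicate or out of order)",
                 data_lines[i]))
  }
  time_s <- m[, 2]
  if (is.null(fps)) {
    fps_meta <- meta("fps")
    fps <- if (!is.null(fps_meta)) as.numeric(fps_meta) else {
      dt <- median(diff(time_s))
      if (!is.finite(dt) || dt <= 0) stop("cannot infer fps from timestamps; pass fps=")
      1 / dt
    }
  }
  landmark_track(m[, -(1:2), drop = FALSE], fps = fps,
                 subject_id = subject_id %||% meta("subject_id") %||% "anon",
                 affected_side = affected_side %||% meta("affected_side") %||% "none",
                 hb_label = hb_label %||% meta("hb_label"),
                 frame_index = frame, time_s = time_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read/write movement-window annotations (JSON)
#'
#' Schema: `{"version": 1, "n_frames": N, "rest": [[a,b], ...],
#' "movement": {"FROWN": [a,b], "SMILE": [a,b]}}` with 0-based half-open
#' frame intervals.
#'
#' @param path JSON file.
#' @param n_frames track length used to validate the intervals; defaults to
#'   the file's own `n_frames` field.
#' @return a [movement_windows()].
#' @export
read_windows_json <- function(path, n_frames = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = FALSE)
  n <- n_frames %||% obj$n_frames
  if (is.null(n)) stop("windows JSON lacks n_frames and none was supplied")
  movement_windows(rest = lapply(obj$rest, unlist),
                   movement = lapply(obj$movement, unlist),
                   n_frames = n)
}

#' @rdname read_windows_json
#' @param windows a `movement_windows` to write.
#' @export
write_windows_json <- function(windows, path) {
  jsonlite::write_json(
    list(version = 1, n_frames = windows$n_frames,
         rest = windows$rest, movement = windows$movement),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assemble a track from a per-frame landmark detector
#'
#' The detector backend is injected: it is called once per frame index
#' (0-based) and must return a 68 x 2 coordinate matrix in the standard
#' numbering, or `NULL` when no face is found. Interior no-face gaps of at
#' most `max_gap_s` are filled by linear interpolation between the flanking
#' detections; longer gaps (or gaps touching either end of the recording)
#' split the track, which is reported as an error.
#'
#' @param n_frames number of frames to request from the backend.
#' @param backend `function(frame_index)` as described above.
#' @param fps frames per second of the source video.
#' @param max_gap_s largest interpolatable no-face gap, seconds.
#' @param ... metadata passed to [landmark_track()].
#' @return a [landmark_track()].
#' @export
detect_landmarks <- function(n_frames, backend, fps = 30, max_gap_s = 0.5, ...) {
  frames <- lapply(seq_len(n_frames) - 1L, function(i) {
    f <- backend(i)
    if (is.null(f)) return(NULL)
    f <- as.matrix(f)
    if (nrow(f) != 68 || ncol(f) != 2) {
      stop(sprintf("detector contract violation at frame %d: got %d x %d, expected 68 x 2",
                   i, nrow(f), ncol(f)))
    }
    f
  })
  missing_ <- vapply(frames, is.null, logical(1))
  if (mean(missing_) >= 0.5) {
    stop(sprintf("undetectable subject: no face in %d of %d frames",
                 sum(missing_), n_frames))
  }
  if (any(missing_)) {
    r <- rle(missing_)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    max_gap <- as.integer(floor(max_gap_s * fps))
    for (j in which(r$values)) {
      a <- starts[j]; b <- ends[j]
      if (a == 1 || b == n_frames || r$lengths[j] > max_gap) {
        stop(sprintf("track split: no-face gap of %d frame(s) at frames %d-%d exceeds the %.2g s interpolation limit",
                     r$lengths[j], a - 1L, b - 1L, max_gap_s))
      }
      left <- frames[[a - 1L]]; right <- frames[[b + 1L]]
      for (i in a:b) {
        w <- (i - (a - 1L)) / (b + 1L - (a - 1L))
        frames[[i]] <- left * (1 - w) + right * w
      }
      message(sprintf("interpolated no-face gap at frames %d-%d", a - 1L, b - 1L))
    }
  }
  coords <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  landmark_track(coords, fps = fps, ...)
}

#' Run the full staging pipeline on one track
#'
#' Extracts the four feature series, resolves windows (annotations win over
#' auto-detection), measures the per-side shifts, assembles shift
#' differences and asymmetry indices, and assigns House-Brackmann grades.
#'
#' @param track a [landmark_track()] with `affected_side` set.
#' @param scale a [scale_calibration()] or `NULL` (pixel units; grading then
#'   falls back to the scale-free asymmetry indices).
#' @param windows optional `movement_windows` annotations.
#' @param map a [side_point_map()].
#' @param ranges a [grade_range_table()].
#' @param robust,smooth_median3,gap_rule tuning switches passed through.
#' @return an object of class `palsy_report`: `subject_id`, `scale`,
#'   `windows`, `result` (the `asymmetry_result`), `grades` (the
#'   `grade_assignment`).
#' @export
analyze_track <- function(track, scale = NULL, windows = NULL,
                          map = side_point_map(), ranges = default_grade_ranges(),
                          robust = FALSE, smooth_median3 = FALSE,
                          gap_rule = "nearest") {
  bundle <- extract_series(track, map = map, scale = scale,
                           smooth_median3 = smooth_median3)
  windows <- detect_windows(bundle, annotations = windows)
  shifts <- track_shifts(bundle, windows, robust = robust)
  result <- assemble_result(shifts, track$affected_side)
  grades <- grade_patient(result, table = ranges, gap_rule = gap_rule)
  structure(list(subject_id = track$subject_id,
                 hb_label = track$hb_label,
                 scale = scale, windows = windows,
                 shifts = shifts, result = result, grades = grades),
            class = "palsy_report")
}

#' @export
print.palsy_report <- function(x, ...) {
  cat(sprintf("<palsy_report> subject %s\n", x$subject_id))
  print(x$result)
  print(x$grades)
  invisible(x)
}

REPORT_SCHEMA_VERSION <- "1.0"

#' Write/read a staging report (JSON)
#'
#' The JSON report carries the subject metadata, scale, windows used, the
#' full asymmetry result with flags, and the grade assignment with its
#' rationale; reading a report back yields exactly the feature values that
#' produced the grades.
#'
#' @param report a `palsy_report`.
#' @param path output JSON file.
#' @return `path` invisibly; for `read_report`, the parsed report list.
#' @export
write_report <- function(report, path) {
  obj <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    tool = list(package = "faceshift",
                version = as.character(utils::packageVersion("faceshift"))),
    subject = list(subject_id = report$subject_id,
                   affected_side = report$result$affected_side,
                   hb_label = report$hb_label),
    scale = if (is.null(report$scale)) NULL else
      list(t = report$scale$t, source = report$scale$source),
    windows = list(rest = report$windows$rest,
                   movement = report$windows$movement,
                   n_frames = report$windows$n_frames),
    result = list(per_movement = report$result$per_movement,
                  total_shift_difference = report$result$total_shift_difference,
                  total_asymmetry_index = report$result$total_asymmetry_index,
                  unit = report$result$unit,
                  flags = report$result$flags),
    grades = list(per_feature = report$grades$per_feature,
                  combined_grade = report$grades$combined_grade,
                  combined_from = report$grades$combined_from,
                  rationale = report$grades$rationale))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path)
}

#' Export a report as a one-row CSV
#'
#' @param report a `palsy_report`.
#' @param path output CSV file.
#' @export
write_report_csv <- function(report, path) {
  pf <- report$grades$per_feature
  row <- as.data.frame(c(
    list(subject_id = report$subject_id,
         affected_side = report$result$affected_side,
         combined_grade = report$grades$combined_grade),
    stats::setNames(as.list(pf$value), tolower(pf$feature)),
    list(flags = paste(report$result$flags, collapse = ";"))))
  utils::write.csv(row, path, row.names = FALSE)
  invisible(path)
}
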