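#' @title Kinematics: from landmark tracks to per-side movement shifts
#' @description
#' A track is reduced to four distance-versus-time signals (forehead and
#' mouth, sides A and B). A shift is a side's maximum feature distance during
#' a movement minus its mean distance at rest; windows come either from an
#' explicit annotation or from a simple automatic segmentation of the
#' still-then-move recording protocol.
#' @name kinematics
NULL

#' Extract the four per-side feature series from a track
#'
#' @param track a [landmark_track()].
#' @param map a [side_point_map()].
#' @param scale a [scale_calibration()], or `NULL` to report pixels (the
#'   resulting series carry `unit = "px"` and are flagged non-comparable to
#'   millimetre-calibrated range tables).
#' @param method distance method passed to [feature_distance()].
#' @param smooth_median3 apply a centred moving median of width 3 frames to
#'   each series (off by default; intended for jittery detectors).
#' @return an object of class `feature_series_bundle`: a list with one
#'   `feature_series` per feature/side combination (named e.g. `FOREHEAD.A`),
#'   plus `fps`, `unit`, `affected_side` and the number of frames.
#' @export
extract_series <- function(track, map = side_point_map(), scale = NULL,
                           method = c("projected", "euclidean"),
                           smooth_median3 = FALSE) {
  method <- match.arg(method)
  t_mm <- if (is.null(scale)) 1 else scale$t
  unit <- if (is.null(scale)) "px" else "mm"
  xcol <- function(id) track$coords[, 2L * id - 1L]
  ycol <- function(id) track$coords[, 2L * id]
  series <- list()
  for (side in SIDES) {
    ids <- map[[side]]
    if (method == "projected") {
      fh <- abs(ycol(ids$eyebrow) - ycol(ids$upper_lid)) * t_mm
      mo <- abs(xcol(ids$corner) - xcol(map$center)) * t_mm
    } else {
      fh <- sqrt((xcol(ids$eyebrow) - xcol(ids$upper_lid))^2 +
                 (ycol(ids$eyebrow) - ycol(ids$upper_lid))^2) * t_mm
      mo <- sqrt((xcol(ids$corner) - xcol(map$center))^2 +
                 (ycol(ids$corner) - ycol(map$center))^2) * t_mm
    }
    if (smooth_median3) {
      fh <- moving_median3(fh)
      mo <- moving_median3(mo)
    }
    series[[paste0("FOREHEAD.", side)]] <-
      structure(list(feature = "FOREHEAD", side = side, values = fh, unit = unit),
                class = "feature_series")
    series[[paste0("MOUTH.", side)]] <-
      structure(list(feature = "MOUTH", side = side, values = mo, unit = unit),
                class = "feature_series")
  }
  structure(c(series,
              list(fps = track$fps, unit = unit, n = nrow(track$coords),
                   affected_side = track$affected_side)),
            class = "feature_series_bundle")
}

moving_median3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  out <- v
  out[2:(n - 1)] <- vapply(2:(n - 1), function(i) median(v[(i - 1):(i + 1)]), numeric(1))
  out
}

#' Rest and movement windows over a track
#'
#' Frame intervals are 0-based and half-open, `[a, b)`, matching the
#' trajectory file convention (point ids, by contrast, are 1-based).
#'
#' @param rest list of rest intervals, each `c(a, b)`.
#' @param movement named list with one interval per expression,
#'   `FROWN` and/or `SMILE`.
#' @param n_frames total frame count of the track the windows refer to.
#' @return an object of class `movement_windows`.
#' @export
movement_windows <- function(rest, movement, n_frames) {
  as_iv <- function(iv, what) {
    iv <- as.integer(iv)
    if (length(iv) != 2 || iv[1] < 0 || iv[2] > n_frames || iv[1] >= iv[2]) {
      stop(sprintf("%s interval [%s) is empty or out of track bounds [0, %d)",
                   what, paste(iv, collapse = ", "), n_frames))
    }
    iv
  }
  if (is.numeric(rest)) rest <- list(rest)
  rest <- lapply(rest, as_iv, what = "rest")
  if (length(rest) == 0) stop("at least one rest interval is required")
  unknown <- setdiff(names(movement), EXPRESSIONS)
  if (length(unknown) > 0) stop("unknown expression: ", paste(unknown, collapse = ", "))
  movement <- lapply(stats::setNames(names(movement), names(movement)),
                     function(e) as_iv(movement[[e]], paste(e, "movement")))
  for (e in names(movement)) {
    for (r in rest) {
      if (movement[[e]][1] < r[2] && r[1] < movement[[e]][2]) {
        stop(sprintf("%s movement window overlaps a rest interval", e))
      }
    }
  }
  if (all(c("FROWN", "SMILE") %in% names(movement))) {
    f <- movement$FROWN; s <- movement$SMILE
    if (f[1] < s[2] && s[1] < f[2]) stop("FROWN and SMILE windows overlap")
  }
  structure(list(rest = rest, movement = movement, n_frames = as.integer(n_frames)),
            class = "movement_windows")
}

iv_idx <- function(iv) (iv[1] + 1L):iv[2]  # 0-based half-open -> 1-based R indices

#' Detect rest and movement windows, or validate supplied annotations
#'
#' With `annotations` supplied they are validated against the track bounds and
#' returned verbatim — manual frame selection always wins. Otherwise the
#' recording protocol (still, then frown, then smile, returning to rest
#' between movements) is segmented automatically:
#' rest is the maximal initial interval during which every series stays within
#' `k_mad` times its initial-second MAD of its initial-second median (an
#' excursion must be sustained for 3 consecutive frames to end rest, so a
#' single jitter spike does not truncate the baseline); the FROWN window of
#' width `movement_s` is centred on the post-rest global maximum of the
#' healthy side's forehead series, and the SMILE window likewise on the
#' healthy mouth series. The protocol order (frown before smile) is enforced.
#'
#' @param bundle a `feature_series_bundle` from [extract_series()].
#' @param annotations optional `movement_windows` to validate and return.
#' @param k_mad rest threshold in MADs (default 3).
#' @param min_rest_s minimum acceptable rest duration, seconds (default 0.5).
#' @param movement_s movement window width, seconds (default 1).
#' @return a `movement_windows` object.
#' @export
detect_windows <- function(bundle, annotations = NULL, k_mad = 3,
                           min_rest_s = 0.5, movement_s = 1) {
  n <- bundle$n
  fps <- bundle$fps
  if (!is.null(annotations)) {
    if (!inherits(annotations, "movement_windows")) {
      stop("annotations must be a movement_windows object")
    }
    if (annotations$n_frames != n) {
      # re-validate the raw intervals against this track's bounds
      return(movement_windows(annotations$rest, annotations$movement, n))
    }
    return(annotations)
  }
  keys <- c(paste0("FOREHEAD.", SIDES), paste0("MOUTH.", SIDES))
  init <- 1:max(2L, min(n, as.integer(round(fps))))
  dev_ok <- matrix(TRUE, nrow = n, ncol = length(keys))
  for (j in seq_along(keys)) {
    v <- bundle[[keys[j]]]$values
    med <- median(v[init])
    mad_v <- stats::mad(v[init], center = med)  # 1.4826-scaled, sigma-consistent
    thr <- k_mad * max(mad_v, 1e-6 * max(abs(med), 1))
    dev_ok[, j] <- abs(v - med) <= thr
  }
  ok <- apply(dev_ok, 1, all)
  # rest ends at the first sustained (>= 3 frame) excursion
  bad_run <- !ok & !c(ok[-1], TRUE) & !c(ok[-(1:2)], TRUE, TRUE)
  rest_end <- if (any(bad_run)) which(bad_run)[1] - 1L else n
  if (rest_end < max(2L, as.integer(ceiling(min_rest_s * fps)))) {
    stop(sprintf("no rest baseline: initial still segment is %.2f s (< %.2f s minimum)",
                 rest_end / fps, min_rest_s))
  }
  if (rest_end >= n - 1L) {
    stop("no movement detected after the rest baseline; supply annotations")
  }
  healthy <- healthy_side(bundle$affected_side)
  w <- max(1L, as.integer(round(movement_s * fps)))
  centre_window <- function(key) {
    v <- if (is.null(healthy)) {
      pmax(bundle[[paste0(key, ".A")]]$values, bundle[[paste0(key, ".B")]]$values)
    } else {
      bundle[[paste0(key, ".", healthy)]]$values
    }
    post <- (rest_end + 1L):n
    apex <- post[which.max(v[post])] - 1L  # 0-based
    a <- max(rest_end, apex - w %/% 2L)
    b <- min(n, a + w)
    c(a, b)
  }
  frown <- centre_window("FOREHEAD")
  smile <- centre_window("MOUTH")
  if (smile[1] < frown[2]) {
    stop("detected SMILE window does not follow the FROWN window; supply annotations")
  }
  movement_windows(rest = list(c(0L, rest_end)),
                   movement = list(FROWN = frown, SMILE = smile),
                   n_frames = n)
}

healthy_side <- function(affected_side) {
  switch(affected_side, A = "B", B = "A", none = NULL)
}

#' Mean feature distance over the rest window(s)
#'
#' @param series a `feature_series`.
#' @param windows a `movement_windows`.
#' @return arithmetic mean of the series over the union of rest intervals.
#' @export
rest_mean <- function(series, windows) {
  idx <- unique(unlist(lapply(windows$rest, iv_idx)))
  if (length(idx) == 0) stop("empty rest window union")
  mean(series$values[idx])
}

#' Maximum feature distance over a movement window
#'
#' @param series a `feature_series`.
#' @param windows a `movement_windows`.
#' @param expression `"FROWN"` or `"SMILE"`.
#' @param robust use the 95th percentile instead of the maximum (off by
#'   default; the staging calibration was built on true maxima).
#' @return maximum (or 95th percentile) of the series over the window.
#' @export
max_excursion <- function(series, windows, expression = c("FROWN", "SMILE"),
                          robust = FALSE) {
  expression <- match.arg(expression)
  iv <- windows$movement[[expression]]
  if (is.null(iv)) stop(sprintf("no movement window for expression %s", expression))
  v <- series$values[iv_idx(iv)]
  if (robust) unname(quantile(v, 0.95, type = 7)) else max(v)
}

#' Movement shift of one side: maximum excursion minus rest mean
#'
#' The rest-baseline subtraction turns the raw distance into the real
#' per-side movement amplitude; it can be zero or negative for a flaccid
#' side whose movement never exceeds its resting distance.
#'
#' @inheritParams max_excursion
#' @return an object of class `shift_measure` with fields `feature`, `side`,
#'   `rest_mean`, `max_excursion`, `shift` (all in the series unit), `unit`.
#' @export
movement_shift <- function(series, windows, expression = c("FROWN", "SMILE"),
                           robust = FALSE) {
  expression <- match.arg(expression)
  rm_ <- rest_mean(series, windows)
  mx <- max_excursion(series, windows, expression, robust = robust)
  structure(list(feature = series$feature, side = series$side,
                 expression = expression, rest_mean = rm_, max_excursion = mx,
                 shift = mx - rm_, unit = series$unit),
            class = "shift_measure")
}

#' All four movement shifts of a track's series bundle
#'
#' Forehead series are measured over the FROWN window, mouth series over the
#' SMILE window, on both sides.
#'
#' @param bundle a `feature_series_bundle`.
#' @param windows a `movement_windows`.
#' @param robust passed to [max_excursion()].
#' @return named list of four `shift_measure`s (`FOREHEAD.A`, `FOREHEAD.B`,
#'   `MOUTH.A`, `MOUTH.B`).
#' @export
track_shifts <- function(bundle, windows, robust = FALSE) {
  out <- list()
  for (side in SIDES) {
    out[[paste0("FOREHEAD.", side)]] <-
      movement_shift(bundle[[paste0("FOREHEAD.", side)]], windows, "FROWN", robust)
    out[[paste0("MOUTH.", side)]] <-
      movement_shift(bundle[[paste0("MOUTH.", side)]], windows, "SMILE", robust)
  }
  out
}
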