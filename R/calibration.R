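#' Pixel-to-millimetre scale calibration
#'
#' A single scalar `t` (mm per pixel) converts image measurements to
#' millimetres: `t = f[mm] / f[px]`, where `f` is any feature of known
#' physical size visible in the frame.
#'
#' @param t mm per pixel; must be finite and positive.
#' @param source one of `"marker"`, `"reference"`, `"explicit"`.
#' @return an object of class `scale_calibration` with fields `t`, `source`.
#' @export
scale_calibration <- function(t, source = c("explicit", "marker", "reference")) {
  source <- match.arg(source)
  t <- as.numeric(t)
  if (length(t) != 1 || !is.finite(t) || t <= 0) {
    stop("scale t must be a single finite positive number (mm per pixel)")
  }
  structure(list(t = t, source = source), class = "scale_calibration")
}

#' Scale from the apparent size of a physical marker
#'
#' Reference markers punched to a known diameter (5 mm by default) yield the
#' scale as marker size in mm over marker size in pixels.
#'
#' @param marker_px marker size on the image, pixels.
#' @param marker_mm physical marker size, mm (default 5).
#' @return a `scale_calibration` with `source = "marker"`.
#' @export
scale_from_marker <- function(marker_px, marker_mm = 5) {
  if (!is.finite(marker_px) || marker_px <= 0) stop("marker_px must be finite and > 0")
  if (!is.finite(marker_mm) || marker_mm <= 0) stop("marker_mm must be finite and > 0")
  scale_calibration(marker_mm / marker_px, source = "marker")
}

#' Scale from any reference length of known physical size
#'
#' Markerless recordings carry no punched markers, so any measured reference
#' (interpupillary distance, a ruler in frame) can supply the scale instead.
#'
#' @param length_px reference length on the image, pixels.
#' @param length_mm physical reference length, mm.
#' @return a `scale_calibration` with `source = "reference"`.
#' @export
scale_from_reference <- function(length_px, length_mm) {
  if (!is.finite(length_px) || length_px <= 0) stop("length_px must be finite and > 0")
  if (!is.finite(length_mm) || length_mm <= 0) stop("length_mm must be finite and > 0")
  scale_calibration(length_mm / length_px, source = "reference")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("<scale_calibration> t = %g mm/px (%s)\n", x$t, x$source))
  invisible(x)
}
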