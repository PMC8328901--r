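#' @title Asymmetry quantities: shift differences and asymmetry indices
#' @description
#' For each movement, the healthy-side shift and the affected-side shift are
#' combined into a shift difference (healthy minus affected, mm) and an
#' asymmetry index (affected over healthy, dimensionless, about 1 in normals
#' and approaching 0 with increasing severity). Totals aggregate the two
#' movements.
#' @name asymmetry
NULL

#' Shift difference between the two hemifaces for one movement
#'
#' @param healthy_shift healthy-side shift, mm.
#' @param affected_shift affected-side shift, mm.
#' @return `healthy_shift - affected_shift`, sign preserved (negative when
#'   the affected side out-moves the healthy one).
#' @export
shift_difference <- function(healthy_shift, affected_shift) {
  healthy_shift - affected_shift
}

#' Asymmetry index: affected-side over healthy-side shift
#'
#' The affected shift is the numerator and the healthy shift the denominator.
#' A negative affected shift is clamped to zero before the ratio (the index is
#' a severity scale; flagged `negative-shift`); a healthy shift at or below
#' `eps` leaves the ratio undefined (`NA`, flagged `unstable-ratio`).
#'
#' @param affected_shift affected-side shift, mm.
#' @param healthy_shift healthy-side shift, mm.
#' @param eps smallest healthy shift considered a usable denominator (mm).
#' @return the index as a number (`NA` when undefined), with a character
#'   vector of flags in `attr(, "flags")`.
#' @export
asymmetry_index <- function(affected_shift, healthy_shift, eps = 1e-6) {
  flags <- character(0)
  if (is.finite(affected_shift) && affected_shift < 0) {
    affected_shift <- 0
    flags <- c(flags, "negative-shift")
  }
  if (!is.finite(healthy_shift) || healthy_shift <= eps) {
    return(structure(NA_real_, flags = c(flags, "unstable-ratio")))
  }
  structure(affected_shift / healthy_shift, flags = flags)
}

#' Assemble the per-movement and total asymmetry quantities of one subject
#'
#' Healthy/affected roles are resolved purely from the `affected_side`
#' metadata. The total shift difference is the sum of the forehead and mouth
#' shift differences; the total asymmetry index is by default the arithmetic
#' mean of the two partial indices, which keeps totals on the same scale
#' (about 1 in normals) as the partial indices.
#'
#' @param shifts named list of four `shift_measure`s as returned by
#'   [track_shifts()].
#' @param affected_side `"A"` or `"B"`; `"none"` is an error — staging is
#'   only defined relative to a declared affected hemiface.
#' @param ai_total `"mean"` (default) or `"sum"` aggregation for the total
#'   asymmetry index.
#' @return an object of class `asymmetry_result`: `per_movement` data frame
#'   (expression, feature, healthy_shift, affected_shift, shift_difference,
#'   asymmetry_index), `total_shift_difference`, `total_asymmetry_index`,
#'   `unit`, `flags`.
#' @export
assemble_result <- function(shifts, affected_side, ai_total = c("mean", "sum")) {
  ai_total <- match.arg(ai_total)
  if (!affected_side %in% c("A", "B")) {
    stop("cannot stage a face without an affected-side label")
  }
  healthy <- healthy_side(affected_side)
  flags <- character(0)
  rows <- list()
  for (spec_ in list(c("FROWN", "FOREHEAD"), c("SMILE", "MOUTH"))) {
    expr <- spec_[1]; feat <- spec_[2]
    hs <- shifts[[paste0(feat, ".", healthy)]]$shift
    as_ <- shifts[[paste0(feat, ".", affected_side)]]$shift
    sd_ <- shift_difference(hs, as_)
    ai <- asymmetry_index(as_, hs)
    flags <- c(flags, attr(ai, "flags"))
    if (as_ < 0 || hs < 0 || sd_ < 0) flags <- c(flags, "negative-shift")
    rows[[expr]] <- data.frame(expression = expr, feature = feat,
                               healthy_shift = hs, affected_shift = as_,
                               shift_difference = sd_,
                               asymmetry_index = as.numeric(ai),
                               stringsAsFactors = FALSE)
  }
  per_movement <- do.call(rbind, rows)
  rownames(per_movement) <- NULL
  unit <- shifts[[1]]$unit
  if (unit != "mm") flags <- c(flags, "no-scale")
  ais <- per_movement$asymmetry_index
  total_ai <- if (anyNA(ais)) NA_real_ else if (ai_total == "mean") mean(ais) else sum(ais)
  structure(
    list(per_movement = per_movement,
         total_shift_difference = sum(per_movement$shift_difference),
         total_asymmetry_index = total_ai,
         unit = unit, affected_side = affected_side,
         flags = unique(flags)),
    class = "asymmetry_result"
  )
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf("<asymmetry_result> affected side %s (unit %s)\n", x$affected_side, x$unit))
  print(x$per_movement, row.names = FALSE)
  cat(sprintf("total shift difference: %.3f %s; total asymmetry index: %.3f\n",
              x$total_shift_difference, x$unit, x$total_asymmetry_index))
  if (length(x$flags) > 0) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
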