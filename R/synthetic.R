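#' @title Synthetic landmark-track simulator
#' @description
#' Emulates a smartphone recording of the staging protocol on a 640 x 480
#' canvas: an initial still segment, a forehead frown, a return to rest, and
#' a smile, with a raised-cosine activation profile (smooth rise, 0.5 s
#' plateau, smooth fall) so the true movement maximum is attained exactly on
#' the plateau. The affected hemiface performs the same movement attenuated
#' by the target asymmetry index; frame-level detector jitter is additive
#' Gaussian noise in pixel space, applied before calibration. Latency shifts
#' and synkinetic coupling are deliberately not simulated.
#' @name synthetic
NULL

#' Bilaterally symmetric neutral 68-point template face
#'
#' A schematic neutral face on a 640 x 480 pixel canvas following the
#' 68-point numbering (jaw 1-17, eyebrows 18-27, nose 28-36, eyes 37-48,
#' mouth 49-68). By construction the eyebrow-to-upper-eyelid vertical gaps
#' and the mouth-corner-to-centre horizontal gaps are identical on the two
#' sides.
#'
#' @return a `landmark_frame`.
#' @export
neutral_template <- function() {
  pts <- matrix(NA_real_, 68, 2)
  mirror <- function(x) 640 - x
  # jaw 1-17: elliptic arc, chin at (320, 340)
  tj <- (0:16) / 16
  pts[1:17, 1] <- 320 - 100 * cos(pi * tj)
  pts[1:17, 2] <- 160 + 180 * sin(pi * tj)
  # eyebrows: 18-22 side A (image left), 23-27 side B (mirrored)
  bx <- c(245, 260, 275, 290, 305)
  by <- c(155, 150, 148, 150, 155)
  pts[18:22, ] <- cbind(bx, by)
  pts[23:27, ] <- cbind(mirror(rev(bx)), rev(by))
  # nose bridge 28-31 and nostril base 32-36
  pts[28:31, ] <- cbind(rep(320, 4), c(180, 200, 220, 240))
  pts[32:36, ] <- cbind(c(300, 310, 320, 330, 340), c(255, 258, 260, 258, 255))
  # eye A 37-42 (37 outer corner, 38-39 upper lid, 40 inner, 41-42 lower lid)
  pts[37:42, ] <- cbind(c(250, 265, 285, 300, 285, 265),
                        c(190, 183, 183, 190, 197, 197))
  # eye B 43-48 (43 inner corner, 44-45 upper lid, 46 outer, 47-48 lower lid)
  pts[43:48, ] <- cbind(c(340, 355, 375, 390, 375, 355),
                        c(190, 183, 183, 190, 197, 197))
  # outer mouth 49-60 (49/55 corners), inner mouth 61-68 (63 upper-lip centre)
  pts[49:60, ] <- cbind(c(270, 285, 305, 320, 335, 355, 370, 355, 335, 320, 305, 285),
                        c(290, 282, 278, 276, 278, 282, 290, 298, 302, 304, 302, 298))
  pts[61:68, ] <- cbind(c(280, 300, 320, 340, 360, 340, 320, 300),
                        c(290, 286, 284, 286, 290, 294, 296, 294))
  validate_frame(pts)
}

#' Simulation parameters
#'
#' Defaults model the recording protocol: 30 fps, 18 s duration with a 3 s
#' initial rest, healthy-side amplitudes of 12 mm (frown) and 10 mm (smile),
#' target asymmetry indices of 1 (symmetric), detector jitter of 0.3 px, and
#' a 0.5 mm/px scale.
#'
#' @param fps frames per second.
#' @param duration_s recording length, seconds.
#' @param rest_s initial still segment, seconds.
#' @param frown_amp,smile_amp healthy-side movement amplitudes, mm.
#' @param frown_ai,smile_ai target asymmetry indices in `[0, 1.2]`.
#' @param noise_sd_px detector jitter SD per coordinate, pixels.
#' @param scale_t mm per pixel.
#' @param affected_side `"A"` or `"B"`.
#' @param seed RNG seed; mandatory whenever `noise_sd_px > 0`.
#' @return an object of class `simulation_params`.
#' @export
simulation_params <- function(fps = 30, duration_s = 18, rest_s = 3,
                              frown_amp = 12, smile_amp = 10,
                              frown_ai = 1, smile_ai = 1,
                              noise_sd_px = 0.3, scale_t = 0.5,
                              affected_side = "A", seed = NULL) {
  stopifnot(fps > 0, duration_s > 0, rest_s > 0, rest_s < duration_s,
            frown_amp >= 0, smile_amp >= 0,
            frown_ai >= 0, frown_ai <= 1.2, smile_ai >= 0, smile_ai <= 1.2,
            noise_sd_px >= 0, scale_t > 0)
  if (!affected_side %in% c("A", "B")) stop("affected_side must be 'A' or 'B'")
  if (noise_sd_px > 0 && is.null(seed)) {
    stop("a seed is mandatory for any randomized simulation")
  }
  structure(list(fps = fps, duration_s = duration_s, rest_s = rest_s,
                 frown_amp = frown_amp, smile_amp = smile_amp,
                 frown_ai = frown_ai, smile_ai = smile_ai,
                 noise_sd_px = noise_sd_px, scale_t = scale_t,
                 affected_side = affected_side, seed = seed),
            class = "simulation_params")
}

raised_cosine <- function(t, onset, rise, plateau) {
  # activation in [0, 1]: cosine rise over `rise` s, plateau, cosine fall
  a <- numeric(length(t))
  up <- t >= onset & t < onset + rise
  a[up] <- 0.5 * (1 - cos(pi * (t[up] - onset) / rise))
  flat <- t >= onset + rise & t < onset + rise + plateau
  a[flat] <- 1
  down <- t >= onset + rise + plateau & t < onset + 2 * rise + plateau
  a[down] <- 0.5 * (1 + cos(pi * (t[down] - onset - rise - plateau) / rise))
  a
}

#' Simulate one landmark track with ground truth
#'
#' The frown raises the ten eyebrow points and the smile translates the two
#' mouth corners laterally; the affected side's apex is the healthy apex
#' times the target asymmetry index. Ground truth records the exact movement
#' windows (1 s, centred on the activation plateau), per-side shifts in mm,
#' shift differences and asymmetry indices.
#'
#' @param params a [simulation_params()].
#' @param subject_id subject id stored in the track.
#' @param hb_label optional HB label stored in the track.
#' @return list with `track` (a [landmark_track()]) and `truth` (list:
#'   `windows`, `shifts`, `shift_difference`, `asymmetry_index`,
#'   `total_shift_difference`, `total_asymmetry_index`, `params`).
#' @export
simulate_track <- function(params, subject_id = "sim", hb_label = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  n <- as.integer(round(p$duration_s * p$fps))
  tt <- (seq_len(n) - 1L) / p$fps
  rise <- 1; plateau <- 0.5
  frown_onset <- p$rest_s + 1
  smile_onset <- frown_onset + 2 * rise + plateau + 1.5
  if (smile_onset + 2 * rise + plateau > p$duration_s) {
    stop("duration too short for the rest-frown-smile protocol")
  }
  act_frown <- raised_cosine(tt, frown_onset, rise, plateau)
  act_smile <- raised_cosine(tt, smile_onset, rise, plateau)

  template <- neutral_template()$points
  healthy <- healthy_side(p$affected_side)
  amp_px <- function(amp_mm) amp_mm / p$scale_t
  side_pts <- list(A = list(brow = 18:22, corner = 49L, corner_dir = -1),
                   B = list(brow = 23:27, corner = 55L, corner_dir = +1))
  coords <- matrix(rep(as.vector(t(template)), each = n), nrow = n)
  for (side in SIDES) {
    fa <- amp_px(p$frown_amp) * (if (side == healthy) 1 else p$frown_ai)
    sa <- amp_px(p$smile_amp) * (if (side == healthy) 1 else p$smile_ai)
    for (id in side_pts[[side]]$brow) {
      coords[, 2L * id] <- coords[, 2L * id] - fa * act_frown  # y up = frown
    }
    cid <- side_pts[[side]]$corner
    coords[, 2L * cid - 1L] <- coords[, 2L * cid - 1L] +
      side_pts[[side]]$corner_dir * sa * act_smile
  }
  if (any(coords < 0) || any(coords[, seq(1, 135, 2)] >= 640) ||
      any(coords[, seq(2, 136, 2)] >= 480)) {
    stop("movement amplitude pushes landmarks outside the 640x480 frame")
  }
  if (p$noise_sd_px > 0) {
    coords <- coords + with_seed(p$seed, matrix(
      stats::rnorm(length(coords), sd = p$noise_sd_px), nrow = n))
  }
  track <- landmark_track(coords, fps = p$fps, subject_id = subject_id,
                          affected_side = p$affected_side, hb_label = hb_label)

  plateau_centre <- function(onset) onset + rise + plateau / 2
  win1s <- function(onset) {
    c0 <- as.integer(round(plateau_centre(onset) * p$fps))
    c(c0 - as.integer(p$fps %/% 2), c0 + as.integer(ceiling(p$fps / 2)))
  }
  windows <- movement_windows(
    rest = list(c(0L, as.integer(round(p$rest_s * p$fps)))),
    movement = list(FROWN = win1s(frown_onset), SMILE = win1s(smile_onset)),
    n_frames = n)
  hs_f <- p$frown_amp; as_f <- p$frown_amp * p$frown_ai
  hs_s <- p$smile_amp; as_s <- p$smile_amp * p$smile_ai
  truth <- list(
    windows = windows,
    shifts = list(frown = c(healthy = hs_f, affected = as_f),
                  smile = c(healthy = hs_s, affected = as_s)),
    shift_difference = c(frown = hs_f - as_f, smile = hs_s - as_s),
    asymmetry_index = c(frown = p$frown_ai, smile = p$smile_ai),
    total_shift_difference = (hs_f - as_f) + (hs_s - as_s),
    total_asymmetry_index = mean(c(p$frown_ai, p$smile_ai)),
    params = p)
  list(track = track, truth = truth)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a grade-labelled cohort
#'
#' For each House-Brackmann grade II-V, draws per-subject target asymmetry
#' indices uniformly inside that grade's calibrated partial-index intervals
#' and target shift differences inside the partial shift-difference
#' intervals (rejecting joint draws whose total falls outside the total
#' interval), then sets the healthy amplitude to `shift_difference / (1 -
#' asymmetry_index)` so the expected quantities land inside the calibration
#' tables. Amplitudes are capped at `amp_max`.
#'
#' @param n_per_grade subjects per grade (0 gives an empty cohort).
#' @param table a [grade_range_table()].
#' @param seed RNG seed (mandatory).
#' @param noise_sd_px detector jitter, pixels.
#' @param amp_max largest admissible healthy amplitude, mm.
#' @param max_tries rejection-sampling budget per subject.
#' @return list of per-subject lists: `track`, `truth`, `grade`.
#' @export
simulate_cohort <- function(n_per_grade, table = default_grade_ranges(), seed,
                            noise_sd_px = 0.3, amp_max = 30, max_tries = 200) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (n_per_grade == 0) return(list())
  iv <- function(f, g) {
    s <- feature_intervals(table, f)
    unlist(s[s$grade == g, c("lo", "hi")])
  }
  draws <- with_seed(seed, {
    out <- list()
    for (g in HB_GRADES) {
      fa_iv <- iv("FOREHEAD_AI", g); ma_iv <- iv("MOUTH_AI", g)
      fs_iv <- iv("FOREHEAD_SD", g); ms_iv <- iv("MOUTH_SD", g)
      ts_iv <- iv("TOTAL_SD", g)
      for (i in seq_len(n_per_grade)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          frown_ai <- stats::runif(1, fa_iv[1], fa_iv[2])
          smile_ai <- stats::runif(1, ma_iv[1], ma_iv[2])
          frown_sd <- stats::runif(1, fs_iv[1], fs_iv[2])
          smile_sd <- stats::runif(1, ms_iv[1], ms_iv[2])
          total <- frown_sd + smile_sd
          frown_amp <- frown_sd / max(1 - frown_ai, 1e-9)
          smile_amp <- smile_sd / max(1 - smile_ai, 1e-9)
          if (total >= ts_iv[1] && total <= ts_iv[2] &&
              frown_amp <= amp_max && smile_amp <= amp_max) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop(sprintf("infeasible joint constraints for grade %s (amp_max %.1f mm)",
                       g, amp_max))
        }
        out[[paste0(g, "-", i)]] <- list(
          grade = g, frown_ai = frown_ai, smile_ai = smile_ai,
          frown_amp = frown_amp, smile_amp = smile_amp,
          sub_seed = sample.int(2^30, 1))
      }
    }
    out
  })
  lapply(stats::setNames(names(draws), names(draws)), function(id) {
    d <- draws[[id]]
    p <- simulation_params(frown_amp = d$frown_amp, smile_amp = d$smile_amp,
                           frown_ai = d$frown_ai, smile_ai = d$smile_ai,
                           noise_sd_px = noise_sd_px,
                           seed = if (noise_sd_px > 0) d$sub_seed else NULL)
    sim <- simulate_track(p, subject_id = id, hb_label = d$grade)
    list(track = sim$track, truth = sim$truth, grade = d$grade)
  })
}
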