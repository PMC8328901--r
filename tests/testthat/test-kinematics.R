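test_that("extract_series reproduces per-frame feature distances", {
  tr <- track_from_y(c(80, 70, 80))
  b <- extract_series(tr, scale = mm_scale(1))
  expect_equal(b$FOREHEAD.A$values, c(40, 50, 40))
  expect_identical(b$unit, "mm")

  # static track -> constant series
  coords <- matrix(rep(as.vector(t(neutral_template()$points)), each = 5), nrow = 5)
  tr2 <- suppressWarnings(landmark_track(coords, fps = 30))
  b2 <- extract_series(tr2, scale = mm_scale(0.5))
  for (k in c("FOREHEAD.A", "FOREHEAD.B", "MOUTH.A", "MOUTH.B")) {
    expect_length(unique(b2[[k]]$values), 1)
  }
})

test_that("extract_series equals the frame-by-frame feature_distance oracle", {
  set.seed(303)
  map <- side_point_map()
  for (rep_ in 1:50) {
    n <- sample(3:8, 1)
    coords <- matrix(runif(n * 136, 0, 600), nrow = n)
    tr <- suppressWarnings(landmark_track(coords, fps = 30))
    sc <- mm_scale(runif(1, 0.2, 1.5))
    b <- extract_series(tr, map, sc)
    for (i in seq_len(n)) {
      f <- track_frame(tr, i)
      expect_equal(b$FOREHEAD.A$values[i], feature_distance(f, "FOREHEAD", "A", map, sc))
      expect_equal(b$MOUTH.B$values[i], feature_distance(f, "MOUTH", "B", map, sc))
    }
  }
})

test_that("rest_mean and max_excursion match brute-force oracles", {
  w <- movement_windows(rest = list(c(0, 3), c(10, 12)),
                        movement = list(FROWN = c(4, 7)), n_frames = 12)
  s <- series_of(c(10, 20, 30, 99, 40, 50, 45, 99, 99, 99, 25, 35))
  # rest union frames {0,1,2,10,11} -> values 10,20,30,25,35
  expect_equal(rest_mean(s, w), mean(c(10, 20, 30, 25, 35)))
  expect_equal(max_excursion(s, w, "FROWN"), 50)

  set.seed(11)
  for (i in 1:30) {
    n <- 40
    v <- runif(n, 0, 100)
    a <- sample(0:10, 1); b <- a + sample(2:5, 1)
    m1 <- b + sample(1:5, 1); m2 <- m1 + sample(2:8, 1)
    w <- movement_windows(rest = list(c(a, b)),
                          movement = list(SMILE = c(m1, min(m2, n))), n_frames = n)
    s <- series_of(v, feature = "MOUTH")
    expect_equal(rest_mean(s, w), sum(v[(a + 1):b]) / (b - a))
    expect_equal(max_excursion(s, w, "SMILE"), max(v[(m1 + 1):min(m2, n)]))
  }
})

test_that("movement shift subtracts the rest baseline and may be zero", {
  w <- movement_windows(rest = list(c(0, 2)), movement = list(FROWN = c(3, 6)),
                        n_frames = 6)
  s <- series_of(c(40, 40, 99, 40, 50, 45))
  m <- movement_shift(s, w, "FROWN")
  expect_equal(m$rest_mean, 40)
  expect_equal(m$max_excursion, 50)
  expect_equal(m$shift, 10)

  flat <- series_of(rep(40, 6))
  expect_equal(movement_shift(flat, w, "FROWN")$shift, 0)
})

test_that("shift is invariant to adding a constant to the whole series", {
  set.seed(23)
  w <- movement_windows(rest = list(c(0, 10)), movement = list(FROWN = c(15, 25)),
                        n_frames = 30)
  for (i in 1:20) {
    v <- runif(30, 0, 50)
    c0 <- runif(1, -100, 100)
    s0 <- movement_shift(series_of(v), w, "FROWN")$shift
    s1 <- movement_shift(series_of(v + c0), w, "FROWN")$shift
    expect_equal(s1, s0, tolerance = 1e-12)
  }
})

test_that("explicit window annotations are validated and returned verbatim", {
  sim <- simulate_track(simulation_params(noise_sd_px = 0))
  b <- extract_series(sim$track, scale = mm_scale(0.5))
  w <- detect_windows(b, annotations = sim$truth$windows)
  expect_identical(w, sim$truth$windows)

  expect_error(movement_windows(rest = list(c(0, 90)),
                                movement = list(FROWN = c(500, 600)),
                                n_frames = 540),
               "out of track bounds")
  expect_error(movement_windows(rest = list(c(0, 90)),
                                movement = list(FROWN = c(50, 80)),
                                n_frames = 540),
               "overlaps a rest interval")
})

test_that("auto-detected windows bracket the true activation apex", {
  # zero-noise: both movement windows must contain the plateau
  sim <- simulate_track(simulation_params(noise_sd_px = 0, frown_ai = 0.5,
                                          smile_ai = 0.5))
  b <- extract_series(sim$track, scale = mm_scale(0.5))
  w <- detect_windows(b)
  true_f <- sim$truth$windows$movement$FROWN
  apex_f <- (true_f[1] + true_f[2]) %/% 2
  expect_true(w$movement$FROWN[1] <= apex_f && apex_f < w$movement$FROWN[2])
  true_s <- sim$truth$windows$movement$SMILE
  apex_s <- (true_s[1] + true_s[2]) %/% 2
  expect_true(w$movement$SMILE[1] <= apex_s && apex_s < w$movement$SMILE[2])
  expect_true(w$rest[[1]][2] >= 0.5 * 30)

  # noisy: apex containment in >= 95% of seeded runs at noise 0.5 px
  hits <- 0
  for (seed in 1:40) {
    sim <- simulate_track(simulation_params(noise_sd_px = 0.5, frown_ai = 0.4,
                                            smile_ai = 0.4, seed = seed))
    b <- extract_series(sim$track, scale = mm_scale(0.5))
    w <- tryCatch(detect_windows(b), error = function(e) NULL)
    if (is.null(w)) next
    tf <- sim$truth$windows$movement$FROWN; ts <- sim$truth$windows$movement$SMILE
    af <- (tf[1] + tf[2]) %/% 2; as_ <- (ts[1] + ts[2]) %/% 2
    if (w$movement$FROWN[1] <= af && af < w$movement$FROWN[2] &&
        w$movement$SMILE[1] <= as_ && as_ < w$movement$SMILE[2]) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("a quiet track yields a no-rest or no-movement diagnosis, not a window", {
  coords <- matrix(rep(as.vector(t(neutral_template()$points)), each = 60), nrow = 60)
  tr <- suppressWarnings(landmark_track(coords, fps = 30))
  b <- extract_series(tr, scale = mm_scale(0.5))
  expect_error(detect_windows(b), "no movement detected")
})

test_that("injected shift is recovered within tolerance under detector jitter", {
  p <- simulation_params(frown_amp = 6, smile_amp = 6, frown_ai = 0.5,
                         smile_ai = 0.5, noise_sd_px = 0.1, seed = 99)
  sim <- simulate_track(p)
  b <- extract_series(sim$track, scale = mm_scale(0.5))
  sh <- track_shifts(b, sim$truth$windows)
  healthy <- "B"  # affected side defaults to A
  expect_equal(sh[[paste0("FOREHEAD.", healthy)]]$shift, 6.0, tolerance = 0.15 / 6)
  expect_equal(sh$FOREHEAD.A$shift, 3.0, tolerance = 0.15 / 3)
})
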