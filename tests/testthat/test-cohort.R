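test_that("group_summary gives exact mean/extrema and sample sd", {
  s <- group_summary(c(7, 7, 7))
  expect_equal(s$mean, 7); expect_equal(s$sd, 0)
  expect_equal(s$min, 7); expect_equal(s$max, 7)

  co <- calibration_cohort()
  fh <- co[co$feature == "FOREHEAD_SD", ]
  # reference cells of the published per-grade summary (2-dec display rounding)
  expect_equal(round_half_away(group_summary(fh$value[fh$grade == "III"])$mean), 4.03)
  expect_equal(round_half_away(group_summary(fh$value[fh$grade == "II"])$sd), 0.89)

  expect_error(group_summary(numeric(0)), "non-empty")
  expect_true(is.na(group_summary(5)$sd))
})

test_that("half-away-from-zero display rounding differs from round-half-even where it must", {
  expect_equal(round_half_away(c(0.125, -0.125, 2.675), 2), c(0.13, -0.13, 2.68))
  expect_equal(round_half_away(1.005, 2), 1.01)
})

test_that("one_way_anova matches a brute-force sum-of-squares oracle", {
  a <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  # hand decomposition: SS_between = 13.5, SS_within = 4, df = 1 and 4
  expect_equal(a$F, (13.5 / 1) / (4 / 4))
  expect_equal(a$r_squared, 13.5 / 17.5)
  expect_equal(a$df_between, 1L)
  expect_equal(a$df_within, 4L)

  set.seed(17)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(2:9, 1), mean = j))
    a <- one_way_anova(groups)
    v <- unlist(groups); gm <- mean(v)
    ss_b <- sum(lengths(groups) * (vapply(groups, mean, 0) - gm)^2)
    ss_w <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
    N <- length(v)
    expect_equal(a$F, (ss_b / (k - 1)) / (ss_w / (N - k)), tolerance = 1e-10)
    expect_equal(a$r_squared, ss_b / (ss_b + ss_w), tolerance = 1e-10)
  }
})

test_that("degenerate ANOVA inputs resolve by convention", {
  a0 <- one_way_anova(list(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(a0$F, 0); expect_equal(a0$r_squared, 0)
  expect_match(a0$note, "identical")

  ainf <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(ainf$F, Inf)
  expect_equal(ainf$r_squared, 1)

  expect_error(one_way_anova(list(c(1, 2))), "two groups")
  expect_error(one_way_anova(list(c(1, 2), 3)), "at least two values")
})

test_that("F and eta-squared are invariant under affine transformation", {
  set.seed(29)
  for (i in 1:20) {
    groups <- lapply(1:3, function(j) rnorm(6, mean = j, sd = 0.5))
    a <- runif(1, -5, 5); if (abs(a) < 0.1) a <- 1
    b <- runif(1, -100, 100)
    f0 <- one_way_anova(groups)
    f1 <- one_way_anova(lapply(groups, function(g) a * g + b))
    expect_equal(f1$F, f0$F, tolerance = 1e-8)
    expect_equal(f1$r_squared, f0$r_squared, tolerance = 1e-8)
  }
})

test_that("reproduce_tables emits per-grade summaries, totals and ANOVA", {
  co <- calibration_cohort()
  rep_ <- reproduce_tables(co, derive_totals = FALSE)
  expect_setequal(unique(rep_$summaries$feature),
                  c("FOREHEAD_SD", "MOUTH_SD", "TOTAL_SD", "FOREHEAD_AI", "MOUTH_AI"))
  expect_equal(nrow(rep_$summaries), 20)
  expect_true(all(rep_$summaries$n == 10))
  s <- rep_$summaries
  expect_true(all(s$min <= s$mean & s$mean <= s$max))

  # derived totals from the partials agree with the printed totals to rounding
  partials <- co[co$feature %in% c("FOREHEAD_SD", "MOUTH_SD", "FOREHEAD_AI", "MOUTH_AI"), ]
  rep_d <- reproduce_tables(partials, derive_totals = TRUE)
  tot_d <- rep_d$cohort[rep_d$cohort$feature == "TOTAL_SD", ]
  tot_p <- co[co$feature == "TOTAL_SD", ]
  m <- merge(tot_d, tot_p, by = "subject")
  expect_equal(nrow(m), 40)
  expect_true(all(abs(m$value.x - m$value.y) <= 0.06))
})

test_that("permuting grade labels permutes summaries and changes F", {
  co <- calibration_cohort()
  fh <- co[co$feature == "FOREHEAD_SD", ]
  rep0 <- reproduce_tables(fh, derive_totals = FALSE)
  # swap labels II <-> V
  fh2 <- fh
  fh2$grade[fh$grade == "II"] <- "V"
  fh2$grade[fh$grade == "V"] <- "II"
  rep1 <- reproduce_tables(fh2, derive_totals = FALSE)
  s0 <- rep0$summaries; s1 <- rep1$summaries
  expect_equal(s1$mean[s1$grade == "V"], s0$mean[s0$grade == "II"])
  expect_equal(s1$mean[s1$grade == "II"], s0$mean[s0$grade == "V"])
  expect_equal(rep1$anova$FOREHEAD_SD$F, rep0$anova$FOREHEAD_SD$F)  # label swap only
  # an actual value permutation across groups must change F
  fh3 <- fh
  set.seed(5)
  fh3$value <- sample(fh3$value)
  rep2 <- reproduce_tables(fh3, derive_totals = FALSE)
  expect_false(isTRUE(all.equal(rep2$anova$FOREHEAD_SD$F, rep0$anova$FOREHEAD_SD$F)))
})

test_that("cohort_from_results flattens labelled asymmetry results", {
  sim <- simulate_track(simulation_params(frown_ai = 0.6, smile_ai = 0.6,
                                          noise_sd_px = 0))
  rep_ <- analyze_track(sim$track, scale = scale_calibration(0.5),
                        windows = sim$truth$windows)
  df <- cohort_from_results(list(rep_$result), grades = "III", subjects = "s1")
  expect_equal(nrow(df), 6)
  expect_equal(df$value[df$feature == "FOREHEAD_AI"], 0.6, tolerance = 1e-9)
})
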