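test_that("the packaged range table loads and satisfies the staging invariants", {
  tab <- default_grade_ranges()
  expect_s3_class(tab, "grade_range_table")
  expect_equal(nrow(tab$intervals), 24)  # 6 features x 4 grades
  # monotonicity is asserted at load; a violating table must be rejected
  bad <- tab$intervals
  bad$lo[bad$feature == "TOTAL_SD" & bad$grade == "III"] <- 0.5  # overlaps II
  expect_error(grade_range_table(bad), "increase with grade")
  bad2 <- tab$intervals
  bad2$hi[bad2$feature == "MOUTH_AI" & bad2$grade == "IV"] <- 0.8  # overlaps III
  expect_error(grade_range_table(bad2), "decrease with grade")
})

test_that("in-range values take their interval's grade", {
  tab <- default_grade_ranges()
  expect_equal(assign_grade(12.92, "TOTAL_SD", tab),
               list(grade = "V", status = "in-range"))
  expect_equal(assign_grade(1.80, "TOTAL_SD", tab),
               list(grade = "II", status = "in-range"))
  expect_equal(assign_grade(0.61, "FOREHEAD_AI", tab),
               list(grade = "III", status = "in-range"))
})

test_that("gap values go to the nearest boundary, severe on ties, matching a brute-force scan", {
  tab <- default_grade_ranges()
  # 6.00 sits in the TOTAL_SD gap 5.13-6.89: 0.87 to II vs 0.89 to III
  g <- assign_grade(6.00, "TOTAL_SD", tab)
  expect_equal(g$grade, "II")
  expect_equal(g$status, "nearest-range")

  # brute-force nearest-boundary oracle over a grid spanning each feature
  grades <- c("II", "III", "IV", "V")
  for (f in c("TOTAL_SD", "FOREHEAD_SD", "MOUTH_AI")) {
    iv <- tab$intervals[tab$intervals$feature == f, ]
    iv <- iv[match(grades, iv$grade), ]
    for (v in seq(min(iv$lo) + 1e-9, max(iv$hi) - 1e-9, length.out = 113)) {
      got <- assign_grade(v, f, tab)$grade
      inside <- which(v >= iv$lo & v <= iv$hi)
      want <- if (length(inside) > 0) {
        grades[inside[1]]
      } else {
        d <- pmin(abs(v - iv$lo), abs(v - iv$hi))
        grades[max(which(d == min(d)))]  # tie -> higher index = more severe
      }
      expect_identical(got, want)
    }
  }

  # exact tie in the FOREHEAD_AI gap (0.52 | 0.54): midpoint 0.53 -> severe (IV)
  expect_equal(assign_grade(0.53, "FOREHEAD_AI", tab)$grade, "IV")
  # refuse mode reports gaps as unclassifiable instead
  expect_equal(assign_grade(6.00, "TOTAL_SD", tab, gap_rule = "refuse")$grade,
               "unclassifiable")
})

test_that("values beyond the calibrated extremes are reported, never extrapolated", {
  tab <- default_grade_ranges()
  expect_equal(assign_grade(1.0, "FOREHEAD_AI", tab),
               list(grade = "better-than-II", status = "out-of-range"))
  expect_equal(assign_grade(0.3, "TOTAL_SD", tab),
               list(grade = "better-than-II", status = "out-of-range"))
  expect_equal(assign_grade(25, "TOTAL_SD", tab),
               list(grade = "V", status = "out-of-range"))
  expect_equal(assign_grade(0.01, "MOUTH_AI", tab),
               list(grade = "V", status = "out-of-range"))
})

result_from_values <- function(fh_sd, mo_sd, fh_ai, mo_ai, unit = "mm") {
  # reconstruct healthy/affected shifts consistent with given SDs and AIs
  fh_h <- fh_sd / (1 - fh_ai); mo_h <- mo_sd / (1 - mo_ai)
  shifts <- list(
    structure(list(feature = "FOREHEAD", side = "B", shift = fh_h, unit = unit),
              class = "shift_measure"),
    structure(list(feature = "FOREHEAD", side = "A", shift = fh_h * fh_ai, unit = unit),
              class = "shift_measure"),
    structure(list(feature = "MOUTH", side = "B", shift = mo_h, unit = unit),
              class = "shift_measure"),
    structure(list(feature = "MOUTH", side = "A", shift = mo_h * mo_ai, unit = unit),
              class = "shift_measure"))
  names(shifts) <- c("FOREHEAD.B", "FOREHEAD.A", "MOUTH.B", "MOUTH.A")
  assemble_result(shifts, "A")
}

test_that("grade_patient combines per-feature grades with a totals-first rule", {
  tab <- default_grade_ranges()
  # all six features inside HBIII intervals -> combined III, no disagreement
  res <- result_from_values(4.0, 3.4, 0.60, 0.62)
  g <- grade_patient(res, tab)
  expect_equal(g$combined_grade, "III")
  expect_equal(unique(g$per_feature$grade), "III")
  expect_false(grepl("disagreement", g$rationale))

  # conflicting partials (forehead IV, mouth II) with total in III
  iv <- function(f, gr) {
    s <- tab$intervals[tab$intervals$feature == f & tab$intervals$grade == gr, ]
    (s$lo + s$hi) / 2
  }
  res2 <- result_from_values(iv("FOREHEAD_SD", "IV"), iv("MOUTH_SD", "II"),
                             iv("FOREHEAD_AI", "IV"), iv("MOUTH_AI", "II"))
  total <- res2$total_shift_difference
  expect_equal(assign_grade(total, "TOTAL_SD", tab)$grade, "III")
  g2 <- grade_patient(res2, tab)
  expect_equal(g2$combined_grade, "III")
  expect_true(grepl("disagreement", g2$rationale))
})

test_that("without a scale the combined grade falls back to the asymmetry index", {
  res <- result_from_values(400, 340, 0.60, 0.62, unit = "px")
  g <- grade_patient(res, default_grade_ranges())
  expect_equal(g$combined_from, "TOTAL_AI")
  expect_equal(g$combined_grade, "III")
  expect_true("no-scale" %in% g$flags)
})

test_that("every severe-grade calibration patient grades as V on all features", {
  tab <- default_grade_ranges()
  co <- calibration_cohort()
  co_v <- co[co$grade == "V", ]
  for (s in unique(co_v$subject)) {
    sub <- co_v[co_v$subject == s, ]
    v <- stats::setNames(sub$value, sub$feature)
    for (f in names(v)) {
      expect_equal(assign_grade(v[[f]], f, tab)$grade, "V")
    }
    total_ai <- mean(c(v[["FOREHEAD_AI"]], v[["MOUTH_AI"]]))
    expect_equal(assign_grade(total_ai, "TOTAL_AI", tab)$grade, "V")
  }
})
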