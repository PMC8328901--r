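#' @title Cohort summaries and one-way ANOVA with effect size
#' @description
#' Group summaries (mean, extrema, sample SD) and the fixed-effects one-way
#' ANOVA used to compare shift differences and asymmetry indices across
#' House-Brackmann grades, with eta-squared (between-group over total sum of
#' squares) as the reported R-squared.
#' @name cohort-stats
NULL

#' Round half away from zero
#'
#' Display rounding used by the cohort report tables (base `round()` rounds
#' half to even). Raw unrounded values are always retained in outputs.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  # nudge compensates for binary representation of decimal halves (2.675 * 100
  # is stored fractionally below 267.5)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Summary statistics of one group of values
#'
#' @param values numeric vector, `n >= 1` (`sd` needs `n >= 2` and is `NA`
#'   below that).
#' @return an object of class `group_summary`: `n`, `mean`, `max`, `min`,
#'   `sd` (sample standard deviation, n-1 denominator).
#' @export
group_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values)) stop("values must be non-empty and free of NA")
  structure(list(n = length(values), mean = mean(values), max = max(values),
                 min = min(values),
                 sd = if (length(values) >= 2) sd(values) else NA_real_),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> n=%d mean=%.2f max=%.2f min=%.2f sd=%.2f\n",
              x$n, round_half_away(x$mean), round_half_away(x$max),
              round_half_away(x$min), round_half_away(x$sd)))
  invisible(x)
}

#' One-way fixed-effects ANOVA with eta-squared
#'
#' The omnibus F is `(SS_between/(k-1)) / (SS_within/(N-k))` and the effect
#' size is eta-squared, `SS_between / SS_total` — the "R-squared" of the
#' grade factor. Fitted through [stats::lm()]/[stats::anova()]. Degenerate
#' inputs are resolved by convention: all values identical gives `F = 0`
#' (noted); zero within-group variance with unequal means gives `F = Inf`.
#'
#' @param groups list of `k >= 2` numeric vectors, each of length `>= 2`.
#' @return an object of class `anova_result`: `F`, `r_squared`,
#'   `df_between`, `df_within`, `group_means`, `note`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) < 2)) stop("each group needs at least two values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  k <- length(groups); N <- length(v)
  note <- NULL
  ss_total <- sum((v - mean(v))^2)
  if (ss_total == 0) {
    f <- 0; r2 <- 0
    note <- "all values identical; F = 0 by convention"
  } else {
    tab <- suppressWarnings(stats::anova(stats::lm(v ~ g)))
    ss_b <- tab$`Sum Sq`[1]; ss_w <- tab$`Sum Sq`[2]
    r2 <- ss_b / (ss_b + ss_w)
    if (ss_w <= 1e-12 * ss_total) {
      f <- Inf
      note <- "zero within-group variance with unequal means"
    } else {
      f <- tab$`F value`[1]
    }
  }
  structure(list(F = f, r_squared = r2, df_between = k - 1L, df_within = N - k,
                 group_means = vapply(groups, mean, numeric(1)), note = note),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.2f, R^2 = %.2f\n",
              x$df_between, x$df_within, x$F, x$r_squared))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Read a labelled cohort feature-value CSV
#'
#' @param path CSV with columns `subject, grade, feature, value` (an optional
#'   `decimals` column records each printed value's decimal precision).
#' @return data frame with those columns.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("subject", "grade", "feature", "value")
  if (!all(need %in% names(df))) {
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' The packaged calibration-cohort feature values
#'
#' Per-patient shift differences and asymmetry indices of the 40-subject
#' calibration cohort (ten per House-Brackmann grade II-V), as printed in the
#' published per-patient tables. These are the inputs from which the packaged
#' grade ranges and the reference cohort statistics are computed.
#'
#' @return data frame `subject, grade, feature, value, decimals`.
#' @export
calibration_cohort <- function() {
  read_cohort_csv(system.file("extdata", "cohort_printed.csv",
                              package = "faceshift", mustWork = TRUE))
}

#' Per-grade summaries and ANOVA for every feature of a labelled cohort
#'
#' For each feature present: per-grade [group_summary()] rows (plus display
#' rounding), a feature-wide [one_way_anova()] across grades with at least
#' two members, and flags for values lying outside their grade's calibrated
#' interval. For subjects with per-movement features present, per-subject
#' totals (`TOTAL_SD` as the sum of the two shift differences, `TOTAL_AI` as
#' the mean of the two indices) are derived when not already supplied.
#'
#' @param cohort data frame `subject, grade, feature, value`, or a list of
#'   `asymmetry_result`s with `grade` labels (see [cohort_from_results()]).
#' @param table a [grade_range_table()] used for the out-of-interval flags.
#' @param derive_totals derive missing `TOTAL_*` rows from the partial
#'   features (default `TRUE`).
#' @return an object of class `cohort_report`: `summaries` (data frame
#'   feature, grade, n, mean, max, min, sd), `anova` (named list of
#'   `anova_result` per feature), `out_of_interval` (data frame of flagged
#'   values), `cohort` (the value rows used).
#' @export
reproduce_tables <- function(cohort, table = default_grade_ranges(),
                             derive_totals = TRUE) {
  if (!is.data.frame(cohort)) stop("cohort must be a data frame (see cohort_from_results)")
  cohort <- cohort[c("subject", "grade", "feature", "value")]
  if (derive_totals) {
    for (tot in c("TOTAL_SD", "TOTAL_AI")) {
      parts <- if (tot == "TOTAL_SD") c("FOREHEAD_SD", "MOUTH_SD") else c("FOREHEAD_AI", "MOUTH_AI")
      have_tot <- unique(cohort$subject[cohort$feature == tot])
      sub <- cohort[cohort$feature %in% parts & !(cohort$subject %in% have_tot), ]
      if (nrow(sub) > 0) {
        agg <- stats::aggregate(value ~ subject + grade, data = sub,
                                FUN = if (tot == "TOTAL_SD") sum else mean)
        counts <- stats::aggregate(value ~ subject, data = sub, FUN = length)
        agg <- agg[agg$subject %in% counts$subject[counts$value == 2], ]
        if (nrow(agg) > 0) {
          agg$feature <- tot
          cohort <- rbind(cohort, agg[c("subject", "grade", "feature", "value")])
        }
      }
    }
  }
  summaries <- list(); anovas <- list(); flagged <- list()
  for (f in intersect(GRADE_FEATURES, unique(cohort$feature))) {
    sub <- cohort[cohort$feature == f, ]
    grades <- intersect(HB_GRADES, unique(sub$grade))
    groups <- lapply(stats::setNames(grades, grades),
                     function(g) sub$value[sub$grade == g])
    for (g in grades) {
      s <- group_summary(groups[[g]])
      summaries[[paste(f, g)]] <- data.frame(
        feature = f, grade = g, n = s$n, mean = s$mean, max = s$max,
        min = s$min, sd = s$sd, stringsAsFactors = FALSE)
      iv <- feature_intervals(table, f)
      iv <- iv[iv$grade == g, ]
      out <- groups[[g]] < iv$lo | groups[[g]] > iv$hi
      if (any(out)) {
        flagged[[paste(f, g)]] <- data.frame(
          feature = f, grade = g,
          subject = sub$subject[sub$grade == g][out],
          value = groups[[g]][out], stringsAsFactors = FALSE)
      }
    }
    usable <- groups[lengths(groups) >= 2]
    if (length(usable) < length(groups)) {
      warning(sprintf("%s: grades with < 2 members excluded from ANOVA", f))
    }
    if (length(usable) >= 2) anovas[[f]] <- one_way_anova(usable)
  }
  structure(list(summaries = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
                 anova = anovas,
                 out_of_interval = if (length(flagged) > 0) {
                   do.call(rbind, c(flagged, list(make.row.names = FALSE)))
                 } else NULL,
                 cohort = cohort),
            class = "cohort_report")
}

#' Flatten labelled asymmetry results into a cohort value table
#'
#' @param results list of `asymmetry_result`s.
#' @param grades character vector of HB labels, one per result.
#' @param subjects optional subject ids.
#' @return data frame `subject, grade, feature, value` with the six staging
#'   features per subject.
#' @export
cohort_from_results <- function(results, grades, subjects = NULL) {
  if (length(results) != length(grades)) stop("one grade label per result required")
  if (is.null(subjects)) subjects <- sprintf("S%03d", seq_along(results))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    pm <- r$per_movement
    data.frame(
      subject = subjects[i], grade = grades[i],
      feature = c("FOREHEAD_SD", "MOUTH_SD", "TOTAL_SD",
                  "FOREHEAD_AI", "MOUTH_AI", "TOTAL_AI"),
      value = c(pm$shift_difference[pm$feature == "FOREHEAD"],
                pm$shift_difference[pm$feature == "MOUTH"],
                r$total_shift_difference,
                pm$asymmetry_index[pm$feature == "FOREHEAD"],
                pm$asymmetry_index[pm$feature == "MOUTH"],
                r$total_asymmetry_index),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.cohort_report <- function(x, ...) {
  s <- x$summaries
  s[c("mean", "max", "min", "sd")] <- lapply(s[c("mean", "max", "min", "sd")],
                                             round_half_away)
  print(s, row.names = FALSE)
  for (f in names(x$anova)) {
    a <- x$anova[[f]]
    cat(sprintf("%s: F(%d, %d) = %.2f, R^2 = %.2f\n",
                f, a$df_between, a$df_within, a$F, a$r_squared))
  }
  if (!is.null(x$out_of_interval)) {
    cat(sprintf("%d value(s) outside their grade's calibrated interval\n",
                nrow(x$out_of_interval)))
  }
  invisible(x)
}
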