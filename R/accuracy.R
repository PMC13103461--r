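# Postoperative accuracy analysis.
#
# The achieved reconstruction is assessed by registering the postoperative
# CBCT-derived bone surfaces to the plan via artificial landmarks on the
# residual mandible (which are unaffected by metal artifacts from the
# osteosynthesis plate), then measuring spatial 3D distances at artificial
# graft landmarks and at the clinically relevant points CON (condyle),
# ANG (jaw angle) and JUN (graft-mandible junction). Agreement between the
# intraoperative navigation measurements and CBCT is quantified with
# Pearson correlation, ordinary least-squares regression and Bland-Altman
# limits of agreement, with Kolmogorov-Smirnov normality checks on the
# paired differences.

#' Packaged per-case model-surgery measurements
#'
#' Per-case measurement rows of an 11-case phantom model-surgery study:
#' registration errors (attempts, FRE, TREs) for mandible and graft,
#' CBCT-versus-plan spatial differences (total graft, per segment, CON, ANG,
#' JUN) and navigation-versus-plan displacements (CON, ANG, JUN). All
#' distances in mm.
#'
#' @return Data frame with columns `case_id`, `object`, `label`, `source`
#'   (`registration`, `cbct` or `navigation`), `value`.
#' @export
model_surgery_cases <- function() {
  path <- system.file("extdata", "model_surgery_cases.csv", package = "emnav",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published summary cells for the packaged model-surgery study
#'
#' The printed mean/SD summary cells and agreement statistics (Pearson r,
#' Bland-Altman limits of agreement, maximum |navigation - CBCT| difference)
#' that [reproduce_tables()] regenerates from the per-case rows.
#'
#' @return Data frame with columns `stat`, `object`, `label`, `source`,
#'   `value`, `digits` (printed decimal places).
#' @export
model_surgery_summary <- function() {
  path <- system.file("extdata", "model_surgery_summary.csv", package = "emnav",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Pull one per-case series (ordered by case) out of the long case table.
case_series <- function(cases, object, label, source) {
  rows <- cases[cases$object == object & cases$label == label &
                  cases$source == source, ]
  rows$value[order(rows$case_id)]
}

#' Register postoperative anatomy to the plan
#'
#' Horn registration of matched artificial-landmark sets on the residual
#' mandible, mapping the postoperative (CBCT) frame into the plan frame.
#' Landmarks are matched by name, so the two sets may list them in any order.
#'
#' @param postop_landmarks `landmark_set` in the postoperative frame.
#' @param plan_landmarks `landmark_set` in the plan frame; must contain the
#'   same names.
#' @return A `rigid_transform` postop frame -> plan frame.
#' @export
register_postop <- function(postop_landmarks, plan_landmarks) {
  idx <- match(postop_landmarks$names, plan_landmarks$names)
  if (anyNA(idx))
    emnav_stop("emnav_correspondence_error", sprintf(
      "landmarks not in plan set: %s",
      paste(postop_landmarks$names[is.na(idx)], collapse = ", ")))
  plan_matched <- landmark_set(plan_landmarks$names[idx],
                               plan_landmarks$points[idx, , drop = FALSE],
                               plan_landmarks$frame)
  horn_register(postop_landmarks, plan_matched)
}

#' Per-landmark deviations between achieved and planned graft
#'
#' Euclidean distances at matched artificial graft landmarks, summarized as
#' the overall mean (`Tx_total`), per-segment means (`Segment_k`, segment 1
#' being the condyle segment and the highest number the segment adjacent to
#' the residual mandible), and the distances at any of CON/ANG/JUN present.
#'
#' @param registered_postop_graft `landmark_set` of achieved graft landmark
#'   positions, already registered into the plan frame.
#' @param planned_graft `landmark_set` of the same landmarks in the plan.
#' @param segment_assignment Named integer vector mapping landmark name ->
#'   segment index; landmarks absent from it (e.g. CON/ANG/JUN) contribute
#'   only to their named entries, not to segment means or `Tx_total`.
#' @return List with `per_landmark` (named distances, mm) and `table` (named
#'   numeric: `Tx_total`, `Segment_k`, and CON/ANG/JUN when present).
#' @export
landmark_deviations <- function(registered_postop_graft, planned_graft,
                                segment_assignment) {
  idx <- match(registered_postop_graft$names, planned_graft$names)
  if (anyNA(idx))
    emnav_stop("emnav_correspondence_error", sprintf(
      "unmatched landmark names: %s",
      paste(registered_postop_graft$names[is.na(idx)], collapse = ", ")))
  d <- row_norms(registered_postop_graft$points -
                   planned_graft$points[idx, , drop = FALSE])
  names(d) <- registered_postop_graft$names
  seg <- segment_assignment[names(d)]
  tab <- c(Tx_total = mean(d[!is.na(seg)]))
  for (k in sort(unique(stats::na.omit(seg))))
    tab[sprintf("Segment_%d", k)] <- mean(d[!is.na(seg) & seg == k])
  for (nm in c("CON", "ANG", "JUN"))
    if (nm %in% names(d)) tab[nm] <- d[[nm]]
  list(per_landmark = d, table = tab)
}

#' Mean and sample standard deviation, table-rounded
#'
#' @param values Non-empty numeric vector.
#' @param digits Decimal places (default 2, the per-case table precision);
#'   rounding is half-away-from-zero, matching table formatting.
#' @return Named numeric `c(mean =, sd =)`; `sd` is the n-1 (sample) SD,
#'   0 for a single value.
#' @examples
#' summarize_mean_sd(c(1.39, 1.82, 3.42, 4.13, 1.96, 1.5,
#'                     3.87, 1.35, 1.54, 1.8, 1.02))  # 2.16 +/- 1.10
#' @export
summarize_mean_sd <- function(values, digits = 2) {
  if (length(values) == 0L)
    emnav_stop("emnav_schema_error", "cannot summarize an empty vector")
  s <- if (length(values) > 1L) stats::sd(values) else 0
  c(mean = round_half_away(mean(values), digits),
    sd = round_half_away(s, digits))
}

#' Pearson correlation coefficient
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with nonzero variance.
#' @return Sample Pearson r.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    emnav_stop("emnav_correspondence_error", "x and y differ in length")
  if (length(x) < 3L)
    emnav_stop("emnav_schema_error", "need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    emnav_stop("emnav_degenerate_error",
               "correlation undefined for zero-variance input")
  stats::cor(x, y)
}

#' Ordinary least-squares line
#'
#' @param x,y Equal-length numeric vectors; `x` must have nonzero variance.
#' @return Named numeric `c(slope =, intercept =)`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y))
    emnav_stop("emnav_correspondence_error", "x and y differ in length")
  if (stats::sd(x) == 0)
    emnav_stop("emnav_degenerate_error", "zero variance in x")
  co <- stats::coef(stats::lm(y ~ x))
  c(slope = unname(co[2]), intercept = unname(co[1]))
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the differences against a normal distribution with
#' sample-estimated mean and SD. Estimating the parameters from the same
#' sample makes the plain KS p-value conservative; a Lilliefors-corrected
#' variant (via the nortest package) is available.
#'
#' @param d Numeric vector, length >= 4, nonzero SD.
#' @param alpha Significance level (default 0.05).
#' @param lilliefors Use the Lilliefors correction (requires nortest).
#' @return List `statistic`, `pvalue`, `is_normal` (`pvalue > alpha`).
#' @export
ks_normality <- function(d, alpha = 0.05, lilliefors = FALSE) {
  if (length(d) < 4L)
    emnav_stop("emnav_schema_error", "need at least 4 values")
  if (stats::sd(d) == 0)
    emnav_stop("emnav_degenerate_error", "zero-variance input")
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE))
      emnav_stop("emnav_schema_error", "the nortest package is required for lilliefors = TRUE")
    kt <- nortest::lillie.test(d)
  } else {
    kt <- suppressWarnings(stats::ks.test(d, "pnorm", mean(d), stats::sd(d)))
  }
  list(statistic = unname(kt$statistic), pvalue = kt$p.value,
       is_normal = kt$p.value > alpha)
}

#' Bland-Altman agreement analysis
#'
#' Paired-method agreement between navigation and CBCT measurements:
#' differences are `x - y` (navigation minus CBCT), limits of agreement are
#' the mean difference +/- `multiplier` sample SDs (1.96 by default), and
#' normality of the differences is checked with [ks_normality()]. Pearson r
#' and the OLS regression line of `y` on `x` are included for the full
#' agreement report.
#'
#' @param x,y Equal-length numeric vectors (navigation and CBCT values, mm).
#' @param multiplier LoA multiplier (default 1.96).
#' @param alpha Normality significance level.
#' @param lilliefors Passed to [ks_normality()].
#' @return An `agreement_report`: `pearson_r`, `slope`, `intercept`,
#'   `mean_diff_mm`, `sd_diff_mm`, `loa_lower_mm`, `loa_upper_mm`,
#'   `ks_statistic`, `ks_pvalue`, `is_normal`, `max_abs_diff_mm`, `n`.
#' @export
bland_altman <- function(x, y, multiplier = 1.96, alpha = 0.05,
                         lilliefors = FALSE) {
  r <- pearson_r(x, y)
  fit <- linear_fit(x, y)
  d <- x - y
  m <- mean(d); s <- stats::sd(d)
  # degenerate differences (x == y + const): limits collapse, normality moot
  ks <- if (s == 0) list(statistic = NA_real_, pvalue = NA_real_,
                         is_normal = NA)
  else ks_normality(d, alpha = alpha, lilliefors = lilliefors)
  structure(list(pearson_r = r, slope = fit[["slope"]],
                 intercept = fit[["intercept"]],
                 mean_diff_mm = m, sd_diff_mm = s,
                 loa_lower_mm = m - multiplier * s,
                 loa_upper_mm = m + multiplier * s,
                 ks_statistic = ks$statistic, ks_pvalue = ks$pvalue,
                 is_normal = ks$is_normal,
                 max_abs_diff_mm = max(abs(d)), n = length(d)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement_report (n = %d)\n", x$n))
  cat(sprintf("  Pearson r: %.2f; fit y = %.2f x + %.2f\n",
              x$pearson_r, x$slope, x$intercept))
  cat(sprintf("  mean diff: %.2f mm, SD %.2f mm, LoA [%.1f, %.1f] mm\n",
              x$mean_diff_mm, x$sd_diff_mm, x$loa_lower_mm, x$loa_upper_mm))
  cat(sprintf("  KS normality: D = %.3f, p = %.3f (%s)\n", x$ks_statistic,
              x$ks_pvalue, if (x$is_normal) "normal" else "not normal"))
  invisible(x)
}

#' Regenerate the published summary statistics from the per-case rows
#'
#' Recomputes every mean/SD summary cell and every agreement statistic
#' (Pearson r, Bland-Altman limits of agreement, maximum absolute
#' navigation-CBCT difference) from the packaged per-case measurements and
#' compares them with the printed values at their printed precision.
#'
#' @param cases Per-case table, as from [model_surgery_cases()].
#' @param summary Printed summary cells, as from [model_surgery_summary()].
#' @param tol_print Acceptable discrepancy in units of the last printed
#'   digit (default 1: computed and printed may differ by at most one unit
#'   in the final decimal place, accommodating cells the source computed on
#'   unrounded internal values).
#' @return Data frame with the printed value, the recomputed value, the
#'   rounded recomputed value and an `ok` flag per cell.
#' @export
reproduce_tables <- function(cases = model_surgery_cases(),
                             summary = model_surgery_summary(),
                             tol_print = 1) {
  computed <- numeric(nrow(summary))
  for (i in seq_len(nrow(summary))) {
    row <- summary[i, ]
    if (row$source == "agreement") {
      nav <- case_series(cases, row$object, row$label, "navigation")
      cb <- case_series(cases, row$object, row$label, "cbct")
      ba <- bland_altman(nav, cb)
      computed[i] <- switch(row$stat,
        pearson_r = ba$pearson_r,
        loa_lower = ba$loa_lower_mm,
        loa_upper = ba$loa_upper_mm,
        max_abs_diff = ba$max_abs_diff_mm)
    } else {
      v <- case_series(cases, row$object, row$label, row$source)
      computed[i] <- if (row$stat == "mean") mean(v) else stats::sd(v)
    }
  }
  rounded <- round_half_away(computed, summary$digits)
  ok <- abs(computed - summary$value) <= tol_print * 10^(-summary$digits) + 1e-12
  data.frame(summary[, c("stat", "object", "label", "source", "digits")],
             printed = summary$value, computed = computed, rounded = rounded,
             exact = abs(rounded - summary$value) < 1e-9, ok = ok)
}
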