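#' Descriptive group summaries
#'
#' Reproduces the layout of a cohort description table: one row-block per
#' group with continuous variables as mean +/- SD and booleans as n (%).
#' Groupings:
#' \itemize{
#'   \item `sport_category`, `sex`: taken from the records;
#'   \item `bmi_class`: `<25`, `25-29.9`, `30-34.9`, `>=35` kg/m^2, with
#'     left-closed boundaries (a BMI of exactly 25.0 falls in `25-29.9`);
#'   \item `fat_mass_class`: normal vs high body fat against the
#'     sex-specific ceiling (`<=22` / `>22` for males, `<=32` / `>32` for
#'     females).
#' }
#' Empty groups are reported with `n = 0` and missing statistics.
#'
#' @param cohort An `athlete_cohort`.
#' @param grouping One of `"sport_category"`, `"sex"`, `"bmi_class"`,
#'   `"fat_mass_class"`.
#' @param thresholds A [threshold_config()] (sex-specific fat-mass limits).
#' @return A tibble in long layout: `group`, `variable`, `statistic`
#'   (`"mean_sd"` or `"n_pct"`), `n`, `mean`, `sd`, `count`, `percent`.
#' @export
summarize_by <- function(cohort,
                         grouping = c("sport_category", "sex", "bmi_class",
                                      "fat_mass_class"),
                         thresholds = threshold_config()) {
  grouping <- match.arg(grouping)
  x <- as_tibble(cohort)
  if (nrow(x) == 0) stop("empty cohort", call. = FALSE)
  prof <- classify_risk_factors(x, thresholds)
  x$bmi <- prof$bmi
  x$ldl_hdl_ratio <- prof$ldl_hdl_ratio

  group <- switch(grouping,
    sport_category = factor(x$sport_category, levels = sport_levels()),
    sex = factor(x$sex, levels = sex_levels()),
    bmi_class = cut(x$bmi, breaks = c(-Inf, 25, 30, 35, Inf), right = FALSE,
                    labels = c("<25", "25-29.9", "30-34.9", ">=35")),
    fat_mass_class = {
      lim <- ifelse(x$sex == "male", thresholds$fat_mass_high_male,
                    thresholds$fat_mass_high_female)
      factor(ifelse(x$fat_mass_pct > lim, "high_fat_mass", "normal_fat_mass"),
             levels = c("normal_fat_mass", "high_fat_mass"))
    }
  )
  if (anyNA(group)) {
    stop("grouping variable not derivable for every record (missing ",
         grouping, ")", call. = FALSE)
  }
  continuous <- c("age", "weight", "bmi", "fat_mass_pct", "waist",
                  "tc", "ldl", "hdl", "tg", "ldl_hdl_ratio")
  booleans <- c("smoker", "family_ath", "family_dyslipidemia",
                "alcohol_user", "hypertension", "diabetes")
  rows <- list()
  for (g in levels(group)) {
    sub <- x[which(group == g), ]
    n <- nrow(sub)
    for (v in continuous) {
      vals <- sub[[v]][!is.na(sub[[v]])]
      rows[[length(rows) + 1]] <- tibble(
        group = g, variable = v, statistic = "mean_sd", n = n,
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1) sd(vals) else NA_real_,
        count = NA_integer_, percent = NA_real_)
    }
    for (v in booleans) {
      vals <- sub[[v]][!is.na(sub[[v]])]
      rows[[length(rows) + 1]] <- tibble(
        group = g, variable = v, statistic = "n_pct", n = n,
        mean = NA_real_, sd = NA_real_,
        count = if (n > 0) sum(vals) else NA_integer_,
        percent = if (length(vals) > 0) 100 * mean(vals) else NA_real_)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "grouping") <- grouping
  out
}

#' Odds ratio from a 2x2 table
#'
#' Point estimate `(a d) / (b c)` with a 95% interval from the log-odds
#' normal approximation (Woolf). When any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to every cell for both the point
#' estimate and the interval. With two empty margins the odds ratio is
#' undefined and reported as missing.
#'
#' @param exposed_pos,exposed_neg,unexposed_pos,unexposed_neg Non-negative
#'   integer cell counts `a`, `b`, `c`, `d` of the exposure-by-condition
#'   table.
#' @param conf Confidence level.
#' @return A list of class `odds_ratio_result`: `table`, `or`, `ci_low`,
#'   `ci_high`, `corrected`.
#' @export
#' @examples
#' odds_ratio_2x2(10, 90, 5, 95)  # OR 2.11
odds_ratio_2x2 <- function(exposed_pos, exposed_neg, unexposed_pos,
                           unexposed_neg, conf = 0.95) {
  cells <- c(a = exposed_pos, b = exposed_neg, c = unexposed_pos,
             d = unexposed_neg)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  undefined <- (cells["a"] + cells["b"] == 0) || (cells["c"] + cells["d"] == 0) ||
    (cells["a"] + cells["c"] == 0) || (cells["b"] + cells["d"] == 0)
  corrected <- !undefined && any(cells == 0)
  w <- if (corrected) cells + 0.5 else cells
  or <- if (undefined) NA_real_ else unname((w["a"] * w["d"]) / (w["b"] * w["c"]))
  if (undefined) {
    ci <- c(NA_real_, NA_real_)
  } else {
    se <- sqrt(sum(1 / w))
    z <- qnorm(1 - (1 - conf) / 2)
    ci <- exp(log(or) + c(-1, 1) * z * se)
  }
  structure(list(table = cells, or = or, ci_low = ci[1], ci_high = ci[2],
                 corrected = corrected, conf = conf),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat("<odds_ratio_result>\n")
  cat(sprintf("  a=%d b=%d c=%d d=%d%s\n", x$table["a"], x$table["b"],
              x$table["c"], x$table["d"],
              if (x$corrected) " (Haldane-Anscombe +0.5)" else ""))
  cat(sprintf("  OR %.3f [%.0f%% CI %.3f-%.3f]\n", x$or, 100 * x$conf,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Univariate odds ratio of a binary factor for a binary condition
#'
#' Convenience wrapper: cross-tabulates an exposure flag against a condition
#' flag over a cohort's risk-factor profiles and calls [odds_ratio_2x2()].
#'
#' @param exposure Logical vector (e.g. `sex == "male"`).
#' @param condition Logical vector (e.g. revised dyslipidemia flag).
#' @inheritParams odds_ratio_2x2
#' @return An `odds_ratio_result`.
#' @export
univariate_or <- function(exposure, condition, conf = 0.95) {
  keep <- !is.na(exposure) & !is.na(condition)
  exposure <- exposure[keep]; condition <- condition[keep]
  odds_ratio_2x2(sum(exposure & condition), sum(exposure & !condition),
                 sum(!exposure & condition), sum(!exposure & !condition),
                 conf = conf)
}
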