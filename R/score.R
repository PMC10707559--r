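#' Count major and minor score criteria
#'
#' Major criteria (lipid): LDL at or above the LDL cut-off; LDL/HDL at or
#' above the revised ratio cut-off. The two are assessed independently, so
#' both can hold. Minor criteria (host factors): male sex; adiposity
#' (BMI at/above the obesity cut-off OR body fat above the sex-specific
#' ceiling); family history of dyslipidemia; presence of any conventional
#' cardiovascular risk factor (smoking, hypertension or diabetes), counted
#' as a single criterion by default regardless of how many of the three are
#' present (`cv_per_factor = TRUE` in the thresholds switches to per-factor
#' counting for sensitivity analysis).
#'
#' @param profiles Output of [classify_risk_factors()].
#' @param thresholds The same [threshold_config()] used for the profiles.
#' @return A tibble: `id`, major/minor flags, `n_major`, `n_minor`.
#' @export
count_criteria <- function(profiles, thresholds = threshold_config()) {
  stopifnot(inherits(thresholds, "threshold_config"))
  p <- as_tibble(profiles)
  if (anyNA(p$ldl_hdl_ratio)) {
    stop("scoring error: record(s) with missing ldl/hdl: ",
         paste(utils::head(p$id[is.na(p$ldl_hdl_ratio)], 5), collapse = ", "),
         call. = FALSE)
  }
  adiposity_bmi <- if (thresholds$adiposity_bmi_inclusive) {
    !is.na(p$bmi) & p$bmi >= thresholds$bmi_obese
  } else {
    !is.na(p$bmi) & p$bmi > thresholds$bmi_obese
  }
  fat_high <- p$fat_mass_high %in% TRUE
  cv_any <- p$smoker | p$hypertension | p$diabetes
  out <- tibble(
    id = p$id,
    major_ldl = p$ldl_high,
    major_ratio = p$ratio_high,
    minor_male = p$sex == "male",
    minor_adiposity = adiposity_bmi | fat_high,
    minor_family_dyslipidemia = p$family_dyslipidemia,
    minor_cv_risk_factor = cv_any
  )
  out$n_major <- out$major_ldl + out$major_ratio
  out$n_minor <- if (thresholds$cv_per_factor) {
    out$minor_male + out$minor_adiposity + out$minor_family_dyslipidemia +
      p$smoker + p$hypertension + p$diabetes
  } else {
    out$minor_male + out$minor_adiposity + out$minor_family_dyslipidemia +
      out$minor_cv_risk_factor
  }
  out
}

risk_levels <- function() c("no_risk", "low", "medium", "high")

#' Four-tier risk category from criteria counts
#'
#' Deterministic classification grid over (number of major criteria, number
#' of minor criteria):
#' \itemize{
#'   \item high: 2 majors and >= 3 minors;
#'   \item medium: 2 majors and 1-2 minors, or 1 major and >= 2 minors;
#'   \item low: 2 majors and no minor, 1 major and 1 minor, or >= 2 minors
#'     without a major;
#'   \item no risk: at most 1 major or 1 minor alone (including none).
#' }
#' The grid is complete, single-valued and monotone: raising either count
#' never lowers the category.
#'
#' @param n_major Integer count(s) in `{0, 1, 2}`. Vectorised.
#' @param n_minor Integer count(s) `>= 0`. Vectorised.
#' @return An ordered factor with levels `no_risk < low < medium < high`.
#' @export
#' @examples
#' classify_risk_category(2, 3)  # high
#' classify_risk_category(1, 2)  # medium
classify_risk_category <- function(n_major, n_minor) {
  if (any(is.na(n_major)) || any(is.na(n_minor)) ||
      any(n_major != as.integer(n_major)) || any(n_minor != as.integer(n_minor)) ||
      any(n_major < 0 | n_major > 2) || any(n_minor < 0)) {
    stop("`n_major` must be in {0, 1, 2} and `n_minor` a count >= 0",
         call. = FALSE)
  }
  out <- rep("no_risk", length(n_major))
  out[(n_major == 2 & n_minor == 0) | (n_major == 1 & n_minor == 1) |
        (n_major == 0 & n_minor >= 2)] <- "low"
  out[(n_major == 2 & n_minor >= 1 & n_minor <= 2) |
        (n_major == 1 & n_minor >= 2)] <- "medium"
  out[n_major == 2 & n_minor >= 3] <- "high"
  factor(out, levels = risk_levels(), ordered = TRUE)
}

#' Score a cohort with the lipid athlete score
#'
#' Excludes athletes on lipid-lowering therapy and records without a lipid
#' panel, computes risk-factor profiles, counts major/minor criteria and
#' assigns the four-tier risk category.
#'
#' @param cohort An `athlete_cohort`.
#' @param thresholds A [threshold_config()].
#' @return A list of class `score_result`:
#'   \describe{
#'     \item{scores}{tibble of per-athlete criteria flags, counts and
#'       `category`;}
#'     \item{frequency}{tibble of category counts and percentages over the
#'       eligible records;}
#'     \item{n_excluded}{records dropped for therapy or missing lipids;}
#'     \item{provenance}{the cohort's provenance label (endurance sport is
#'       noted as a protective factor in the tier description but does not
#'       alter the category).}
#'   }
#' @export
score_cohort <- function(cohort, thresholds = threshold_config()) {
  stopifnot(inherits(cohort, "athlete_cohort"))
  eligible <- eligible_records(cohort)
  if (nrow(eligible) == 0) {
    stop("degenerate input: no eligible records ",
         "(all therapy-flagged or missing lipid panel)", call. = FALSE)
  }
  profiles <- classify_risk_factors(eligible, thresholds)
  crit <- count_criteria(profiles, thresholds)
  crit$category <- classify_risk_category(pmin(crit$n_major, 2L), crit$n_minor)
  freq <- tibble(
    category = risk_levels(),
    n = as.integer(table(factor(crit$category, levels = risk_levels())))
  )
  freq$percent = 100 * freq$n / sum(freq$n)
  structure(list(
    scores = crit,
    frequency = freq,
    n_excluded = nrow(cohort) - nrow(eligible),
    provenance = provenance(cohort)
  ), class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("# Lipid athlete score: %d athlete(s) scored, %d excluded [%s]\n",
              nrow(x$scores), x$n_excluded, x$provenance))
  f <- x$frequency
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-8s %5d (%.1f%%)\n", f$category[i], f$n[i], f$percent[i]))
  }
  invisible(x)
}
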