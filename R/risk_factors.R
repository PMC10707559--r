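#' Body mass index
#'
#' BMI = weight (kg) / height (m)^2, with height supplied in cm.
#'
#' @param weight Body weight in kg (> 0). Vectorised.
#' @param height Standing height in cm (> 0). Vectorised.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' compute_bmi(80, 180)   # 24.69
compute_bmi <- function(weight, height) {
  check_positive(weight, "weight")
  check_positive(height, "height")
  weight / (height / 100)^2
}

#' Body surface area (Mosteller)
#'
#' BSA = sqrt(height (cm) x weight (kg) / 3600), in m^2.
#'
#' @inheritParams compute_bmi
#' @return BSA in m^2.
#' @export
#' @examples
#' compute_bsa_mosteller(80, 180)  # exactly 2
compute_bsa_mosteller <- function(weight, height) {
  check_positive(weight, "weight")
  check_positive(height, "height")
  sqrt(height * weight / 3600)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.na(x) & x <= 0)) {
    stop("`", name, "` must be positive", call. = FALSE)
  }
  invisible(x)
}

#' Classify cardiovascular risk factors and dyslipidemia
#'
#' Computes derived anthropometrics (BMI, Mosteller BSA, waist/hip ratio,
#' LDL/HDL ratio) and every screening risk-factor flag for each record of a
#' cohort:
#' \itemize{
#'   \item `overweight`: waist above the sex-specific limit OR BMI above the
#'     obesity cut-off (waist-based to avoid misclassifying muscular
#'     athletes);
#'   \item `fat_mass_high`: body-fat percentage above the sex-specific
#'     ceiling;
#'   \item `low_hdl`: HDL below the sex-specific limit;
#'   \item `hypertriglyceridemia`: TG above the cut-off;
#'   \item `dyslipidemia_original`: LDL >= `ldl_threshold` OR low HDL OR
#'     LDL/HDL > `ratio_threshold_old`;
#'   \item `dyslipidemia_revised`: LDL >= `ldl_threshold` OR
#'     LDL/HDL >= `ratio_threshold_new`.
#' }
#' Hypertension and diabetes come from the recorded history booleans.
#' Records with missing `ldl` or `hdl` get `NA` lipid flags and are excluded
#' from downstream scoring rather than raising an error.
#'
#' @param cohort An `athlete_cohort` (or any data frame with its columns).
#' @param thresholds A [threshold_config()].
#' @return A tibble, one row per input record: `id`, derived anthropometrics
#'   and all boolean flags.
#' @export
classify_risk_factors <- function(cohort, thresholds = threshold_config()) {
  stopifnot(inherits(thresholds, "threshold_config"))
  x <- as_tibble(cohort)
  if (nrow(x) == 0) stop("empty cohort", call. = FALSE)
  if (any(!x$sex %in% sex_levels())) {
    stop("classification error: every record needs a known sex", call. = FALSE)
  }
  male <- x$sex == "male"
  bmi <- ifelse(!is.na(x$weight) & !is.na(x$height),
                compute_bmi(pmax(x$weight, 1e-9), pmax(x$height, 1e-9)), NA_real_)
  bsa <- ifelse(!is.na(x$weight) & !is.na(x$height),
                compute_bsa_mosteller(pmax(x$weight, 1e-9), pmax(x$height, 1e-9)),
                NA_real_)
  whr <- x$waist / x$hip
  ratio <- x$ldl / x$hdl

  hdl_lim <- ifelse(male, thresholds$hdl_low_male, thresholds$hdl_low_female)
  waist_lim <- ifelse(male, thresholds$waist_male, thresholds$waist_female)
  fat_lim <- ifelse(male, thresholds$fat_mass_high_male,
                    thresholds$fat_mass_high_female)

  low_hdl <- x$hdl < hdl_lim
  ldl_high <- x$ldl >= thresholds$ldl_threshold
  ratio_new <- ratio >= thresholds$ratio_threshold_new
  ratio_old <- ratio > thresholds$ratio_threshold_old
  or_na <- function(a, b) {
    # three-valued OR: TRUE wins over NA, NA wins over FALSE
    out <- a | b
    out[is.na(out) & (a %in% TRUE | b %in% TRUE)] <- TRUE
    out
  }
  tibble(
    id = x$id,
    sex = x$sex,
    bmi = bmi,
    bsa = bsa,
    waist_hip_ratio = whr,
    ldl_hdl_ratio = ratio,
    overweight = or_na(x$waist > waist_lim, bmi > thresholds$bmi_obese),
    fat_mass_high = x$fat_mass_pct > fat_lim,
    hypertension = x$hypertension %in% TRUE,
    diabetes = x$diabetes %in% TRUE,
    smoker = x$smoker %in% TRUE,
    family_ath = x$family_ath %in% TRUE,
    family_dyslipidemia = x$family_dyslipidemia %in% TRUE,
    hypertriglyceridemia = x$tg > thresholds$tg_threshold,
    low_hdl = low_hdl,
    ldl_high = ldl_high,
    ratio_high = ratio_new,
    dyslipidemia_original = or_na(or_na(ldl_high, low_hdl), ratio_old),
    dyslipidemia_revised = or_na(ldl_high, ratio_new)
  )
}
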