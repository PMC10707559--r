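#' Clinical threshold configuration
#'
#' Bundles every cut-point used by the risk-factor classifier and the lipid
#' athlete score. Defaults follow the screening conventions for elite
#' athletes: LDL >= 115 mg/dL, the athlete-specific LDL/HDL ratio cut-off
#' 1.90 (the "revised" dyslipidemia definition), the conventional ratio
#' cut-off 2.78 (the "original" definition), sex-specific low-HDL limits
#' (40/50 mg/dL), triglycerides > 150 mg/dL, waist > 94/80 cm, BMI > 30
#' kg/m^2 and sex-specific body-fat ceilings (22%/32%).
#'
#' Boundary conventions are deliberately asymmetric and mirror the source
#' definitions: LDL and the new ratio cut-off are inclusive (`>=`), the old
#' ratio cut-off, triglycerides, waist and fat-mass limits are strict (`>`),
#' and low HDL is strict below (`<`).
#'
#' @param ldl_threshold LDL cholesterol cut-off, mg/dL (inclusive).
#' @param ratio_threshold_new Revised LDL/HDL ratio cut-off (inclusive).
#' @param ratio_threshold_old Conventional LDL/HDL ratio cut-off (exclusive).
#' @param hdl_low_male,hdl_low_female Low-HDL limits, mg/dL (exclusive below).
#' @param tg_threshold Hypertriglyceridemia cut-off, mg/dL (exclusive).
#' @param bmi_obese BMI cut-off for obesity, kg/m^2.
#' @param waist_male,waist_female Waist-circumference limits, cm (exclusive).
#' @param fat_mass_high_male,fat_mass_high_female Body-fat ceilings, percent
#'   (exclusive).
#' @param sbp_threshold,dbp_threshold Blood-pressure limits, mmHg (inclusive);
#'   used only when numeric pressures are supplied, otherwise the recorded
#'   hypertension history is taken as-is.
#' @param glucose_threshold Fasting glucose limit, mg/dL (inclusive); same
#'   remark as for blood pressure.
#' @param adiposity_bmi_inclusive Logical; if `TRUE` (default) the score's
#'   adiposity minor criterion uses BMI >= `bmi_obese`, if `FALSE` a strict
#'   `>`. At one-decimal BMI precision the two are practically identical.
#' @param cv_per_factor Logical; if `FALSE` (default) smoking, hypertension
#'   and diabetes together count as one minor criterion, if `TRUE` each
#'   counts separately (sensitivity analysis only).
#'
#' @return An object of class `threshold_config` (a named list).
#' @export
#' @examples
#' th <- threshold_config()
#' th$ratio_threshold_new
threshold_config <- function(ldl_threshold = 115,
                             ratio_threshold_new = 1.90,
                             ratio_threshold_old = 2.78,
                             hdl_low_male = 40,
                             hdl_low_female = 50,
                             tg_threshold = 150,
                             bmi_obese = 30,
                             waist_male = 94,
                             waist_female = 80,
                             fat_mass_high_male = 22,
                             fat_mass_high_female = 32,
                             sbp_threshold = 140,
                             dbp_threshold = 90,
                             glucose_threshold = 126,
                             adiposity_bmi_inclusive = TRUE,
                             cv_per_factor = FALSE) {
  th <- list(
    ldl_threshold = ldl_threshold,
    ratio_threshold_new = ratio_threshold_new,
    ratio_threshold_old = ratio_threshold_old,
    hdl_low_male = hdl_low_male,
    hdl_low_female = hdl_low_female,
    tg_threshold = tg_threshold,
    bmi_obese = bmi_obese,
    waist_male = waist_male,
    waist_female = waist_female,
    fat_mass_high_male = fat_mass_high_male,
    fat_mass_high_female = fat_mass_high_female,
    sbp_threshold = sbp_threshold,
    dbp_threshold = dbp_threshold,
    glucose_threshold = glucose_threshold,
    adiposity_bmi_inclusive = isTRUE(adiposity_bmi_inclusive),
    cv_per_factor = isTRUE(cv_per_factor)
  )
  numeric_fields <- setdiff(names(th), c("adiposity_bmi_inclusive", "cv_per_factor"))
  for (nm in numeric_fields) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("threshold `", nm, "` must be a single positive finite number",
           call. = FALSE)
    }
  }
  if (th$ratio_threshold_new >= th$ratio_threshold_old) {
    stop("`ratio_threshold_new` must be below `ratio_threshold_old`",
         call. = FALSE)
  }
  structure(th, class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  cat(sprintf("  LDL >= %g mg/dL; LDL/HDL >= %g (revised) / > %g (original)\n",
              x$ldl_threshold, x$ratio_threshold_new, x$ratio_threshold_old))
  cat(sprintf("  low HDL < %g (M) / < %g (F) mg/dL; TG > %g mg/dL\n",
              x$hdl_low_male, x$hdl_low_female, x$tg_threshold))
  cat(sprintf("  obesity BMI %s %g kg/m^2; waist > %g (M) / > %g (F) cm\n",
              if (x$adiposity_bmi_inclusive) ">=" else ">",
              x$bmi_obese, x$waist_male, x$waist_female))
  cat(sprintf("  fat mass > %g%% (M) / > %g%% (F); CV factors counted %s\n",
              x$fat_mass_high_male, x$fat_mass_high_female,
              if (x$cv_per_factor) "per factor" else "as one criterion"))
  invisible(x)
}

#' Read or write a threshold configuration as YAML
#'
#' @param path File path of a YAML key-value file.
#' @return `read_thresholds()` returns a `threshold_config`;
#'   `write_thresholds()` returns `path` invisibly.
#' @export
read_thresholds <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(threshold_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown threshold field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(threshold_config, vals)
}

#' @rdname read_thresholds
#' @param thresholds A `threshold_config`.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "threshold_config"))
  yaml::write_yaml(unclass(thresholds), path)
  invisible(path)
}
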