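#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @importFrom stats rnorm runif rbinom qnorm pnorm sd quantile binom.test setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

# canonical column order of an athlete cohort table
cohort_columns <- function() {
  c("id", "sex", "age", "ethnicity", "sport_category",
    "height", "weight", "waist", "hip", "fat_mass_pct",
    "tc", "ldl", "hdl", "tg",
    "smoker", "family_ath", "family_dyslipidemia",
    "hypertension", "diabetes", "alcohol_user", "lipid_lowering_therapy")
}

cohort_numeric_columns <- function() {
  c("age", "height", "weight", "waist", "hip", "fat_mass_pct",
    "tc", "ldl", "hdl", "tg")
}

cohort_logical_columns <- function() {
  c("smoker", "family_ath", "family_dyslipidemia",
    "hypertension", "diabetes", "alcohol_user", "lipid_lowering_therapy")
}

sex_levels <- function() c("male", "female")
sport_levels <- function() c("power", "skills", "endurance", "mixed")
ethnicity_levels <- function() c("caucasian", "black", "other")

#' Construct an athlete cohort
#'
#' An athlete cohort is a tibble with one row per athlete, a fixed column
#' dictionary (demographics, sport category, anthropometrics, lipid panel in
#' mg/dL, risk-factor history) and a free-text provenance label. Missing
#' optional fields (`hip`, `ethnicity`, `alcohol_user`, and any lipid or
#' anthropometric value) are carried as `NA`; records lacking `ldl` or `hdl`
#' are retained but skipped by scoring and cut-off analysis.
#'
#' @param records A data frame with at least `id`, `sex`, `ldl`, `hdl`.
#'   Unlisted dictionary columns are added as `NA`.
#' @param provenance Free-text origin label (e.g. `"synthetic, seed=42"`).
#' @param validate Validation mode: `"strict"` (any invariant violation is an
#'   error), `"lenient"` (offending records are dropped with a message), or
#'   `"none"`.
#' @return A tibble of class `athlete_cohort`.
#' @export
athlete_cohort <- function(records, provenance = "unspecified",
                           validate = c("strict", "lenient", "none")) {
  validate <- match.arg(validate)
  records <- as_tibble(records)
  mandatory <- c("id", "sex", "ldl", "hdl")
  missing_cols <- setdiff(mandatory, names(records))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(cohort_columns(), names(records))) {
    records[[col]] <- if (col %in% cohort_numeric_columns()) NA_real_
                      else if (col %in% cohort_logical_columns()) NA
                      else NA_character_
  }
  records <- records[, cohort_columns()]
  records$id <- as.character(records$id)
  for (col in cohort_numeric_columns()) records[[col]] <- as.numeric(records[[col]])
  for (col in cohort_logical_columns()) records[[col]] <- as.logical(records[[col]])
  records$sex <- as.character(records$sex)
  records$sport_category <- as.character(records$sport_category)
  records$ethnicity <- as.character(records$ethnicity)

  if (validate != "none") {
    violations <- record_violations(records)
    bad <- !is.na(violations)
    if (any(bad)) {
      msgs <- paste0("record ", records$id[bad], ": ", violations[bad])
      if (validate == "strict") {
        stop("cohort validation failed for ", sum(bad), " record(s):\n  ",
             paste(utils::head(msgs, 10), collapse = "\n  "), call. = FALSE)
      }
      message("dropped ", sum(bad), " invalid record(s): ",
              paste(utils::head(msgs, 5), collapse = "; "))
      records <- records[!bad, ]
    }
  }
  if (anyDuplicated(records$id)) {
    stop("cohort validation failed: duplicated athlete ids", call. = FALSE)
  }
  structure(records, provenance = provenance,
            class = c("athlete_cohort", class(as_tibble(records))))
}

# one violation string per record, NA when the record is valid; validation is
# total: a record is either accepted or attributed its first specific violation
record_violations <- function(records) {
  n <- nrow(records)
  out <- rep(NA_character_, n)
  note <- function(bad, msg) {
    bad <- which(bad & is.na(out))
    out[bad] <<- msg
  }
  in_range <- function(x, lo, hi) !is.na(x) & (x < lo | x > hi)
  note(is.na(records$id) | records$id == "", "missing id")
  note(!records$sex %in% sex_levels(), "sex not in {male, female}")
  note(!is.na(records$sport_category) &
         !records$sport_category %in% sport_levels(),
       "unknown sport_category")
  note(!is.na(records$ethnicity) &
         !records$ethnicity %in% ethnicity_levels(), "unknown ethnicity")
  note(in_range(records$age, 10, 60), "age outside [10, 60] years")
  note(in_range(records$height, 120, 230), "height outside [120, 230] cm")
  note(in_range(records$weight, 30, 200), "weight outside [30, 200] kg")
  for (col in c("tc", "ldl", "hdl", "tg")) {
    note(!is.na(records[[col]]) & records[[col]] <= 0,
         paste0("non-positive ", col))
  }
  note(!is.na(records$fat_mass_pct) &
         (records$fat_mass_pct <= 0 | records$fat_mass_pct >= 60),
       "fat_mass_pct outside (0, 60)")
  out
}

#' @export
print.athlete_cohort <- function(x, ...) {
  cat(sprintf("# Athlete cohort: %d record(s) [%s]\n",
              nrow(x), attr(x, "provenance") %||% "unspecified"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Provenance label of a cohort
#' @param cohort An `athlete_cohort`.
#' @return The provenance string.
#' @export
provenance <- function(cohort) attr(cohort, "provenance") %||% "unspecified"

#' Read an athlete cohort from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row and `.` decimal
#' separator; `id`, `sex`, `ldl`, `hdl` are mandatory columns. Logical
#' columns accept `true/false`, `TRUE/FALSE`, `1/0` and empty cells (`NA`).
#' In strict mode any invariant violation or unparseable numeric aborts the
#' read; in lenient mode offending records are dropped and counted in a
#' message. Records flagged `lipid_lowering_therapy` are retained here and
#' excluded later by [score_cohort()] and friends.
#'
#' @param path CSV file path.
#' @param strict Logical; strict (default) or lenient validation.
#' @param provenance Provenance label; defaults to the file name.
#' @return An `athlete_cohort`.
#' @export
read_cohort <- function(path, strict = TRUE, provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                  colClasses = "character", fileEncoding = "UTF-8")
  mandatory <- c("id", "sex", "ldl", "hdl")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_fail <- rep(NA_character_, nrow(raw))
  for (col in intersect(cohort_numeric_columns(), names(raw))) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !is.na(raw[[col]]) & is.na(vals)
    parse_fail[bad & is.na(parse_fail)] <-
      paste0("unparseable numeric in `", col, "`")
    raw[[col]] <- vals
  }
  for (col in intersect(cohort_logical_columns(), names(raw))) {
    low <- tolower(raw[[col]])
    vals <- ifelse(low %in% c("true", "1", "t"), TRUE,
                   ifelse(low %in% c("false", "0", "f"), FALSE, NA))
    bad <- !is.na(raw[[col]]) & is.na(vals)
    parse_fail[bad & is.na(parse_fail)] <-
      paste0("unparseable logical in `", col, "`")
    raw[[col]] <- as.logical(vals)
  }
  if (any(!is.na(parse_fail))) {
    bad <- !is.na(parse_fail)
    msgs <- paste0("row ", which(bad), ": ", parse_fail[bad])
    if (strict) {
      stop("cohort record error(s):\n  ",
           paste(utils::head(msgs, 10), collapse = "\n  "), call. = FALSE)
    }
    message("dropped ", sum(bad), " unparseable record(s): ",
            paste(utils::head(msgs, 5), collapse = "; "))
    raw <- raw[!bad, ]
  }
  athlete_cohort(raw, provenance = provenance,
                 validate = if (strict) "strict" else "lenient")
}

#' Write an athlete cohort to CSV
#'
#' Emits the canonical column order; missing values become empty cells so
#' that `read_cohort(write_cohort(x))` reproduces every value and every
#' missingness marker exactly.
#'
#' @param cohort A non-empty `athlete_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "athlete_cohort"))
  if (nrow(cohort) == 0) stop("cannot write an empty cohort", call. = FALSE)
  out <- as.data.frame(cohort)[, cohort_columns()]
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8",
            quote = FALSE)
  invisible(path)
}

#' Records eligible for scoring and cut-off analysis
#'
#' Keeps records with a complete LDL/HDL panel that are not flagged for
#' lipid-lowering therapy (treated athletes are excluded from all lipid
#' analyses by design).
#'
#' @param cohort An `athlete_cohort`.
#' @return The eligible subset, same class.
#' @export
eligible_records <- function(cohort) {
  keep <- !is.na(cohort$ldl) & !is.na(cohort$hdl) &
    !(cohort$lipid_lowering_therapy %in% TRUE)
  cohort[keep, ]
}
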