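#' Run the screening pipeline end to end
#'
#' Wires the stages together: generate (or read) a cohort, classify risk
#' factors, derive the maximum-efficiency LDL/HDL cut-off against the
#' original dyslipidemia definition, score every athlete with the lipid
#' athlete score, and write the descriptive tables. Each run writes exactly
#' one JSON manifest (command, configuration hash, file paths, seed,
#' package version, timestamp) next to the outputs, and all randomness
#' flows from the single generator seed, so identical invocations produce
#' byte-identical output CSVs (the manifest timestamp aside).
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional `athlete_cohort`; if `NULL` one is generated from
#'   `gen_config`.
#' @param gen_config A [generator_config()] used when `cohort` is `NULL`.
#' @param thresholds A [threshold_config()].
#' @param stages Character subset of
#'   `c("simulate", "classify", "cutoff", "score", "tables")`.
#' @return Invisibly, a list with the computed objects (`cohort`,
#'   `profiles`, `cutoff`, `score`, `tables`) and `manifest`.
#' @export
run_pipeline <- function(out_dir,
                         cohort = NULL,
                         gen_config = generator_config(),
                         thresholds = threshold_config(),
                         stages = c("simulate", "classify", "cutoff",
                                    "score", "tables")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  result <- list()

  if (is.null(cohort)) {
    cohort <- generate_cohort(gen_config)
    if ("simulate" %in% stages) {
      p <- file.path(out_dir, "cohort.csv")
      write_cohort(cohort, p)
      paths["cohort"] <- p
    }
  }
  result$cohort <- cohort
  eligible <- eligible_records(cohort)
  profiles <- classify_risk_factors(eligible, thresholds)
  result$profiles <- profiles
  if ("classify" %in% stages) {
    p <- file.path(out_dir, "risk_factors.csv")
    write.csv(profiles, p, row.names = FALSE, na = "")
    paths["risk_factors"] <- p
  }
  if ("cutoff" %in% stages) {
    cut <- max_efficiency_cutoff(profiles$ldl_hdl_ratio,
                                 profiles$dyslipidemia_original)
    result$cutoff <- cut
    p <- file.path(out_dir, "roc_coordinates.csv")
    write.csv(roc_coordinates(profiles$ldl_hdl_ratio,
                              profiles$dyslipidemia_original),
              p, row.names = FALSE)
    paths["roc_coordinates"] <- p
    writeLines(cutoff_report_lines(cut), file.path(out_dir, "cutoff.txt"))
    paths["cutoff"] <- file.path(out_dir, "cutoff.txt")
  }
  if ("score" %in% stages) {
    sc <- score_cohort(cohort, thresholds)
    result$score <- sc
    p <- file.path(out_dir, "scores.csv")
    write.csv(sc$scores, p, row.names = FALSE)
    paths["scores"] <- p
    p2 <- file.path(out_dir, "score_summary.csv")
    write.csv(sc$frequency, p2, row.names = FALSE)
    paths["score_summary"] <- p2
  }
  if ("tables" %in% stages) {
    for (by in c("sport_category", "sex")) {
      p <- file.path(out_dir, paste0("table_", by, ".csv"))
      write.csv(summarize_by(cohort, by, thresholds), p, row.names = FALSE,
                na = "")
      paths[paste0("table_", by)] <- p
    }
  }
  manifest <- list(
    command = paste(stages, collapse = "+"),
    config_hash = config_hash(list(gen = unclass(gen_config),
                                   thresholds = unclass(thresholds))),
    seed = gen_config$seed,
    paths = as.list(paths),
    package_version = as.character(packageVersion("lipidscore")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  result$manifest <- manifest
  invisible(result)
}

# key-value report of a cutoff_result; raw proportions alongside
# one-decimal percentages (rounded half-up)
cutoff_report_lines <- function(cut) {
  pct1 <- function(p) sprintf("%.1f", floor(1000 * p + 0.5) / 10)
  lines <- c(
    sprintf("threshold: %g", cut$threshold),
    sprintf("auc: %.6f", cut$auc),
    sprintf("auc_ci: %.6f %.6f", cut$auc_ci[1], cut$auc_ci[2]))
  for (nm in c("efficiency", "sensitivity", "specificity", "ppv", "npv")) {
    p <- cut[[nm]]
    ci <- cut$ci[[nm]]
    lines <- c(lines,
      sprintf("%s: %s", nm, if (is.na(p)) "NA" else sprintf("%.6f", p)),
      sprintf("%s_pct: %s", nm, if (is.na(p)) "NA" else pct1(p)),
      sprintf("%s_ci: %s", nm,
              if (anyNA(ci)) "NA" else sprintf("%.6f %.6f", ci[1], ci[2])))
  }
  c(lines, sprintf("n_pos: %d", cut$n_pos), sprintf("n_neg: %d", cut$n_neg))
}

config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  # Adler-32 checksum of the serialized configuration; avoids a digest
  # dependency and is exact in double arithmetic
  bytes <- utf8ToInt(s)
  n <- length(bytes)
  a <- (1 + sum(bytes)) %% 65521
  b <- (n + sum(cumsum(bytes))) %% 65521
  sprintf("%08x", b * 65536 + a)
}
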