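#' Area under the empirical ROC curve
#'
#' AUC in the Mann-Whitney form: the probability that a randomly chosen
#' positive carries a higher marker value than a randomly chosen negative,
#' ties counted one half. This equals the trapezoidal area under the
#' empirical ROC curve. Orientation is fixed to "higher marker = more
#' positive"; an AUC below 0.5 is reported as-is (with a warning) rather
#' than auto-flipped.
#'
#' @param values Numeric marker values.
#' @param labels Logical reference condition, same length as `values`.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(1, 2, 2, 3), c(FALSE, TRUE, FALSE, TRUE))  # 0.75
roc_auc <- function(values, labels) {
  check_marker_input(values, labels)
  pos <- values[labels]
  neg <- values[!labels]
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  if (auc < 0.5) {
    warning("AUC below 0.5: the marker is oriented against the condition",
            call. = FALSE)
  }
  auc
}

check_marker_input <- function(values, labels) {
  if (length(values) != length(labels)) {
    stop("`values` and `labels` must have the same length", call. = FALSE)
  }
  if (anyNA(values) || anyNA(labels)) {
    stop("missing values in marker or labels", call. = FALSE)
  }
  if (!any(labels) || all(labels)) {
    stop("degenerate input: need at least one positive and one negative label",
         call. = FALSE)
  }
  invisible(NULL)
}

# Clopper-Pearson exact two-sided 95% CI for x successes out of n
exact_ci <- function(x, n, conf = 0.95) {
  if (is.na(x) || is.na(n) || n == 0) return(c(NA_real_, NA_real_))
  as.numeric(binom.test(x, n, conf.level = conf)$conf.int)
}

# Hanley-McNeil standard-error CI for the AUC
auc_ci_hanley <- function(auc, n_pos, n_neg, conf = 0.95) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- qnorm(1 - (1 - conf) / 2)
  c(max(0, auc - z * se), min(1, auc + z * se))
}

new_cutoff_result <- function(threshold, values, labels, conf = 0.95,
                              auc = NULL) {
  call_pos <- values >= threshold
  tp <- sum(call_pos & labels)
  fp <- sum(call_pos & !labels)
  fn <- sum(!call_pos & labels)
  tn <- sum(!call_pos & !labels)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  prop <- list(
    efficiency = ratio(tp + tn, tp + tn + fp + fn),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn)
  )
  num <- list(efficiency = tp + tn, sensitivity = tp, specificity = tn,
              ppv = tp, npv = tn)
  den <- list(efficiency = tp + tn + fp + fn, sensitivity = tp + fn,
              specificity = tn + fp, ppv = tp + fp, npv = tn + fn)
  ci <- lapply(names(prop), function(nm) {
    if (den[[nm]] == 0) c(NA_real_, NA_real_)
    else exact_ci(num[[nm]], den[[nm]], conf)
  })
  names(ci) <- names(prop)
  if (is.null(auc)) auc <- suppressWarnings(roc_auc(values, labels))
  structure(list(
    threshold = threshold,
    efficiency = prop$efficiency,
    auc = auc,
    auc_ci = auc_ci_hanley(auc, sum(labels), sum(!labels), conf),
    sensitivity = prop$sensitivity,
    specificity = prop$specificity,
    ppv = prop$ppv,
    npv = prop$npv,
    ci = ci,
    table = c(tp = tp, fp = fp, fn = fn, tn = tn),
    n_pos = sum(labels),
    n_neg = sum(!labels),
    conf = conf
  ), class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  pct <- function(p, ci) {
    if (is.na(p)) return("--")
    if (is.null(ci) || anyNA(ci)) return(sprintf("%.1f%%", 100 * p))
    sprintf("%.1f%% [%.1f-%.1f]", 100 * p, 100 * ci[1], 100 * ci[2])
  }
  cat("<cutoff_result>\n")
  cat(sprintf("  threshold (marker >= t positive): %g\n", x$threshold))
  cat(sprintf("  efficiency %s  AUC %.3f [%.3f-%.3f]\n",
              pct(x$efficiency, x$ci$efficiency), x$auc,
              x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  Se %s  Sp %s\n", pct(x$sensitivity, x$ci$sensitivity),
              pct(x$specificity, x$ci$specificity)))
  cat(sprintf("  PPV %s  NPV %s\n", pct(x$ppv, x$ci$ppv), pct(x$npv, x$ci$npv)))
  cat(sprintf("  positives %d, negatives %d\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' Maximum-efficiency cut-point for a continuous marker
#'
#' Scans every observed unique marker value (plus a `+Inf` sentinel
#' representing the call-nobody-positive rule) as a candidate threshold for
#' the decision rule "positive if value >= threshold" and returns the one
#' that maximises efficiency, the overall proportion correctly classified
#' (TP + TN) / N. The chosen efficiency therefore never falls below the
#' majority-class rate. Ties are broken toward the smallest qualifying
#' threshold
#' (which maximises sensitivity at equal efficiency); set
#' `ties = "largest"` for the opposite convention. Sensitivity,
#' specificity, PPV and NPV carry exact Clopper-Pearson 95% intervals; the
#' AUC interval uses the Hanley-McNeil standard error.
#'
#' @inheritParams roc_auc
#' @param ties Tie-break between equally efficient thresholds.
#' @param conf Confidence level for all intervals.
#' @return A `cutoff_result`.
#' @export
max_efficiency_cutoff <- function(values, labels, ties = c("smallest", "largest"),
                                  conf = 0.95) {
  ties <- match.arg(ties)
  check_marker_input(values, labels)
  n <- length(values)
  # observed unique values plus a +Inf sentinel (the call-nobody-positive
  # rule); without the sentinel the efficiency could fall below the
  # majority-class rate. The smallest-threshold tie-break keeps the
  # reported cut-off at an attainable observed value whenever one is
  # equally efficient.
  cand <- c(sort(unique(values)), Inf)
  # efficiency at threshold t: (#pos >= t) + (#neg < t), computed for all
  # candidates at once from cumulative class counts over the sorted values
  ord <- order(values)
  lab_sorted <- labels[ord]
  val_sorted <- values[ord]
  first_idx <- match(cand, val_sorted)           # first position with value >= t
  first_idx[length(cand)] <- n + 1L              # sentinel: nothing called
  cum_pos <- cumsum(lab_sorted)
  cum_neg <- cumsum(!lab_sorted)
  pos_ge <- sum(labels) - c(0, cum_pos)[first_idx]
  neg_lt <- c(0, cum_neg)[first_idx]
  eff <- (pos_ge + neg_lt) / n
  best <- which(eff == max(eff))
  pick <- if (ties == "smallest") best[1] else best[length(best)]
  new_cutoff_result(cand[pick], values, labels, conf)
}

#' Diagnostic performance at a fixed threshold
#'
#' Builds the 2x2 confusion table for the rule "positive if value >=
#' threshold" and reports efficiency, sensitivity, specificity, PPV and NPV
#' with exact intervals. Ratios with an empty denominator (e.g. PPV when no
#' record is called positive) are reported as `NA`, never as zero.
#'
#' @inheritParams roc_auc
#' @param threshold Finite decision threshold, in marker units.
#' @param conf Confidence level.
#' @return A `cutoff_result`.
#' @export
diagnostic_table <- function(values, labels, threshold, conf = 0.95) {
  check_marker_input(values, labels)
  if (!is.finite(threshold)) stop("`threshold` must be finite", call. = FALSE)
  new_cutoff_result(threshold, values, labels, conf)
}

#' ROC curve coordinates
#'
#' Empirical (1 - specificity, sensitivity) pairs for every observed
#' threshold, suitable for plotting or CSV export.
#'
#' @inheritParams roc_auc
#' @return A tibble with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_coordinates <- function(values, labels) {
  check_marker_input(values, labels)
  cand <- c(sort(unique(values)), Inf)
  rows <- lapply(cand, function(t) {
    tp <- sum(values >= t & labels); fn <- sum(values < t & labels)
    tn <- sum(values < t & !labels); fp <- sum(values >= t & !labels)
    tibble(threshold = t, sensitivity = tp / (tp + fn),
           specificity = tn / (tn + fp))
  })
  dplyr::bind_rows(rows)
}
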