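# Independent brute-force oracles for the ROC / cut-point machinery.
# These enumerate directly from the definitions and share no code with the
# implementation they check.

# AUC as the average over all positive-negative pairs of
# 1{pos > neg} + 0.5 * 1{pos == neg}
oracle_auc_pairs <- function(values, labels) {
  pos <- values[labels]
  neg <- values[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# AUC as the trapezoidal area under the empirical ROC curve
oracle_auc_trapezoid <- function(values, labels) {
  thr <- c(-Inf, sort(unique(values)), Inf)
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    sens[i] <- sum(values >= thr[i] & labels) / sum(labels)
    spec[i] <- sum(values < thr[i] & !labels) / sum(!labels)
  }
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  fpr <- fpr[ord]; sens <- sens[ord]
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

# exhaustive maximum-efficiency scan over the observed unique values plus
# the call-nobody-positive rule, smallest threshold winning ties
oracle_max_efficiency <- function(values, labels) {
  cand <- c(sort(unique(values)), Inf)
  eff <- vapply(cand, function(t) {
    mean((values >= t) == labels)
  }, numeric(1))
  list(threshold = cand[which.max(eff)], efficiency = max(eff))
}

# random marker/label instance with ties made likely by value rounding
random_marker_instance <- function(n) {
  values <- round(runif(n, 0, 5), 1)
  labels <- runif(n) < plogis(values - 2.5)
  if (!any(labels)) labels[which.max(values)] <- TRUE
  if (all(labels)) labels[which.min(values)] <- FALSE
  list(values = values, labels = labels)
}

# truncated-normal mean, for the age recovery oracle
truncnorm_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  mu + sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# closed-form ratio-exceedance for the sex-mixture bivariate-normal lipid
# model without sport/family/adiposity effects:
# P(LDL - t * HDL >= 0) per sex, mixed by the male proportion
closed_form_ratio_exceedance <- function(config, rho, threshold = 1.9) {
  p_male <- sum(config$sport_props * config$male_prop_by_sport)
  tail_one <- function(lip) {
    mu <- lip$ldl_mean - threshold * lip$hdl_mean
    s2 <- lip$ldl_sd^2 + threshold^2 * lip$hdl_sd^2 -
      2 * threshold * rho * lip$ldl_sd * lip$hdl_sd
    pnorm(0, mu, sqrt(s2), lower.tail = FALSE)
  }
  p_male * tail_one(config$lipids$male) +
    (1 - p_male) * tail_one(config$lipids$female)
}

# a generator configuration with every non-parametric effect switched off,
# so the lipid panel is exactly the per-sex bivariate-normal model of the
# closed-form oracle above (sport offsets vanish when every sport target
# equals the sex-mixture mean)
plain_lipid_config <- function(n = 50000, seed = 1, rho = 0.5) {
  cfg <- generator_config(n = n, seed = seed, ldl_hdl_correlation = rho,
                          adiposity_lipid_slope = 0,
                          family_dyslipidemia_ldl_shift = 0,
                          endurance_zero_adiposity = FALSE)
  p_m <- cfg$male_prop_by_sport
  mix <- function(m, f) p_m * m + (1 - p_m) * f
  cfg$sport_hdl_means <- mix(cfg$lipids$male$hdl_mean, cfg$lipids$female$hdl_mean)
  cfg
}
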