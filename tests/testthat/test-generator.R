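test_that("the same seed reproduces the identical cohort, new seeds differ", {
  cfg <- generator_config(n = 400, seed = 1)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- generate_cohort(generator_config(n = 400, seed = 2))
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_cohort(generator_config(n = 50, seed = 5)))
  expect_identical(runif(3), before)
})

test_that("generated cohorts satisfy every record invariant", {
  coh <- generate_cohort(generator_config(n = 3000, seed = 8))
  expect_true(all(is.na(lipidscore:::record_violations(as.data.frame(coh)))))
  expect_false(anyDuplicated(coh$id) > 0)
  expect_true(all(coh$ldl > 0 & coh$hdl > 0 & coh$tg > 0 & coh$tc > 0))
  expect_true(all(coh$height >= 120 & coh$height <= 230))
  expect_true(all(coh$age >= 15 & coh$age <= 47))
})

test_that("configured parameters are recovered at large n", {
  # resampling of endurance adiposity deliberately trims that group's upper
  # tail, so the clean parametric layer is checked with it off
  n <- 50000
  cfg <- generator_config(n = n, seed = 13, endurance_zero_adiposity = FALSE)
  coh <- generate_cohort(cfg)
  male <- coh$sex == "male"
  n_m <- sum(male); n_f <- n - n_m
  within3se <- function(est, tgt, se, lbl) {
    expect_lt(abs(est - tgt), 3 * se, label = sprintf("%s (%g vs %g)", lbl, est, tgt))
  }
  # composition
  for (s in names(cfg$sport_props)) {
    p <- cfg$sport_props[[s]]
    within3se(mean(coh$sport_category == s), p, sqrt(p * (1 - p) / n), s)
  }
  p_male <- sum(cfg$sport_props * cfg$male_prop_by_sport)
  within3se(mean(male), p_male, sqrt(p_male * (1 - p_male) / n), "male share")
  # per-sex lipid and anthropometric moments
  bmi <- compute_bmi(coh$weight, coh$height)
  for (sx in c("male", "female")) {
    idx <- if (sx == "male") male else !male
    k <- sum(idx)
    lip <- cfg$lipids[[sx]]; an <- cfg$anthro[[sx]]
    within3se(mean(coh$ldl[idx]), lip$ldl_mean, lip$ldl_sd / sqrt(k), paste(sx, "ldl mean"))
    within3se(sd(coh$ldl[idx]), lip$ldl_sd, lip$ldl_sd / sqrt(2 * k), paste(sx, "ldl sd"))
    within3se(mean(coh$hdl[idx]), lip$hdl_mean, lip$hdl_sd / sqrt(k), paste(sx, "hdl mean"))
    within3se(sd(coh$hdl[idx]), lip$hdl_sd, lip$hdl_sd / sqrt(2 * k), paste(sx, "hdl sd"))
    within3se(mean(coh$tg[idx]), lip$tg_mean, lip$tg_sd / sqrt(k), paste(sx, "tg mean"))
    within3se(mean(coh$weight[idx]), an$weight_mean, an$weight_sd / sqrt(k), paste(sx, "weight"))
    within3se(sd(coh$weight[idx]), an$weight_sd, an$weight_sd / sqrt(2 * k), paste(sx, "weight sd"))
    within3se(mean(bmi[idx]), an$bmi_mean, an$bmi_sd / sqrt(k), paste(sx, "bmi"))
    within3se(sd(bmi[idx]), an$bmi_sd, an$bmi_sd / sqrt(2 * k), paste(sx, "bmi sd"))
    within3se(mean(coh$fat_mass_pct[idx]), an$fat_mean, an$fat_sd / sqrt(k), paste(sx, "fat"))
    within3se(sd(coh$fat_mass_pct[idx]), an$fat_sd, an$fat_sd / sqrt(2 * k), paste(sx, "fat sd"))
    within3se(mean(coh$waist[idx]), an$waist_mean, an$waist_sd / sqrt(k), paste(sx, "waist"))
  }
  # prevalences
  prev_cols <- c(smoker = "smoker", family_ath = "family_ath",
                 family_dyslipidemia = "family_dyslipidemia",
                 hypertension = "hypertension", diabetes = "diabetes",
                 alcohol_user = "alcohol_user")
  for (nm in names(prev_cols)) {
    p <- cfg$prevalence[[nm]]
    within3se(mean(coh[[prev_cols[[nm]]]]), p, sqrt(p * (1 - p) / n), nm)
  }
  # age against the truncated-normal expectation
  age_mu <- truncnorm_mean(cfg$age_mean, cfg$age_sd, cfg$age_min, cfg$age_max)
  within3se(mean(coh$age), age_mu, cfg$age_sd / sqrt(n), "age")
  # sport-level HDL group means land on their configured targets
  for (s in names(cfg$sport_hdl_means)) {
    idx <- coh$sport_category == s
    within3se(mean(coh$hdl[idx]), cfg$sport_hdl_means[[s]],
              15 / sqrt(sum(idx)) + 0.1, paste(s, "hdl"))
  }
  # total cholesterol is Friedewald-consistent
  resid <- coh$tc - (coh$ldl + coh$hdl + coh$tg / 5)
  within3se(mean(resid), 0, cfg$tc_residual_sd / sqrt(n), "tc residual")
  within3se(sd(resid), cfg$tc_residual_sd, 0.1, "tc residual sd")
})

test_that("default-config means survive the endurance adiposity resampling", {
  coh <- generate_cohort(generator_config(n = 50000, seed = 14))
  male <- coh$sex == "male"
  expect_lt(abs(mean(coh$ldl[male]) - 100.8), 3 * 29.4 / sqrt(sum(male)))
  expect_lt(abs(mean(coh$hdl[male]) - 60.7), 3 * 14.8 / sqrt(sum(male)))
  expect_lt(abs(mean(coh$hdl[!male]) - 72.4), 3 * 14.9 / sqrt(sum(!male)))
  # and no endurance athlete carries obesity-range BMI or high body fat
  endur <- coh$sport_category == "endurance"
  bmi <- compute_bmi(coh$weight, coh$height)
  lim <- ifelse(coh$sex == "male", 22, 32)
  expect_true(all(bmi[endur] < 30))
  expect_true(all(coh$fat_mass_pct[endur] <= lim[endur]))
})

test_that("near-zero spread collapses lipid values onto the configured means", {
  cfg <- generator_config(n = 50, seed = 4)
  for (sx in c("male", "female")) {
    cfg$lipids[[sx]]$ldl_sd <- 1e-9
    cfg$lipids[[sx]]$hdl_sd <- 1e-9
    cfg$lipids[[sx]]$tg_sd <- 1e-9
  }
  cfg$adiposity_lipid_slope <- 0
  cfg$family_dyslipidemia_ldl_shift <- 0
  # per-sport sex-mixture means so every sport offset vanishes exactly
  cfg$sport_hdl_means <- cfg$male_prop_by_sport * cfg$lipids$male$hdl_mean +
    (1 - cfg$male_prop_by_sport) * cfg$lipids$female$hdl_mean
  coh <- generate_cohort(cfg)
  male <- coh$sex == "male"
  expect_true(all(abs(coh$ldl[male] - 100.8) < 0.06))   # 0.05 rounding grain
  expect_true(all(abs(coh$ldl[!male] - 95) < 0.06))
  expect_true(all(abs(coh$hdl[male] - 60.7) < 0.06))
})

test_that("infeasible configurations raise configuration errors", {
  cfg <- generator_config(n = 20, seed = 1)
  cfg$adiposity_lipid_slope <- 40   # exceeds the female LDL variance budget
  expect_error(generate_cohort(cfg), "configuration error")
  expect_error(generator_config(sport_props = c(power = 1, skills = 1,
                                                endurance = 0, mixed = 0)),
               "sum to 1")
  expect_error(generator_config(ldl_hdl_correlation = 1.2), "-1, 1")
})

test_that("ratio-correlation calibration matches the closed-form oracle", {
  # with sport, family and adiposity effects off, the exceedance of
  # LDL/HDL >= 1.90 is a two-component normal tail with known solution
  cfg <- plain_lipid_config(n = 60000, seed = 2, rho = 0.5)
  target <- closed_form_ratio_exceedance(cfg, rho = 0.5)
  rho_hat <- calibrate_ratio_correlation(cfg, target_prevalence = target,
                                         tolerance = 0.004, n_sim = 60000)
  expect_lt(abs(as.numeric(rho_hat) - 0.5), 0.1)
  expect_lt(abs(attr(rho_hat, "achieved") - target), 0.004)
  # fixed point: the exceedance at the configured correlation calibrates
  # back to (approximately) that correlation by construction
  expect_error(calibrate_ratio_correlation(cfg, target_prevalence = 0.999),
               "calibration error")
  expect_error(calibrate_ratio_correlation(cfg, target_prevalence = 1.5),
               "target_prevalence")
})

test_that("the hand-written fixture covers the documented edge cases", {
  coh <- fixture_cohort()
  expect_equal(nrow(coh), 12)
  expect_setequal(unique(coh$sport_category), sport_levels())
  expect_setequal(unique(coh$sex), sex_levels())
  expect_true(any(coh$ldl == 115))                       # LDL boundary
  expect_true(any(abs(coh$ldl / coh$hdl - 1.9) < 1e-12)) # ratio boundary
  expect_equal(sum(coh$lipid_lowering_therapy), 1)
  expect_equal(sum(is.na(coh$hdl)), 1)
  sc <- score_cohort(coh)
  expect_true(all(sc$frequency$n >= 1))  # every tier represented
})
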