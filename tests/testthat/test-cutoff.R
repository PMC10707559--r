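test_that("AUC handles separation, inversion and ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_warning(a <- roc_auc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE)),
                 "oriented against")
  expect_equal(a, 0)
  # positives {2, 3} vs negatives {1, 2}: pairs (2>1) + (2==2)/2 + (3>1) +
  # (3>2) = 3.5 of 4
  expect_equal(roc_auc(c(1, 2, 2, 3), c(FALSE, TRUE, FALSE, TRUE)), 0.875)
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), "degenerate")
})

test_that("AUC equals both brute-force forms on random instances", {
  set.seed(101)
  for (i in 1:200) {
    inst <- random_marker_instance(sample(4:50, 1))
    a <- suppressWarnings(roc_auc(inst$values, inst$labels))
    expect_equal(a, oracle_auc_pairs(inst$values, inst$labels),
                 tolerance = 1e-12)
    expect_equal(a, oracle_auc_trapezoid(inst$values, inst$labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant to label permutation and monotone transforms", {
  set.seed(202)
  for (i in 1:25) {
    inst <- random_marker_instance(40)
    a <- suppressWarnings(roc_auc(inst$values, inst$labels))
    perm <- sample(40)
    expect_equal(suppressWarnings(roc_auc(inst$values[perm], inst$labels[perm])), a)
    expect_equal(suppressWarnings(roc_auc(exp(inst$values), inst$labels)), a)
    expect_equal(suppressWarnings(roc_auc(inst$values^3 + 2, inst$labels)), a)
  }
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(303)
  for (i in 1:20) {
    inst <- random_marker_instance(45)
    ref <- as.numeric(pROC::auc(pROC::roc(inst$labels, inst$values,
                                          quiet = TRUE, direction = "<")))
    expect_equal(suppressWarnings(roc_auc(inst$values, inst$labels)), ref,
                 tolerance = 1e-12)
  }
})

test_that("maximum-efficiency cut-point equals the exhaustive scan", {
  set.seed(404)
  for (i in 1:200) {
    inst <- random_marker_instance(sample(4:40, 1))
    got <- max_efficiency_cutoff(inst$values, inst$labels)
    want <- oracle_max_efficiency(inst$values, inst$labels)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$efficiency, want$efficiency, tolerance = 1e-12)
    # never worse than the majority-class guess
    prev <- mean(inst$labels)
    expect_gte(got$efficiency, max(prev, 1 - prev) - 1e-12)
  }
})

test_that("cut-point edge cases: separation, uninformative marker, ties", {
  r <- max_efficiency_cutoff(c(1.0, 1.5, 2.0, 2.5), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$threshold, 2.0)
  expect_equal(r$efficiency, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # constant marker: efficiency 0.5 everywhere, smallest threshold returned
  r <- max_efficiency_cutoff(c(1, 1, 1, 1), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(r$threshold, 1)
  expect_equal(r$efficiency, 0.5)
  r_lg <- max_efficiency_cutoff(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE),
                                ties = "largest")
  r_sm <- max_efficiency_cutoff(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))
  expect_lte(r_sm$threshold, r_lg$threshold)
  expect_gte(r_sm$sensitivity, r_lg$sensitivity)
  expect_error(max_efficiency_cutoff(1:4, rep(TRUE, 4)), "degenerate")
})

test_that("diagnostic table enumerates the 2x2 cells correctly", {
  r <- diagnostic_table(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE), 3)
  expect_equal(unname(r$table), c(1, 1, 1, 1))  # tp fp fn tn
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$specificity, 0.5)
  expect_equal(r$ppv, 0.5)
  expect_equal(r$npv, 0.5)
  # threshold above every value: nothing called positive, PPV undefined
  r <- diagnostic_table(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE), 10)
  expect_equal(r$sensitivity, 0)
  expect_equal(r$specificity, 1)
  expect_true(is.na(r$ppv))
  # perfect separation at the separating threshold
  r <- diagnostic_table(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE), 10)
  expect_equal(c(r$sensitivity, r$specificity, r$ppv, r$npv), rep(1, 4))
  expect_error(diagnostic_table(1:4, c(TRUE, TRUE, FALSE, FALSE), Inf), "finite")
})

test_that("confidence intervals bracket their point estimates", {
  set.seed(505)
  inst <- random_marker_instance(60)
  r <- max_efficiency_cutoff(inst$values, inst$labels)
  for (nm in c("efficiency", "sensitivity", "specificity", "ppv", "npv")) {
    ci <- r$ci[[nm]]
    if (!anyNA(ci)) {
      expect_lte(ci[1], r[[nm]])
      expect_gte(ci[2], r[[nm]])
      expect_true(all(ci >= 0 & ci <= 1))
    }
  }
  expect_lte(r$auc_ci[1], r$auc)
  expect_gte(r$auc_ci[2], r$auc)
  # Clopper-Pearson agrees with the exact binomial test interval
  expect_equal(r$ci$sensitivity,
               as.numeric(binom.test(r$table["tp"],
                                     r$table["tp"] + r$table["fn"])$conf.int))
})

test_that("ROC coordinates start at (1,0) and end at (0,1) in Se/Sp terms", {
  set.seed(606)
  inst <- random_marker_instance(30)
  rc <- roc_coordinates(inst$values, inst$labels)
  expect_equal(rc$sensitivity[1], 1)
  expect_equal(rc$sensitivity[nrow(rc)], 0)
  expect_equal(rc$specificity[nrow(rc)], 1)
  expect_true(all(diff(rc$sensitivity) <= 0))
  expect_true(all(diff(rc$specificity) >= 0))
})
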