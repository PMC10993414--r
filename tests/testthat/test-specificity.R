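test_that("baseline QSAR prediction follows its closed form", {
  m <- baseline_model(1, 0)
  expect_equal(predict_baseline_ic10(3, m), 1e-3)
  # one log unit more hydrophobic -> 10-fold lower predicted IC10
  expect_equal(predict_baseline_ic10(4, m), predict_baseline_ic10(3, m) / 10)
  # brute-force grid against the formula
  for (slope in c(0.5, 0.8, 1.2)) {
    for (intercept in c(-1, 0, 1.7)) {
      mm <- baseline_model(slope, intercept)
      for (ld in c(-1, 0, 2.5, 6)) {
        expect_equal(predict_baseline_ic10(ld, mm),
                     10^(-(slope * ld + intercept)), tolerance = 1e-15)
      }
    }
  }
  expect_warning(predict_baseline_ic10(NA_real_, m), "missing log_dlipw")
  expect_error(baseline_model(-0.5, 0))
})

test_that("toxic ratio and specificity ratios obey their algebra", {
  expect_equal(toxic_ratio(1e-4, 1e-4), 1)
  set.seed(13)
  for (i in 1:50) {
    ic10_b <- 10^runif(1, -8, -2)
    ic10 <- 10^runif(1, -8, -2)
    ec10 <- 10^runif(1, -9, -3)
    tr <- toxic_ratio(ic10_b, ic10)
    expect_equal(tr * ic10, ic10_b, tolerance = 1e-12)
    sr <- specificity_ratios(ic10, ec10, ic10_b)
    expect_equal(sr$sr_baseline, tr * sr$sr_cyto, tolerance = 1e-12)
  }
  # absent inputs propagate as absent
  expect_true(is.na(toxic_ratio(1e-4, NA)))
  sr <- specificity_ratios(NA, 1e-6, 1e-4)
  expect_true(is.na(sr$sr_cyto))
  expect_equal(sr$sr_baseline, 100)
})

test_that("classification follows the strict threshold-10 rules", {
  expect_equal(classify_specificity(1.2, 1.1, 1.3), "baseline_like")
  expect_equal(classify_specificity(381, 46, NA), "specific_both")
  expect_equal(classify_specificity(10, 10, 10), "baseline_like")  # strict
  expect_equal(classify_specificity(2, 46, 120), "specific_mmp")
  expect_equal(classify_specificity(50, 2, 3), "specific_cytotoxic")
  expect_equal(classify_specificity(NA, NA, NA), "inactive")
  expect_equal(classify_specificity(NA, 15, NA), "specific_mmp")
  # configurable threshold
  expect_equal(classify_specificity(8, 1, 1, threshold = 5),
               "specific_cytotoxic")
})

test_that("classification is invariant under common concentration rescaling", {
  set.seed(17)
  m <- baseline_model(0.9, 1.1)
  for (i in 1:25) {
    ld <- runif(1, 0, 5)
    ic10 <- 10^runif(1, -8, -2)
    ec10 <- 10^runif(1, -9, -3)
    base <- predict_baseline_ic10(ld, m)
    cls <- classify_specificity(toxic_ratio(base, ic10),
                                ic10 / ec10, base / ec10)
    for (g in c(1e-3, 1e3)) {
      # rescaling all concentrations by g leaves every ratio unchanged
      cls_g <- classify_specificity(toxic_ratio(base * g, ic10 * g),
                                    (ic10 * g) / (ec10 * g),
                                    (base * g) / (ec10 * g))
      expect_equal(cls_g, cls)
    }
  }
})

test_that("the specificity table joins, predicts and classifies per chemical", {
  chems <- chemical_table(example_chemicals())
  ecs <- data.frame(chem_id = chems$chem_id,
                    ic10 = c(1e-5, 5e-7, 6e-6, 3e-5, 1e-6, 2e-4),
                    ec10_mmp = c(1e-8, 1e-8, 3e-7, 1e-5, 8e-7, 2e-4))
  model <- baseline_model(0.8, 1.2)
  tab <- specificity_table(ecs, chems, model)
  expect_equal(nrow(tab), nrow(chems))
  ok <- is.finite(tab$tr) & is.finite(tab$sr_cyto) & is.finite(tab$sr_baseline)
  expect_equal(tab$sr_baseline[ok], tab$tr[ok] * tab$sr_cyto[ok],
               tolerance = 1e-12)
  expect_error(specificity_table(data.frame(chem_id = "ghost", ic10 = 1e-6,
                                            ec10_mmp = 1e-7),
                                 chems, model), "missing from")
})
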