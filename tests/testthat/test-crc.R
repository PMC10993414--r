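test_that("noise-free log-logistic curves are recovered to <= 1% relative", {
  truth <- list(top = 100, ec50 = 1e-6, hill = 1.5)
  doses <- dilution_series(1e-4, 11)
  data <- data.frame(dose = rep(doses, 2),
                     value = loglogistic_effect(rep(doses, 2), 0, truth$top,
                                                truth$ec50, truth$hill))
  fit <- fit_loglogistic(data, "noiseless", "mmp")
  expect_true(fit$active)
  expect_lt(abs(fit$params[["top"]] - truth$top) / truth$top, 0.01)
  expect_lt(abs(fit$params[["ec50"]] - truth$ec50) / truth$ec50, 0.01)
  expect_lt(abs(fit$params[["hill"]] - truth$hill) / truth$hill, 0.01)
})

test_that("flat responses and failures yield inactive fits, not crashes", {
  doses <- dilution_series(1e-4, 11)
  flat <- data.frame(dose = doses, value = 0)
  fit <- fit_loglogistic(flat, "flat", "mmp")
  expect_false(fit$active)
  expect_match(fit$reason, "below 10")

  expect_error(fit_loglogistic(flat[1:3, ], "few", "mmp"), ">= 5")
})

test_that("effect_conc_at matches its closed forms and is monotone in level", {
  f <- manual_fit(top = 100, ec50 = 3e-7, hill = 1)
  expect_equal(effect_conc_at(f, 10), 3e-7 / 9)
  expect_equal(effect_conc_at(f, 50), 3e-7)
  levels <- seq(5, 95, by = 5)
  ecs <- vapply(levels, function(l) effect_conc_at(f, l), 0)
  expect_true(all(diff(ecs) > 0))
  # not reached within the model
  expect_true(is.na(effect_conc_at(manual_fit(8, 1e-6, 2), 10)))
})

test_that("closed-form inversion agrees with root finding on random fits", {
  set.seed(99)
  for (i in 1:200) {
    top <- runif(1, 15, 100)
    ec50 <- 10^runif(1, -9, -3)
    hill <- runif(1, 0.3, 5)
    level <- runif(1, 1, top * 0.95)
    f <- manual_fit(top, ec50, hill)
    ec <- effect_conc_at(f, level)
    root <- uniroot(function(lc) loglogistic_effect(10^lc, 0, top, ec50,
                                                    hill) - level,
                    lower = log10(ec50) - 12, upper = log10(ec50) + 12,
                    tol = 1e-13)$root
    expect_lt(abs(ec - 10^root) / ec, 1e-9)
  }
})

test_that("the EC_IR1.5 linear fit honours its closed form and masking", {
  # slope 0.5 per uM => EC_IR1.5 = 1 uM (doses in uM here)
  doses <- 1:8
  data <- data.frame(dose = doses, value = 1 + 0.5 * doses)
  fit <- fit_ecir15(data, ic10 = NULL, treatment_id = "lin")
  expect_true(fit$active)
  expect_equal(fit$params[["slope"]], 0.5, tolerance = 1e-12)
  expect_equal(fit$effect_conc, 1, tolerance = 1e-12)

  # all doses above ic10 -> over-masked
  fit2 <- fit_ecir15(data, ic10 = 0.5)
  expect_false(fit2$active)
  expect_equal(fit2$reason, "over-masked")

  # masked doses form the upper tail, none below ic10; masking idempotent
  fit3 <- fit_ecir15(data, ic10 = 4.5)
  expect_true(all(fit3$mask_info$excluded_doses > 4.5))
  expect_equal(sort(fit3$mask_info$excluded_doses), 5:8)
  kept <- data[data$dose <= 4.5, ]
  fit4 <- fit_ecir15(kept, ic10 = 4.5)
  expect_equal(fit4$params[["slope"]], fit3$params[["slope"]])

  # negative slope is inactive
  neg <- data.frame(dose = doses, value = 1 - 0.01 * doses)
  expect_false(fit_ecir15(neg)$active)
})

test_that("the 10 x IC10 rule retains at and below the boundary only", {
  ic10 <- 1e-6
  mk <- function(ratio) {
    f <- manual_fit(90, 1, 1, endpoint = "mmp")
    f$effect_conc <- ratio * ic10
    f$active <- TRUE
    f
  }
  expect_true(derive_ec10_mmp(mk(5), ic10)$active)
  expect_true(derive_ec10_mmp(mk(10), ic10)$active)   # inclusive boundary
  out <- derive_ec10_mmp(mk(20), ic10)
  expect_false(out$active)
  expect_equal(out$reason, "secondary to cytotoxicity")
  # no cytotoxicity cutoff -> rule not applied
  expect_true(derive_ec10_mmp(mk(20), NA_real_)$active)
})

test_that("a tBHQ-like oxidative stress response is recovered at design noise", {
  # positive-control-like inducer: EC_IR1.5 = 3.14 uM generative truth,
  # cytotoxicity well above it so masking keeps the informative region
  truth_ec <- 3.14e-6
  chem <- generative_chemical("tbhq_like", ox_slope = 0.5 / truth_ec,
                              cyto_top = 70, cyto_ec50 = 1e-4,
                              cyto_hill = 2)
  errs <- vapply(1:40, function(s) {
    wells <- simulate_plate(list(chem), noise = noise_model(), seed = 400 + s)
    m <- quantify_plate(wells)
    cyto <- fit_loglogistic(m[m$endpoint == "cytotoxicity" & m$dose > 0, ],
                            "tbhq_like", "cytotoxicity")
    fit <- fit_ecir15(m[m$endpoint == "oxidative_stress" & m$dose > 0, ],
                      ic10 = cyto$effect_conc, treatment_id = "tbhq_like")
    expect_true(fit$active)
    abs(fit$effect_conc - truth_ec) / truth_ec
  }, 0)
  expect_lt(median(errs), 0.25)
  expect_lt(mean(errs > 0.25), 0.1)
})

test_that("EC10 recovery stays accurate across potencies at design noise", {
  # smaller companion to the full recovery study: 12 chemicals over the
  # potency span, median |log10 error| well under 0.1
  set.seed(31)
  n <- 12
  chems <- lapply(seq_len(n), function(i)
    generative_chemical(sprintf("c%02d", i), mmp_top = runif(1, 60, 100),
                        mmp_ec50 = 10^runif(1, -9, -3),
                        mmp_hill = runif(1, 0.8, 2.5)))
  wells <- simulate_plate(chems, noise = noise_model(), seed = 32)
  m <- quantify_plate(wells)
  truth <- truth_table(chems)
  err <- vapply(seq_len(n), function(i) {
    sub <- m[m$treatment_id == chems[[i]]$chem_id & m$endpoint == "mmp" &
               m$dose > 0, ]
    fit <- fit_loglogistic(sub, chems[[i]]$chem_id, "mmp")
    abs(log10(fit$effect_conc / truth$ec10_mmp[i]))
  }, 0)
  expect_lt(median(err), 0.1)
})
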