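test_that("dilution ladders are exactly geometric and strictly decreasing", {
  d <- dilution_series(1e-4, 11, 2)
  expect_length(d, 11)
  expect_true(all(diff(d) < 0))
  expect_equal(d[-length(d)] / d[-1], rep(2, 10), tolerance = 1e-15)
})

test_that("the generator is reproducible from its seed", {
  chems <- example_chemicals()[1:2]
  a <- simulate_plate(chems, seed = 123)
  b <- simulate_plate(chems, seed = 123)
  expect_identical(a, b)
  c <- simulate_plate(chems, seed = 124)
  expect_false(identical(a, c))
})

test_that("plates honour the 384-well capacity and seeding density", {
  wells <- simulate_plate(example_chemicals(), seed = 2)
  per_plate <- table(wells$plate_id)
  expect_true(all(per_plate <= 384))
  expect_true(all(table(wells$plate_id, wells$treatment_kind)[, "solvent_control"] >= 16))
  ctrl <- wells[wells$treatment_kind == "solvent_control", ]
  expect_lt(abs(mean(ctrl$cell_count) - 10000), 200)
  # design overflow: a series longer than one plate
  expect_error(simulate_plate(example_chemicals()[[1]],
                              plate_design(n_conc = 200, n_tech_rep = 2)),
               "overflow")
})

test_that("noise-free plates let the pipeline recover truth exactly", {
  chems <- example_chemicals()
  wells <- simulate_plate(chems, noise = no_noise(), seed = 1)
  m <- quantify_plate(wells)
  truth <- truth_table(chems)
  for (chem in chems[c(3, 6)]) {
    fits <- fit_treatment(m[m$treatment_id == chem$chem_id, ])
    tr <- truth[truth$chem_id == chem$chem_id, ]
    expect_equal(fits$mmp$effect_conc, tr$ec10_mmp, tolerance = 1e-3)
    expect_equal(fits$cyto$effect_conc, tr$ic10, tolerance = 1e-3)
  }
  # cI_potent's ladder brackets its MMP potency; cytotoxicity lies above
  # the tested range and stays inactive
  fits <- fit_treatment(m[m$treatment_id == "cI_potent", ])
  expect_equal(fits$mmp$effect_conc,
               truth$ec10_mmp[truth$chem_id == "cI_potent"],
               tolerance = 1e-3)
  expect_false(fits$cyto$active)
})

test_that("a single-constituent mixture matches the single-chemical curve", {
  chem <- example_chemicals()$unc_24dnp_like
  conc <- 2e-6  # mol/L water; REF ladder spans the curve
  mix <- simulate_mixture_sample(list(list(chem = chem, conc = conc)),
                                 noise = no_noise(), seed = 3,
                                 top_ref = chem$top_conc / conc)
  # at REF rho the mixture sees dose rho * conc of the chemical
  m <- quantify_plate(mix$wells)
  trt <- m[m$endpoint == "mmp" & m$dose > 0, ]
  expected <- loglogistic_effect(trt$dose * conc, 0, chem$mmp[["top"]],
                                 chem$mmp[["ec50"]], chem$mmp[["hill"]])
  expect_equal(trt$value, expected, tolerance = 1e-6)
  # true REF-scale EC10 maps back to the molar EC10
  expect_equal(mix$truth$mmp_ec10_ref * conc,
               truth_table(list(chem))$ec10_mmp, tolerance = 1e-12)
})

test_that("two half-doses of the same chemical equal one full dose", {
  chem <- example_chemicals()$unc_potent
  conc <- 1e-6
  one <- simulate_mixture_sample(list(list(chem = chem, conc = conc)),
                                 noise = no_noise(), seed = 5)
  two <- simulate_mixture_sample(list(list(chem = chem, conc = conc / 2),
                                      list(chem = chem, conc = conc / 2)),
                                 noise = no_noise(), seed = 5)
  expect_equal(one$wells$red_signal, two$wells$red_signal, tolerance = 1e-12)
  expect_equal(one$wells$cell_count, two$wells$cell_count)
  expect_equal(one$truth$mmp_ec10_ref, two$truth$mmp_ec10_ref,
               tolerance = 1e-12)
})

test_that("mixtures with unequal curve shapes need the approximate flag", {
  a <- generative_chemical("a", mmp_top = 90, mmp_ec50 = 1e-6, mmp_hill = 1.5)
  b <- generative_chemical("b", mmp_top = 90, mmp_ec50 = 1e-7, mmp_hill = 3)
  cons <- list(list(chem = a, conc = 1e-8), list(chem = b, conc = 1e-9))
  expect_error(simulate_mixture_sample(cons), "shared curve shape")
  expect_silent(out <- simulate_mixture_sample(cons, approximate = TRUE,
                                               noise = no_noise()))
  expect_true(is.finite(out$truth$mmp_ec10_ref))
})

test_that("withheld constituents vanish from the detection table only", {
  chems <- example_chemicals()
  cons <- list(list(chem = chems$unc_24dnp_like, conc = 1e-6),
               list(chem = chems$unc_potent, conc = 1e-8))
  full <- simulate_mixture_sample(cons, noise = no_noise(), seed = 9)
  part <- simulate_mixture_sample(cons, noise = no_noise(), seed = 9,
                                  withhold = "unc_potent")
  expect_identical(full$wells, part$wells)
  expect_setequal(part$detections$chem_id, "unc_24dnp_like")
})
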