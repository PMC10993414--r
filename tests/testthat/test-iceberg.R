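test_that("relative effect potency follows its definition and is antitone", {
  expect_equal(rep_potency(1e-5, 1e-5), 1)
  expect_equal(rep_potency(1e-5, 1e-7), 100)
  expect_true(is.na(rep_potency(1e-5, NA)))
  set.seed(4)
  ec_i <- sort(10^runif(20, -9, -3))
  reps <- rep_potency(1e-5, ec_i)
  expect_true(all(diff(reps) < 0))
})

test_that("BEQ_bio converts sample potency to water-referenced equivalents", {
  expect_equal(beq_bio(1e-5, 10), 1e-6)
  expect_equal(beq_bio(1e-5, 5), 2 * beq_bio(1e-5, 10))
  expect_true(is.na(beq_bio(1e-5, NA)))
})

test_that("BEQ_chem sums covered detections and tracks the uncovered", {
  reps <- c(a = 1, b = 100, c = NA)
  one <- data.frame(chem_id = "a", concentration = 2e-9)
  r1 <- beq_chem(one, reps)
  expect_equal(r1$beq_chem, 2e-9)
  expect_equal(unname(r1$contributions), 1)

  two <- data.frame(chem_id = c("a", "b"), concentration = c(1e-7, 1e-9))
  r2 <- beq_chem(two, reps)  # equal BEQ_i of 1e-7 each
  expect_equal(unname(r2$contributions), c(0.5, 0.5))
  expect_equal(sum(r2$contributions), 1)

  with_unc <- data.frame(chem_id = c("a", "c"), concentration = c(1e-8, 5e-8))
  r3 <- beq_chem(with_unc, reps)
  expect_equal(r3$uncovered, "c")
  expect_equal(r3$beq_chem, 1e-8)

  r0 <- beq_chem(NULL, reps)
  expect_equal(r0$beq_chem, 0)
  expect_length(r0$contributions, 0)
})

test_that("brute-force summation matches beq_chem on random tables", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(1:8, 1)
    ids <- paste0("x", seq_len(n))
    reps <- 10^runif(n, -2, 3)
    names(reps) <- ids
    det <- data.frame(chem_id = ids, concentration = 10^runif(n, -12, -6))
    got <- beq_chem(det, reps)
    want <- sum(reps[det$chem_id] * det$concentration)
    expect_equal(got$beq_chem, want, tolerance = 1e-12)
    # removing any chemical never increases beq_chem
    for (j in seq_len(n))
      expect_lte(beq_chem(det[-j, , drop = FALSE], reps)$beq_chem,
                 got$beq_chem)
  }
})

test_that("percent explained closes and degrades as defined", {
  expect_equal(pct_explained(2e-6, 2e-6), 100)
  expect_equal(pct_explained(0, 2e-6), 0)
  expect_true(is.na(pct_explained(1e-6, NA)))
})

test_that("rescaling the reference potency leaves the accounting unchanged", {
  set.seed(6)
  ec10_ref <- 2e-5
  ec10_i <- 10^runif(4, -8, -4)
  det <- data.frame(chem_id = paste0("c", 1:4),
                    concentration = 10^runif(4, -10, -7))
  ec10_sample <- 12  # REF
  for (g in c(1, 0.01, 50)) {
    reps <- rep_potency(ec10_ref * g, ec10_i)
    names(reps) <- det$chem_id
    r <- iceberg_sample("s", ec10_ref * g, ec10_sample, det, reps)
    if (g == 1) base <- r
    expect_equal(r$pct_explained, base$pct_explained, tolerance = 1e-12)
    expect_equal(r$contributions, base$contributions, tolerance = 1e-12)
    expect_equal(r$beq_bio / base$beq_bio, g, tolerance = 1e-12)
    expect_equal(r$beq_chem / base$beq_chem, g, tolerance = 1e-12)
  }
})

test_that("iceberg tables tidy per-sample summaries and contributions", {
  reps <- c(a = 2, b = 50)
  det <- data.frame(sample_id = "s1", chem_id = c("a", "b"),
                    concentration = c(1e-8, 1e-9))
  r <- iceberg_sample("s1", 1e-5, 20, det, reps)
  tabs <- iceberg_tables(list(r))
  expect_equal(tabs$summary$beq_bio, 5e-7)
  expect_equal(nrow(tabs$contributions), 2)
  expect_equal(sum(tabs$contributions$contribution), 1)
})
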