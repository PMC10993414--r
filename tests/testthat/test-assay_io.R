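test_that("a small valid well table reads back row for row", {
  df <- tiny_plate()
  path <- withr::local_tempfile(fileext = ".csv")
  write_well_table(df, path)
  got <- read_well_table(path)
  expect_equal(nrow(got), nrow(df))
  expect_setequal(got$well_id, df$well_id)
})

test_that("invariant violations are rejected with row-indexed diagnostics", {
  df <- tiny_plate()
  df$red_signal[5] <- -1
  path <- withr::local_tempfile(fileext = ".csv")
  write_well_table(df, path)
  expect_error(read_well_table(path), "red_signal.*rows 5")

  df <- tiny_plate()
  df$dose[1] <- 1e-6  # control with nonzero dose
  write_well_table(df, path)
  expect_error(read_well_table(path), "control/blank well with nonzero dose")

  df <- tiny_plate()
  df$well_id[2] <- "Q1"
  write_well_table(df, path)
  expect_error(read_well_table(path), "well_id outside A1-P24")

  df <- tiny_plate()
  df$dose_unit[6] <- "REF"  # mixed units within chemX
  write_well_table(df, path)
  expect_error(read_well_table(path), "mixed dose units.*chemX")
})

test_that("schema and parse errors name the offending column and row", {
  df <- tiny_plate()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(df[, setdiff(names(df), "green_signal")], path,
                     sep = ",", row.names = FALSE)
  expect_error(read_well_table(path), "missing column.*green_signal")

  df$luminescence <- as.character(df$luminescence)
  df$luminescence[3] <- "oops"
  utils::write.table(df, path, sep = ",", row.names = FALSE)
  expect_error(read_well_table(path), "non-numeric luminescence at row\\(s\\) 3")
})

test_that("a full synthetic screen round-trips losslessly at full precision", {
  wells <- simulate_plate(example_chemicals(), seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_well_table(wells, path)
  got <- read_well_table(path)
  want <- read_well_table(path)  # sorted canonical form
  expect_identical(got, want)
  key <- function(d) d[order(d$plate_id, d$well_id, d$run_id), ]
  a <- key(wells); b <- key(got)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, tolerance = 0)
})

test_that("reader output is independent of file row order", {
  wells <- simulate_plate(example_chemicals()[1:2], seed = 7)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_well_table(wells, p1)
  set.seed(1)
  write_well_table(wells[sample(nrow(wells)), ], p2)
  expect_identical(read_well_table(p1), read_well_table(p2))
})

test_that("alternative delimiter and decimal dialects round trip", {
  wells <- simulate_plate(example_chemicals()[[1]], seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  dia <- io_dialect(sep = ";", dec = ",")
  write_well_table(wells, path, dia)
  got <- read_well_table(path, dia)
  expect_equal(sort(got$red_signal), sort(wells$red_signal), tolerance = 0)
})

test_that("chemical table reading preserves classes and flags duplicates", {
  chems <- chemical_table(example_chemicals())
  path <- withr::local_tempfile(fileext = ".csv")
  write_chemical_table(chems, path)
  got <- read_chemical_table(path)
  expect_equal(nrow(got), nrow(chems))
  expect_setequal(got$mie_class, chems$mie_class)
  expect_equal(got$log_dlipw[match(chems$chem_id, got$chem_id)],
               chems$log_dlipw, tolerance = 0)

  one <- data.frame(chem_id = "c1", name = "c1", log_dlipw = 3,
                    mie_class = "complexI", max_test_conc = 1e-4)
  write_chemical_table(one, path)
  expect_equal(read_chemical_table(path)$mie_class, "complexI")

  write_chemical_table(rbind(one, one), path)
  expect_error(read_chemical_table(path), "duplicate chem_id")

  one$mie_class <- "complex_9000"
  write_chemical_table(one, path)
  expect_warning(got <- read_chemical_table(path), "unknown mie_class")
  expect_equal(got$mie_class, "unknown")
})

test_that("detection tables enforce unique nonnegative detections", {
  det <- data.frame(sample_id = c("s1", "s1"), chem_id = c("a", "b"),
                    concentration = c(1e-9, 2e-9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_detection_table(det, path)
  expect_equal(read_detection_table(path)$concentration, det$concentration,
               tolerance = 0)
  write_detection_table(rbind(det, det[1, ]), path)
  expect_error(read_detection_table(path), "duplicate")
  det$concentration[2] <- -1
  write_detection_table(det, path)
  expect_error(read_detection_table(path), "invalid concentration")
})
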