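# Synthetic plate-data generator with known ground truth.
#
# Emulates the screening design: 11-point geometric serial dilutions with
# two technical replicates per concentration on 384-well plates carrying
# solvent controls, repeated over independent runs. Signals are generated
# from per-chemical sigmoidal effect curves (MMP, cytotoxicity) and a
# linear induction-ratio model (oxidative stress), with multiplicative
# lognormal noise on fluorescence/luminescence and overdispersed counts
# for cells — strictly positive signals with a realistic CV structure.
# Every generated quantity is reproducible from an explicit seed; no
# hidden global state beyond R's RNG, which is seeded per call.

# Baseline instrument levels for a control well. Arbitrary-unit scales;
# all downstream effects are gain-invariant so the values only set the
# numerical range.
SIGNAL_BASELINE <- list(green = 1000, ratio0 = 2, cells = 10000, lum = 5000)

#' Define a generative chemical with known true curve parameters
#'
#' Per-endpoint truth: (top %, ec50, hill) log-logistic curves for MMP and
#' cytotoxicity, and a linear luciferase induction slope (IR units per M)
#' for oxidative stress. Potency patterns of the screened classes can be
#' emulated by the choice of parameters, e.g. complex I inhibitors with
#' MMP ec50 far below the cytotoxicity ec50, uncouplers with the two
#' coupled, and baseline toxicants with both near the hydrophobicity-QSAR
#' prediction.
#'
#' @param chem_id identifier
#' @param mmp_top,mmp_ec50,mmp_hill MMP truth (top in (0,100], ec50 > 0 M,
#'   hill > 0)
#' @param cyto_top,cyto_ec50,cyto_hill cytotoxicity truth
#' @param ox_slope induction-ratio slope (IR per M, >= 0)
#' @param log_dlipw hydrophobicity descriptor for the QSAR
#' @param mie_class molecular-initiating-event class label
#' @param top_conc highest tested concentration (M); default 100 * the
#'   smaller of the two ec50s, so the dilution ladder brackets the
#'   potency by at least two orders of magnitude
#' @return object of class `generative_chemical`
#' @export
generative_chemical <- function(chem_id, mmp_top = 0, mmp_ec50 = 1e-6,
                                mmp_hill = 1, cyto_top = 0,
                                cyto_ec50 = 1e-6, cyto_hill = 1,
                                ox_slope = 0, log_dlipw = 2,
                                mie_class = "unknown", top_conc = NULL) {
  stopifnot(mmp_ec50 > 0, cyto_ec50 > 0, mmp_hill > 0, cyto_hill > 0,
            mmp_top >= 0, mmp_top <= 100, cyto_top >= 0, cyto_top <= 100,
            ox_slope >= 0)
  if (is.null(top_conc)) {
    active_ec50 <- c(if (mmp_top > 0) mmp_ec50, if (cyto_top > 0) cyto_ec50,
                     if (ox_slope > 0) 0.5 / ox_slope)
    top_conc <- if (length(active_ec50)) 100 * min(active_ec50) else 1e-4
  }
  stopifnot(top_conc > 0)
  structure(list(chem_id = chem_id,
                 mmp = c(top = mmp_top, ec50 = mmp_ec50, hill = mmp_hill),
                 cyto = c(top = cyto_top, ec50 = cyto_ec50, hill = cyto_hill),
                 ox_slope = ox_slope, log_dlipw = log_dlipw,
                 mie_class = mie_class, top_conc = top_conc),
            class = "generative_chemical")
}

#' Noise model for synthetic plates
#'
#' Fluorescence and luminescence get multiplicative lognormal noise with
#' coefficient of variation `signal_cv` (mean-one factors). Cell counts
#' are drawn from a negative binomial with variance mu + dispersion*mu^2;
#' dispersion 0 gives deterministic rounded counts. `signal_cv = 0` and
#' `count_dispersion = 0` yield noise-free plates.
#'
#' @param signal_cv CV of the lognormal signal noise (default 0.05, the
#'   screening design level)
#' @param count_dispersion negative-binomial overdispersion (default
#'   0.0025, approx. 5\% count CV at 10,000 cells/well)
#' @return object of class `noise_model`
#' @export
noise_model <- function(signal_cv = 0.05, count_dispersion = 0.0025) {
  stopifnot(signal_cv >= 0, count_dispersion >= 0)
  structure(list(signal_cv = signal_cv, count_dispersion = count_dispersion),
            class = "noise_model")
}

#' Plate design for the synthetic screen
#'
#' Defaults mirror the screening design: 11 test concentrations per
#' treatment from a geometric 1:2 serial dilution, two technical
#' replicates per concentration, three independent runs, and 16 solvent
#' controls per 384-well plate.
#'
#' @param n_conc concentrations per series (default 11)
#' @param n_tech_rep technical replicates per concentration (default 2)
#' @param n_runs independent experimental runs (default 3)
#' @param dilution_factor serial dilution step (default 2)
#' @param n_controls solvent-control wells per plate (default 16, min 16)
#' @return object of class `plate_design`
#' @export
plate_design <- function(n_conc = 11, n_tech_rep = 2, n_runs = 3,
                         dilution_factor = 2, n_controls = 16) {
  stopifnot(n_conc >= 1, n_tech_rep >= 1, n_runs >= 1, dilution_factor > 1,
            n_controls >= 16)
  structure(list(n_conc = n_conc, n_tech_rep = n_tech_rep, n_runs = n_runs,
                 dilution_factor = dilution_factor,
                 n_controls = n_controls), class = "plate_design")
}

#' Geometric dilution ladder, highest dose first
#'
#' @param top_conc highest dose
#' @param n_conc number of doses
#' @param dilution_factor step between consecutive doses
#' @return strictly decreasing dose vector
#' @export
dilution_series <- function(top_conc, n_conc, dilution_factor = 2) {
  top_conc / dilution_factor^(seq_len(n_conc) - 1)
}

all_well_ids <- function() {
  as.vector(t(outer(LETTERS[1:16], 1:24, paste0)))
}

lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

noisy_count <- function(mu, dispersion) {
  if (dispersion == 0) return(round(mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

# Expected raw signals for a vector of fractional effects (percent) and
# induction ratios.
expected_signals <- function(f_mmp, f_cyto, ir) {
  b <- SIGNAL_BASELINE
  list(green = rep(b$green, length(f_mmp)),
       red = b$green * b$ratio0 * (1 - f_mmp / 100),
       cells = b$cells * (1 - f_cyto / 100),
       lum = b$lum * ir)
}

apply_noise <- function(sig, noise) {
  n <- length(sig$green)
  list(green = sig$green * lognormal_factor(n, noise$signal_cv),
       red = sig$red * lognormal_factor(n, noise$signal_cv),
       cells = noisy_count(sig$cells, noise$count_dispersion),
       lum = sig$lum * lognormal_factor(n, noise$signal_cv))
}

well_rows <- function(plate_id, well_id, treatment_id, treatment_kind,
                      dose, dose_unit, sig, run_id) {
  data.frame(plate_id = plate_id, well_id = well_id,
             treatment_id = treatment_id, treatment_kind = treatment_kind,
             dose = dose, dose_unit = dose_unit, red_signal = sig$red,
             green_signal = sig$green, cell_count = sig$cells,
             luminescence = sig$lum, run_id = run_id,
             stringsAsFactors = FALSE)
}

# Lay one run's treatments out over as many 384-well plates as needed,
# each plate carrying its own controls.
plates_needed <- function(n_chems, design) {
  per_plate <- (384 - design$n_controls) %/% (design$n_conc * design$n_tech_rep)
  if (per_plate < 1)
    stop("design overflow: one dilution series does not fit on a plate",
         call. = FALSE)
  split(seq_len(n_chems), ceiling(seq_len(n_chems) / per_plate))
}

#' Simulate a multi-plate chemical screen with known truth
#'
#' Generates raw well records for a list of generative chemicals under the
#' given design and noise model. Each run lays the chemicals out over as
#' many 384-well plates as needed (each with its own solvent controls);
#' within a plate every chemical gets an 11-point (by default) geometric
#' dilution series with technical replicates. Expected signals per well:
#' green = G0; red = G0 * ratio0 * (1 - f_mmp(c)/100); cell count =
#' N0 * (1 - f_cyto(c)/100) with N0 = 10,000 cells/well seeding; and
#' luminescence = L0 * (1 + slope*c), all before noise.
#'
#' @param chems list of [generative_chemical()] objects
#' @param design a [plate_design()]
#' @param noise a [noise_model()]
#' @param seed integer seed; the output is fully reproducible from it
#' @return well-record data.frame spanning all runs and plates
#' @export
simulate_plate <- function(chems, design = plate_design(),
                           noise = noise_model(), seed = 1) {
  if (inherits(chems, "generative_chemical")) chems <- list(chems)
  set.seed(seed)
  wells <- all_well_ids()
  out <- list()
  layout <- plates_needed(length(chems), design)
  for (run in seq_len(design$n_runs)) {
    run_id <- sprintf("run%d", run)
    for (p in seq_along(layout)) {
      plate_id <- sprintf("plate%02d_%s", p, run_id)
      rows <- list(); cursor <- 1L
      for (ci in layout[[p]]) {
        chem <- chems[[ci]]
        doses <- dilution_series(chem$top_conc, design$n_conc,
                                 design$dilution_factor)
        dose_rep <- rep(doses, each = design$n_tech_rep)
        n <- length(dose_rep)
        f_mmp <- loglogistic_effect(dose_rep, 0, chem$mmp[["top"]],
                                    chem$mmp[["ec50"]], chem$mmp[["hill"]])
        f_cyto <- loglogistic_effect(dose_rep, 0, chem$cyto[["top"]],
                                     chem$cyto[["ec50"]],
                                     chem$cyto[["hill"]])
        ir <- 1 + chem$ox_slope * dose_rep
        sig <- apply_noise(expected_signals(f_mmp, f_cyto, ir), noise)
        rows[[length(rows) + 1L]] <-
          well_rows(plate_id, wells[cursor:(cursor + n - 1L)],
                    chem$chem_id, "chemical", dose_rep, "M", sig, run_id)
        cursor <- cursor + n
      }
      nc <- design$n_controls
      if (cursor + nc - 1L > 384)
        stop("design overflow: controls do not fit on the plate",
             call. = FALSE)
      sig <- apply_noise(expected_signals(rep(0, nc), rep(0, nc),
                                          rep(1, nc)), noise)
      rows[[length(rows) + 1L]] <-
        well_rows(plate_id, wells[cursor:(cursor + nc - 1L)], "DMSO",
                  "solvent_control", 0, "none", sig, run_id)
      out[[length(out) + 1L]] <- do.call(rbind, rows)
    }
  }
  reset_rows(do.call(rbind, out))
}

#' Simulate a concentration-additive water-extract sample
#'
#' Builds a synthetic enriched water extract from known constituents.
#' At relative enrichment factor rho the mixture's toxic units per
#' endpoint are T(rho) = sum(rho * C_i / ec50_i) and the expected effect
#' is top / (1 + T^-hill) with the constituents' common hill (and top);
#' induction ratios add linearly, IR = 1 + rho * sum(C_i * slope_i). The
#' REF dilution ladder (default top REF 100) is simulated as one plate
#' per run, and the matching detected-concentration table is emitted,
#' optionally withholding constituents to mimic unidentified chemicals.
#'
#' @param constituents data.frame with columns chem (list of
#'   [generative_chemical()]) and conc (mol per L of original water), or a
#'   list of `list(chem=, conc=)` pairs
#' @param design a [plate_design()]
#' @param noise a [noise_model()]
#' @param seed integer seed
#' @param sample_id sample identifier (default "sample1")
#' @param top_ref highest tested REF (default 100)
#' @param withhold chem_ids omitted from the detection table
#' @param approximate allow constituents with unequal hill/top, combined
#'   with toxic-unit-weighted parameters (default FALSE: unequal
#'   parameters are an error)
#' @return list with `wells` (well records), `detections` (sample_id,
#'   chem_id, concentration), and `truth` (per-endpoint true sample EC10
#'   on the REF scale)
#' @export
simulate_mixture_sample <- function(constituents, design = plate_design(),
                                    noise = noise_model(), seed = 1,
                                    sample_id = "sample1", top_ref = 100,
                                    withhold = character(0),
                                    approximate = FALSE) {
  if (!is.data.frame(constituents)) {
    chem_list <- lapply(constituents, `[[`, "chem")
    conc <- vapply(constituents, `[[`, numeric(1), "conc")
  } else {
    chem_list <- constituents$chem
    conc <- constituents$conc
  }
  stopifnot(length(chem_list) >= 1, all(conc >= 0))
  set.seed(seed)

  mix_params <- function(endpoint) {
    tops <- vapply(chem_list, function(ch) ch[[endpoint]][["top"]], 0)
    hills <- vapply(chem_list, function(ch) ch[[endpoint]][["hill"]], 0)
    ec50s <- vapply(chem_list, function(ch) ch[[endpoint]][["ec50"]], 0)
    act <- tops > 0
    if (!any(act)) return(list(tu_per_ref = 0, top = 0, hill = 1))
    if (!approximate &&
        (length(unique(hills[act])) > 1 || length(unique(tops[act])) > 1))
      stop(sprintf(
        "constituents differ in %s hill/top; concentration addition %s",
        endpoint, "requires a shared curve shape (set approximate = TRUE)"),
        call. = FALSE)
    tu <- conc[act] / ec50s[act]
    w <- tu / sum(tu)
    list(tu_per_ref = sum(tu), top = sum(w * tops[act]),
         hill = sum(w * hills[act]))
  }
  mmp <- mix_params("mmp"); cyto <- mix_params("cyto")
  slope_ref <- sum(conc * vapply(chem_list, `[[`, 0, "ox_slope"))

  ca_effect <- function(ref, par) {
    if (par$tu_per_ref == 0) return(rep(0, length(ref)))
    tu <- ref * par$tu_per_ref
    ifelse(tu > 0, par$top / (1 + tu^(-par$hill)), 0)
  }
  refs <- dilution_series(top_ref, design$n_conc, design$dilution_factor)
  wells <- all_well_ids()
  out <- list()
  for (run in seq_len(design$n_runs)) {
    run_id <- sprintf("run%d", run)
    plate_id <- sprintf("%s_%s", sample_id, run_id)
    dose_rep <- rep(refs, each = design$n_tech_rep)
    n <- length(dose_rep)
    sig <- apply_noise(expected_signals(ca_effect(dose_rep, mmp),
                                        ca_effect(dose_rep, cyto),
                                        1 + slope_ref * dose_rep), noise)
    trt <- well_rows(plate_id, wells[seq_len(n)], sample_id,
                     "water_extract", dose_rep, "REF", sig, run_id)
    nc <- design$n_controls
    sigc <- apply_noise(expected_signals(rep(0, nc), rep(0, nc),
                                         rep(1, nc)), noise)
    ctl <- well_rows(plate_id, wells[(n + 1L):(n + nc)], "DMSO",
                     "solvent_control", 0, "none", sigc, run_id)
    out[[length(out) + 1L]] <- rbind(trt, ctl)
  }
  ids <- vapply(chem_list, `[[`, "", "chem_id")
  keep <- !ids %in% withhold & conc > 0
  detections <- data.frame(sample_id = sample_id, chem_id = ids[keep],
                           concentration = conc[keep],
                           stringsAsFactors = FALSE)
  true_ec10_ref <- function(par) {
    if (par$top <= 10) return(NA_real_)
    (10 / (par$top - 10))^(1 / par$hill) / par$tu_per_ref
  }
  list(wells = reset_rows(do.call(rbind, out)),
       detections = detections,
       truth = list(mmp_ec10_ref = true_ec10_ref(mmp),
                    cyto_ic10_ref = true_ec10_ref(cyto)))
}

#' Ground-truth effect concentrations for generative chemicals
#'
#' @param chems list of [generative_chemical()] objects
#' @return data.frame with true EC10 (MMP), IC10 (cytotoxicity) and
#'   EC_IR1.5 per chemical (NA where the endpoint's truth never reaches
#'   the effect level)
#' @export
truth_table <- function(chems) {
  if (inherits(chems, "generative_chemical")) chems <- list(chems)
  ec <- function(par, level = 10) {
    if (par[["top"]] <= level) return(NA_real_)
    par[["ec50"]] * (level / (par[["top"]] - level))^(1 / par[["hill"]])
  }
  do.call(rbind, lapply(chems, function(ch) {
    data.frame(chem_id = ch$chem_id,
               ec10_mmp = ec(ch$mmp), ic10 = ec(ch$cyto),
               ec_ir15 = if (ch$ox_slope > 0) 0.5 / ch$ox_slope else NA_real_,
               log_dlipw = ch$log_dlipw, mie_class = ch$mie_class,
               top_conc = ch$top_conc, stringsAsFactors = FALSE)
  }))
}

#' Chemical property table for generative chemicals
#'
#' @param chems list of [generative_chemical()] objects
#' @return data.frame in the [read_chemical_table()] schema
#' @export
chemical_table <- function(chems) {
  if (inherits(chems, "generative_chemical")) chems <- list(chems)
  do.call(rbind, lapply(chems, function(ch) {
    data.frame(chem_id = ch$chem_id, name = ch$chem_id,
               log_dlipw = ch$log_dlipw, mie_class = ch$mie_class,
               max_test_conc = ch$top_conc, stringsAsFactors = FALSE)
  }))
}

#' Example chemical set spanning the screened potency patterns
#'
#' Six synthetic chemicals emulating the classes seen in mitochondrial
#' screening: two complex I inhibitor profiles (MMP disruption orders of
#' magnitude more potent than cytotoxicity), a complex III profile, an
#' uncoupler profile with MMP and cytotoxicity potency coupled (reference
#' 24DNP-like, with a mild oxidative stress response), a second uncoupler,
#' and a baseline toxicant whose cytotoxicity equals the hydrophobicity-
#' QSAR prediction under `model` and whose MMP effect tracks cytotoxicity.
#'
#' @param model a [baseline_model()] used to place the baseline toxicant's
#'   potency on its own QSAR prediction
#' @return named list of [generative_chemical()] objects
#' @export
example_chemicals <- function(model = baseline_model(0.8, 1.2)) {
  base_ic10 <- predict_baseline_ic10(3.0, model)
  base_ec50 <- base_ic10 * 6  # top 70, hill 1: ec10 = ec50 * 10/60
  list(
    cI_potent = generative_chemical(
      "cI_potent", mmp_top = 95, mmp_ec50 = 5e-8, mmp_hill = 1.5,
      cyto_top = 70, cyto_ec50 = 2e-5, cyto_hill = 2, log_dlipw = 2.5,
      mie_class = "complexI", top_conc = 5e-6),
    cI_rotenone_like = generative_chemical(
      "cI_rotenone_like", mmp_top = 95, mmp_ec50 = 1e-8, mmp_hill = 1.5,
      cyto_top = 80, cyto_ec50 = 5e-7, cyto_hill = 2, log_dlipw = 4.0,
      mie_class = "complexI", top_conc = 5e-6),
    cIII_moderate = generative_chemical(
      "cIII_moderate", mmp_top = 90, mmp_ec50 = 3e-7, mmp_hill = 1.2,
      cyto_top = 60, cyto_ec50 = 6e-6, cyto_hill = 2, log_dlipw = 3.2,
      mie_class = "complexIII", top_conc = 3e-5),
    unc_24dnp_like = generative_chemical(
      "unc_24dnp_like", mmp_top = 95, mmp_ec50 = 2e-5, mmp_hill = 1.8,
      cyto_top = 90, cyto_ec50 = 6e-5, cyto_hill = 1.8, ox_slope = 5e4,
      log_dlipw = 1.8, mie_class = "uncoupler", top_conc = 2e-3),
    unc_potent = generative_chemical(
      "unc_potent", mmp_top = 95, mmp_ec50 = 8e-7, mmp_hill = 1.8,
      cyto_top = 90, cyto_ec50 = 2e-6, cyto_hill = 1.8, log_dlipw = 2.9,
      mie_class = "uncoupler", top_conc = 1e-4),
    baseline_tox = generative_chemical(
      "baseline_tox", mmp_top = 70, mmp_ec50 = base_ec50, mmp_hill = 1,
      cyto_top = 70, cyto_ec50 = base_ec50, cyto_hill = 1,
      log_dlipw = 3.0, mie_class = "baseline", top_conc = 100 * base_ic10)
  )
}
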