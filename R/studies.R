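# Self-contained simulation studies used to validate the pipeline end to
# end: potency recovery across the screened range, iceberg closure under
# concentration addition, and specificity-class recovery. Each study
# generates its own data with the synthetic generator, runs the ordinary
# analysis path, and reports summary statistics.

#' EC10 recovery study at the screening design
#'
#' Draws `n_chems` synthetic chemicals with MMP potencies spanning six
#' orders of magnitude (ec50 uniform on log10 [1e-9, 1e-3] M, top uniform
#' on [60, 100]%, hill uniform on [0.8, 2.5]), simulates them at the
#' screening design (11 concentrations, duplicate wells, 3 runs) under the
#' given noise model, refits each curve, and reports the log10 recovery
#' error of the EC10.
#'
#' @param n_chems number of chemicals (default 100)
#' @param noise a [noise_model()] (default the 5\% CV design level)
#' @param seed integer seed for both truth generation and simulation
#' @param design a [plate_design()]
#' @return data.frame with chem_id, true and estimated EC10, active flag
#'   and `log10_err` = log10(est/true)
#' @export
ec10_recovery_study <- function(n_chems = 100, noise = noise_model(),
                                seed = 1, design = plate_design()) {
  set.seed(seed)
  chems <- lapply(seq_len(n_chems), function(i)
    generative_chemical(sprintf("sim%03d", i),
                        mmp_top = stats::runif(1, 60, 100),
                        mmp_ec50 = 10^stats::runif(1, -9, -3),
                        mmp_hill = stats::runif(1, 0.8, 2.5)))
  wells <- simulate_plate(chems, design, noise, seed = seed + 1)
  m <- quantify_plate(wells)
  m <- m[m$endpoint == "mmp" & m$dose > 0, ]
  truth <- truth_table(chems)
  rows <- lapply(seq_len(n_chems), function(i) {
    id <- chems[[i]]$chem_id
    fit <- fit_loglogistic(m[m$treatment_id == id, ], id, "mmp")
    est <- if (is.finite(fit$effect_conc)) fit$effect_conc else NA_real_
    data.frame(chem_id = id, true_ec10 = truth$ec10_mmp[i], est_ec10 = est,
               active = isTRUE(fit$active),
               log10_err = log10(est / truth$ec10_mmp[i]),
               stringsAsFactors = FALSE)
  })
  reset_rows(do.call(rbind, rows))
}

# Uncoupler-like constituents sharing a common curve shape, so strict
# concentration addition holds exactly; the first is the BEQ reference.
closure_constituents <- function() {
  shape <- list(top = 95, hill = 1.8)
  mk <- function(id, ec50, ld) generative_chemical(
    id, mmp_top = shape$top, mmp_ec50 = ec50, mmp_hill = shape$hill,
    cyto_top = 90, cyto_ec50 = ec50 * 4, cyto_hill = 1.8, log_dlipw = ld,
    mie_class = "uncoupler")
  list(ref_unc = mk("ref_unc", 2e-5, 1.8),
       unc_a = mk("unc_a", 4e-6, 2.4),
       unc_b = mk("unc_b", 8e-7, 2.9))
}

#' Iceberg closure study under concentration addition
#'
#' Simulates single-chemical screens for three same-shape uncoupler-like
#' constituents (the first being the BEQ reference), fits their molar
#' EC10s and relative effect potencies, then simulates a fully
#' characterised concentration-additive water sample containing all
#' three, fits the sample's REF-scale EC10, and closes the BEQ
#' accounting. With every constituent detected the percent of the
#' measured mixture effect explained converges to 100 as noise vanishes.
#'
#' @param noise a [noise_model()]
#' @param seed integer seed
#' @param withhold chem_ids excluded from the detection table, simulating
#'   unidentified mixture constituents
#' @return list: `pct_explained`, `beq_bio`, `beq_chem`, `contributions`,
#'   `withheld_beq_fraction` (true BEQ fraction of withheld constituents),
#'   and the fitted `ec10_ref` and `ec10_sample_ref`
#' @export
mixture_closure_study <- function(noise = noise_model(), seed = 1,
                                  withhold = character(0)) {
  chems <- closure_constituents()
  conc <- c(ref_unc = 3e-6, unc_a = 4e-7, unc_b = 6e-8)
  wells <- simulate_plate(chems, noise = noise, seed = seed)
  m <- quantify_plate(wells)
  m <- m[m$endpoint == "mmp" & m$dose > 0, ]
  ec10 <- vapply(names(chems), function(id) {
    fit <- fit_loglogistic(m[m$treatment_id == id, ], id, "mmp")
    if (isTRUE(fit$active)) fit$effect_conc else NA_real_
  }, 0)
  reps <- rep_potency(ec10[["ref_unc"]], ec10)
  names(reps) <- names(chems)

  cons <- lapply(names(chems), function(id)
    list(chem = chems[[id]], conc = conc[[id]]))
  mix <- simulate_mixture_sample(cons, noise = noise, seed = seed + 1,
                                 sample_id = "closure", top_ref = 30,
                                 withhold = withhold)
  mm <- quantify_plate(mix$wells)
  sample_fit <- fit_loglogistic(mm[mm$endpoint == "mmp" & mm$dose > 0, ],
                                "closure", "mmp")
  bb <- beq_bio(ec10[["ref_unc"]],
                if (isTRUE(sample_fit$active)) sample_fit$effect_conc
                else NA_real_)
  bc <- beq_chem(mix$detections, reps)
  true_beq <- vapply(names(chems), function(id)
    conc[[id]] / truth_table(chems[id])$ec10_mmp, 0)
  list(pct_explained = pct_explained(bc$beq_chem, bb), beq_bio = bb,
       beq_chem = bc$beq_chem, contributions = bc$contributions,
       withheld_beq_fraction = sum(true_beq[withhold]) / sum(true_beq),
       ec10_ref = ec10[["ref_unc"]],
       ec10_sample_ref = sample_fit$effect_conc)
}

#' Specificity-class recovery study
#'
#' Repeatedly simulates a noisy plate carrying one pure baseline toxicant
#' (cytotoxicity IC10 placed exactly on its hydrophobicity-QSAR
#' prediction, MMP tracking cytotoxicity) and one complex-I-inhibitor
#' profile (MMP potency far below cytotoxicity), runs quantification,
#' fitting, masking and classification, and reports how often each
#' profile lands in its expected class (`baseline_like` and
#' `specific_mmp`/`specific_both` respectively).
#'
#' @param n_rep number of replicate simulations (default 200)
#' @param noise a [noise_model()]
#' @param seed integer seed
#' @param model a [baseline_model()] shared by generation and analysis
#' @return list with `baseline_rate`, `complexI_rate`, and the raw
#'   per-replicate class table
#' @export
classification_recovery_study <- function(n_rep = 200,
                                          noise = noise_model(), seed = 1,
                                          model = baseline_model(0.8, 1.2)) {
  base_ic10 <- predict_baseline_ic10(3.0, model)
  chems <- list(
    baseline = generative_chemical(
      "baseline", mmp_top = 70, mmp_ec50 = base_ic10 * 6, mmp_hill = 1,
      cyto_top = 70, cyto_ec50 = base_ic10 * 6, cyto_hill = 1,
      log_dlipw = 3.0, mie_class = "baseline",
      top_conc = 100 * base_ic10),
    complexI = generative_chemical(
      "complexI", mmp_top = 95, mmp_ec50 = 5e-8, mmp_hill = 1.5,
      cyto_top = 70, cyto_ec50 = 2e-5, cyto_hill = 2, log_dlipw = 2.5,
      mie_class = "complexI", top_conc = 5e-6))
  chem_tab <- chemical_table(chems)
  cls <- matrix(NA_character_, n_rep, 2,
                dimnames = list(NULL, names(chems)))
  for (r in seq_len(n_rep)) {
    wells <- simulate_plate(chems, noise = noise, seed = seed + r)
    m <- quantify_plate(wells)
    ecs <- do.call(rbind, lapply(names(chems), function(id) {
      f <- fit_treatment(m[m$treatment_id == id, ])
      data.frame(chem_id = id,
                 ic10 = if (isTRUE(f$cyto$active)) f$cyto$effect_conc else NA,
                 ec10_mmp = if (isTRUE(f$mmp$active)) f$mmp$effect_conc else NA)
    }))
    spec <- specificity_table(ecs, chem_tab, model)
    cls[r, ] <- spec$classification[match(names(chems), spec$chem_id)]
  }
  list(baseline_rate = mean(cls[, "baseline"] == "baseline_like"),
       complexI_rate = mean(cls[, "complexI"] %in%
                              c("specific_mmp", "specific_both")),
       classes = cls)
}
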