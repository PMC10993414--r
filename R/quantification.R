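# Per-well effect quantification against same-plate solvent controls.
#
# Normalisation is plate-internal: every plate carries its own solvent
# controls, which absorbs plate-to-plate gain differences. All three
# measures are invariant under a uniform positive rescaling of the raw
# signals on a plate.

MIN_CONTROL_WELLS <- 3L

control_rows <- function(plate) plate$treatment_kind == "solvent_control"

#' Per-well MMP effect from the red/green dye ratio
#'
#' For each well the red/green fluorescence ratio r is formed and expressed
#' relative to the mean solvent-control ratio on the same plate:
#' effect\% = (1 - r / mean(r_control)) * 100. The effect is 0 at control
#' level and 100 at complete loss of the red aggregate signal (complete
#' loss of mitochondrial membrane potential). Negative values (ratio above
#' control, e.g. hyperpolarisation or noise) are retained.
#'
#' Wells with zero green signal cannot form a ratio; they are dropped with
#' a warning. At least 3 usable solvent-control wells per plate are
#' required.
#'
#' @param wells well-record data.frame for one or more plates
#' @return data.frame (treatment_id, dose, dose_unit, endpoint, value,
#'   plate_id, well_id, run_id) with endpoint "mmp" and value in percent
#' @export
mmp_effect <- function(wells) {
  per_plate(wells, function(plate) {
    zero_green <- plate$green_signal == 0
    if (any(zero_green)) {
      warning(sprintf("plate %s: %d well(s) with zero green signal excluded",
                      plate$plate_id[1], sum(zero_green)), call. = FALSE)
      plate <- plate[!zero_green, , drop = FALSE]
    }
    ctrl <- control_rows(plate)
    if (sum(ctrl) < MIN_CONTROL_WELLS)
      stop(sprintf("plate %s: fewer than %d usable solvent-control wells",
                   plate$plate_id[1], MIN_CONTROL_WELLS), call. = FALSE)
    r <- plate$red_signal / plate$green_signal
    r_ctrl <- mean(r[ctrl])
    measures(plate, "mmp", (1 - r / r_ctrl) * 100)
  })
}

#' Per-well cytotoxicity effect from cell counts
#'
#' effect\% = (1 - N / mean(N_control)) * 100 with N the well cell count
#' and the mean taken over the plate's solvent controls; 0 at control
#' level, 100 when no cells remain.
#'
#' @inheritParams mmp_effect
#' @return data.frame as for [mmp_effect()], endpoint "cytotoxicity"
#' @export
cytotoxicity_effect <- function(wells) {
  per_plate(wells, function(plate) {
    ctrl <- control_rows(plate)
    if (sum(ctrl) < MIN_CONTROL_WELLS)
      stop(sprintf("plate %s: fewer than %d solvent-control wells",
                   plate$plate_id[1], MIN_CONTROL_WELLS), call. = FALSE)
    n_ctrl <- mean(plate$cell_count[ctrl])
    if (n_ctrl == 0)
      stop(sprintf("plate %s: mean control cell count is zero",
                   plate$plate_id[1]), call. = FALSE)
    measures(plate, "cytotoxicity", (1 - plate$cell_count / n_ctrl) * 100)
  })
}

#' Per-well luciferase induction ratio
#'
#' IR = L / mean(L_control) with L the well luminescence; solvent-control
#' wells average to IR = 1 by construction.
#'
#' @inheritParams mmp_effect
#' @return data.frame as for [mmp_effect()], endpoint "oxidative_stress",
#'   value is the unitless induction ratio (>= 0)
#' @export
induction_ratio <- function(wells) {
  per_plate(wells, function(plate) {
    ctrl <- control_rows(plate)
    if (sum(ctrl) < MIN_CONTROL_WELLS)
      stop(sprintf("plate %s: fewer than %d solvent-control wells",
                   plate$plate_id[1], MIN_CONTROL_WELLS), call. = FALSE)
    l_ctrl <- mean(plate$luminescence[ctrl])
    if (l_ctrl == 0)
      stop(sprintf("plate %s: mean control luminescence is zero",
                   plate$plate_id[1]), call. = FALSE)
    measures(plate, "oxidative_stress", plate$luminescence / l_ctrl)
  })
}

#' Quantify all three endpoints for a set of plates
#'
#' Convenience wrapper returning the row-bound output of [mmp_effect()],
#' [cytotoxicity_effect()] and [induction_ratio()]. Technical replicates
#' stay as separate rows; averaging happens only in curve fitting.
#'
#' @inheritParams mmp_effect
#' @return tidy data.frame of per-well endpoint measures
#' @export
quantify_plate <- function(wells) {
  rbind(mmp_effect(wells), cytotoxicity_effect(wells), induction_ratio(wells))
}

per_plate <- function(wells, f) {
  parts <- lapply(split(wells, wells$plate_id), f)
  out <- do.call(rbind, parts)
  reset_rows(out[order(out$plate_id, out$treatment_id, out$dose), ])
}

measures <- function(plate, endpoint, value) {
  data.frame(treatment_id = plate$treatment_id, dose = plate$dose,
             dose_unit = plate$dose_unit, endpoint = endpoint,
             value = value, plate_id = plate$plate_id,
             well_id = plate$well_id, run_id = plate$run_id,
             stringsAsFactors = FALSE)
}
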