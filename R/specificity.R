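# Baseline-toxicity prediction and specificity analysis.
#
# Baseline toxicity is the minimal, hydrophobicity-driven toxicity any
# chemical exerts through membrane intercalation; it is predicted from the
# liposome-water distribution ratio D_lip/w(pH 7.4) by a linear QSAR on
# the log scale. Measured potencies are compared against it (toxic ratio)
# and against each other (specificity ratios) to decide whether MMP
# disruption is a specific mode of action or rides along with general
# cytotoxicity. All ratios are unitless and computed on the molar scale;
# water extracts (REF scale) never enter this module.

#' Baseline-toxicity QSAR model
#'
#' Coefficients of log10(1 / IC10_baseline [M]) = slope * log_dlipw +
#' intercept. The coefficients are required configuration: published
#' cell-line-specific values (e.g. for the AREc32 line) must be supplied
#' by the user from the QSAR literature.
#'
#' @param slope positive slope on log10 D_lip/w
#' @param intercept intercept on the log10(1/M) scale
#' @return object of class `baseline_model`
#' @export
baseline_model <- function(slope, intercept) {
  stopifnot(is.numeric(slope), is.finite(slope), slope > 0,
            is.numeric(intercept), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept),
            class = "baseline_model")
}

#' Predict baseline-toxicity IC10 from hydrophobicity
#'
#' IC10_baseline = 10^-(slope * log_dlipw + intercept), in molar units.
#' More hydrophobic chemicals (higher log D_lip/w) get proportionally
#' lower predicted baseline IC10.
#'
#' @param log_dlipw log10 liposome-water distribution ratio at pH 7.4
#' @param model a [baseline_model()]
#' @return predicted IC10 in M (NA with a warning when log_dlipw missing)
#' @export
predict_baseline_ic10 <- function(log_dlipw, model) {
  stopifnot(inherits(model, "baseline_model"))
  out <- 10^(-(model$slope * log_dlipw + model$intercept))
  if (anyNA(log_dlipw) || any(!is.finite(log_dlipw)))
    warning("missing log_dlipw: baseline prediction absent", call. = FALSE)
  out[!is.finite(log_dlipw)] <- NA_real_
  out
}

#' Toxic ratio: excess cytotoxicity over baseline
#'
#' TR = IC10_baseline / IC10. TR near 1 means the chemical is no more
#' cytotoxic than its hydrophobicity predicts; TR above the specificity
#' threshold (default 10) flags a specific cytotoxic mode of action.
#'
#' @param ic10_baseline predicted baseline IC10 (M)
#' @param ic10 measured cytotoxicity IC10 (M); NA when not reached
#' @return TR, or NA when either input is absent
#' @export
toxic_ratio <- function(ic10_baseline, ic10) {
  ifelse(is.finite(ic10_baseline) & is.finite(ic10) & ic10 > 0,
         ic10_baseline / ic10, NA_real_)
}

#' Specificity ratios of MMP disruption
#'
#' SR_cytotoxicity = IC10 / EC10_mmp measures how much more potently a
#' chemical disrupts the membrane potential than it kills cells;
#' SR_baseline = IC10_baseline / EC10_mmp compares against predicted
#' baseline cytotoxicity instead. The identity SR_baseline = TR *
#' SR_cytotoxicity holds whenever all three exist.
#'
#' @param ic10 measured cytotoxicity IC10 (M) or NA
#' @param ec10_mmp measured MMP EC10 (M), > 0
#' @param ic10_baseline predicted baseline IC10 (M) or NA
#' @return list with `sr_cyto` and `sr_baseline` (NA where inputs absent)
#' @export
specificity_ratios <- function(ic10, ec10_mmp, ic10_baseline) {
  ok <- is.finite(ec10_mmp) & ec10_mmp > 0
  list(sr_cyto = ifelse(ok & is.finite(ic10), ic10 / ec10_mmp, NA_real_),
       sr_baseline = ifelse(ok & is.finite(ic10_baseline),
                            ic10_baseline / ec10_mmp, NA_real_))
}

#' Classify a chemical from its toxic and specificity ratios
#'
#' Strict threshold comparisons (default threshold 10):
#' \itemize{
#'   \item `specific_cytotoxic` — TR > threshold only (excess cytotoxicity)
#'   \item `specific_mmp` — SR_cytotoxicity or SR_baseline > threshold only
#'   \item `specific_both` — both of the above
#'   \item `baseline_like` — at least one ratio present, all present
#'     ratios <= threshold
#'   \item `inactive` — no ratio derivable
#' }
#'
#' The classification is invariant under a common rescaling of all
#' concentrations, since every ratio is unitless.
#'
#' @param tr toxic ratio or NA
#' @param sr_cyto,sr_baseline specificity ratios or NA
#' @param threshold specificity threshold (default 10)
#' @return classification string
#' @export
classify_specificity <- function(tr, sr_cyto, sr_baseline, threshold = 10) {
  stopifnot(length(tr) == 1, length(sr_cyto) == 1, length(sr_baseline) == 1)
  present <- c(tr = is.finite(tr), sr_cyto = is.finite(sr_cyto),
               sr_baseline = is.finite(sr_baseline))
  if (!any(present)) return("inactive")
  cyto_specific <- isTRUE(is.finite(tr) && tr > threshold)
  mmp_specific <- isTRUE(is.finite(sr_cyto) && sr_cyto > threshold) ||
    isTRUE(is.finite(sr_baseline) && sr_baseline > threshold)
  if (cyto_specific && mmp_specific) return("specific_both")
  if (cyto_specific) return("specific_cytotoxic")
  if (mmp_specific) return("specific_mmp")
  "baseline_like"
}

#' Specificity table for a set of chemicals
#'
#' Joins measured effect concentrations with the baseline QSAR prediction
#' and returns one row per chemical with IC10, EC10_mmp, IC10_baseline,
#' TR, SR_cytotoxicity, SR_baseline and the classification. Rows of the
#' output double as the data behind the SR_baseline-vs-SR_cytotoxicity
#' scatter (on which lines of constant TR are diagonals, since
#' SR_baseline = TR * SR_cytotoxicity).
#'
#' @param effect_concs data.frame with columns chem_id, ic10, ec10_mmp
#'   (molar; NA where not derived)
#' @param chems chemical table from [read_chemical_table()]
#' @param model a [baseline_model()]
#' @param threshold specificity threshold (default 10)
#' @return data.frame, one row per chemical
#' @export
specificity_table <- function(effect_concs, chems, model, threshold = 10) {
  idx <- match(effect_concs$chem_id, chems$chem_id)
  if (anyNA(idx))
    stop(sprintf("chemical(s) missing from property table: %s",
                 paste(effect_concs$chem_id[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  log_dlipw <- chems$log_dlipw[idx]
  ic10_baseline <- suppressWarnings(predict_baseline_ic10(log_dlipw, model))
  tr <- toxic_ratio(ic10_baseline, effect_concs$ic10)
  sr <- specificity_ratios(effect_concs$ic10, effect_concs$ec10_mmp,
                           ic10_baseline)
  cls <- mapply(classify_specificity, tr, sr$sr_cyto, sr$sr_baseline,
                MoreArgs = list(threshold = threshold))
  data.frame(chem_id = effect_concs$chem_id,
             mie_class = chems$mie_class[idx],
             ic10 = effect_concs$ic10, ec10_mmp = effect_concs$ec10_mmp,
             ic10_baseline = ic10_baseline, tr = tr,
             sr_cyto = sr$sr_cyto, sr_baseline = sr$sr_baseline,
             classification = cls, stringsAsFactors = FALSE)
}
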