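# Iceberg (bioanalytical equivalent) mixture accounting.
#
# A water extract's measured MMP effect is expressed as the concentration
# of a reference chemical (default the uncoupler 2,4-dinitrophenol, 24DNP)
# that would cause the same effect: BEQ_bio = EC10_ref / EC10_sample, in
# mol reference chemical per L of original water (the sample EC10 is on
# the unitless REF enrichment scale). The same quantity is predicted from
# chemical analysis by concentration addition: every detected chemical
# contributes its concentration weighted by its relative effect potency
# REP_i = EC10_ref / EC10_i, and BEQ_chem = sum(REP_i * C_i). Comparing
# the two quantifies how much of the measured mixture effect the detected
# chemicals explain — the visible tip of the iceberg.

#' Relative effect potency of a chemical versus the reference
#'
#' REP_i = EC10_ref / EC10_i. Chemicals inactive on the MMP endpoint have
#' no REP (NA) and contribute zero to BEQ_chem.
#'
#' @param ec10_ref reference chemical's EC10 (M)
#' @param ec10_i chemical i's EC10 (M), or NA when inactive
#' @return REP (unitless), NA when ec10_i is absent
#' @export
rep_potency <- function(ec10_ref, ec10_i) {
  stopifnot(is.finite(ec10_ref), ec10_ref > 0)
  ifelse(is.finite(ec10_i) & ec10_i > 0, ec10_ref / ec10_i, NA_real_)
}

#' Bioanalytical equivalent concentration from the bioassay
#'
#' BEQ_bio = EC10_ref / EC10_sample with the sample EC10 in REF units
#' (L water per L bioassay), giving mol reference-equivalents per L of
#' original water.
#'
#' @param ec10_ref reference chemical's EC10 (M)
#' @param ec10_sample sample EC10 on the REF scale, or NA when the sample
#'   is inactive
#' @return BEQ_bio in mol/L water, NA for inactive samples
#' @export
beq_bio <- function(ec10_ref, ec10_sample) {
  stopifnot(is.finite(ec10_ref), ec10_ref > 0)
  ifelse(is.finite(ec10_sample) & ec10_sample > 0,
         ec10_ref / ec10_sample, NA_real_)
}

#' Bioanalytical equivalent concentration from chemical analysis
#'
#' BEQ_i = REP_i * C_i per detected chemical and BEQ_chem = sum(BEQ_i).
#' Detected chemicals without a REP (not tested, or tested but inactive
#' on MMP) contribute zero and are reported in `uncovered` rather than
#' silently dropped.
#'
#' @param detections data.frame with columns chem_id and concentration
#'   (mol per L of original water) for one sample
#' @param reps named numeric vector mapping chem_id to REP (NA = no REP)
#' @return list with `beq_chem` (mol/L water), `contributions` (named
#'   fractions summing to 1 when beq_chem > 0), `beq_i` (named BEQ_i), and
#'   `uncovered` (chem_ids contributing zero)
#' @export
beq_chem <- function(detections, reps) {
  if (is.null(detections) || nrow(detections) == 0)
    return(list(beq_chem = 0, contributions = numeric(0),
                beq_i = numeric(0), uncovered = character(0)))
  rep_i <- reps[detections$chem_id]
  names(rep_i) <- detections$chem_id
  covered <- !is.na(rep_i)
  beq_i <- ifelse(covered, rep_i * detections$concentration, 0)
  names(beq_i) <- detections$chem_id
  total <- sum(beq_i)
  contributions <- if (total > 0) beq_i / total else beq_i * 0
  list(beq_chem = total, contributions = contributions, beq_i = beq_i,
       uncovered = detections$chem_id[!covered])
}

#' Percent of the measured mixture effect explained by detected chemicals
#'
#' 100 * BEQ_chem / BEQ_bio. Under strict concentration addition with all
#' constituents detected this closes to 100%; in real samples the
#' detected, toxicologically characterised chemicals typically explain
#' only a small fraction of the measured effect.
#'
#' @param beq_chem predicted BEQ from chemical analysis (mol/L water)
#' @param beq_bio measured BEQ from the bioassay (mol/L water), > 0
#' @return percent explained, NA when beq_bio is absent
#' @export
pct_explained <- function(beq_chem, beq_bio) {
  ifelse(is.finite(beq_bio) & beq_bio > 0, 100 * beq_chem / beq_bio,
         NA_real_)
}

#' Full iceberg accounting for one water sample
#'
#' @param sample_id sample identifier
#' @param ec10_ref reference chemical's EC10 (M)
#' @param ec10_sample sample EC10 on the REF scale (NA when inactive)
#' @param detections detection rows for this sample (chem_id,
#'   concentration in mol/L water)
#' @param reps named REP vector (see [rep_potency()])
#' @return list with sample_id, beq_bio, beq_chem, pct_explained,
#'   contributions, beq_i, uncovered
#' @export
iceberg_sample <- function(sample_id, ec10_ref, ec10_sample, detections,
                           reps) {
  bb <- beq_bio(ec10_ref, ec10_sample)
  bc <- beq_chem(detections, reps)
  list(sample_id = sample_id, beq_bio = bb, beq_chem = bc$beq_chem,
       pct_explained = pct_explained(bc$beq_chem, bb),
       contributions = bc$contributions, beq_i = bc$beq_i,
       uncovered = bc$uncovered)
}

#' Tidy per-chemical contribution table for a set of iceberg results
#'
#' One row per (sample, chemical) with BEQ_i and contribution fraction,
#' plus a `sample summary` attribute-free header row layout mirroring a
#' stacked-bar accounting: use the `summary` element for per-sample totals.
#'
#' @param results list of [iceberg_sample()] results
#' @return list with `summary` (sample_id, beq_bio, beq_chem,
#'   pct_explained) and `contributions` (sample_id, chem_id, beq_i,
#'   contribution, covered)
#' @export
iceberg_tables <- function(results) {
  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = r$sample_id, beq_bio = r$beq_bio,
               beq_chem = r$beq_chem, pct_explained = r$pct_explained,
               n_uncovered = length(r$uncovered), stringsAsFactors = FALSE)
  }))
  contributions <- do.call(rbind, lapply(results, function(r) {
    if (!length(r$beq_i)) return(NULL)
    data.frame(sample_id = r$sample_id, chem_id = names(r$beq_i),
               beq_i = unname(r$beq_i),
               contribution = unname(r$contributions),
               covered = !names(r$beq_i) %in% r$uncovered,
               stringsAsFactors = FALSE)
  }))
  list(summary = reset_rows(summary),
       contributions = reset_rows(contributions))
}
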