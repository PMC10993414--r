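# Orchestration: end-to-end screens from raw well tables to result tables.
#
# Two entry points mirror the two halves of the study design: a chemical
# screen (molar doses -> effect concentrations -> specificity
# classification) and a water screen (REF doses -> per-sample effect
# concentrations -> iceberg BEQ accounting). Both are deterministic given
# their inputs; a JSON manifest records configuration and versions for
# provenance.

#' Load a run configuration from YAML
#'
#' Flat key-value YAML. Recognised keys: input paths (`well_table`,
#' `chemical_table`, `detection_table`, `ec10_table`), baseline QSAR
#' coefficients (`baseline_slope`, `baseline_intercept`), thresholds
#' (`specificity_threshold`, `mmp_cutoff_multiplier`, `ir_threshold`,
#' `effect_level`), `reference_chem`, `out_dir`, `seed`, and dialect
#' (`sep`, `dec`). Unset thresholds take the screen defaults (10, 10,
#' 1.5, 10).
#'
#' @param path YAML file path
#' @return validated config list
#' @export
load_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Validate and complete a run configuration
#'
#' @param config named list (see [load_run_config()])
#' @return config with defaults filled in
#' @export
validate_run_config <- function(config) {
  defaults <- list(specificity_threshold = 10, mmp_cutoff_multiplier = 10,
                   ir_threshold = 1.5, effect_level = 10, seed = 1,
                   sep = ",", dec = ".", out_dir = ".")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  with(config, {
    stopifnot(specificity_threshold > 0, mmp_cutoff_multiplier > 0,
              ir_threshold > 1)
    if (effect_level <= 0 || effect_level >= 50)
      stop("effect_level must lie in (0, 50)", call. = FALSE)
  })
  config
}

config_dialect <- function(config) io_dialect(config$sep, config$dec)

#' Fit all three endpoints for one treatment
#'
#' Given tidy endpoint measures for a single treatment, fits cytotoxicity
#' first (its IC10 gates the other endpoints), then MMP with the
#' 10 x IC10 secondary-cytotoxicity rule, then the linear oxidative
#' stress model with doses above IC10 masked.
#'
#' @param measures endpoint-measure rows for one treatment (output of
#'   [quantify_plate()] subset to one treatment_id)
#' @param effect_level percent effect for IC10/EC10 (default 10)
#' @param mmp_cutoff_multiplier the 10 x IC10 rule multiplier
#' @param ir_threshold induction-ratio threshold for EC_IR (default 1.5)
#' @return list of `mitotox_fit`: `cyto`, `mmp`, `ox`
#' @export
fit_treatment <- function(measures, effect_level = 10,
                          mmp_cutoff_multiplier = 10, ir_threshold = 1.5) {
  trt <- unique(measures$treatment_id)
  stopifnot(length(trt) == 1)
  sub <- function(ep) measures[measures$endpoint == ep, ]
  safe_fit <- function(data, endpoint) {
    tryCatch(fit_loglogistic(data, treatment_id = trt, endpoint = endpoint,
                             effect_level = effect_level),
             error = function(e) {
               f <- fit_skeleton(trt, endpoint, "loglogistic4",
                                 list(excluded_doses = numeric(0),
                                      reason = NA_character_),
                                 nrow(data), 0L)
               f$active <- FALSE
               f$reason <- conditionMessage(e)
               f
             })
  }
  cyto <- safe_fit(sub("cytotoxicity"), "cytotoxicity")
  ic10 <- if (isTRUE(cyto$active)) cyto$effect_conc else NA_real_
  mmp <- safe_fit(sub("mmp"), "mmp")
  mmp <- derive_ec10_mmp(mmp, ic10, mmp_cutoff_multiplier)
  ox <- fit_ecir15(sub("oxidative_stress"), ic10, treatment_id = trt,
                   ir_threshold = ir_threshold)
  list(cyto = cyto, mmp = mmp, ox = ox)
}

screen_fits <- function(measures, config) {
  trts <- unique(measures$treatment_id[measures$dose > 0])
  fits <- lapply(sort(trts), function(trt)
    fit_treatment(measures[measures$treatment_id == trt, ],
                  effect_level = config$effect_level,
                  mmp_cutoff_multiplier = config$mmp_cutoff_multiplier,
                  ir_threshold = config$ir_threshold))
  names(fits) <- sort(trts)
  fits
}

effect_conc_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(trt) {
    f <- fits[[trt]]
    pick <- function(fit) if (isTRUE(fit$active)) fit$effect_conc else NA_real_
    data.frame(chem_id = trt, ic10 = pick(f$cyto), ec10_mmp = pick(f$mmp),
               ec_ir15 = pick(f$ox), stringsAsFactors = FALSE)
  }))
}

#' Run the chemical screen end to end
#'
#' Quantifies per-well effects against plate solvent controls, fits
#' concentration-response curves per chemical and endpoint with the
#' masking rules, predicts baseline toxicity from the QSAR, and writes
#' the specificity table plus a ratio-scatter export (SR_baseline vs
#' SR_cytotoxicity, on which constant-TR lines are diagonals).
#'
#' @param config list (or [load_run_config()] output) with at least
#'   `well_table`, `chemical_table`, `baseline_slope`,
#'   `baseline_intercept`; see [load_run_config()] for thresholds
#' @return (invisibly) list with `measures`, `fits` (table), `effect_concs`,
#'   `specificity`, and output file paths
#' @export
run_chemical_screen <- function(config) {
  config <- validate_run_config(config)
  if (is.null(config$baseline_slope) || is.null(config$baseline_intercept))
    stop("config error: baseline_slope and baseline_intercept are required",
         call. = FALSE)
  dialect <- config_dialect(config)
  wells <- read_well_table(config$well_table, dialect)
  if (nrow(wells) == 0)
    stop(sprintf("schema error: empty well table '%s'", config$well_table),
         call. = FALSE)
  chems <- read_chemical_table(config$chemical_table, dialect)
  measures <- quantify_plate(wells)
  fits <- screen_fits(measures, config)
  fit_tab <- fits_to_table(unlist(fits, recursive = FALSE))
  ecs <- effect_conc_table(fits)
  model <- baseline_model(config$baseline_slope, config$baseline_intercept)
  spec <- specificity_table(ecs, chems, model,
                            threshold = config$specificity_threshold)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(effects = file.path(config$out_dir, "effects.csv"),
             fits = file.path(config$out_dir, "fits.csv"),
             specificity = file.path(config$out_dir, "specificity.csv"),
             sr_scatter = file.path(config$out_dir, "sr_scatter.csv"),
             manifest = file.path(config$out_dir, "manifest.json"))
  write_full_precision(measures, paths[["effects"]], dialect)
  write_full_precision(fit_tab, paths[["fits"]], dialect)
  write_full_precision(spec, paths[["specificity"]], dialect)
  scatter <- spec[is.finite(spec$sr_cyto) | is.finite(spec$sr_baseline),
                  c("chem_id", "mie_class", "sr_cyto", "sr_baseline", "tr",
                    "classification")]
  write_full_precision(scatter, paths[["sr_scatter"]], dialect)
  write_manifest(config, paths[["manifest"]],
                 inputs = c(config$well_table, config$chemical_table))
  invisible(list(measures = measures, fits = fit_tab, effect_concs = ecs,
                 specificity = spec, paths = paths))
}

#' Run the water-extract screen end to end
#'
#' Quantifies and fits each water sample on the REF enrichment scale
#' (IC10, EC10, EC_IR1.5 in REF units; SR_cytotoxicity as the unitless
#' IC10/EC10 ratio), converts sample EC10s to BEQ_bio against the
#' reference chemical, predicts BEQ_chem from the detected concentrations
#' via relative effect potencies under concentration addition, and writes
#' per-sample iceberg summaries plus the per-chemical contribution table.
#'
#' @param config list with `well_table` (REF doses), `detection_table`,
#'   `ec10_table` (chem_id, ec10_mmp in M from a chemical screen) and
#'   `reference_chem`; thresholds as in [load_run_config()]
#' @return (invisibly) list with `sample_fits`, `iceberg` (summary),
#'   `contributions`, `reps`, and output file paths
#' @export
run_water_screen <- function(config) {
  config <- validate_run_config(config)
  for (k in c("well_table", "detection_table", "ec10_table",
              "reference_chem"))
    if (is.null(config[[k]]))
      stop(sprintf("config error: '%s' is required", k), call. = FALSE)
  dialect <- config_dialect(config)
  wells <- read_well_table(config$well_table, dialect)
  detections <- read_detection_table(config$detection_table, dialect)
  ec10s <- read_delim_table(config$ec10_table, dialect)
  require_columns(ec10s, c("chem_id", "ec10_mmp"), config$ec10_table)
  ec10s <- coerce_numeric(ec10s, "ec10_mmp", config$ec10_table)

  ref_row <- match(config$reference_chem, ec10s$chem_id)
  if (is.na(ref_row) || !is.finite(ec10s$ec10_mmp[ref_row]))
    stop(sprintf("config error: reference chemical '%s' has no EC10",
                 config$reference_chem), call. = FALSE)
  ec10_ref <- ec10s$ec10_mmp[ref_row]
  reps <- rep_potency(ec10_ref, ec10s$ec10_mmp)
  names(reps) <- ec10s$chem_id

  unknown <- setdiff(unique(detections$chem_id), ec10s$chem_id)
  if (length(unknown))
    warning(sprintf("detected chemical(s) without toxicity data: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)

  measures <- quantify_plate(wells)
  fits <- screen_fits(measures, config)
  fit_tab <- fits_to_table(unlist(fits, recursive = FALSE))
  ecs <- effect_conc_table(fits)
  sr_cyto <- ifelse(is.finite(ecs$ic10) & is.finite(ecs$ec10_mmp),
                    ecs$ic10 / ecs$ec10_mmp, NA_real_)
  sample_fits <- data.frame(sample_id = ecs$chem_id, ic10_ref = ecs$ic10,
                            ec10_ref = ecs$ec10_mmp,
                            ec_ir15_ref = ecs$ec_ir15, sr_cyto = sr_cyto,
                            stringsAsFactors = FALSE)

  results <- lapply(seq_len(nrow(sample_fits)), function(i) {
    sid <- sample_fits$sample_id[i]
    iceberg_sample(sid, ec10_ref, sample_fits$ec10_ref[i],
                   detections[detections$sample_id == sid, , drop = FALSE],
                   reps)
  })
  tabs <- iceberg_tables(results)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sample_fits = file.path(config$out_dir, "sample_fits.csv"),
             iceberg = file.path(config$out_dir, "iceberg_summary.csv"),
             contributions = file.path(config$out_dir, "contributions.csv"),
             manifest = file.path(config$out_dir, "manifest.json"))
  write_full_precision(sample_fits, paths[["sample_fits"]], dialect)
  write_full_precision(tabs$summary, paths[["iceberg"]], dialect)
  if (!is.null(tabs$contributions))
    write_full_precision(tabs$contributions, paths[["contributions"]],
                         dialect)
  write_manifest(config, paths[["manifest"]],
                 inputs = c(config$well_table, config$detection_table,
                            config$ec10_table))
  invisible(list(sample_fits = sample_fits, fits = fit_tab,
                 iceberg = tabs$summary, contributions = tabs$contributions,
                 reps = reps, ec10_ref = ec10_ref, paths = paths))
}

# Provenance manifest: configuration (hashed and verbatim), package and R
# versions, input paths. Deliberately excludes wall-clock time so reruns
# with identical config and inputs are byte-identical.
write_manifest <- function(config, path, inputs = character(0)) {
  cfg <- config[order(names(config))]
  manifest <- list(
    package = "mitotox",
    version = as.character(utils::packageVersion("mitotox")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = cfg,
    config_hash = config_hash(cfg),
    inputs = as.character(inputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# Structural fingerprint of the canonical (name-sorted) configuration:
# a 31-bit polynomial rolling hash over its deparsed form.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
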