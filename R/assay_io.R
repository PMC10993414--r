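# Plate-level table input/output and validation.
#
# All tables are plain data.frames in delimited-text form. Wells live on
# 384-well plates (rows A-P, columns 1-24); plate positions are metadata
# only, no positional corrections are applied.

WELL_COLUMNS <- c("plate_id", "well_id", "treatment_id", "treatment_kind",
                  "dose", "dose_unit", "red_signal", "green_signal",
                  "cell_count", "luminescence", "run_id")

TREATMENT_KINDS <- c("chemical", "water_extract", "solvent_control",
                     "positive_control", "blank")

CONTROL_KINDS <- c("solvent_control", "blank")

MIE_CLASSES <- c("complexI", "complexII", "complexIII", "complexV",
                 "uncoupler", "multiple", "baseline", "unknown")

reset_rows <- function(df) {
  if (is.null(df)) return(NULL)
  rownames(df) <- NULL
  df
}

#' Default text dialect for plate tables
#'
#' @param sep field separator (default comma)
#' @param dec decimal mark (default period)
#' @return a list with elements `sep` and `dec`
#' @export
io_dialect <- function(sep = ",", dec = ".") {
  stopifnot(is.character(sep), nchar(sep) == 1L,
            is.character(dec), dec %in% c(".", ","))
  if (sep == dec) stop("separator and decimal mark must differ")
  list(sep = sep, dec = dec)
}

# Parse "A1".."P24" well ids; returns data.frame(row, col) or NA rows for
# ids that do not parse.
parse_well_id <- function(well_id) {
  m <- regmatches(well_id, regexec("^([A-P])([0-9]{1,2})$", well_id))
  row <- vapply(m, function(x) if (length(x) == 3L) x[2] else NA_character_,
                character(1))
  col <- vapply(m, function(x) if (length(x) == 3L) as.integer(x[3]) else NA_integer_,
                integer(1))
  bad <- !is.na(col) & (col < 1L | col > 24L)
  row[bad] <- NA_character_
  col[bad] <- NA_integer_
  data.frame(row = row, col = col, stringsAsFactors = FALSE)
}

# Collect row-indexed invariant violations for a well table. Returns a
# character vector of messages (empty when clean).
well_table_violations <- function(df) {
  msgs <- character(0)
  flag <- function(bad, what) {
    if (any(bad)) {
      rows <- which(bad)
      shown <- paste(utils::head(rows, 10), collapse = ", ")
      if (length(rows) > 10) shown <- paste0(shown, ", ...")
      msgs <<- c(msgs, sprintf("%s (rows %s)", what, shown))
    }
  }
  pw <- parse_well_id(df$well_id)
  flag(is.na(pw$row), "well_id outside A1-P24")
  flag(!df$treatment_kind %in% TREATMENT_KINDS,
       sprintf("treatment_kind not one of {%s}",
               paste(TREATMENT_KINDS, collapse = ", ")))
  num_cols <- c("dose", "red_signal", "green_signal", "cell_count",
                "luminescence")
  for (cc in num_cols) {
    v <- df[[cc]]
    flag(!is.finite(v) | v < 0, sprintf("%s not finite and >= 0", cc))
  }
  flag(is.finite(df$cell_count) & df$cell_count != round(df$cell_count),
       "cell_count not integer-valued")
  is_ctrl <- df$treatment_kind %in% CONTROL_KINDS
  flag(is_ctrl & df$dose != 0, "control/blank well with nonzero dose")
  flag(!is_ctrl & is.finite(df$dose) & df$dose == 0,
       "treated well with zero dose")
  # one dose unit per treatment
  trt <- df[!is_ctrl, , drop = FALSE]
  if (nrow(trt)) {
    units_per_trt <- tapply(trt$dose_unit, trt$treatment_id,
                            function(u) length(unique(u)))
    mixed <- names(units_per_trt)[units_per_trt > 1]
    if (length(mixed))
      msgs <- c(msgs, sprintf("mixed dose units within treatment(s): %s",
                              paste(mixed, collapse = ", ")))
  }
  msgs
}

read_delim_table <- function(path, dialect) {
  utils::read.csv(path, sep = dialect$sep, dec = dialect$dec,
                  stringsAsFactors = FALSE, check.names = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("schema error in '%s': missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

coerce_numeric <- function(df, cols, path) {
  for (cc in cols) {
    raw <- df[[cc]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- is.na(v) & !is.na(raw) & trimws(as.character(raw)) != ""
    if (any(bad))
      stop(sprintf("parse error in '%s': non-numeric %s at row(s) %s", path,
                   cc, paste(utils::head(which(bad), 10), collapse = ", ")),
           call. = FALSE)
    df[[cc]] <- v
  }
  df
}

# Canonical deterministic ordering: plate, then plate row letter, then
# column number, then run. Reader output is independent of file row order.
sort_well_table <- function(df) {
  pw <- parse_well_id(df$well_id)
  df[order(df$plate_id, pw$row, pw$col, df$run_id), , drop = FALSE]
}

#' Read a per-well measurement table
#'
#' Reads a delimited text table of raw multiplexed well readouts (red and
#' green fluorescence, cell count, luminescence) with treatment annotation,
#' validates every row against the well-record invariants and returns the
#' table sorted deterministically by (plate, well row, well column, run).
#'
#' Doses are molar concentrations for chemicals and relative enrichment
#' factors (REF, L water per L bioassay) for water extracts; the
#' `dose_unit` column ("M" or "REF") disambiguates, and mixing units within
#' one treatment is an error. Controls and blanks carry dose 0.
#'
#' @param path path to a delimited text file whose header names all of:
#'   plate_id, well_id, treatment_id, treatment_kind, dose, dose_unit,
#'   red_signal, green_signal, cell_count, luminescence, run_id
#' @param dialect list from [io_dialect()] giving separator and decimal mark
#' @return a validated, sorted data.frame of well records
#' @export
read_well_table <- function(path, dialect = io_dialect()) {
  df <- read_delim_table(path, dialect)
  require_columns(df, WELL_COLUMNS, path)
  df <- df[, WELL_COLUMNS]
  df <- coerce_numeric(df, c("dose", "red_signal", "green_signal",
                             "cell_count", "luminescence"), path)
  for (cc in c("plate_id", "well_id", "treatment_id", "treatment_kind",
               "dose_unit", "run_id"))
    df[[cc]] <- as.character(df[[cc]])
  msgs <- well_table_violations(df)
  if (length(msgs))
    stop(sprintf("invalid well table '%s':\n  %s", path,
                 paste(msgs, collapse = "\n  ")), call. = FALSE)
  reset_rows(sort_well_table(df))
}

#' Write a per-well measurement table
#'
#' Inverse of [read_well_table()]; numeric fields are written at full
#' double precision so that write-then-read round trips losslessly.
#'
#' @param wells well-record data.frame
#' @param path output file path
#' @param dialect list from [io_dialect()]
#' @export
write_well_table <- function(wells, path, dialect = io_dialect()) {
  write_full_precision(wells[, WELL_COLUMNS], path, dialect)
}

#' Write any result table at full double precision
#'
#' General delimited-text writer used for all package outputs: doubles are
#' serialised with 17 significant digits so values survive a write/read
#' round trip bit-for-bit.
#'
#' @param df data.frame to write
#' @param path output file path
#' @param dialect list from [io_dialect()]
#' @export
write_full_precision <- function(df, path, dialect = io_dialect()) {
  out <- df
  for (cc in names(out)) {
    if (is.double(out[[cc]])) {
      s <- formatC(out[[cc]], format = "g", digits = 17)
      s <- trimws(s)
      if (dialect$dec != ".") s <- gsub(".", dialect$dec, s, fixed = TRUE)
      out[[cc]] <- s
    }
  }
  utils::write.table(out, path, sep = dialect$sep, dec = dialect$dec,
                     row.names = FALSE, quote = TRUE, qmethod = "double")
  invisible(path)
}

#' Read a chemical property table
#'
#' One row per chemical: identifier, name, hydrophobicity descriptor
#' log10 D_lip/w (liposome-water distribution ratio at pH 7.4, L/kg lipid),
#' molecular-initiating-event class and maximum tested concentration (M).
#' Unrecognised MIE class strings are mapped to `"unknown"` with a warning;
#' duplicate chemical identifiers are an error.
#'
#' @param path delimited text file with header including chem_id, name,
#'   log_dlipw, mie_class, max_test_conc
#' @param dialect list from [io_dialect()]
#' @return data.frame of chemical records, sorted by chem_id
#' @export
read_chemical_table <- function(path, dialect = io_dialect()) {
  df <- read_delim_table(path, dialect)
  require_columns(df, c("chem_id", "log_dlipw", "mie_class"), path)
  if (!"name" %in% names(df)) df$name <- df$chem_id
  if (!"max_test_conc" %in% names(df)) df$max_test_conc <- NA_real_
  df <- coerce_numeric(df, c("log_dlipw", "max_test_conc"), path)
  df$chem_id <- as.character(df$chem_id)
  df$mie_class <- as.character(df$mie_class)
  dup <- unique(df$chem_id[duplicated(df$chem_id)])
  if (length(dup))
    stop(sprintf("duplicate chem_id in '%s': %s", path,
                 paste(dup, collapse = ", ")), call. = FALSE)
  unk <- !df$mie_class %in% MIE_CLASSES
  if (any(unk)) {
    warning(sprintf("unknown mie_class value(s) mapped to 'unknown': %s",
                    paste(unique(df$mie_class[unk]), collapse = ", ")),
            call. = FALSE)
    df$mie_class[unk] <- "unknown"
  }
  df <- df[order(df$chem_id),
           c("chem_id", "name", "log_dlipw", "mie_class", "max_test_conc")]
  reset_rows(df)
}

#' Write a chemical property table
#' @param chems chemical-record data.frame
#' @param path output file path
#' @param dialect list from [io_dialect()]
#' @export
write_chemical_table <- function(chems, path, dialect = io_dialect()) {
  write_full_precision(chems, path, dialect)
}

#' Read a detected-concentration table for water samples
#'
#' One row per (sample, chemical) pair with the detected molar
#' concentration referenced to the original water (REF = 1 basis, mol per
#' L of water). Pairs must be unique and concentrations nonnegative.
#'
#' @param path delimited text file with header sample_id, chem_id,
#'   concentration
#' @param dialect list from [io_dialect()]
#' @return data.frame sorted by (sample_id, chem_id)
#' @export
read_detection_table <- function(path, dialect = io_dialect()) {
  df <- read_delim_table(path, dialect)
  require_columns(df, c("sample_id", "chem_id", "concentration"), path)
  df <- coerce_numeric(df, "concentration", path)
  df$sample_id <- as.character(df$sample_id)
  df$chem_id <- as.character(df$chem_id)
  bad <- !is.finite(df$concentration) | df$concentration < 0
  if (any(bad))
    stop(sprintf("invalid concentration at row(s) %s in '%s'",
                 paste(utils::head(which(bad), 10), collapse = ", "), path),
         call. = FALSE)
  key <- paste(df$sample_id, df$chem_id, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("duplicate (sample_id, chem_id) pair(s) in '%s'", path),
         call. = FALSE)
  df <- df[order(df$sample_id, df$chem_id),
           c("sample_id", "chem_id", "concentration")]
  reset_rows(df)
}

#' Write a detected-concentration table
#' @param detections detection data.frame
#' @param path output file path
#' @param dialect list from [io_dialect()]
#' @export
write_detection_table <- function(detections, path, dialect = io_dialect()) {
  write_full_precision(detections, path, dialect)
}
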