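#' @section File schemas:
#' All tables are plain CSV with a header, decimal points (never commas),
#' and empty fields for missing values (never 0, which means an integrated
#' but empty peak).
#' @name io-schemas
#' @noRd
NULL

transition_schema <- c(
  sample_id = "character", plate = "character", well = "character",
  protein = "character", peptide = "character",
  precursor_charge = "integer", fragment = "character",
  product_charge = "integer", label = "character", area = "numeric",
  rt_min = "numeric", irt_ref = "numeric", dotp = "numeric"
)

# translation of genuine Skyline transition-report export headers
skyline_header_map <- c(
  "Replicate Name" = "sample_id",
  "Protein Name" = "protein",
  "Peptide Modified Sequence" = "peptide",
  "Precursor Charge" = "precursor_charge",
  "Fragment Ion" = "fragment",
  "Product Charge" = "product_charge",
  "Isotope Label Type" = "label",
  "Area" = "area",
  "Retention Time" = "rt_min",
  "iRT Value" = "irt_ref",
  "Library Dot Product" = "dotp"
)

#' Coerce a column to numeric with row-numbered diagnostics
#' @noRd
parse_num_col <- function(dt, col, path, integer = FALSE) {
  x <- dt[[col]]
  if (is.character(x)) {
    x[x == ""] <- NA_character_
    conv <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(conv))
    if (length(bad))
      sq_stop("parse_error",
              "%s: non-numeric value in column '%s' at data row(s) %s",
              path, col, paste(head(bad, 5L), collapse = ", "))
    x <- conv
  }
  data.table::set(dt, j = col, value = if (integer) as.integer(x) else as.numeric(x))
  invisible(dt)
}

require_columns <- function(dt, need, path) {
  miss <- setdiff(need, names(dt))
  if (length(miss))
    sq_stop("schema_error", "%s: missing required column(s): %s",
            path, paste(miss, collapse = ", "))
  invisible(dt)
}

#' Read a transition-level quantification report
#'
#' Parses the CSV export of integrated fragment-ion peak areas (one row per
#' sample x peptide x fragment x isotope channel) with strict validation:
#' missing columns, non-numeric areas and duplicate transition keys are
#' errors with row context. With `skyline = TRUE` the original Skyline
#' export headers ("Peptide Modified Sequence", "Isotope Label Type",
#' "Area", ...) are translated to the package schema.
#'
#' @param path CSV file path.
#' @param skyline Translate Skyline export headers first (default FALSE).
#' @return data.table of validated transition records.
#' @export
read_transition_report <- function(path, skyline = FALSE) {
  if (!file.exists(path)) sq_stop("io_error", "file not found: %s", path)
  dt <- fread(path, na.strings = c("", "NA"), colClasses = list(
    character = intersect(names(transition_schema)[transition_schema == "character"],
                          names(fread(path, nrows = 0L)))))
  if (skyline) {
    hit <- names(dt) %in% names(skyline_header_map)
    setnames(dt, names(dt)[hit], unname(skyline_header_map[names(dt)[hit]]))
    if (!"plate" %in% names(dt)) dt[, plate := NA_character_]
    if (!"well" %in% names(dt)) dt[, well := NA_character_]
    if (!"irt_ref" %in% names(dt)) dt[, irt_ref := NA_real_]
  }
  require_columns(dt, names(transition_schema), path)
  for (col in c("area", "rt_min", "irt_ref", "dotp"))
    parse_num_col(dt, col, path)
  for (col in c("precursor_charge", "product_charge"))
    parse_num_col(dt, col, path, integer = TRUE)
  validate_transition_records(dt, path)
  dt[]
}

#' Validate transition records against the schema invariants
#' @param dt data.table of transition records.
#' @param path Label used in error messages.
#' @return The records, invisibly.
#' @export
validate_transition_records <- function(dt, path = "transition report") {
  bad_lab <- which(!dt$label %in% c("light", "heavy"))
  if (length(bad_lab))
    sq_stop("validation_error", "%s: label must be 'light' or 'heavy' (row %d)",
            path, bad_lab[1L])
  bad_area <- which(!is.na(dt$area) & dt$area < 0)
  if (length(bad_area))
    sq_stop("validation_error", "%s: negative area at data row(s) %s",
            path, paste(head(bad_area, 5L), collapse = ", "))
  bad_dotp <- which(!is.na(dt$dotp) & (dt$dotp < 0 | dt$dotp > 1))
  if (length(bad_dotp))
    sq_stop("validation_error", "%s: dotp outside [0, 1] at data row(s) %s",
            path, paste(head(bad_dotp, 5L), collapse = ", "))
  key <- paste(dt$sample_id, dt$peptide, dt$precursor_charge, dt$fragment,
               dt$product_charge, dt$label, sep = "\r")
  d <- which(duplicated(key))
  if (length(d)) {
    first <- match(key[d[1L]], key)
    sq_stop("duplicate_key_error",
            "%s: duplicate transition key at data rows %d and %d",
            path, first, d[1L])
  }
  invisible(dt)
}

#' Read a spike-in panel table
#'
#' @param path CSV with columns `protein`, `peptide`, `standard_id`,
#'   `spike_conc_pmol_per_ul` (> 0).
#' @return Validated data.table.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) sq_stop("io_error", "file not found: %s", path)
  dt <- fread(path, na.strings = c("", "NA"))
  require_columns(dt, c("protein", "peptide", "standard_id",
                        "spike_conc_pmol_per_ul"), path)
  parse_num_col(dt, "spike_conc_pmol_per_ul", path)
  if (any(is.na(dt$spike_conc_pmol_per_ul)) ||
      any(dt$spike_conc_pmol_per_ul <= 0))
    sq_stop("validation_error",
            "%s: spike concentrations must be present and > 0", path)
  if (anyDuplicated(dt[, .(protein, peptide)]))
    sq_stop("validation_error", "%s: duplicate (protein, peptide) rows", path)
  dt[]
}

#' Read a sample manifest
#'
#' @param path CSV with columns `sample_id`, `plate`, `well`, `sample_type`,
#'   `cancer`, `sex`.
#' @return Validated data.table (see [validate_manifest()]).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) sq_stop("io_error", "file not found: %s", path)
  dt <- fread(path, na.strings = c("", "NA"), colClasses = list(
    character = c("sample_id", "plate", "well", "sample_type", "cancer", "sex")))
  require_columns(dt, c("sample_id", "plate", "well", "sample_type",
                        "cancer", "sex"), path)
  validate_manifest(dt)
  dt[]
}

#' Write / read a wide concentration matrix
#'
#' Samples in rows (first column `sample_id`), analytes in columns, values
#' in pmol/uL, empty fields for missing.
#'
#' @param mat Numeric matrix with sample row names, or a `conc_matrix`.
#' @param path CSV path.
#' @return `write_matrix`: the path, invisibly. `read_matrix`: a numeric
#'   matrix with sample row names.
#' @export
write_matrix <- function(mat, path) {
  if (inherits(mat, "conc_matrix")) mat <- mat$values
  dt <- data.table(sample_id = rownames(mat))
  for (j in colnames(mat)) dt[, (j) := mat[, j]]
  fwrite(dt, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) sq_stop("io_error", "file not found: %s", path)
  dt <- fread(path, na.strings = c("", "NA"))
  require_columns(dt, "sample_id", path)
  ids <- as.character(dt$sample_id)
  dt[, sample_id := NULL]
  m <- as.matrix(dt)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write / read a differential-abundance result table
#' @param de data.table of DE results ([one_vs_rest()]).
#' @param path CSV path.
#' @export
write_de_table <- function(de, path) {
  fwrite(as.data.table(de), path)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) sq_stop("io_error", "file not found: %s", path)
  fread(path, na.strings = c("", "NA"))
}

#' Write a classifier report as JSON
#' @param report A `classifier_report` ([train_and_evaluate()]).
#' @param path JSON path.
#' @export
write_classifier_report <- function(report, path) {
  write_json_file(unclass(report), path)
  invisible(path)
}

#' @rdname write_classifier_report
#' @export
read_classifier_report <- function(path) {
  if (!file.exists(path)) sq_stop("io_error", "file not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
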