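#' Build the sample manifest of a synthetic cohort
#'
#' Lays out patients and pool samples on plates. Each plate carries exactly
#' `pool_replicates` pooled-plasma wells; patients are assigned to the
#' remaining wells by a seeded random permutation (full randomization over
#' plate slots). Sexes are drawn consistently with cancer type: male-only
#' cancers get male patients, female-only cancers female, all others ~1:1.
#'
#' @param config A [cohort_config()].
#' @return data.table with columns `sample_id`, `plate`, `well`,
#'   `sample_type` ("patient" or "pool"), `cancer` (NA for pools), `sex`
#'   (NA for pools).
#' @export
#' @examples
#' m <- build_manifest(cohort_config(cancer_counts = c(MM = 5, CRC = 5),
#'                                   seed = 7))
#' table(m$sample_type)
build_manifest <- function(config) {
  config <- validate_cohort_config(config)
  set.seed(config$seed)
  counts <- config$cancer_counts
  n_pat <- sum(counts)
  n_plates <- plate_count(config)
  cap <- config$wells_per_plate - config$pool_replicates
  if (n_pat > n_plates * cap)
    sq_stop("capacity_error", "patients + pools exceed plate slots")

  pool_wells <- seq_len(config$pool_replicates)
  patient_wells <- setdiff(seq_len(config$wells_per_plate), pool_wells)

  pools <- data.table(
    sample_id = sprintf("POOL_P%02d_R%d",
                        rep(seq_len(n_plates), each = config$pool_replicates),
                        rep(seq_len(config$pool_replicates), n_plates)),
    plate = sprintf("P%02d", rep(seq_len(n_plates), each = config$pool_replicates)),
    well = well_name(rep(pool_wells, n_plates)),
    sample_type = "pool", cancer = NA_character_, sex = NA_character_
  )

  if (n_pat > 0L) {
    cancer <- rep(names(counts), counts)
    fixed_sex <- rep(NA_character_, n_pat)
    fixed_sex[cancer %in% config$sex_specific$male] <- "male"
    fixed_sex[cancer %in% config$sex_specific$female] <- "female"
    n_free <- sum(is.na(fixed_sex))
    sex <- fixed_sex
    sex[is.na(fixed_sex)] <- sample(c("male", "female"), n_free, replace = TRUE)

    # seeded permutation of patients over sequential plate slots
    ord <- sample.int(n_pat)
    slot_plate <- rep(seq_len(n_plates), each = length(patient_wells))[seq_len(n_pat)]
    slot_well <- rep(patient_wells, n_plates)[seq_len(n_pat)]
    patients <- data.table(
      sample_id = sprintf("S%04d", seq_len(n_pat)),
      plate = sprintf("P%02d", slot_plate[order(ord)]),
      well = well_name(slot_well[order(ord)]),
      sample_type = "patient", cancer = cancer, sex = sex
    )
    out <- rbindlist(list(patients, pools))
  } else {
    out <- pools
  }
  setorder(out, plate, well, sample_id)
  out[]
}

#' 96-well-style well name from a 1-based well index (12 columns)
#' @noRd
well_name <- function(i) {
  sprintf("%s%02d", LETTERS[(i - 1L) %/% 12L + 1L], (i - 1L) %% 12L + 1L)
}

#' Validate a sample manifest
#'
#' Checks the manifest invariants: unique sample ids, a constant number of
#' pool wells per plate, cancer labels only on patient rows and present on
#' every patient row.
#'
#' @param manifest data.table as returned by [build_manifest()].
#' @param pool_replicates Expected pools per plate, or `NULL` to accept any
#'   constant count.
#' @return The manifest, invisibly (errors on violation).
#' @export
validate_manifest <- function(manifest, pool_replicates = NULL) {
  manifest <- as.data.table(manifest)
  need <- c("sample_id", "plate", "well", "sample_type", "cancer", "sex")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    sq_stop("schema_error", "manifest is missing column(s): %s",
            paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$sample_id))
    sq_stop("validation_error", "duplicate sample ids in manifest")
  if (!all(manifest$sample_type %in% c("patient", "pool")))
    sq_stop("validation_error", "sample_type must be 'patient' or 'pool'")
  if (any(!is.na(manifest$cancer[manifest$sample_type == "pool"])))
    sq_stop("validation_error", "pool rows must not carry a cancer label")
  pat <- manifest[sample_type == "patient"]
  if (nrow(pat) && any(is.na(pat$cancer)))
    sq_stop("validation_error", "patient rows must carry a cancer label")
  pools_per_plate <- manifest[sample_type == "pool", .N, by = plate]$N
  if (length(pools_per_plate) && length(unique(pools_per_plate)) > 1L)
    sq_stop("validation_error", "plates carry unequal numbers of pool wells")
  if (!is.null(pool_replicates) && length(pools_per_plate) &&
      any(pools_per_plate != pool_replicates))
    sq_stop("validation_error", "plates must carry exactly %d pool wells",
            pool_replicates)
  invisible(manifest)
}
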