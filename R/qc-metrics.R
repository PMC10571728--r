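#' Intra-assay coefficient of variation from pool injections
#'
#' Per peptide x plate, CV = sd/mean x 100 over that plate's pool
#' injections (sample sd, n-1 denominator); the per-plate summary is the
#' median over peptides. The overall summary pools ALL pool injections
#' across plates into one CV per peptide and takes the median over
#' peptides — this cross-plate computation is what makes the overall CV
#' exceed every per-plate median when plate effects exist.
#'
#' @param cm A peptide-level [conc_matrix()] or plain samples x peptides
#'   matrix.
#' @param manifest Sample manifest (identifies pool injections and plates).
#' @return List: `per_plate` (data.table plate, median_cv, n_peptides),
#'   `per_peptide_overall` (named vector), `overall_median_cv`,
#'   `per_plate_median_cv` (median of the per-plate medians).
#' @export
intra_assay_cv <- function(cm, manifest) {
  m <- if (inherits(cm, "conc_matrix")) cm$values else cm
  manifest <- as.data.table(manifest)
  info <- manifest[match(rownames(m), sample_id)]
  pool <- info$sample_type == "pool"
  if (sum(pool) < 2L)
    sq_stop("validation_error", "need at least 2 pool injections")
  plates <- unique(info$plate[pool])
  per_plate <- list()
  for (pl in plates) {
    rows <- which(pool & info$plate == pl)
    if (length(rows) < 2L) {
      warning(sprintf("plate %s has < 2 pool injections; skipped", pl))
      next
    }
    cvs <- apply(m[rows, , drop = FALSE], 2L, cv_percent)
    per_plate[[pl]] <- data.table(plate = pl,
                                  median_cv = stats::median(cvs, na.rm = TRUE),
                                  n_peptides = sum(!is.na(cvs)))
  }
  overall <- apply(m[pool, , drop = FALSE], 2L, cv_percent)
  per_plate <- rbindlist(per_plate)
  list(per_plate = per_plate,
       per_peptide_overall = overall,
       overall_median_cv = stats::median(overall, na.rm = TRUE),
       per_plate_median_cv = if (nrow(per_plate))
         stats::median(per_plate$median_cv) else NA_real_)
}

#' Pairwise Pearson correlation between pool injections
#'
#' Correlates every pair of pool injections over the log10 concentrations
#' of their shared quantified peptides; pairs sharing fewer than 3 peptides
#' are skipped with a warning.
#'
#' @param cm Peptide-level [conc_matrix()] or matrix.
#' @param manifest Sample manifest.
#' @return List: `pairs` (data.table sample_a, sample_b, r, n_shared),
#'   `median_r`.
#' @export
pool_correlation <- function(cm, manifest) {
  m <- if (inherits(cm, "conc_matrix")) cm$values else cm
  manifest <- as.data.table(manifest)
  info <- manifest[match(rownames(m), sample_id)]
  pool_ids <- rownames(m)[info$sample_type == "pool"]
  if (length(pool_ids) < 2L)
    sq_stop("validation_error", "need at least 2 pool injections")
  lp <- log10(m[pool_ids, , drop = FALSE])
  cmb <- utils::combn(length(pool_ids), 2L)
  res <- vector("list", ncol(cmb))
  skipped <- 0L
  for (j in seq_len(ncol(cmb))) {
    a <- cmb[1L, j]; b <- cmb[2L, j]
    ok <- !is.na(lp[a, ]) & !is.na(lp[b, ])
    if (sum(ok) < 3L) { skipped <- skipped + 1L; next }
    res[[j]] <- data.table(sample_a = pool_ids[a], sample_b = pool_ids[b],
                           r = stats::cor(lp[a, ok], lp[b, ok]),
                           n_shared = sum(ok))
  }
  if (skipped) warning(sprintf("%d pool pairs shared < 3 peptides; skipped",
                               skipped))
  pairs <- rbindlist(res[!vapply(res, is.null, logical(1L))])
  list(pairs = pairs,
       median_r = if (nrow(pairs)) stats::median(pairs$r) else NA_real_)
}

#' Normalized interquartile range of patient concentrations per protein
#'
#' Default definition is the fold range of the interquartile interval,
#' `nIQR = Q3/Q1` (>= 1, scale-free), read against the observation that
#' most between-patient variation is below two-fold; the alternative
#' `(Q3 - Q1)/median` is available via `method = "relative"`. Quartiles use
#' linear interpolation between order statistics (R quantile type 7).
#' Pools are excluded; proteins with fewer than 4 patient values are
#' skipped with a warning.
#'
#' @param cm Protein-level [conc_matrix()] or matrix.
#' @param manifest Sample manifest.
#' @param method "fold" (Q3/Q1, default) or "relative" ((Q3-Q1)/median).
#' @return List: `per_protein` (named vector), `median_niqr`, `method`.
#' @export
normalized_iqr <- function(cm, manifest, method = c("fold", "relative")) {
  method <- match.arg(method)
  m <- if (inherits(cm, "conc_matrix")) cm$values else cm
  manifest <- as.data.table(manifest)
  info <- manifest[match(rownames(m), sample_id)]
  pat <- info$sample_type == "patient"
  if (!any(pat)) sq_stop("validation_error", "no patient samples in matrix")
  mm <- m[pat, , drop = FALSE]
  vals <- apply(mm, 2L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 4L) return(NA_real_)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7L)
    if (method == "fold") q[3L] / q[1L] else (q[3L] - q[1L]) / q[2L]
  })
  if (anyNA(vals))
    warning(sprintf("%d protein(s) with < 4 patient values skipped",
                    sum(is.na(vals))))
  list(per_protein = vals,
       median_niqr = stats::median(vals, na.rm = TRUE),
       method = method)
}

#' Assemble the assay QC report
#'
#' Bundles intra-assay CV, pool correlation and normalized IQR together
#' with the sample-QC exclusions into one JSON-serializable list.
#'
#' @param quant A `quant_result` from [quantify()].
#' @param manifest Sample manifest.
#' @param niqr_method Passed to [normalized_iqr()].
#' @param cv_on "raw" (default; un-normalized concentrations, so the CV is
#'   not deflated by dividing pools by their own plate median) or
#'   "normalized".
#' @return List of class `qc_report`.
#' @export
qc_report <- function(quant, manifest, niqr_method = "fold",
                      cv_on = c("raw", "normalized")) {
  cv_on <- match.arg(cv_on)
  stopifnot(inherits(quant, "quant_result"))
  cv_mat <- if (cv_on == "raw") quant$peptide_matrix_raw else
    quant$peptide_matrix
  cv <- intra_assay_cv(cv_mat, manifest)
  pc <- pool_correlation(quant$peptide_matrix, manifest)
  has_patients <- any(as.data.table(manifest)[
    sample_id %in% rownames(quant$protein_matrix$values), sample_type
  ] == "patient")
  niqr <- if (has_patients)
    normalized_iqr(quant$protein_matrix, manifest, method = niqr_method)
  else list(per_protein = NULL, median_niqr = NA_real_, method = niqr_method)
  structure(list(
    per_plate_cv = cv$per_plate,
    per_plate_median_cv = cv$per_plate_median_cv,
    overall_median_cv = cv$overall_median_cv,
    cv_on = cv_on,
    pool_pearson_median = pc$median_r,
    pool_pearson_pairs = pc$pairs,
    median_niqr = niqr$median_niqr,
    niqr_method = niqr$method,
    per_protein_niqr = niqr$per_protein,
    excluded_samples = quant$sample_qc[pass == FALSE,
                                       .(sample_id, reasons)]
  ), class = "qc_report")
}
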