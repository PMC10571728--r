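#' Pair light and heavy transitions
#'
#' A transition (fragment, product charge) of a sample x peptide is paired
#' iff a present, positive area exists in BOTH isotope channels; non-paired
#' transitions are dropped and logged with a reason.
#'
#' @param records Validated transition records (anchor-only, light-only
#'   peptides simply yield zero pairs).
#' @return data.table with one row per candidate transition: key columns,
#'   `area_light`, `area_heavy`, `dotp_light`, logical `paired` and
#'   `drop_reason` (NA when paired; otherwise one of `missing_light`,
#'   `missing_heavy`, `nonpositive_area`).
#' @export
pair_transitions <- function(records) {
  rec <- as.data.table(records)
  key <- c("sample_id", "peptide", "fragment", "product_charge")
  light <- rec[label == "light",
               c(key, "protein", "plate", "area", "dotp"), with = FALSE]
  setnames(light, c("area", "dotp"), c("area_light", "dotp_light"))
  heavy <- rec[label == "heavy", c(key, "protein", "plate", "area"), with = FALSE]
  setnames(heavy, "area", "area_heavy")
  pairs <- merge(light, heavy, by = key, all = TRUE, suffixes = c("", ".h"))
  pairs[is.na(protein), protein := get("protein.h")]
  pairs[is.na(plate), plate := get("plate.h")]
  pairs[, c("protein.h", "plate.h") := NULL]
  pairs[, paired := !is.na(area_light) & !is.na(area_heavy) &
          area_light > 0 & area_heavy > 0]
  pairs[, drop_reason := NA_character_]
  pairs[!paired & is.na(area_heavy), drop_reason := "missing_heavy"]
  pairs[!paired & is.na(area_light), drop_reason := "missing_light"]
  pairs[!paired & is.na(drop_reason), drop_reason := "nonpositive_area"]
  pairs[]
}

#' Summed-area ratio to standard of one paired transition set
#'
#' `L` and `H` are the summed areas over paired transitions only; the ratio
#' to standard is `r = L / H` (endogenous light over spiked heavy), so that
#' `r * S_p` is the endogenous concentration.
#'
#' @param light,heavy Equal-length numeric vectors of paired areas.
#' @return List with `L`, `H`, `r`.
#' @export
compute_ratio <- function(light, heavy) {
  if (length(light) != length(heavy))
    sq_stop("validation_error", "paired area vectors differ in length")
  if (length(light) < 1L)
    sq_stop("no_pairs_error", "ratio undefined without paired transitions")
  L <- sum(light)
  H <- sum(heavy)
  if (H == 0) sq_stop("undefined_ratio_error", "summed heavy area is zero")
  list(L = L, H = H, r = L / H)
}

#' Ratio dot product of one paired transition set
#'
#' Cosine similarity between the light and heavy paired-area vectors; 1 for
#' proportional fragment patterns, 0 for orthogonal ones (or a zero vector).
#'
#' @param light,heavy Equal-length numeric vectors of paired areas.
#' @return Scalar in [0, 1].
#' @export
compute_rdotp <- function(light, heavy) {
  if (length(light) != length(heavy))
    sq_stop("validation_error", "paired area vectors differ in length")
  nl <- sqrt(sum(light^2))
  nh <- sqrt(sum(heavy^2))
  if (nl == 0 || nh == 0) return(0)
  min(1, sum(light * heavy) / (nl * nh))
}

#' Per sample x peptide quantities from paired transitions
#'
#' Sums paired areas into `L`, `H` and the ratio `r = L/H`, recomputes the
#' ratio dot product from the paired-area vectors, and carries the input
#' library dot product (median of the peptide's light-transition dotp
#' values). Peptides with zero pairs get `n_paired = 0` and NA quantities.
#'
#' @param pairs Output of [pair_transitions()].
#' @return data.table keyed by (`sample_id`, `peptide`) with `protein`,
#'   `plate`, `n_paired`, `L`, `H`, `ratio`, `rdotp`, `dotp`.
#' @export
peptide_quants <- function(pairs) {
  q <- pairs[, {
    p <- paired
    l <- area_light[p]
    h <- area_heavy[p]
    L <- sum(l)
    H <- sum(h)
    list(protein = protein[1L], plate = plate[1L], n_paired = sum(p),
         L = if (sum(p)) L else NA_real_,
         H = if (sum(p)) H else NA_real_,
         ratio = if (sum(p) && H > 0) L / H else NA_real_,
         rdotp = if (sum(p)) compute_rdotp(l, h) else NA_real_,
         dotp = stats::median(dotp_light, na.rm = TRUE))
  }, by = .(sample_id, peptide)]
  q[]
}

#' Apply the peptide-level quantification filters
#'
#' A peptide observation is quantified iff `rdotp > 0.7`, `dotp > 0.5` and
#' `0.01 < r < 1000` (all strict, thresholds configurable) and at least one
#' paired transition exists. Every rejection carries its reason code(s)
#' from {`no_pairs`, `low_rdotp`, `low_dotp`, `ratio_out_of_bounds`}.
#'
#' @param quants Output of [peptide_quants()].
#' @param rdotp_min,dotp_min,ratio_min,ratio_max Thresholds (strict
#'   inequalities as printed: `rdotp > 0.7`, `dotp > 0.5`,
#'   `1000 > r > 0.01`).
#' @return `quants` with `status` ("quantified"/"rejected") and `reasons`
#'   (comma-joined codes, NA when quantified).
#' @export
filter_peptides <- function(quants, rdotp_min = 0.7, dotp_min = 0.5,
                            ratio_min = 0.01, ratio_max = 1000) {
  q <- copy(as.data.table(quants))
  no_pairs <- q$n_paired == 0L | is.na(q$ratio)
  low_rdotp <- !no_pairs & !(q$rdotp > rdotp_min)
  low_dotp <- !no_pairs & !(!is.na(q$dotp) & q$dotp > dotp_min)
  bad_ratio <- !no_pairs & !(q$ratio > ratio_min & q$ratio < ratio_max)
  reasons <- mapply(function(a, b, c, d) {
    r <- c("no_pairs", "low_rdotp", "low_dotp", "ratio_out_of_bounds")[c(a, b, c, d)]
    if (length(r)) paste(r, collapse = ",") else NA_character_
  }, no_pairs, low_rdotp, low_dotp, bad_ratio, USE.NAMES = FALSE)
  q[, status := ifelse(is.na(reasons), "quantified", "rejected")]
  q[, reasons := reasons]
  q[]
}

#' Fit the per-sample retention-time regression on anchor peptides
#'
#' Ordinary least squares of measured retention time on reference iRT over
#' the detected anchor peptides of each sample. Fewer than two detected
#' anchors leaves the fit undefined (the sample later fails QC).
#'
#' @param records Transition records; anchors are the light rows of
#'   `anchor_peptides` carrying a non-missing `irt_ref` and `rt_min`.
#' @param anchor_peptides Character vector of anchor peptide ids; `NULL`
#'   auto-detects every peptide with a non-missing `irt_ref`.
#' @return data.table per sample: `sample_id`, `slope`, `intercept`, `r2`,
#'   `n_anchors`.
#' @export
fit_irt_regression <- function(records, anchor_peptides = NULL) {
  rec <- as.data.table(records)
  if (is.null(anchor_peptides))
    anchor_peptides <- unique(rec[!is.na(irt_ref), peptide])
  if (!length(anchor_peptides))
    sq_stop("config_error", "anchor peptide list is empty")
  a <- rec[label == "light" & peptide %in% anchor_peptides &
             !is.na(irt_ref) & !is.na(rt_min),
           .(rt = rt_min[1L], irt = irt_ref[1L]), by = .(sample_id, peptide)]
  fits <- a[, {
    n <- .N
    if (n < 2L || stats::var(irt) == 0) {
      list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
           n_anchors = n)
    } else {
      b <- stats::cov(irt, rt) / stats::var(irt)
      a0 <- mean(rt) - b * mean(irt)
      r2 <- if (stats::var(rt) == 0) 1 else stats::cor(irt, rt)^2
      list(slope = b, intercept = a0, r2 = r2, n_anchors = n)
    }
  }, by = sample_id]
  fits[]
}

#' Sample-level quality control
#'
#' A sample is excluded iff its anchor retention-time regression fails
#' (undefined, `R^2 < min_r2` or fewer than `min_anchors` anchors) or it
#' has fewer than `min_proteins` distinct quantified proteins (strict
#' "fewer than", so exactly `min_proteins` is retained).
#'
#' @param quants Filtered quants ([filter_peptides()]).
#' @param manifest Sample manifest (enumerates the samples to judge).
#' @param irt_fits Output of [fit_irt_regression()].
#' @param min_proteins Minimum quantified proteins (default 120).
#' @param min_r2 Minimum anchor-regression R^2 (default 0.99).
#' @param min_anchors Minimum detected anchors (default 6).
#' @return data.table per sample: `sample_id`, `n_proteins`, `r2`,
#'   `n_anchors`, `pass`, `reasons`.
#' @export
qc_samples <- function(quants, manifest, irt_fits, min_proteins = 120L,
                       min_r2 = 0.99, min_anchors = 6L) {
  manifest <- as.data.table(manifest)
  nprot <- as.data.table(quants)[status == "quantified",
                                 .(n_proteins = length(unique(protein))),
                                 by = sample_id]
  out <- data.table(sample_id = manifest$sample_id)
  out <- merge(out, nprot, by = "sample_id", all.x = TRUE)
  out[is.na(n_proteins), n_proteins := 0L]
  out <- merge(out, as.data.table(irt_fits)[, .(sample_id, r2, n_anchors)],
               by = "sample_id", all.x = TRUE)
  out[is.na(n_anchors), n_anchors := 0L]
  irt_fail <- is.na(out$r2) | out$r2 < min_r2 | out$n_anchors < min_anchors
  few <- out$n_proteins < min_proteins
  out[, pass := !(irt_fail | few)]
  out[, reasons := {
    r <- character(.N)
    r[irt_fail & few] <- "irt_regression,few_proteins"
    r[irt_fail & !few] <- "irt_regression"
    r[!irt_fail & few] <- "few_proteins"
    r[r == ""] <- NA_character_
    r
  }]
  out[]
}

#' Convert ratios to absolute concentrations
#'
#' `C = r * S_p` in pmol/uL raw plasma, for quantified peptide observations
#' only. Every quantified peptide must appear in the spike panel.
#'
#' @param quants Filtered quants ([filter_peptides()]), typically already
#'   restricted to QC-passing samples.
#' @param panel Spike panel ([read_panel()] / [build_spike_panel()]).
#' @return A peptide-level [conc_matrix()] (un-normalized).
#' @export
to_absolute <- function(quants, panel) {
  q <- as.data.table(quants)[status == "quantified"]
  panel <- as.data.table(panel)
  missing_pep <- setdiff(unique(q$peptide), panel$peptide)
  if (length(missing_pep))
    sq_stop("config_error", "quantified peptide(s) absent from panel: %s",
            paste(head(missing_pep, 5L), collapse = ", "))
  q <- merge(q, panel[, .(peptide, spike_conc_pmol_per_ul)], by = "peptide")
  q[, conc := ratio * spike_conc_pmol_per_ul]
  samples <- sort(unique(as.data.table(quants)$sample_id))
  peps <- sort(unique(q$peptide))
  m <- matrix(NA_real_, length(samples), length(peps),
              dimnames = list(samples, peps))
  m[cbind(match(q$sample_id, samples), match(q$peptide, peps))] <- q$conc
  conc_matrix(m, analytes = unique(q[, .(analyte = peptide, protein)]),
              level = "peptide")
}

#' Exclude peptides with a low quantification rate
#'
#' A peptide is kept iff it is quantified in at least `min_rate` of the
#' samples in the matrix ("less than 50%" excluded, so a rate of exactly
#' 0.5 is kept).
#'
#' @param cm A peptide-level [conc_matrix()] (post sample-QC, so the
#'   denominator is retained samples).
#' @param min_rate Minimum quantification rate (default 0.5).
#' @return The filtered `conc_matrix`; dropped peptides recorded in
#'   provenance.
#' @export
filter_by_quant_rate <- function(cm, min_rate = 0.5) {
  stopifnot(inherits(cm, "conc_matrix"))
  rate <- colMeans(!is.na(cm$values))
  keep <- rate >= min_rate
  prov <- cm$provenance
  prov$quant_rate <- list(min_rate = min_rate, n_in = ncol(cm$values),
                          n_kept = sum(keep), n_dropped = sum(!keep),
                          dropped = colnames(cm$values)[!keep])
  conc_matrix(cm$values[, keep, drop = FALSE],
              cm$analytes[analyte %in% colnames(cm$values)[keep]],
              level = cm$level, norm_factors = cm$norm_factors,
              provenance = prov)
}

#' Pool-based plate median normalization
#'
#' For each peptide x plate the factor is the global median of that peptide
#' over ALL pool injections divided by the median over that plate's pool
#' injections; all of the plate's values of the peptide (patients and pools
#' alike) are multiplied by it. Peptides without pool values on a plate get
#' factor 1 (logged). Applying the normalization twice is a no-op.
#'
#' @param cm A peptide-level [conc_matrix()].
#' @param manifest Sample manifest (provides plate and pool membership).
#' @return The normalized `conc_matrix` with `norm_factors` filled.
#' @export
median_normalize <- function(cm, manifest) {
  stopifnot(inherits(cm, "conc_matrix"))
  manifest <- as.data.table(manifest)
  m <- cm$values
  info <- manifest[match(rownames(m), sample_id)]
  pool_rows <- which(info$sample_type == "pool")
  if (!length(pool_rows))
    sq_stop("validation_error", "median normalization requires pool samples")
  plates <- unique(info$plate)
  global_med <- apply(m[pool_rows, , drop = FALSE], 2L,
                      stats::median, na.rm = TRUE)
  factors <- list()
  for (pl in plates) {
    rows <- which(info$plate == pl)
    prow <- intersect(rows, pool_rows)
    f <- rep(1, ncol(m))
    if (length(prow)) {
      plate_med <- apply(m[prow, , drop = FALSE], 2L,
                         stats::median, na.rm = TRUE)
      ok <- !is.na(plate_med) & plate_med > 0 & !is.na(global_med)
      f[ok] <- global_med[ok] / plate_med[ok]
    }
    m[rows, ] <- sweep(m[rows, , drop = FALSE], 2L, f, `*`)
    factors[[pl]] <- data.table(plate = pl, analyte = colnames(m), factor = f)
  }
  conc_matrix(m, cm$analytes, level = cm$level,
              norm_factors = rbindlist(factors), provenance = cm$provenance)
}

#' Roll peptide concentrations up to proteins
#'
#' Protein concentration per sample is the median over that protein's
#' quantified peptides (even counts use the mean of the two middle values);
#' missing when no peptide is quantified.
#'
#' @param cm A peptide-level [conc_matrix()].
#' @return A protein-level [conc_matrix()].
#' @export
rollup_protein <- function(cm) {
  stopifnot(inherits(cm, "conc_matrix"), cm$level == "peptide")
  map <- cm$analytes[match(colnames(cm$values), analyte)]
  prots <- unique(map$protein)
  out <- matrix(NA_real_, nrow(cm$values), length(prots),
                dimnames = list(rownames(cm$values), prots))
  for (pr in prots) {
    cols <- which(map$protein == pr)
    sub <- cm$values[, cols, drop = FALSE]
    med <- apply(sub, 1L, function(x)
      if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE))
    out[, pr] <- med
  }
  conc_matrix(out, data.table(analyte = prots, protein = prots),
              level = "protein", norm_factors = cm$norm_factors,
              provenance = cm$provenance)
}

#' Run the full quantification pipeline on a transition report
#'
#' Pairs channels, computes summed-area ratios and scores, applies the
#' peptide filters (`rdotp > 0.7`, `dotp > 0.5`, `0.01 < r < 1000`), the
#' anchor retention-time sample gate and the minimum-quantified-proteins
#' gate, converts to absolute concentrations (`C = r * S_p`), excludes
#' peptides quantified in fewer than half of the retained samples, applies
#' pool median normalization and rolls concentrations up to proteins.
#' Every stage logs additive counts into the provenance.
#'
#' @param records Transition records ([read_transition_report()]).
#' @param panel Spike panel.
#' @param manifest Sample manifest.
#' @param rdotp_min,dotp_min,ratio_min,ratio_max Peptide filter thresholds.
#' @param min_proteins,min_r2,min_anchors Sample QC thresholds (note the
#'   default `min_proteins = 120` targets the full-scale assay; scale it
#'   with the panel for smaller synthetic runs).
#' @param min_quant_rate Peptide quantification-rate threshold.
#' @param normalize Apply pool median normalization (default TRUE).
#' @param anchor_peptides Anchor list for the retention-time gate; `NULL`
#'   auto-detects peptides carrying `irt_ref`.
#' @return List of class `quant_result`: `peptide_quants`, `irt_fits`,
#'   `sample_qc`, `peptide_matrix_raw` (post rate filter, un-normalized),
#'   `peptide_matrix` (normalized), `protein_matrix`, `provenance`.
#' @export
quantify <- function(records, panel, manifest,
                     rdotp_min = 0.7, dotp_min = 0.5,
                     ratio_min = 0.01, ratio_max = 1000,
                     min_proteins = 120L, min_r2 = 0.99, min_anchors = 6L,
                     min_quant_rate = 0.5, normalize = TRUE,
                     anchor_peptides = NULL) {
  records <- as.data.table(records)
  validate_transition_records(records)
  manifest <- validate_manifest(manifest)
  panel <- as.data.table(panel)

  if (is.null(anchor_peptides))
    anchor_peptides <- unique(records[!is.na(irt_ref), peptide])
  irt_fits <- if (length(anchor_peptides))
    fit_irt_regression(records, anchor_peptides)
  else data.table(sample_id = unique(records$sample_id), slope = NA_real_,
                  intercept = NA_real_, r2 = NA_real_, n_anchors = 0L)

  quant_rec <- records[!peptide %in% anchor_peptides]
  pairs <- pair_transitions(quant_rec)
  quants <- filter_peptides(peptide_quants(pairs),
                            rdotp_min = rdotp_min, dotp_min = dotp_min,
                            ratio_min = ratio_min, ratio_max = ratio_max)
  sample_qc <- qc_samples(quants, manifest, irt_fits,
                          min_proteins = min_proteins, min_r2 = min_r2,
                          min_anchors = min_anchors)
  retained <- sample_qc[pass == TRUE, sample_id]
  if (!length(retained))
    sq_stop("qc_error", "no sample passed QC; check min_proteins vs panel size")
  kept_quants <- quants[sample_id %in% retained]

  pepmat <- to_absolute(kept_quants, panel)
  pepmat$provenance <- list(
    thresholds = list(rdotp_min = rdotp_min, dotp_min = dotp_min,
                      ratio_min = ratio_min, ratio_max = ratio_max,
                      min_proteins = min_proteins, min_r2 = min_r2,
                      min_anchors = min_anchors,
                      min_quant_rate = min_quant_rate),
    transitions = list(
      n_in = nrow(quant_rec),
      n_paired = 2L * sum(pairs$paired),
      n_dropped = nrow(quant_rec) - 2L * sum(pairs$paired),
      drop_reasons = as.list(table(pairs$drop_reason[!pairs$paired]))),
    peptides = list(
      n_in = nrow(quants),
      n_quantified = sum(quants$status == "quantified"),
      n_rejected = sum(quants$status == "rejected"),
      reject_reasons = as.list(table(unlist(
        strsplit(quants$reasons[quants$status == "rejected"], ","))))),
    samples = list(
      n_in = nrow(sample_qc), n_retained = length(retained),
      n_excluded = nrow(sample_qc) - length(retained),
      excluded = sample_qc[pass == FALSE, sample_id],
      exclude_reasons = as.list(table(sample_qc$reasons[!sample_qc$pass])))
  )
  pepmat <- filter_by_quant_rate(pepmat, min_rate = min_quant_rate)
  raw <- pepmat
  if (normalize) pepmat <- median_normalize(pepmat, manifest)
  protmat <- rollup_protein(pepmat)

  structure(list(peptide_quants = quants, irt_fits = irt_fits,
                 sample_qc = sample_qc, peptide_matrix_raw = raw,
                 peptide_matrix = pepmat, protein_matrix = protmat,
                 provenance = pepmat$provenance),
            class = "quant_result")
}

utils::globalVariables(c("paired", "drop_reason", "pass", "L", "H", "slope",
                         "intercept", "r2", "n_anchors", "n_proteins"))
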