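#' Concentration matrix container
#'
#' Samples x analytes absolute concentrations (pmol/uL raw plasma) with the
#' analyte-to-protein map, the normalization factors applied (if any) and a
#' provenance list of filter thresholds and per-stage counts.
#'
#' @param values Numeric matrix, samples in rows (named), analytes in
#'   columns (named); `NA` where not quantified.
#' @param analytes data.table mapping `analyte` to `protein` (for a
#'   protein-level matrix both columns equal the protein).
#' @param level "peptide" or "protein".
#' @param norm_factors data.table of applied normalization factors
#'   (`plate`, `analyte`, `factor`), or `NULL` before normalization.
#' @param provenance Named list of thresholds and counts.
#' @return Object of class `conc_matrix`.
#' @export
conc_matrix <- function(values, analytes, level = c("peptide", "protein"),
                        norm_factors = NULL, provenance = list()) {
  level <- match.arg(level)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  analytes <- as.data.table(analytes)
  stopifnot(all(c("analyte", "protein") %in% names(analytes)))
  if (!all(colnames(values) %in% analytes$analyte))
    sq_stop("validation_error", "every matrix column needs an analyte entry")
  if (any(values[!is.na(values)] <= 0))
    sq_stop("validation_error", "concentrations must be > 0 where present")
  structure(list(values = values, analytes = analytes, level = level,
                 norm_factors = norm_factors, provenance = provenance),
            class = "conc_matrix")
}

#' @export
print.conc_matrix <- function(x, ...) {
  cat(sprintf("<conc_matrix> %d samples x %d %ss (%.1f%% quantified)%s\n",
              nrow(x$values), ncol(x$values), x$level,
              100 * mean(!is.na(x$values)),
              if (is.null(x$norm_factors)) "" else ", pool-normalized"))
  invisible(x)
}

#' @export
dim.conc_matrix <- function(x) dim(x$values)
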