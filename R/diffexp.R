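#' Default sex restriction map for one-vs-rest comparisons
#'
#' For male- and female-specific cancers only patients of the relevant sex
#' enter the rest group: prostate cancer is compared within males; breast,
#' ovarian, endometrial and cervical cancers within females.
#'
#' @return Named character vector cancer -> "male"/"female".
#' @export
default_sex_restriction <- function() {
  sp <- default_sex_specific()
  stats::setNames(c(rep("male", length(sp$male)), rep("female", length(sp$female))),
                  c(sp$male, sp$female))
}

#' Vectorized two-sample t statistics over matrix columns
#' @noRd
two_group_t <- function(X, case_idx, rest_idx, var_equal = FALSE) {
  gstat <- function(rows) {
    sub <- X[rows, , drop = FALSE]
    M <- !is.na(sub)
    sub[!M] <- 0
    n <- colSums(M)
    s <- colSums(sub)
    m <- ifelse(n > 0, s / n, NA_real_)
    ss <- colSums(sub^2)
    v <- ifelse(n > 1, (ss - n * m^2) / (n - 1), NA_real_)
    list(n = n, m = m, v = pmax(v, 0))
  }
  g1 <- gstat(case_idx)
  g2 <- gstat(rest_idx)
  ok <- g1$n >= 2L & g2$n >= 2L
  delta <- g1$m - g2$m
  if (var_equal) {
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * g1$v + (g2$n - 1) * g2$v) / df
    se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    se2a <- g1$v / g1$n
    se2b <- g2$v / g2$n
    se <- sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 /
      (se2a^2 / (g1$n - 1) + se2b^2 / (g2$n - 1))
  }
  t <- delta / se
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate zero-variance, zero-delta columns: no evidence against null
  p[!is.na(se) & se == 0 & !is.na(delta) & delta == 0] <- 1
  list(ok = ok, n_case = g1$n, n_rest = g2$n, mean_case = g1$m,
       mean_rest = g2$m, delta = delta, t = t, df = df, p = p)
}

#' One-vs-rest differential abundance screen
#'
#' For each cancer type, compares its patients against all other patients
#' with a two-sided t test per peptide on log2 concentrations (Welch by
#' default; the classic pooled-variance test via `var_equal = TRUE`).
#' For sex-specific cancers the rest group is restricted to the relevant
#' sex. Raw p values are Bonferroni-adjusted within each comparison
#' (multiplied by the number of peptides tested there, capped at 1) and
#' flagged significant below `alpha`. Pools never enter.
#'
#' @param cm Peptide-level [conc_matrix()] (linear concentrations; the test
#'   runs on log2) or a plain samples x peptides matrix.
#' @param manifest Sample manifest.
#' @param sex_map Named vector cancer -> sex restriction
#'   ([default_sex_restriction()]).
#' @param alpha Significance level on the adjusted p (default 0.0005).
#' @param var_equal Pooled-variance t instead of Welch (default FALSE).
#' @param family Bonferroni family: "per_comparison" (default; each
#'   volcano panel stands alone) or "global" (peptides x comparisons).
#' @return data.table: `comparison`, `peptide`, `protein`, `n_case`,
#'   `n_rest`, `mean_case`, `mean_rest`, `delta_log2`, `t`, `df`,
#'   `p_value`, `padj`, `significant`. Peptides with fewer than two
#'   non-missing values in either group are skipped (absent from the
#'   table for that comparison).
#' @export
one_vs_rest <- function(cm, manifest, sex_map = default_sex_restriction(),
                        alpha = 0.0005, var_equal = FALSE,
                        family = c("per_comparison", "global")) {
  family <- match.arg(family)
  m <- if (inherits(cm, "conc_matrix")) cm$values else cm
  analytes <- if (inherits(cm, "conc_matrix")) cm$analytes else
    data.table(analyte = colnames(m), protein = colnames(m))
  manifest <- as.data.table(manifest)
  info <- manifest[match(rownames(m), sample_id)]
  pat <- which(info$sample_type == "patient")
  if (!length(pat)) sq_stop("validation_error", "no patient samples")
  X <- log2(m)
  cancers <- sort(unique(info$cancer[pat]))
  out <- vector("list", length(cancers))
  for (i in seq_along(cancers)) {
    cc <- cancers[i]
    case_idx <- pat[info$cancer[pat] == cc]
    rest_idx <- pat[info$cancer[pat] != cc]
    if (cc %in% names(sex_map))
      rest_idx <- rest_idx[info$sex[rest_idx] == sex_map[[cc]]]
    if (length(case_idx) < 2L || length(rest_idx) < 2L) next
    st <- two_group_t(X, case_idx, rest_idx, var_equal = var_equal)
    keep <- which(st$ok)
    if (!length(keep)) next
    out[[i]] <- data.table(
      comparison = cc, peptide = colnames(X)[keep],
      protein = analytes$protein[match(colnames(X)[keep], analytes$analyte)],
      n_case = as.integer(st$n_case[keep]),
      n_rest = as.integer(st$n_rest[keep]),
      mean_case = st$mean_case[keep], mean_rest = st$mean_rest[keep],
      delta_log2 = st$delta[keep], t = st$t[keep], df = st$df[keep],
      p_value = st$p[keep]
    )
  }
  res <- rbindlist(out)
  if (!nrow(res)) return(res)
  if (family == "per_comparison") {
    res[, padj := pmin(1, p_value * .N), by = comparison]
  } else {
    res[, padj := pmin(1, p_value * nrow(res))]
  }
  res[, significant := padj < alpha]
  res[]
}

#' Volcano-plot input table
#'
#' @param results Output of [one_vs_rest()].
#' @return data.table: `comparison`, `peptide`, `protein`, `delta_log2`,
#'   `neg_log10_padj`, `significant`.
#' @export
volcano_table <- function(results) {
  res <- as.data.table(results)
  if (!nrow(res))
    return(data.table(comparison = character(), peptide = character(),
                      protein = character(), delta_log2 = numeric(),
                      neg_log10_padj = numeric(), significant = logical()))
  res[, .(comparison, peptide, protein, delta_log2,
          neg_log10_padj = -log10(pmax(padj, .Machine$double.xmin)),
          significant)]
}

#' Network edge table of significant proteins
#'
#' One edge per (cancer, protein) with at least one significant peptide;
#' direction is the sign of the fold change of the most significant
#' supporting peptide, and the number of supporting peptides is retained.
#'
#' @param results Output of [one_vs_rest()].
#' @return data.table: `comparison`, `protein`, `direction` ("up"/"down"),
#'   `n_support`.
#' @export
network_edge_table <- function(results) {
  res <- as.data.table(results)
  empty <- data.table(comparison = character(), protein = character(),
                      direction = character(), n_support = integer())
  if (!nrow(res)) return(empty)
  sig <- res[significant == TRUE]
  if (!nrow(sig)) return(empty)
  sig[, .(direction = ifelse(delta_log2[which.min(padj)] > 0, "up", "down"),
          n_support = .N), by = .(comparison, protein)]
}

utils::globalVariables(c("mean_case", "mean_rest", "df", "neg_log10_padj"))
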