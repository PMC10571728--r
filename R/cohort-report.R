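#' Emit a synthetic transition-level quantification report
#'
#' For peptide p in sample s the total light (endogenous) area is
#' `kappa_p * C_true(s, protein(p)) * exp(eta) * exp(eta_inj) * exp(delta_plate)`
#' and the total heavy (standard) area is `kappa_p * S_p * exp(eta_inj)`,
#' with `eta, eta_inj ~ Normal(0, sigma_intra)`. The injection-scale factor
#' `eta_inj` is shared by the two co-measured channels and cancels in the
#' light/heavy ratio, so the ratio (and hence concentration) noise is the
#' channel-specific `eta` alone and the pool concentration CV calibrates to
#' the lognormal closed form `sqrt(exp(sigma_intra^2) - 1)`.
#' `delta ~ Normal(0, sigma_plate)` per plate x peptide hits the light
#' channel only, so plate effects survive into the ratio and are
#' correctable by pool normalization. Each total is split across transitions by the peptide's
#' fragment profile. Transitions and whole channels drop out at the
#' configured rates; a configured fraction of sample x peptide observations
#' gets a library dot product planted below the 0.5 filter threshold.
#'
#' Retention-time anchor peptides are emitted light-only with their
#' reference iRT, at `rt = slope * iRT + intercept + Normal(0, rt_noise_sd)`.
#' Designed QC-fail samples either have their anchor retention times
#' scrambled ("irt" mode) or most panel peptides removed ("low_yield" mode).
#'
#' @param truth `ground_truth` from [draw_true_concentrations()].
#' @param manifest Manifest from [build_manifest()].
#' @param panel Spike panel from [build_spike_panel()].
#' @param config The generating [cohort_config()].
#' @return data.table in the transition-report schema: `sample_id`, `plate`,
#'   `well`, `protein`, `peptide`, `precursor_charge`, `fragment`,
#'   `product_charge`, `label`, `area`, `rt_min`, `irt_ref`, `dotp`.
#' @export
emit_transition_report <- function(truth, manifest, panel, config) {
  stopifnot(inherits(truth, "ground_truth"))
  config <- validate_cohort_config(config)
  validate_manifest(manifest)
  if (!all(panel$peptide %in% truth$peptides$peptide))
    sq_stop("config_error", "panel peptides must be a subset of truth peptides")
  set.seed(truth$seed_used + 2L)

  S <- nrow(manifest)
  pinfo <- truth$peptides[match(panel$peptide, truth$peptides$peptide)]
  K <- nrow(pinfo)
  Tn <- config$transitions_per_peptide
  n_plates <- length(unique(manifest$plate))
  plate_levels <- sort(unique(manifest$plate))
  plate_idx <- match(manifest$plate, plate_levels)

  Cmat <- truth$concentrations[manifest$sample_id, pinfo$protein, drop = FALSE]
  kap <- matrix(pinfo$kappa, S, K, byrow = TRUE)
  spk <- matrix(truth$spike_conc[pinfo$peptide], S, K, byrow = TRUE)

  delta <- matrix(rnorm(n_plates * K, 0, config$sigma_plate), n_plates, K)
  # injection-scale factor eta_inj is shared by the co-measured channels and
  # cancels in the ratio; eta is the channel-specific (ratio) noise, so the
  # concentration CV calibrates to sqrt(exp(sigma_intra^2) - 1)
  eta_inj <- matrix(rnorm(S * K, 0, config$sigma_intra), S, K)
  light_tot <- kap * Cmat *
    exp(matrix(rnorm(S * K, 0, config$sigma_intra), S, K)) *
    exp(eta_inj) * exp(delta[plate_idx, , drop = FALSE])
  heavy_tot <- kap * spk * exp(eta_inj)

  rt <- config$irt_slope * matrix(pinfo$irt, S, K, byrow = TRUE) +
    config$irt_intercept + matrix(rnorm(S * K, 0, config$rt_noise_sd), S, K)

  dotp <- matrix(pmin(1, pmax(0, 1 - abs(rnorm(S * K, 0, 0.02)))), S, K)
  corrupt <- matrix(runif(S * K) < config$corrupted_fraction, S, K)
  if (any(corrupt)) dotp[corrupt] <- runif(sum(corrupt), 0, 0.45)

  # designed low-yield samples keep ~10% of panel peptides
  keep_sp <- matrix(TRUE, S, K)
  low_ids <- truth$qc_fail[mode == "low_yield", sample_id]
  if (length(low_ids)) {
    li <- match(low_ids, manifest$sample_id)
    keep_sp[li, ] <- matrix(runif(length(li) * K) < 0.1, length(li), K)
  }

  # expand (sample, peptide) grid to transitions x channels
  gi <- rep(seq_len(S), times = K)        # sample index, peptide-major blocks
  ki <- rep(seq_len(K), each = S)
  nG <- S * K
  ti <- rep(seq_len(Tn), each = nG)
  gl <- rep(seq_len(nG), times = Tn)
  w <- truth$fragment_profiles[pinfo$peptide, , drop = FALSE]

  frag_names <- paste0("y", seq_len(Tn) + 3L)
  base_cols <- function(channel_area, label) {
    data.table(
      sample_id = manifest$sample_id[gi[gl]],
      plate = manifest$plate[gi[gl]],
      well = manifest$well[gi[gl]],
      protein = pinfo$protein[ki[gl]],
      peptide = pinfo$peptide[ki[gl]],
      precursor_charge = 2L,
      fragment = frag_names[ti],
      product_charge = 1L,
      label = label,
      area = channel_area,
      rt_min = rt[cbind(gi[gl], ki[gl])],
      irt_ref = NA_real_,
      dotp = if (label == "light") dotp[cbind(gi[gl], ki[gl])] else NA_real_
    )
  }
  area_l <- light_tot[cbind(gi[gl], ki[gl])] * w[cbind(ki[gl], ti)]
  area_h <- heavy_tot[cbind(gi[gl], ki[gl])] * w[cbind(ki[gl], ti)]
  light <- base_cols(area_l, "light")
  heavy <- base_cols(area_h, "heavy")

  # dropout masks (channel-level, then transition-level), plus low-yield
  keep_gl <- keep_sp[cbind(gi[gl], ki[gl])]
  ch_l <- matrix(runif(nG) >= config$missing_channel_rate, S, K)[cbind(gi[gl], ki[gl])]
  ch_h <- matrix(runif(nG) >= config$missing_channel_rate, S, K)[cbind(gi[gl], ki[gl])]
  tr_l <- runif(nG * Tn) >= config$missing_transition_rate
  tr_h <- runif(nG * Tn) >= config$missing_transition_rate
  light <- light[keep_gl & ch_l & tr_l]
  heavy <- heavy[keep_gl & ch_h & tr_h]

  # anchor peptides: one light-only row per anchor per sample
  anch <- truth$peptides[is_anchor == TRUE]
  nA <- nrow(anch)
  arows <- data.table(
    sample_id = rep(manifest$sample_id, each = nA),
    plate = rep(manifest$plate, each = nA),
    well = rep(manifest$well, each = nA),
    protein = rep(anch$protein, S),
    peptide = rep(anch$peptide, S),
    precursor_charge = 2L,
    fragment = "y4",
    product_charge = 1L,
    label = "light",
    area = anch$kappa[rep(seq_len(nA), S)] *
      exp(rnorm(S * nA, 0, config$sigma_intra)),
    rt_min = config$irt_slope * rep(anch$irt, S) + config$irt_intercept +
      rnorm(S * nA, 0, config$rt_noise_sd),
    irt_ref = rep(anch$irt, S),
    dotp = 0.99
  )
  irt_ids <- truth$qc_fail[mode == "irt", sample_id]
  for (sid in irt_ids) {
    rows <- which(arows$sample_id == sid)
    # random permutation, not reversal: a reversed series is still perfectly
    # (negatively) correlated with iRT and would pass an R^2 gate
    arows$rt_min[rows] <- arows$rt_min[sample(rows)]
  }

  out <- rbindlist(list(light, heavy, arows), use.names = TRUE)
  setorder(out, sample_id, peptide, fragment, label)
  out[]
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [build_manifest()],
#' [draw_true_concentrations()], [build_spike_panel()] and
#' [emit_transition_report()], optionally writing all generated tables plus
#' a ground-truth CSV and a JSON provenance file.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory, or `NULL` to only return objects.
#' @return List with `manifest`, `truth`, `panel`, `report` (and `files`
#'   when written).
#' @export
simulate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  manifest <- build_manifest(config)
  truth <- draw_true_concentrations(config, manifest)
  panel <- build_spike_panel(truth)
  report <- emit_transition_report(truth, manifest, panel, config)
  res <- list(manifest = manifest, truth = truth, panel = panel,
              report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      report = file.path(out_dir, "transition_report.csv"),
      panel = file.path(out_dir, "panel.csv"),
      manifest = file.path(out_dir, "manifest.csv"),
      truth = file.path(out_dir, "ground_truth.csv"),
      provenance = file.path(out_dir, "simulate_provenance.json")
    )
    fwrite(report, files["report"])
    fwrite(panel, files["panel"])
    fwrite(manifest, files["manifest"])
    gt <- as.data.table(as.table(truth$concentrations))
    setnames(gt, c("sample_id", "protein", "true_conc"))
    fwrite(gt, files["truth"])
    cfg <- unclass(config)
    cfg$effect_table <- as.data.frame(config$effect_table)
    write_json_file(list(config = cfg, seed = config$seed,
                         n_report_rows = nrow(report)),
                    files["provenance"])
    res$files <- files
  }
  res
}
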