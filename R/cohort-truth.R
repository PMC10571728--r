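#' Draw ground-truth concentrations for a synthetic cohort
#'
#' Protein baseline medians are log-uniform over the configured number of
#' decades. A patient's true concentration is
#' `baseline * 2^eps_bio * 2^effect[cancer, protein] * sexfactor`, with
#' `eps_bio ~ Normal(0, sigma_bio)` and `sexfactor` the configured
#' female/male fold change (1 for males). Pool samples share one fixed
#' profile: the linear mean of five virtual donors (3 male, 2 female),
#' identical across plates before measurement noise.
#'
#' Also draws the per-peptide assay parameters used downstream: the response
#' factor kappa (area units per pmol/uL), the fragment-intensity profile
#' (positive weights summing to 1), the reference iRT of every peptide, the
#' spike concentration of each standard (close to endogenous), and the list
#' of designed QC-fail samples.
#'
#' @param config A [cohort_config()].
#' @param manifest Manifest from [build_manifest()].
#' @param seed Seed for this stage; defaults to the config master seed (the
#'   stage offsets its stream internally so manifest and truth draws do not
#'   collide).
#' @return A list of class `ground_truth`: `concentrations` (samples x
#'   proteins matrix, pmol/uL), `peptides` (data.table: peptide, protein,
#'   kappa, irt, is_anchor), `fragment_profiles` (peptides x transitions),
#'   `spike_conc` (named by peptide; NA for anchors), `effect_table`,
#'   `sex_effect`, `qc_fail` (data.table: sample_id, mode), `pool_profile`,
#'   `baseline`, `seed_used`.
#' @export
draw_true_concentrations <- function(config, manifest, seed = config$seed) {
  config <- validate_cohort_config(config)
  validate_manifest(manifest)
  set.seed(seed + 1L)

  P <- config$n_proteins
  prots <- protein_names(P)
  decades <- config$dynamic_range_decades
  baseline <- 10^runif(P, config$log10_conc_min, config$log10_conc_min + decades)
  names(baseline) <- prots

  sexf <- rep(1, P)
  names(sexf) <- prots
  common <- intersect(names(config$sex_effect), prots)
  sexf[common] <- config$sex_effect[common]

  pat <- manifest[sample_type == "patient"]
  n_pat <- nrow(pat)
  log2C <- matrix(0, nrow = n_pat, ncol = P,
                  dimnames = list(pat$sample_id, prots))
  if (n_pat) {
    log2C <- log2C + matrix(log2(baseline), n_pat, P, byrow = TRUE) +
      matrix(rnorm(n_pat * P, 0, config$sigma_bio), n_pat, P)
    eff <- config$effect_table
    if (nrow(eff)) {
      for (i in seq_len(nrow(eff))) {
        if (eff$protein[i] %in% prots) {
          hit <- pat$cancer == eff$cancer[i]
          log2C[hit, eff$protein[i]] <- log2C[hit, eff$protein[i]] + eff$log2fc[i]
        }
      }
    }
    log2C <- log2C + outer(pat$sex == "female", log2(sexf))
  }

  # fixed pool: linear blend of 3 male + 2 female virtual donors
  donor_sex <- c("male", "male", "male", "female", "female")
  donor_l2 <- matrix(log2(baseline), 5L, P, byrow = TRUE) +
    matrix(rnorm(5L * P, 0, config$sigma_bio), 5L, P) +
    outer(donor_sex == "female", log2(sexf))
  pool_profile <- colMeans(2^donor_l2)
  names(pool_profile) <- prots

  conc <- matrix(NA_real_, nrow(manifest), P,
                 dimnames = list(manifest$sample_id, prots))
  if (n_pat) conc[pat$sample_id, ] <- 2^log2C
  pool_ids <- manifest[sample_type == "pool", sample_id]
  if (length(pool_ids))
    conc[pool_ids, ] <- matrix(pool_profile, length(pool_ids), P, byrow = TRUE)

  # peptide-level assay parameters
  k <- config$peptides_per_protein
  peps <- data.table(
    protein = rep(prots, each = k),
    peptide = paste0(rep(prots, each = k), "_PEP", rep(seq_len(k), P)),
    is_anchor = FALSE
  )
  nK <- nrow(peps)
  peps[, `:=`(kappa = 10^runif(nK, 4, 6), irt = runif(nK, 0, 100))]
  Tn <- config$transitions_per_peptide
  profiles <- matrix(runif(nK * Tn, 0.2, 1), nK, Tn)
  profiles <- profiles / rowSums(profiles)
  spike <- baseline[peps$protein] * 2^rnorm(nK, 0, config$spike_log2_sd)
  names(spike) <- peps$peptide
  rownames(profiles) <- peps$peptide

  # retention-time anchors (light-only, not part of the spike panel)
  nA <- config$n_anchor_peptides
  anchors <- data.table(
    protein = config$anchor_protein,
    peptide = sprintf("%s_ANCH%02d", config$anchor_protein, seq_len(nA)),
    is_anchor = TRUE,
    kappa = 1e6,
    irt = seq(5, 95, length.out = nA)
  )
  peptides <- rbindlist(list(peps, anchors), use.names = TRUE)

  # designed QC-fail samples, alternating failure modes
  n_fail <- round(config$qc_fail_fraction * n_pat)
  qc_fail <- if (n_fail > 0) {
    ids <- sample(pat$sample_id, n_fail)
    data.table(sample_id = ids,
               mode = rep(c("irt", "low_yield"), length.out = n_fail))
  } else {
    data.table(sample_id = character(), mode = character())
  }

  structure(list(
    concentrations = conc, peptides = peptides,
    fragment_profiles = profiles, spike_conc = spike,
    effect_table = config$effect_table, sex_effect = config$sex_effect,
    qc_fail = qc_fail, pool_profile = pool_profile, baseline = baseline,
    seed_used = seed
  ), class = "ground_truth")
}

#' Spike-in panel table from a ground truth
#'
#' One row per standard peptide with its spiked concentration in pmol per uL
#' raw plasma; anchor peptides are excluded (they carry no heavy standard).
#'
#' @param truth A `ground_truth` from [draw_true_concentrations()].
#' @return data.table with columns `protein`, `peptide`, `standard_id`,
#'   `spike_conc_pmol_per_ul`.
#' @export
build_spike_panel <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  peps <- truth$peptides[is_anchor == FALSE]
  prots <- unique(peps$protein)
  data.table(
    protein = peps$protein,
    peptide = peps$peptide,
    standard_id = sprintf("SIS%03d", match(peps$protein, prots)),
    spike_conc_pmol_per_ul = unname(truth$spike_conc[peps$peptide])
  )
}

utils::globalVariables(c("is_anchor", "kappa", "irt", "mode"))
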