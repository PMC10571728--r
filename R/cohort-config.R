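#' Per-cancer patient counts of the full pan-cancer cohort
#'
#' Fifteen cancer types with the sample sizes of the 1800-patient plasma
#' cohort that the synthetic generator emulates: pituitary neuroendocrine
#' tumor, lymphoma, chronic lymphocytic leukemia, acute myeloid leukemia,
#' multiple myeloma, breast, ovarian, endometrial, cervical, prostate,
#' colorectal, small-intestinal neuroendocrine tumor, lung, meningioma and
#' glioma.
#'
#' @return Named integer vector of patient counts summing to 1800.
#' @export
#' @examples
#' sum(full_cohort_counts())
full_cohort_counts <- function() {
  c("PIT-NET" = 50L, "Lymphoma" = 56L, "CLL" = 50L, "AML" = 52L,
    "MM" = 55L, "BRC" = 164L, "OVC" = 179L, "ENDC" = 110L, "CVX" = 110L,
    "PRC" = 172L, "CRC" = 248L, "SI-NET" = 54L, "LUNGC" = 289L,
    "Meningioma" = 51L, "Glioma" = 160L)
}

#' Desk-scale patient counts proportional to the full cohort
#'
#' Scales the full per-cancer counts down to roughly `total` patients while
#' preserving the cancer proportions (simple rounding, minimum depends on
#' rounding).
#'
#' @param total Approximate total number of patients (default 350).
#' @return Named integer vector.
#' @export
desk_cohort_counts <- function(total = 350L) {
  full <- full_cohort_counts()
  out <- as.integer(round(full * total / sum(full)))
  names(out) <- names(full)
  out
}

#' Default sex-specificity of cancer types
#'
#' Prostate cancer is male-only; breast, ovarian, endometrial and cervical
#' cancers are treated as female-only. All other types are drawn ~1:1.
#'
#' @return List with character vectors `male` and `female`.
#' @export
default_sex_specific <- function() {
  list(male = "PRC", female = c("BRC", "OVC", "ENDC", "CVX"))
}

#' Default planted disease-effect table: the multiple-myeloma panel
#'
#' The synthetic cohort plants a multiple-myeloma signature on ten proteins:
#' complement C1 components (C1QB, C1QC, C1R, C1S), JCHAIN, CD5L and CPN1
#' down-regulated, and TGFBI, CFD and MGP up-regulated in MM patients. The
#' fold-change magnitudes (-1 and +0.7 log2 units) are synthetic defaults
#' chosen for this generator; they are not measured values.
#'
#' @return data.table with columns `cancer`, `protein`, `log2fc`.
#' @export
mm_effect_table <- function() {
  data.table(
    cancer = "MM",
    protein = c("C1QB", "C1QC", "C1R", "C1S", "JCHAIN", "CD5L", "CPN1",
                "TGFBI", "CFD", "MGP"),
    log2fc = c(rep(-1, 7), rep(0.7, 3))
  )
}

#' Protein identifiers used by the generator
#'
#' The first twelve names are real plasma targets carried by the default
#' effect tables (the MM panel plus the sex-dimorphic PZP and the
#' genotype-variable LPA); the remainder are generic fillers.
#' @param n Number of proteins.
#' @return Character vector of length `n`.
#' @export
protein_names <- function(n) {
  named <- c("C1QB", "C1QC", "C1R", "C1S", "JCHAIN", "CD5L", "CPN1",
             "TGFBI", "CFD", "MGP", "PZP", "LPA")
  if (n <= length(named)) return(named[seq_len(n)])
  c(named, sprintf("PROT%03d", seq_len(n - length(named)) + length(named)))
}

#' Configuration of the synthetic cohort generator
#'
#' Describes the stated world the generator draws from: the plate/pool
#' design, assay scale, noise model and planted biology. Defaults are the
#' desk-scale configuration: 350 patients proportional to the full cohort
#' on four 96-well plates with pooled-plasma triplicates, 60 proteins with
#' two peptides of five transitions each, a six-decade dynamic range,
#' lognormal noise at three levels and the planted MM panel plus a 10-fold
#' female/male PZP effect.
#'
#' @param cancer_counts Named integer vector, patients per cancer type.
#' @param wells_per_plate Wells per plate (default 96).
#' @param pool_replicates Pool-sample injections per plate (default 3).
#' @param n_plates Number of plates; `NULL` (default) uses the minimum that
#'   holds all patients.
#' @param n_proteins,peptides_per_protein,transitions_per_peptide Assay scale.
#' @param dynamic_range_decades Width of the log-uniform protein baseline
#'   distribution, in orders of magnitude (default 6).
#' @param log10_conc_min Lower bound of the baseline distribution in
#'   log10(pmol/uL) (default -4, i.e. baselines span 1e-4 to 1e2 pmol/uL
#'   at the default 6 decades).
#' @param sigma_bio Between-subject biological SD in log2 units.
#' @param sigma_intra Injection-level (intra-assay) SD in natural-log units;
#'   implies a lognormal CV of `sqrt(exp(sigma_intra^2) - 1)`.
#' @param sigma_plate Plate-effect SD in natural-log units, drawn per
#'   plate x peptide and applied to the light (endogenous) channel.
#' @param missing_channel_rate Probability a whole channel of a
#'   sample x peptide is missing.
#' @param missing_transition_rate Probability a single transition row is
#'   missing.
#' @param corrupted_fraction Fraction of sample x peptide observations whose
#'   library dot product (dotp) is planted below the 0.5 filter threshold.
#' @param qc_fail_fraction Fraction of patient samples designed to fail
#'   sample QC (half by scrambled retention times, half by low peptide
#'   yield).
#' @param effect_table data.table(cancer, protein, log2fc) of planted
#'   disease effects; default [mm_effect_table()].
#' @param sex_effect Named numeric vector of female/male concentration fold
#'   changes per protein; default `c(PZP = 10)`.
#' @param sex_specific List of male-only / female-only cancers, see
#'   [default_sex_specific()].
#' @param n_anchor_peptides Number of retention-time anchor peptides
#'   (default 12, mimicking the 12 most intense APOA1 peptides).
#' @param anchor_protein Protein accession carrying the anchors.
#' @param irt_slope,irt_intercept True linear map from reference iRT to
#'   retention time in minutes.
#' @param rt_noise_sd Retention-time noise SD in minutes (default 0.1).
#' @param spike_log2_sd SD (log2) of the spike concentration around the
#'   protein baseline; spikes are "close to endogenous".
#' @param seed Master seed; all generator stages derive their streams from
#'   it deterministically.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(cancer_counts = desk_cohort_counts(),
                          wells_per_plate = 96L,
                          pool_replicates = 3L,
                          n_plates = NULL,
                          n_proteins = 60L,
                          peptides_per_protein = 2L,
                          transitions_per_peptide = 5L,
                          dynamic_range_decades = 6,
                          log10_conc_min = -4,
                          sigma_bio = 0.5,
                          sigma_intra = 0.1,
                          sigma_plate = 0.1,
                          missing_channel_rate = 0.01,
                          missing_transition_rate = 0.02,
                          corrupted_fraction = 0.02,
                          qc_fail_fraction = 0.02,
                          effect_table = mm_effect_table(),
                          sex_effect = c(PZP = 10),
                          sex_specific = default_sex_specific(),
                          n_anchor_peptides = 12L,
                          anchor_protein = "APOA1",
                          irt_slope = 0.5,
                          irt_intercept = 10,
                          rt_noise_sd = 0.1,
                          spike_log2_sd = 0.25,
                          seed = 1L) {
  cfg <- list(
    cancer_counts = cancer_counts, wells_per_plate = as.integer(wells_per_plate),
    pool_replicates = as.integer(pool_replicates),
    n_plates = if (is.null(n_plates)) NULL else as.integer(n_plates),
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    transitions_per_peptide = as.integer(transitions_per_peptide),
    dynamic_range_decades = dynamic_range_decades,
    log10_conc_min = log10_conc_min,
    sigma_bio = sigma_bio, sigma_intra = sigma_intra,
    sigma_plate = sigma_plate,
    missing_channel_rate = missing_channel_rate,
    missing_transition_rate = missing_transition_rate,
    corrupted_fraction = corrupted_fraction,
    qc_fail_fraction = qc_fail_fraction,
    effect_table = as.data.table(effect_table),
    sex_effect = sex_effect,
    sex_specific = sex_specific,
    n_anchor_peptides = as.integer(n_anchor_peptides),
    anchor_protein = anchor_protein,
    irt_slope = irt_slope, irt_intercept = irt_intercept,
    rt_noise_sd = rt_noise_sd, spike_log2_sd = spike_log2_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' Validate a cohort configuration
#' @param config A `cohort_config`.
#' @return The config, invisibly validated (errors on violation).
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  probs <- c(config$missing_channel_rate, config$missing_transition_rate,
             config$corrupted_fraction, config$qc_fail_fraction)
  if (any(probs < 0 | probs > 1))
    sq_stop("config_error", "all rates/fractions must lie in [0, 1]")
  sds <- c(config$sigma_bio, config$sigma_intra, config$sigma_plate,
           config$rt_noise_sd, config$spike_log2_sd)
  if (any(sds < 0)) sq_stop("config_error", "all SDs must be >= 0")
  if (any(config$cancer_counts < 0))
    sq_stop("config_error", "per-cancer counts must be >= 0")
  if (is.null(names(config$cancer_counts)) && length(config$cancer_counts))
    sq_stop("config_error", "cancer_counts must be named")
  if (config$pool_replicates >= config$wells_per_plate)
    sq_stop("config_error", "pool replicates fill the whole plate")
  cap <- config$wells_per_plate - config$pool_replicates
  n_pat <- sum(config$cancer_counts)
  if (!is.null(config$n_plates) && n_pat > config$n_plates * cap)
    sq_stop("capacity_error",
            "%d patients exceed the %d slots of %d plates with %d pool wells each",
            n_pat, config$n_plates * cap, config$n_plates,
            config$pool_replicates)
  scale_pos <- c(config$n_proteins, config$peptides_per_protein,
                 config$transitions_per_peptide)
  if (any(scale_pos < 1)) sq_stop("config_error", "assay scale must be >= 1")
  config
}

#' Number of plates implied by a configuration
#' @noRd
plate_count <- function(config) {
  cap <- config$wells_per_plate - config$pool_replicates
  config$n_plates %||% max(1L, as.integer(ceiling(sum(config$cancer_counts) / cap)))
}
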