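# Shared fixture builders. Everything is generated in code; no files.

# A small fully deterministic (noise-free) cohort configuration.
noiseless_config <- function(counts = c(MM = 20, CRC = 30, BRC = 25),
                             n_proteins = 20L, seed = 42L, ...) {
  cohort_config(cancer_counts = counts, n_proteins = n_proteins,
                sigma_intra = 0, sigma_plate = 0,
                missing_channel_rate = 0, missing_transition_rate = 0,
                corrupted_fraction = 0, qc_fail_fraction = 0,
                seed = seed, ...)
}

# Hand-built two-plate fixture: 2 pools + 2 patients per plate, 3 peptides,
# with plate P02 carrying a planted 2x effect on every peptide.
two_plate_fixture <- function(plate_factor = 2) {
  manifest <- data.table::data.table(
    sample_id = c("PL1_POOL1", "PL1_POOL2", "PL1_PAT1", "PL1_PAT2",
                  "PL2_POOL1", "PL2_POOL2", "PL2_PAT1", "PL2_PAT2"),
    plate = rep(c("P01", "P02"), each = 4L),
    well = rep(c("A01", "A02", "A03", "A04"), 2L),
    sample_type = rep(c("pool", "pool", "patient", "patient"), 2L),
    cancer = rep(c(NA, NA, "MM", "CRC"), 2L),
    sex = rep(c(NA, NA, "male", "female"), 2L)
  )
  base <- matrix(c(1, 2, 4,
                   1, 2, 4,
                   1.5, 2.5, 3.5,
                   0.5, 1.5, 4.5), nrow = 4L, byrow = TRUE)
  vals <- rbind(base, base * plate_factor)
  dimnames(vals) <- list(manifest$sample_id, c("A_PEP1", "A_PEP2", "B_PEP1"))
  cm <- conc_matrix(vals,
                    data.table::data.table(
                      analyte = colnames(vals),
                      protein = c("A", "A", "B")),
                    level = "peptide")
  list(manifest = manifest, cm = cm)
}

# Minimal valid transition-record table for io/quantify unit tests.
make_records <- function(sample_id = "S1", peptide = "P_PEP1",
                         protein = "P", fragments = c("y4", "y5"),
                         light = c(100, 200), heavy = c(50, 100),
                         dotp = 0.9, rt = 20, irt = NA_real_,
                         plate = "P01", well = "A01") {
  n <- length(fragments)
  rows <- list()
  if (length(light))
    rows$l <- data.table::data.table(
      sample_id = sample_id, plate = plate, well = well, protein = protein,
      peptide = peptide, precursor_charge = 2L,
      fragment = fragments[seq_along(light)], product_charge = 1L,
      label = "light", area = light, rt_min = rt, irt_ref = irt, dotp = dotp)
  if (length(heavy))
    rows$h <- data.table::data.table(
      sample_id = sample_id, plate = plate, well = well, protein = protein,
      peptide = peptide, precursor_charge = 2L,
      fragment = fragments[seq_along(heavy)], product_charge = 1L,
      label = "heavy", area = heavy, rt_min = rt, irt_ref = NA_real_,
      dotp = NA_real_)
  data.table::rbindlist(rows)
}

# Memoized desk-scale simulation + quantification shared by slow tests.
.desk_cache <- new.env(parent = emptyenv())
desk_quantified <- function() {
  if (is.null(.desk_cache$res)) {
    cfg <- cohort_config(seed = 20260910L)
    sim <- simulate_cohort(cfg)
    qr <- quantify(sim$report, sim$panel, sim$manifest, min_proteins = 30L)
    .desk_cache$res <- list(cfg = cfg, sim = sim, qr = qr)
  }
  .desk_cache$res
}

# Planted multiple-myeloma panel peptides at desk scale.
mm_panel_peptides <- function() {
  prot <- mm_effect_table()$protein
  as.vector(outer(prot, c("_PEP1", "_PEP2"), paste0))
}
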