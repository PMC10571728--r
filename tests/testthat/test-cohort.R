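test_that("build_manifest lays out patients, pools and plates correctly", {
  # empty cohort: pools only
  m0 <- build_manifest(cohort_config(cancer_counts = c(MM = 0L), seed = 1))
  expect_identical(nrow(m0), 3L)
  expect_true(all(m0$sample_type == "pool"))

  # 10 patients fit one 96-well plate (93 patient slots): 13 rows total
  m10 <- build_manifest(cohort_config(cancer_counts = c(MM = 10L), seed = 1))
  expect_identical(nrow(m10), 13L)
  expect_identical(length(unique(m10$plate)), 1L)

  # every plate carries exactly the configured pool replicates
  cfg <- cohort_config(cancer_counts = c(MM = 100L, CRC = 100L),
                       pool_replicates = 3L, seed = 5)
  m <- build_manifest(cfg)
  expect_true(all(m[sample_type == "pool", .N, by = plate]$N == 3L))
  expect_identical(sum(m$sample_type == "patient"), 200L)
  expect_silent(validate_manifest(m, pool_replicates = 3L))
})

test_that("manifest respects capacity, sex specificity and determinism", {
  expect_error(
    build_manifest(cohort_config(cancer_counts = c(MM = 200L), n_plates = 2L,
                                 wells_per_plate = 96L)),
    class = "capacity_error")

  cfg <- cohort_config(cancer_counts = c(PRC = 30L, BRC = 30L, CRC = 30L),
                       seed = 3)
  m <- build_manifest(cfg)
  expect_true(all(m[cancer == "PRC", sex] == "male"))
  expect_true(all(m[cancer == "BRC", sex] == "female"))
  expect_true(all(m[cancer == "CRC", sex] %in% c("male", "female")))

  expect_identical(build_manifest(cfg), build_manifest(cfg))
  cfg2 <- cohort_config(cancer_counts = c(PRC = 30L, BRC = 30L, CRC = 30L),
                        seed = 4)
  expect_false(identical(build_manifest(cfg), build_manifest(cfg2)))
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(qc_fail_fraction = 1.5), class = "config_error")
  expect_error(cohort_config(sigma_bio = -1), class = "config_error")
  expect_error(cohort_config(cancer_counts = c(MM = -1L)),
               class = "config_error")
  expect_error(cohort_config(pool_replicates = 96L, wells_per_plate = 96L),
               class = "config_error")
})

test_that("true concentrations follow the stated generative model", {
  # zero biology, no effects: every patient sits exactly on the baseline
  cfg <- noiseless_config(sigma_bio = 0, effect_table = mm_effect_table()[0],
                          sex_effect = c(PZP = 1))
  man <- build_manifest(cfg)
  tr <- draw_true_concentrations(cfg, man)
  pat <- man[sample_type == "patient", sample_id]
  for (p in colnames(tr$concentrations))
    expect_equal(unname(tr$concentrations[pat, p]),
                 rep(unname(tr$baseline[p]), length(pat)))

  # 10x female/male fold on a PZP-like protein is exact at sigma_bio = 0
  cfg2 <- noiseless_config(counts = c(CRC = 60), sigma_bio = 0,
                           effect_table = mm_effect_table()[0],
                           sex_effect = c(PZP = 10), seed = 9)
  man2 <- build_manifest(cfg2)
  tr2 <- draw_true_concentrations(cfg2, man2)
  fem <- man2[sample_type == "patient" & sex == "female", sample_id]
  mal <- man2[sample_type == "patient" & sex == "male", sample_id]
  expect_equal(median(tr2$concentrations[fem, "PZP"]) /
                 median(tr2$concentrations[mal, "PZP"]), 10)

  # planted MM effect shifts the MM medians by the configured log2 fold
  cfg3 <- noiseless_config(sigma_bio = 0, seed = 10)
  man3 <- build_manifest(cfg3)
  tr3 <- draw_true_concentrations(cfg3, man3)
  mm <- man3[cancer == "MM", sample_id]
  crc <- man3[cancer == "CRC", sample_id]
  expect_equal(log2(median(tr3$concentrations[mm, "C1QB"]) /
                      median(tr3$concentrations[crc, "C1QB"])), -1)
  expect_equal(log2(median(tr3$concentrations[mm, "TGFBI"]) /
                      median(tr3$concentrations[crc, "TGFBI"])), 0.7,
               tolerance = 1e-12)
})

test_that("baselines span the configured dynamic range", {
  cfg <- cohort_config(cancer_counts = c(MM = 2L), n_proteins = 200L,
                       dynamic_range_decades = 6, seed = 123)
  man <- build_manifest(cfg)
  tr <- draw_true_concentrations(cfg, man)
  expect_gte(log10(max(tr$baseline) / min(tr$baseline)), 5.9)
  # fragment profiles are positive and sum to 1
  expect_true(all(tr$fragment_profiles > 0))
  expect_equal(unname(rowSums(tr$fragment_profiles)),
               rep(1, nrow(tr$fragment_profiles)), tolerance = 1e-12)
})

test_that("designed QC-fail samples appear in the manifest", {
  cfg <- cohort_config(cancer_counts = c(MM = 100L, CRC = 100L),
                       qc_fail_fraction = 0.05, seed = 8)
  man <- build_manifest(cfg)
  tr <- draw_true_concentrations(cfg, man)
  expect_identical(nrow(tr$qc_fail), 10L) # 5% of 200
  expect_true(all(tr$qc_fail$sample_id %in% man$sample_id))
  expect_setequal(unique(tr$qc_fail$mode), c("irt", "low_yield"))
})

test_that("transition report is noiseless-exact, conservative and deterministic", {
  cfg <- noiseless_config()
  sim <- simulate_cohort(cfg)
  rep <- sim$report

  # noiseless identity: summed light/heavy ratio equals C_true / S_p exactly
  agg <- rep[!grepl("ANCH", peptide),
             .(tot = sum(area)), by = .(sample_id, peptide, label)]
  wide <- data.table::dcast(agg, sample_id + peptide ~ label,
                            value.var = "tot")
  prot <- sub("_PEP[0-9]+$", "", wide$peptide)
  expected <- sim$truth$concentrations[cbind(wide$sample_id, prot)] /
    sim$truth$spike_conc[wide$peptide]
  expect_equal(wide$light / wide$heavy, unname(expected), tolerance = 1e-12)

  # conservation: per-peptide transition areas sum to the drawn totals
  kap <- sim$truth$peptides[match(wide$peptide, sim$truth$peptides$peptide),
                            kappa]
  expect_equal(wide$heavy, unname(kap * sim$truth$spike_conc[wide$peptide]),
               tolerance = 1e-9)

  # determinism: identical config + seed gives an identical report
  expect_identical(rep, simulate_cohort(cfg)$report)
})

test_that("planted dotp corruption and missingness hit their configured rates", {
  cfg <- cohort_config(cancer_counts = c(MM = 40L, CRC = 40L),
                       n_proteins = 30L, corrupted_fraction = 0.1,
                       missing_channel_rate = 0, missing_transition_rate = 0.05,
                       qc_fail_fraction = 0, seed = 77)
  sim <- simulate_cohort(cfg)
  lt <- sim$report[label == "light" & !grepl("ANCH", peptide)]
  frac_low <- mean(lt[, any(dotp < 0.5), by = .(sample_id, peptide)]$V1)
  expect_equal(frac_low, 0.1, tolerance = 0.25)
  # transition dropout: light rows vs the full per-channel grid
  full_per_channel <- (40 + 40 + 3) * (30 * 2) * 5
  expect_equal(1 - nrow(lt) / full_per_channel, 0.05, tolerance = 0.3)
})
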