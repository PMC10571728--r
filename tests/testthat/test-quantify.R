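test_that("pair_transitions keeps only transitions present in both channels", {
  # fully paired
  full <- pair_transitions(make_records(fragments = c("y4", "y5"),
                                        light = c(100, 200),
                                        heavy = c(50, 100)))
  expect_true(all(full$paired))

  # heavy-only y6 dropped as non-paired
  rec <- rbind(make_records(fragments = "y4", light = 100, heavy = 100),
               make_records(fragments = "y6", light = numeric(),
                            heavy = 50))
  p <- pair_transitions(rec)
  expect_identical(p[fragment == "y4", paired], TRUE)
  expect_identical(p[fragment == "y6", paired], FALSE)
  expect_identical(p[fragment == "y6", drop_reason], "missing_light")

  # no heavy channel at all: zero pairs, later rejected with no_pairs
  p0 <- pair_transitions(make_records(fragments = "y4", light = 100,
                                      heavy = numeric()))
  expect_identical(sum(p0$paired), 0L)
  q0 <- filter_peptides(peptide_quants(p0))
  expect_identical(q0$status, "rejected")
  expect_match(q0$reasons, "no_pairs")
})

test_that("compute_ratio sums paired areas and matches a brute-force oracle", {
  expect_equal(compute_ratio(c(100, 200), c(50, 100))$r, 2)
  expect_equal(compute_ratio(100, 100)$r, 1)
  expect_error(compute_ratio(100, 0), class = "undefined_ratio_error")
  expect_error(compute_ratio(numeric(), numeric()), class = "no_pairs_error")

  set.seed(1)
  for (i in 1:200) {
    n <- sample(1:8, 1)
    l <- runif(n, 0, 1e6)
    h <- runif(n, 1, 1e6)
    got <- compute_ratio(l, h)
    # independent element-by-element accumulation
    sl <- 0; sh <- 0
    for (j in seq_len(n)) { sl <- sl + l[j]; sh <- sh + h[j] }
    expect_equal(got$r, sl / sh)
  }
})

test_that("compute_rdotp is a cosine on paired areas", {
  expect_equal(compute_rdotp(c(100, 200), c(50, 100)), 1)
  expect_equal(compute_rdotp(c(1, 0), c(0, 1)), 0)
  expect_equal(compute_rdotp(c(3, 4), c(4, 3)), 24 / 25)
  expect_equal(compute_rdotp(c(0, 0), c(1, 2)), 0)
})

test_that("peptide_quants agrees with the standalone operations per group", {
  set.seed(7)
  recs <- data.table::rbindlist(lapply(1:25, function(i) {
    n <- sample(2:5, 1)
    make_records(sample_id = sprintf("S%02d", i %% 5),
                 peptide = sprintf("P%d_PEP1", i %/% 5),
                 protein = sprintf("P%d", i %/% 5),
                 fragments = paste0("y", 3 + seq_len(n)),
                 light = runif(n, 1, 1e4), heavy = runif(n, 1, 1e4))
  }))
  q <- peptide_quants(pair_transitions(recs))
  for (i in seq_len(nrow(q))) {
    sub <- recs[sample_id == q$sample_id[i] & peptide == q$peptide[i]]
    l <- sub[label == "light", area]
    h <- sub[label == "heavy", area]
    expect_equal(q$ratio[i], compute_ratio(l, h)$r)
    expect_equal(q$rdotp[i], compute_rdotp(l, h))
  }
})

test_that("filter_peptides applies strict printed thresholds with reasons", {
  mk <- function(rdotp, dotp, ratio)
    data.table::data.table(sample_id = "S", peptide = "P", protein = "P",
                           plate = "P01", n_paired = 2L, L = 1, H = 1,
                           ratio = ratio, rdotp = rdotp, dotp = dotp)
  expect_identical(filter_peptides(mk(0.71, 0.51, 1))$status, "quantified")
  f1 <- filter_peptides(mk(0.7, 0.51, 1))  # boundary: strict >
  expect_identical(f1$status, "rejected")
  expect_identical(f1$reasons, "low_rdotp")
  f2 <- filter_peptides(mk(0.9, 0.5, 1))
  expect_identical(f2$reasons, "low_dotp")
  f3 <- filter_peptides(mk(0.9, 0.9, 1000))
  expect_identical(f3$reasons, "ratio_out_of_bounds")
  f4 <- filter_peptides(mk(0.9, 0.9, 0.01))
  expect_identical(f4$reasons, "ratio_out_of_bounds")
  f5 <- filter_peptides(mk(0.5, 0.4, 2000))
  expect_identical(f5$reasons, "low_rdotp,low_dotp,ratio_out_of_bounds")
})

test_that("iRT regression recovers exact linear anchors and flags degenerate fits", {
  irts <- seq(10, 90, by = 10)
  rec <- make_records(peptide = paste0("A_ANCH", 1:9),
                      fragments = rep("y4", 9),
                      light = rep(1e5, 9), heavy = numeric(),
                      rt = 0.5 * irts + 10, irt = irts)
  fit <- fit_irt_regression(rec)
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, 10)
  expect_equal(fit$r2, 1)
  expect_identical(fit$n_anchors, 9L)

  # seeded scramble destroys the fit
  set.seed(4)
  rec2 <- data.table::copy(rec)[, rt_min := sample(rt_min)]
  expect_lt(fit_irt_regression(rec2)$r2, 0.5)

  # one anchor: regression undefined
  fit1 <- fit_irt_regression(rec[1])
  expect_true(is.na(fit1$r2))
  expect_error(fit_irt_regression(make_records(), anchor_peptides = character()),
               class = "config_error")
})

test_that("qc_samples applies the strict fewer-than-120-proteins rule", {
  mkq <- function(id, nprot) data.table::data.table(
    sample_id = id, peptide = sprintf("PR%03d_PEP1", seq_len(nprot)),
    protein = sprintf("PR%03d", seq_len(nprot)), status = "quantified")
  quants <- rbind(mkq("S119", 119L), mkq("S120", 120L), mkq("S121", 121L))
  man <- data.table::data.table(
    sample_id = c("S119", "S120", "S121"), plate = "P01",
    well = c("A01", "A02", "A03"), sample_type = "patient",
    cancer = "MM", sex = "male")
  fits <- data.table::data.table(sample_id = man$sample_id, slope = 0.5,
                                 intercept = 10, r2 = 1, n_anchors = 12L)
  qc <- qc_samples(quants, man, fits, min_proteins = 120L)
  expect_identical(qc[sample_id == "S119", pass], FALSE)
  expect_identical(qc[sample_id == "S119", reasons], "few_proteins")
  expect_identical(qc[sample_id == "S120", pass], TRUE)
  expect_identical(qc[sample_id == "S121", pass], TRUE)

  # failed iRT regression excludes even a protein-rich sample
  fits$r2[3] <- 0.5
  qc2 <- qc_samples(quants, man, fits, min_proteins = 120L)
  expect_identical(qc2[sample_id == "S121", pass], FALSE)
  expect_identical(qc2[sample_id == "S121", reasons], "irt_regression")
})

test_that("quant-rate filter keeps exactly-50% peptides and drops below", {
  set.seed(11)
  vals <- matrix(runif(100 * 3, 1, 2), 100, 3,
                 dimnames = list(sprintf("S%03d", 1:100),
                                 c("A_PEP1", "A_PEP2", "B_PEP1")))
  vals[1:50, 1] <- NA   # rate exactly 0.50: kept
  vals[1:51, 2] <- NA   # rate 0.49: dropped
  vals[, 3] <- NA       # all missing: dropped
  vals[!is.na(vals)] <- abs(vals[!is.na(vals)]) + 1
  cm <- conc_matrix(vals, data.table::data.table(
    analyte = colnames(vals), protein = c("A", "A", "B")), "peptide")
  out <- filter_by_quant_rate(cm, 0.5)
  expect_identical(colnames(out$values), "A_PEP1")
  expect_identical(out$provenance$quant_rate$n_dropped, 2L)
})

test_that("to_absolute converts ratios by the spiked concentration", {
  q <- data.table::data.table(
    sample_id = c("S1", "S1"), peptide = c("A_PEP1", "B_PEP1"),
    protein = c("A", "B"), plate = "P01", n_paired = 2L, L = 2, H = 1,
    ratio = c(2, 1), rdotp = 0.99, dotp = 0.9, status = "quantified",
    reasons = NA_character_)
  panel <- data.table::data.table(
    protein = c("A", "B"), peptide = c("A_PEP1", "B_PEP1"),
    standard_id = c("SIS001", "SIS002"),
    spike_conc_pmol_per_ul = c(0.5, 0.25))
  cm <- to_absolute(q, panel)
  expect_equal(cm$values["S1", "A_PEP1"], 1.0)   # r = 2, S_p = 0.5
  expect_equal(cm$values["S1", "B_PEP1"], 0.25)  # r = 1 -> C = S_p
  expect_error(to_absolute(q, panel[1]), class = "config_error")
})

test_that("median normalization equalizes planted plate effects and is idempotent", {
  fx <- two_plate_fixture(plate_factor = 2)
  norm <- median_normalize(fx$cm, fx$manifest)
  pool_ids <- fx$manifest[sample_type == "pool", sample_id]
  for (pep in colnames(norm$values)) {
    med1 <- median(norm$values[pool_ids[1:2], pep])
    med2 <- median(norm$values[pool_ids[3:4], pep])
    expect_equal(med1, med2)
  }
  # second application is a no-op
  norm2 <- median_normalize(norm, fx$manifest)
  expect_equal(norm2$values, norm$values)
  expect_true(all(abs(norm2$norm_factors$factor - 1) < 1e-12))

  # single plate: all factors are 1
  one <- two_plate_fixture()
  keep <- one$manifest$plate == "P01"
  cm1 <- conc_matrix(one$cm$values[keep, ], one$cm$analytes, "peptide")
  n1 <- median_normalize(cm1, one$manifest[plate == "P01"])
  expect_true(all(n1$norm_factors$factor == 1))
  expect_error(median_normalize(cm1, data.table::copy(one$manifest)[
    , sample_type := "patient"]), class = "validation_error")
})

test_that("normalization shrinks between-plate pool variance on synthetic data", {
  cfg <- cohort_config(cancer_counts = c(MM = 0L), n_plates = 6L,
                       n_proteins = 40L, sigma_plate = 0.3,
                       sigma_intra = 0.05, qc_fail_fraction = 0,
                       corrupted_fraction = 0, missing_channel_rate = 0,
                       missing_transition_rate = 0, seed = 31)
  sim <- simulate_cohort(cfg)
  qr <- quantify(sim$report, sim$panel, sim$manifest, min_proteins = 20L)
  plate_of <- sim$manifest[match(rownames(qr$peptide_matrix$values),
                                 sample_id), plate]
  between_plate_var <- function(m) {
    apply(m, 2L, function(x) {
      med <- tapply(log(x), plate_of, median, na.rm = TRUE)
      var(med)
    })
  }
  v_pre <- between_plate_var(qr$peptide_matrix_raw$values)
  v_post <- between_plate_var(qr$peptide_matrix$values)
  expect_gte(mean(v_post < v_pre, na.rm = TRUE), 0.95)
})

test_that("protein roll-up takes the median across peptides", {
  vals <- matrix(c(1, 2, 9, 1, 3, NA), 2L, 3L, byrow = TRUE,
                 dimnames = list(c("S1", "S2"),
                                 c("A_PEP1", "A_PEP2", "A_PEP3")))
  cm <- conc_matrix(vals, data.table::data.table(
    analyte = colnames(vals), protein = "A"), "peptide")
  pm <- rollup_protein(cm)
  expect_equal(pm$values["S1", "A"], 2)   # odd count
  expect_equal(pm$values["S2", "A"], 2)   # even count: mean of middle two
  # single peptide: identity
  cm1 <- conc_matrix(vals[, 1, drop = FALSE], data.table::data.table(
    analyte = "A_PEP1", protein = "A"), "peptide")
  expect_equal(rollup_protein(cm1)$values[, "A"], vals[, 1])
})

test_that("quantify is insensitive to input row order and conserves counts", {
  cfg <- noiseless_config(counts = c(MM = 10L, CRC = 10L), n_proteins = 10L,
                          seed = 55)
  sim <- simulate_cohort(cfg)
  qr1 <- quantify(sim$report, sim$panel, sim$manifest, min_proteins = 5L)
  set.seed(1)
  shuffled <- sim$report[sample(.N)]
  qr2 <- quantify(shuffled, sim$panel, sim$manifest, min_proteins = 5L)
  expect_equal(qr1$peptide_matrix$values, qr2$peptide_matrix$values)

  prov <- qr1$provenance
  expect_identical(prov$transitions$n_in,
                   prov$transitions$n_paired + prov$transitions$n_dropped)
  expect_identical(prov$peptides$n_in,
                   prov$peptides$n_quantified + prov$peptides$n_rejected)
  expect_identical(prov$samples$n_in,
                   prov$samples$n_retained + prov$samples$n_excluded)
})
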