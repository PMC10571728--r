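#' Default pipeline configuration
#'
#' One flat key/value set covering every stage threshold, mirrored into
#' each output's provenance so every reported number is traceable. Paths
#' default to `out_dir`-relative names written by the simulate stage.
#'
#' @return Named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    out_dir = "spikequant_out",
    report_path = NA_character_,   # default: <out_dir>/transition_report.csv
    panel_path = NA_character_,
    manifest_path = NA_character_,
    seed = 1L,
    # simulate
    simulate = TRUE,
    sim_scale = "desk",            # "desk" or "full"
    sim_n_proteins = 60L,
    sim_peptides_per_protein = 2L,
    sim_transitions_per_peptide = 5L,
    sim_sigma_bio = 0.5,
    sim_sigma_intra = 0.1,
    sim_sigma_plate = 0.1,
    sim_qc_fail_fraction = 0.02,
    sim_corrupted_fraction = 0.02,
    # quantify
    rdotp_min = 0.7, dotp_min = 0.5, ratio_min = 0.01, ratio_max = 1000,
    min_proteins = 30L, min_r2 = 0.99, min_anchors = 6L,
    min_quant_rate = 0.5,
    # qc
    niqr_method = "fold", cv_on = "raw",
    # diffexp
    alpha = 0.0005, t_test = "welch", bonferroni_family = "per_comparison",
    # classify
    positive = "MM", split_fraction = 0.7, cv_folds = 5L, num_trees = 500L,
    min_node = 5L, prob_threshold = 0.5, impute_k = 10L,
    impute_mode = "within_split"
  )
}

#' Read a flat key/value pipeline configuration file
#'
#' Minimal YAML-style syntax: one `key: value` per line, `#` comments and
#' blank lines ignored. Values are coerced to the type of the default for
#' that key; unknown keys are an error. Missing keys keep their defaults.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @return Named list (validated).
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (is.null(path)) return(validate_pipeline_config(cfg))
  if (!file.exists(path)) sq_stop("io_error", "config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      sq_stop("config_error", "cannot parse config line: '%s'", ln)
    key <- m[2L]
    val <- trimws(m[3L])
    if (!key %in% names(cfg))
      sq_stop("config_error", "unknown config key: '%s'", key)
    proto <- cfg[[key]]
    cfg[[key]] <- if (is.logical(proto)) {
      tolower(val) %in% c("true", "yes", "1")
    } else if (is.integer(proto)) {
      as.integer(val)
    } else if (is.numeric(proto)) {
      as.numeric(val)
    } else val
  }
  validate_pipeline_config(cfg)
}

#' @noRd
validate_pipeline_config <- function(cfg) {
  stopifnot(cfg$sim_scale %in% c("desk", "full"),
            cfg$niqr_method %in% c("fold", "relative"),
            cfg$cv_on %in% c("raw", "normalized"),
            cfg$t_test %in% c("welch", "pooled"),
            cfg$bonferroni_family %in% c("per_comparison", "global"),
            cfg$impute_mode %in% c("within_split", "paper_faithful"),
            cfg$split_fraction > 0, cfg$split_fraction < 1,
            cfg$alpha > 0, cfg$alpha < 1)
  cfg
}

#' @noRd
cohort_config_from_pipeline <- function(cfg) {
  counts <- if (cfg$sim_scale == "full") full_cohort_counts() else
    desk_cohort_counts()
  cohort_config(
    cancer_counts = counts,
    n_proteins = cfg$sim_n_proteins,
    peptides_per_protein = cfg$sim_peptides_per_protein,
    transitions_per_peptide = cfg$sim_transitions_per_peptide,
    sigma_bio = cfg$sim_sigma_bio, sigma_intra = cfg$sim_sigma_intra,
    sigma_plate = cfg$sim_sigma_plate,
    qc_fail_fraction = cfg$sim_qc_fail_fraction,
    corrupted_fraction = cfg$sim_corrupted_fraction,
    seed = cfg$seed
  )
}

#' @noRd
stage_provenance <- function(out_dir, stage, cfg, extra, t0) {
  prov <- list(stage = stage, config = cfg,
               wall_time_s = round(as.numeric(Sys.time()) - t0, 3))
  prov <- c(prov, extra)
  write_json_file(prov, file.path(out_dir, sprintf("%s_provenance.json", stage)))
}

#' Run the full pipeline
#'
#' Stages run in order simulate -> quantify -> qc -> diffexp -> classify;
#' each writes its output tables plus a JSON provenance block (thresholds,
#' per-filter counts, seeds, wall time) into `out_dir`. Any stage failure
#' aborts with a stage-named error. With fixed config and seed the numeric
#' outputs are reproducible.
#'
#' @param config Named list from [read_pipeline_config()] /
#'   [default_pipeline_config()], or a path to a config file.
#' @return Invisible list of artifact paths by stage.
#' @export
run_all <- function(config = default_pipeline_config()) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else
    validate_pipeline_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      sq_stop("stage_error", "stage '%s' failed: %s", stage,
              conditionMessage(e))
    })
  }

  # -- simulate ------------------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    t0 <- as.numeric(Sys.time())
    artifacts$simulate <- run_stage("simulate", function() {
      sim <- simulate_cohort(cohort_config_from_pipeline(cfg), out_dir)
      sim$files
    })
  }
  report_path <- if (!is.na(cfg$report_path)) cfg$report_path else
    file.path(out_dir, "transition_report.csv")
  panel_path <- if (!is.na(cfg$panel_path)) cfg$panel_path else
    file.path(out_dir, "panel.csv")
  manifest_path <- if (!is.na(cfg$manifest_path)) cfg$manifest_path else
    file.path(out_dir, "manifest.csv")

  # -- quantify ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  qr <- run_stage("quantify", function() {
    records <- read_transition_report(report_path)
    panel <- read_panel(panel_path)
    manifest <- read_manifest(manifest_path)
    quantify(records, panel, manifest,
             rdotp_min = cfg$rdotp_min, dotp_min = cfg$dotp_min,
             ratio_min = cfg$ratio_min, ratio_max = cfg$ratio_max,
             min_proteins = cfg$min_proteins, min_r2 = cfg$min_r2,
             min_anchors = cfg$min_anchors,
             min_quant_rate = cfg$min_quant_rate)
  })
  manifest <- read_manifest(manifest_path)
  artifacts$quantify <- c(
    peptide = write_matrix(qr$peptide_matrix,
                           file.path(out_dir, "peptide_concentrations.csv")),
    peptide_raw = write_matrix(
      qr$peptide_matrix_raw,
      file.path(out_dir, "peptide_concentrations_raw.csv")),
    protein = write_matrix(qr$protein_matrix,
                           file.path(out_dir, "protein_concentrations.csv")),
    annotations = {
      p <- file.path(out_dir, "peptide_annotations.csv")
      fwrite(qr$peptide_matrix$analytes, p)
      p
    })
  stage_provenance(out_dir, "quantify", cfg, qr$provenance, t0)

  # -- qc ------------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  qc <- run_stage("qc", function()
    qc_report(qr, manifest, niqr_method = cfg$niqr_method, cv_on = cfg$cv_on))
  qc_path <- file.path(out_dir, "qc_report.json")
  write_json_file(list(
    per_plate_cv = qc$per_plate_cv, per_plate_median_cv = qc$per_plate_median_cv,
    overall_median_cv = qc$overall_median_cv, cv_on = qc$cv_on,
    pool_pearson_median = qc$pool_pearson_median,
    median_niqr = qc$median_niqr, niqr_method = qc$niqr_method,
    excluded_samples = qc$excluded_samples), qc_path)
  artifacts$qc <- qc_path
  stage_provenance(out_dir, "qc", cfg, list(), t0)

  # -- diffexp -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  de <- run_stage("diffexp", function()
    one_vs_rest(qr$peptide_matrix, manifest, alpha = cfg$alpha,
                var_equal = cfg$t_test == "pooled",
                family = cfg$bonferroni_family))
  artifacts$diffexp <- c(
    de_table = write_de_table(de, file.path(out_dir, "de_table.csv")),
    edges = {
      p <- file.path(out_dir, "edges.csv")
      fwrite(network_edge_table(de), p)
      p
    })
  stage_provenance(out_dir, "diffexp", cfg,
                   list(n_tests = nrow(de),
                        n_significant = sum(de$significant)), t0)

  # -- classify ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  rep <- run_stage("classify", function() {
    m <- qr$peptide_matrix$values
    pat <- as.data.table(manifest)[sample_type == "patient" &
                                     sample_id %in% rownames(m)]
    labels <- stats::setNames(pat$cancer, pat$sample_id)
    train_and_evaluate(log2(m[pat$sample_id, , drop = FALSE]), labels,
                       positive = cfg$positive,
                       split_fraction = cfg$split_fraction,
                       cv_folds = cfg$cv_folds, num_trees = cfg$num_trees,
                       min_node = cfg$min_node,
                       threshold = cfg$prob_threshold,
                       impute_k = cfg$impute_k,
                       impute_mode = cfg$impute_mode, seed = cfg$seed)
  })
  cr_path <- file.path(out_dir, "classifier_report.json")
  write_classifier_report(rep, cr_path)
  roc_path <- file.path(out_dir, "roc.csv")
  fwrite(rep$roc, roc_path)
  artifacts$classify <- c(report = cr_path, roc = roc_path)
  stage_provenance(out_dir, "classify", cfg,
                   list(auc = rep$auc, chosen_mtry = rep$chosen_mtry), t0)

  invisible(artifacts)
}
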