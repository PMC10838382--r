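#' Default analysis configuration
#'
#' Thresholds mirror the conventions of checkerboard/transport resistance
#' studies: Bliss-index flag at |BI| >= 0.15 with call counts at 12% of the
#' matrix (3 of 25 for a 5 x 5 grid), efflux-ratio cutoff 2, DEG filter at
#' fold >= 2 and FDR < 0.05, 0.7 cm^2 membrane area, log-CPM pseudocount 0.5
#' and 3 robust z-units for sample-outlier flags.
#'
#' @export
default_config <- function() {
  list(
    bi_threshold = 0.15,
    flag_fraction = 0.12,
    er_cutoff = 2,
    deg_fdr = 0.05,
    deg_fold = 2,
    transwell_area = 0.7,
    pseudocount = 0.5,
    outlier_flag_z = 3
  )
}

#' Simulate a complete resistance-reversal study
#'
#' Generates, from one seed, the full set of inputs the analysis chain
#' consumes: single-agent dose-response plates for a parental line
#' (efflux factor 0) and a resistant line (efflux factor 21.3, i.e. ~22-fold
#' apparent IC50 shift), duplicate 5 x 5 checkerboards for both lines,
#' a bidirectional transwell dataset (substrate alone and under two
#' inhibitors), and a 12-sample count matrix (two parental/resistant pairs in
#' triplicate, transporter-like gene up ~3000-fold in the resistant groups).
#'
#' @param seed Integer seed driving every generator.
#' @param resistant_e Efflux factor of the resistant line.
#' @return Named list of datasets (each carrying its truth attribute).
#' @export
simulate_study <- function(seed = 1, resistant_e = 21.3) {
  doc_conc <- 10^seq(-10.5, -6.5, length.out = 10) # 0.03 nM .. 316 nM
  doc_grid <- c(1, 3.16, 10, 31.6, 100) * 1e-9
  rit_grid <- c(0.3, 0.949, 3, 9.49, 30) * 1e-6

  parental <- viability_truth(efflux_e = 0)
  resistant <- viability_truth(efflux_e = resistant_e)
  # checkerboards at the lower plate noise of the combination campaign
  parental_cb <- viability_truth(efflux_e = 0, noise_cv = 0.05)
  resistant_cb <- viability_truth(efflux_e = resistant_e, noise_cv = 0.05)

  # per-line DE specifications: each resistant line carries the
  # transporter-like gene (~3300- and ~2800-fold) plus its own secondary set
  de <- withr::with_seed(seed + 40L, bind_rows(
    tibble(
      gene = 1L, group = "lineA_resistant", log2fc = log2(3287),
      baseline_mean = 50
    ),
    tibble(
      gene = 2:101, group = "lineA_resistant",
      log2fc = sample(c(-1, 1), 100, TRUE) * stats::runif(100, 1, 6),
      baseline_mean = NA_real_
    ),
    tibble(
      gene = 1L, group = "lineB_resistant", log2fc = log2(2772),
      baseline_mean = 50
    ),
    tibble(
      gene = 102:201, group = "lineB_resistant",
      log2fc = sample(c(-1, 1), 100, TRUE) * stats::runif(100, 1, 6),
      baseline_mean = NA_real_
    )
  ))

  list(
    dr_parental = gen_viability_plate(
      parental,
      conc_a = doc_conc, seed = seed + 11L,
      assay_id = "dr-parental", cell_line = "parental", drug_a = "docetaxel"
    ),
    dr_resistant = gen_viability_plate(
      resistant,
      conc_a = doc_conc, seed = seed + 12L,
      assay_id = "dr-resistant", cell_line = "resistant", drug_a = "docetaxel"
    ),
    checkerboard_parental = gen_viability_plate(
      parental_cb,
      conc_a = doc_grid, conc_b = rit_grid, seed = seed + 21L,
      assay_id = "cb-parental", cell_line = "parental",
      drug_a = "docetaxel", drug_b = "ritonavir"
    ),
    checkerboard_resistant = gen_viability_plate(
      resistant_cb,
      conc_a = doc_grid, conc_b = rit_grid, seed = seed + 22L,
      assay_id = "cb-resistant", cell_line = "resistant",
      drug_a = "docetaxel", drug_b = "ritonavir"
    ),
    transwell = gen_transwell(seed = seed + 31L),
    counts = gen_counts(
      counts_truth(de = de),
      groups = rep(c("lineA_parental", "lineA_resistant",
                     "lineB_parental", "lineB_resistant"), each = 3),
      seed = seed + 41L
    )
  )
}

#' Run the full analysis chain on a simulated study
#'
#' Fits the single-agent curves and the relative-resistance ratio, scores
#' both checkerboards with Bliss independence, analyzes the transwell assay,
#' screens the count matrix for sample outliers and differential expression,
#' and writes all result tables (plus a machine-readable `summary.json`
#' carrying the seed and a hash of the configuration) to `out_dir`. Rerunning
#' with the same seed and configuration reproduces every output byte for
#' byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed passed to [simulate_study()].
#' @param config Configuration list, see [default_config()].
#' @return The summary list, invisibly.
#' @export
run_study_pipeline <- function(out_dir, seed = 1, config = default_config()) {
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data <- simulate_study(seed = seed)

  # --- dose response ------------------------------------------------------
  fit_par <- fit_dose_response(data$dr_parental)
  fit_res <- fit_dose_response(data$dr_resistant)
  fits <- bind_rows(
    mutate(glance(fit_par), cell_line = "parental", .before = 1),
    mutate(glance(fit_res), cell_line = "resistant", .before = 1)
  )
  readr::write_csv(fits, file.path(out_dir, "fits.csv"))
  rr <- ic50_ratio(fit_res, fit_par)

  # --- Bliss synergy ------------------------------------------------------
  bliss <- lapply(
    list(
      parental = data$checkerboard_parental,
      resistant = data$checkerboard_resistant
    ),
    analyze_bliss,
    bi_threshold = config$bi_threshold, flag_fraction = config$flag_fraction
  )
  for (line in names(bliss)) {
    write_tc_matrix(
      as_tc_matrix_from_result(bliss[[line]]),
      file.path(out_dir, paste0("bliss_modeled_tc_", line, ".csv"))
    )
    readr::write_csv(
      tidy(bliss[[line]]),
      file.path(out_dir, paste0("bliss_index_", line, ".csv"))
    )
    jsonlite::write_json(
      c(
        as.list(glance(bliss[[line]])),
        list(thresholds = bliss[[line]]$thresholds)
      ),
      file.path(out_dir, paste0("bliss_call_", line, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }

  # --- transwell ----------------------------------------------------------
  tw <- analyze_transwell(
    data$transwell,
    er_cutoff = config$er_cutoff, default_area = config$transwell_area
  )
  readr::write_csv(tw, file.path(out_dir, "transwell_results.csv"))

  # --- expression screen --------------------------------------------------
  lcpm <- log_cpm(data$counts, pseudocount = config$pseudocount)
  qc <- outlier_stats(lcpm, flag_z = config$outlier_flag_z)
  jsonlite::write_json(
    qc, file.path(out_dir, "qc_report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  )
  sheet <- sample_sheet(data$counts)
  pair_a <- sheet$sample[sheet$group %in% c("lineA_parental", "lineA_resistant")]
  deg <- deg_screen(
    data$counts[, c("gene", pair_a)],
    groups = sub("_[0-9]+$", "", pair_a),
    ref = "lineA_parental",
    pseudocount = config$pseudocount,
    fdr = config$deg_fdr, fold = config$deg_fold
  )
  readr::write_tsv(deg, file.path(out_dir, "deg_table.tsv"))

  # --- summary ------------------------------------------------------------
  tw_alone_10_60 <- tw |>
    filter(.data$inhibitor == "none", .data$conc_uM == 10, .data$time_min == 60)
  tw_inh_10_60 <- tw |>
    filter(.data$inhibitor != "none", .data$conc_uM == 10, .data$time_min == 60)
  summary <- list(
    seed = seed,
    config = config,
    config_hash = rlang::hash(config),
    ic50_parental_nM = fit_par$ic50_rel * 1e9,
    ic50_resistant_nM = fit_res$ic50_rel * 1e9,
    relative_resistance = rr$fold,
    bliss_call_parental = bliss$parental$call,
    bliss_call_resistant = bliss$resistant$call,
    er_substrate_alone = tw_alone_10_60$er,
    substrate_call = tw_alone_10_60$substrate_call,
    er_with_inhibitor = setNames(tw_inh_10_60$er, tw_inh_10_60$inhibitor),
    inhibition_calls = setNames(tw_inh_10_60$inhibition_call, tw_inh_10_60$inhibitor),
    n_outlier_flags = sum(qc$flagged),
    n_degs = sum(deg$is_deg),
    top_deg_gene = deg$gene[1],
    top_deg_fold = deg$fold_change[1]
  )
  jsonlite::write_json(
    summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(summary)
}

# rebuild a tc_matrix view (including margins) from a bliss_result for export
as_tc_matrix_from_result <- function(res) {
  tc <- res$tc
  structure(
    list(
      conc_a = res$conc_a, conc_b = res$conc_b, tc = tc,
      replicates = tibble(), meta = res$meta
    ),
    class = "tc_matrix"
  )
}
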