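#' Ground-truth parameter sets for the simulators
#'
#' Each generator takes a truth object and attaches it (plus the seed) to its
#' output, so parameter-recovery tests can always compare against the exact
#' generating values. Defaults emulate the regimes typical of taxane
#' resistance-reversal studies: a parental line with ~1 nM docetaxel-like
#' IC50 and a steep Hill slope; an efflux-inhibitor partner that is nearly
#' inactive alone (IC50 ~22 uM); resistance expressed as an efflux factor `E`
#' that divides the intracellular drug concentration by `1 + E` when the
#' transporter is unopposed; and one-site inhibitor binding with Ki ~5 uM so
#' saturating inhibitor restores parental potency.
#'
#' @param top,bottom,ic50,hill 4PL parameters of the cytotoxic drug
#'   (concentrations molar).
#' @param inh_top,inh_bottom,inh_ic50,inh_hill 4PL parameters of the
#'   inhibitor's own (weak) cytotoxicity.
#' @param efflux_e Efflux factor `E >= 0`; 0 gives Bliss-null behavior, large
#'   values give resistance reversed by the inhibitor.
#' @param ki Inhibitor binding constant, molar.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   signal noise.
#' @param control_mean Mean raw signal of untreated control wells.
#' @return A list of class `viability_truth`.
#' @export
viability_truth <- function(top = 1, bottom = 0, ic50 = 1e-9, hill = 2,
                            inh_top = 1, inh_bottom = 0, inh_ic50 = 2.2e-5,
                            inh_hill = 1, efflux_e = 0, ki = 5e-6,
                            noise_cv = 0.1, control_mean = 1000) {
  check_number(ic50, "ic50", positive = TRUE)
  check_number(inh_ic50, "inh_ic50", positive = TRUE)
  check_number(efflux_e, "efflux_e", non_negative = TRUE)
  check_number(ki, "ki", positive = TRUE)
  check_number(noise_cv, "noise_cv", non_negative = TRUE)
  check_number(control_mean, "control_mean", positive = TRUE)
  structure(
    list(
      top = top, bottom = bottom, ic50 = ic50, hill = hill,
      inh_top = inh_top, inh_bottom = inh_bottom, inh_ic50 = inh_ic50,
      inh_hill = inh_hill, efflux_e = efflux_e, ki = ki,
      noise_cv = noise_cv, control_mean = control_mean
    ),
    class = c("viability_truth", "effluxr_truth")
  )
}

#' Effective cytotoxic concentration under efflux and inhibition
#'
#' `C_eff = C / (1 + E * (1 - c_inh / (c_inh + Ki)))`: with no inhibitor the
#' efflux pump dilutes the intracellular drug by `1 + E` (so the apparent
#' IC50 shifts `(1 + E)`-fold); a saturating inhibitor (`c_inh >> Ki`,
#' one-site occupancy) restores `C_eff = C`.
#'
#' @param conc_drug Drug concentration(s), molar, non-negative.
#' @param conc_inh Inhibitor concentration(s), molar, non-negative.
#' @param efflux_e Efflux factor `E >= 0`.
#' @param ki Inhibitor binding constant, molar.
#' @export
effective_conc <- function(conc_drug, conc_inh, efflux_e, ki) {
  check_number(conc_drug, "conc_drug", non_negative = TRUE)
  check_number(conc_inh, "conc_inh", non_negative = TRUE)
  check_number(efflux_e, "efflux_e", non_negative = TRUE)
  check_number(ki, "ki", positive = TRUE)
  unbound <- 1 - conc_inh / (conc_inh + ki)
  conc_drug / (1 + efflux_e * unbound)
}

#' Simulate a viability/checkerboard plate
#'
#' Raw well signal is `control_mean * f(C_eff) * g(c_inh) * noise`, with `f`
#' the drug's 4PL survival curve evaluated at the efflux-adjusted
#' concentration ([effective_conc()]), `g` the inhibitor's own 4PL survival
#' factor and log-normal multiplicative noise. With `efflux_e = 0` the
#' combination effect is exactly multiplicative (a Bliss-null plate); with
#' `efflux_e >> 1` the inhibitor restores drug potency, producing genuine
#' synergy. Single-agent margins (concentration 0 of the partner) and
#' untreated control wells are included.
#'
#' @param truth A [viability_truth()].
#' @param conc_a Nonzero drug concentrations, molar.
#' @param conc_b Nonzero inhibitor concentrations, molar; use `numeric(0)`
#'   for a single-agent plate.
#' @param replicates Wells per condition (default 2, the usual duplicate
#'   checkerboard design).
#' @param n_controls Untreated control wells (default 6).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param assay_id,cell_line,drug_a,drug_b Metadata carried into the table.
#' @return Long plate tibble (`conc_a`, `conc_b` molar, `replicate`,
#'   `signal`, `is_control`, metadata columns) with the truth (plus seed)
#'   attached as attribute `"truth"` (see [synthetic_truth()]).
#' @export
gen_viability_plate <- function(truth = viability_truth(), conc_a,
                                conc_b = numeric(0), replicates = 2,
                                n_controls = 6, seed = NULL,
                                assay_id = "assay-1", cell_line = "cell-1",
                                drug_a = "drugA", drug_b = "drugB") {
  stopifnot(inherits(truth, "viability_truth"))
  check_number(conc_a, "conc_a", positive = TRUE)
  if (length(conc_b)) check_number(conc_b, "conc_b", positive = TRUE)

  grid <- tidyr::expand_grid(
    conc_a = c(0, sort(conc_a)),
    conc_b = c(0, sort(conc_b)),
    replicate = seq_len(replicates)
  ) |>
    filter(!(.data$conc_a == 0 & .data$conc_b == 0))
  controls <- tibble(
    conc_a = 0, conc_b = 0, replicate = seq_len(n_controls)
  )
  wells <- bind_rows(controls, grid)
  wells$is_control <- as.integer(wells$conc_a == 0 & wells$conc_b == 0)

  c_eff <- effective_conc(wells$conc_a, wells$conc_b, truth$efflux_e, truth$ki)
  f <- four_pl0(c_eff, truth$top, truth$bottom, truth$ic50, truth$hill)
  g <- four_pl0(
    wells$conc_b, truth$inh_top, truth$inh_bottom, truth$inh_ic50, truth$inh_hill
  )
  mean_signal <- truth$control_mean * f * g

  wells$signal <- with_seed_if(seed, {
    mean_signal * cv_noise(nrow(wells), truth$noise_cv)
  })
  out <- wells |>
    mutate(
      assay_id = assay_id, cell_line = cell_line,
      drug_a = drug_a, drug_b = drug_b, .before = 1
    )
  attr(out, "truth") <- c(unclass(truth), list(
    seed = seed, replicates = replicates, n_controls = n_controls
  ))
  out
}

#' Ground truth for the transwell simulator
#'
#' Directional permeability follows a symmetric efflux model:
#' `Papp(A-B) = p_passive / (1 + M * u)` and
#' `Papp(B-A) = p_passive * (1 + M * u)`, with `u = 1 - c_inh/(c_inh + Ki)`
#' the unoccupied-transporter fraction, so the noiseless efflux ratio is
#' `(1 + M u)^2`: `M = 0` (or saturating inhibitor) gives ER = 1, and the
#' default `M = sqrt(31.8) - 1` reproduces the ER ~32 regime typical of a
#' strong P-gp substrate at 10 uM.
#'
#' @param p_passive Passive permeability, cm/s.
#' @param efflux_m Efflux multiplier `M >= 0`.
#' @param ki Default inhibitor binding constant, molar (per-condition
#'   overrides via a `ki_uM` column in the conditions table).
#' @param cell_fraction Fraction of the applied amount retained in the
#'   cellular compartment.
#' @param area Membrane area, cm^2.
#' @param vol_apical,vol_basolateral Chamber volumes, cm^3.
#' @param noise_cv CV of the multiplicative measurement noise on each
#'   measured quantity.
#' @export
transwell_truth <- function(p_passive = 5.3e-6, efflux_m = sqrt(31.8) - 1,
                            ki = 1e-6, cell_fraction = 0.03, area = 0.7,
                            vol_apical = 0.4, vol_basolateral = 0.8,
                            noise_cv = 0.05) {
  check_number(p_passive, "p_passive", positive = TRUE)
  check_number(efflux_m, "efflux_m", non_negative = TRUE)
  check_number(ki, "ki", positive = TRUE)
  check_number(cell_fraction, "cell_fraction", non_negative = TRUE)
  check_number(noise_cv, "noise_cv", non_negative = TRUE)
  structure(
    list(
      p_passive = p_passive, efflux_m = efflux_m, ki = ki,
      cell_fraction = cell_fraction, area = area,
      vol_apical = vol_apical, vol_basolateral = vol_basolateral,
      noise_cv = noise_cv
    ),
    class = c("transwell_truth", "effluxr_truth")
  )
}

#' Default bidirectional transwell design
#'
#' Substrate at 10 and 5 uM, alone and with a strong reference inhibitor
#' (10 uM, tight binding) or a weaker clinical inhibitor (50 uM), both
#' directions, 60- and 120-minute sampling.
#'
#' @export
transwell_conditions <- function() {
  tidyr::expand_grid(
    compound = "substrate",
    arm = c("none", "reference_inhibitor", "clinical_inhibitor"),
    conc_uM = c(10, 5),
    time_min = c(60, 120)
  ) |>
    mutate(
      inhibitor = .data$arm,
      inh_conc_uM = c(none = 0, reference_inhibitor = 10, clinical_inhibitor = 50)[.data$arm],
      ki_uM = c(none = NA, reference_inhibitor = 0.1, clinical_inhibitor = 1)[.data$arm]
    ) |>
    select(-"arm")
}

#' Simulate a bidirectional transwell assay
#'
#' For each condition and direction, the true directional Papp follows the
#' model in [transwell_truth()]; the translocated amount is
#' `dq = Papp * A * C0 * dt`, the donor-side remainder is
#' `q0 - dq - q_cells`, and the cellular compartment holds a fixed fraction
#' of the applied amount, so the noiseless output conserves mass exactly
#' (recovery 100%). Multiplicative measurement noise is applied independently
#' to each measured quantity per replicate.
#'
#' @param truth A [transwell_truth()].
#' @param conditions Tibble like [transwell_conditions()]: columns `compound`,
#'   `inhibitor`, `conc_uM`, `time_min`, `inh_conc_uM`, optional `ki_uM`.
#' @param replicates Replicate wells per condition/direction (default 3).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Tibble in the layout [analyze_transwell()] expects, with truth
#'   attached as attribute `"truth"`.
#' @export
gen_transwell <- function(truth = transwell_truth(),
                          conditions = transwell_conditions(),
                          replicates = 3, seed = NULL) {
  stopifnot(inherits(truth, "transwell_truth"))
  check_columns(
    conditions, c("compound", "inhibitor", "conc_uM", "time_min", "inh_conc_uM"),
    "conditions"
  )
  if (!"ki_uM" %in% names(conditions)) conditions$ki_uM <- NA_real_

  rows <- conditions |>
    tidyr::expand_grid(
      direction = c("A_B", "B_A"), replicate = seq_len(replicates)
    )
  ki <- ifelse(is.na(rows$ki_uM), truth$ki, rows$ki_uM * 1e-6)
  unbound <- 1 - (rows$inh_conc_uM * 1e-6) / (rows$inh_conc_uM * 1e-6 + ki)
  papp_true <- ifelse(
    rows$direction == "A_B",
    truth$p_passive / (1 + truth$efflux_m * unbound),
    truth$p_passive * (1 + truth$efflux_m * unbound)
  )
  c0 <- rows$conc_uM * 1000 # pmol/cm^3
  v_donor <- ifelse(rows$direction == "A_B", truth$vol_apical, truth$vol_basolateral)
  q0 <- c0 * v_donor
  dt <- rows$time_min * 60
  dq_true <- papp_true * truth$area * c0 * dt
  if (any(dq_true + truth$cell_fraction * q0 >= q0)) {
    stop_domain(paste(
      "Design leaves the linear transport regime:",
      "translocated amount would exceed the donor quantity."
    ))
  }
  qc_true <- truth$cell_fraction * q0
  qdonor_true <- q0 - dq_true - qc_true

  out <- with_seed_if(seed, {
    n <- nrow(rows)
    dq <- dq_true * cv_noise(n, truth$noise_cv)
    qc <- qc_true * cv_noise(n, truth$noise_cv)
    qd <- qdonor_true * cv_noise(n, truth$noise_cv)
    rows |>
      mutate(
        area_cm2 = truth$area,
        dq_pmol = dq,
        q_apical = ifelse(.data$direction == "A_B", qd, dq),
        q_basolateral = ifelse(.data$direction == "A_B", dq, qd),
        q_cells = qc,
        q0 = q0,
        qc_pass = TRUE
      )
  })
  attr(out, "truth") <- c(unclass(truth), list(seed = seed, replicates = replicates))
  out
}

#' Ground truth for the count-matrix simulator
#'
#' Negative-binomial counts with gene means drawn from a log-normal baseline
#' shared by all samples; differential expression is injected by multiplying
#' the baseline mean of selected genes in selected groups by `2^log2fc`. The
#' default DE specification emulates an acquired-efflux-resistance
#' transcriptome at desk scale: one transporter-like gene at ~3000-fold
#' up-regulation in the `"resistant"` group (from a pinned low parental
#' baseline, since parental lines express no detectable transporter) plus ~5%
#' of genes changed 2-64-fold in either direction, the DEG burden and fold
#' range reported for such resistant sublines.
#'
#' @param n_genes Number of genes.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion);
#'   default 0.01, i.e. a biological CV of 10%, the conventional scale for
#'   triplicate cultures of a clonal cell line.
#' @param lib_size Target library size per sample.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline of gene means.
#' @param de Tibble with columns `gene` (index or id), `group`, `log2fc` and
#'   optionally `baseline_mean` (overrides the drawn baseline for that gene;
#'   the default spec pins the transporter-like gene to a low-but-
#'   quantifiable parental baseline of ~25 CPM, consistent with a measured
#'   ~3000-fold induction); `NULL` for the
#'   default specification, `tibble()` for a null dataset.
#' @export
counts_truth <- function(n_genes = 2000, dispersion = 0.01, lib_size = 2e6,
                         baseline_meanlog = log(100), baseline_sdlog = 1.5,
                         de = NULL) {
  check_number(n_genes, "n_genes", positive = TRUE)
  check_number(dispersion, "dispersion", positive = TRUE)
  structure(
    list(
      n_genes = n_genes, dispersion = dispersion, lib_size = lib_size,
      baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
      de = de
    ),
    class = c("counts_truth", "effluxr_truth")
  )
}

default_de_spec <- function(n_genes, group = "resistant") {
  # transporter-like gene ~3000-fold up, plus a realistic burden of secondary
  # changes: ~5% of genes at 2-16-fold in either direction, the scale seen in
  # acquired-resistance transcriptomes
  n_sec <- min(round(0.05 * n_genes), n_genes - 1)
  bind_rows(
    # transporter gene is essentially unexpressed in the parental background
    tibble(gene = 1L, group = group, log2fc = log2(3000), baseline_mean = 50),
    tibble(
      gene = seq(2L, 1L + n_sec),
      group = group,
      log2fc = sample(c(-1, 1), n_sec, replace = TRUE) *
        stats::runif(n_sec, 1, 6),
      baseline_mean = NA_real_
    )
  )
}

#' Simulate an RNA-seq style count matrix
#'
#' @param truth A [counts_truth()].
#' @param groups Character/factor vector of group labels, one per sample
#'   (at least 2 samples per group).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Tibble with a `gene` id column and one count column per sample
#'   (named `<group>_<replicate>`); the truth (with the realized DE table)
#'   is attached as attribute `"truth"`, and the sample sheet as attribute
#'   `"samples"`.
#' @export
gen_counts <- function(truth = counts_truth(),
                       groups = rep(c("parental", "resistant"), each = 3),
                       seed = NULL) {
  stopifnot(inherits(truth, "counts_truth"))
  groups <- as.character(groups)
  if (any(table(groups) < 2)) {
    stop_domain("At least 2 samples per group are required.")
  }
  n_genes <- as.integer(truth$n_genes)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  gene_ids[1] <- "ABCB1like" # conventional position of the transporter gene

  samples <- tibble(group = groups) |>
    group_by(.data$group) |>
    mutate(sample = paste0(.data$group, "_", dplyr::row_number())) |>
    ungroup()

  out <- with_seed_if(seed, {
    base_mu <- stats::rlnorm(n_genes, truth$baseline_meanlog, truth$baseline_sdlog)
    de <- truth$de %||% default_de_spec(n_genes)
    if (nrow(de) > 0 && is.character(de$gene)) {
      de$gene <- match(de$gene, gene_ids)
    }
    if (nrow(de) > 0 && "baseline_mean" %in% names(de)) {
      ov <- !is.na(de$baseline_mean)
      base_mu[de$gene[ov]] <- de$baseline_mean[ov]
    }
    mu <- matrix(base_mu, nrow = n_genes, ncol = nrow(samples))
    if (nrow(de) > 0) {
      for (r in seq_len(nrow(de))) {
        cols <- which(samples$group == de$group[r])
        mu[de$gene[r], cols] <- mu[de$gene[r], cols] * 2^de$log2fc[r]
      }
    }
    mu <- sweep(mu, 2, colSums(mu), "/") * truth$lib_size
    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / truth$dispersion),
      nrow = n_genes
    )
    colnames(counts) <- samples$sample
    list(counts = counts, de = de)
  })

  result <- bind_cols(tibble(gene = gene_ids), as_tibble(out$counts))
  attr(result, "truth") <- c(
    unclass(truth)[setdiff(names(unclass(truth)), "de")],
    list(de = out$de, seed = seed)
  )
  attr(result, "samples") <- samples[, c("sample", "group")]
  result
}

#' Retrieve the ground truth attached to a simulated dataset
#'
#' @param x Output of one of the `gen_*()` simulators.
#' @export
synthetic_truth <- function(x) {
  attr(x, "truth", exact = TRUE)
}

#' @rdname synthetic_truth
#' @export
sample_sheet <- function(x) {
  attr(x, "samples", exact = TRUE)
}
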