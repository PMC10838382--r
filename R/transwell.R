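#' Apparent permeability coefficient
#'
#' `Papp = (dQ/dT) / (A * C0)`: translocated amount per unit time, normalized
#' by membrane area and the donor concentration at t0. Single-timepoint slope
#' approximation, appropriate for sampling within the linear transport regime.
#'
#' @param dq Translocated amount in the receiver compartment, pmol.
#' @param dt Incubation time, seconds (> 0).
#' @param area Membrane area, cm^2 (> 0; 0.7 is the standard 24-well insert).
#' @param c0 Initial donor concentration, pmol/cm^3 (> 0; 1 uM = 1000).
#' @return Papp in cm/s, vectorized.
#' @examples
#' papp(529.96, 3600, 0.7, 10000) # 21.03e-6 cm/s
#' @export
papp <- function(dq, dt, area = 0.7, c0) {
  check_number(dq, "dq", non_negative = TRUE)
  check_number(dt, "dt", positive = TRUE)
  check_number(area, "area", positive = TRUE)
  check_number(c0, "c0", positive = TRUE)
  (dq / dt) / (area * c0)
}

#' Efflux ratio
#'
#' `ER = Papp(B-A) / Papp(A-B)`. Ratios above 2 indicate active (efflux-
#' transporter-mediated) secretion towards the apical side.
#'
#' @param papp_ab Apical-to-basolateral Papp, cm/s.
#' @param papp_ba Basolateral-to-apical Papp, cm/s.
#' @return Dimensionless ratio; `Inf` with a warning when `papp_ab` is zero.
#' @examples
#' efflux_ratio(5.33e-6, 6.62e-6) # 1.24
#' @export
efflux_ratio <- function(papp_ab, papp_ba) {
  check_number(papp_ab, "papp_ab", non_negative = TRUE)
  check_number(papp_ba, "papp_ba", non_negative = TRUE)
  if (any(papp_ab == 0)) {
    warn("Papp(A-B) is zero; returning an infinite efflux ratio.")
  }
  ifelse(papp_ab == 0, Inf, papp_ba / papp_ab)
}

#' Compound recovery across transwell compartments
#'
#' `R = 100 * (Q_apical + Q_basolateral + Q_cells) / Q0`, estimating loss to
#' metabolism and/or non-specific binding. Values near 100% indicate mass
#' balance.
#'
#' @param q_apical,q_basolateral,q_cells Quantities recovered per
#'   compartment, pmol (non-negative).
#' @param q0 Quantity applied at t0, pmol (> 0).
#' @return Recovery in percent, vectorized.
#' @examples
#' recovery(300, 150, 50, 1000) # 50
#' @export
recovery <- function(q_apical, q_basolateral, q_cells, q0) {
  check_number(q_apical, "q_apical", non_negative = TRUE)
  check_number(q_basolateral, "q_basolateral", non_negative = TRUE)
  check_number(q_cells, "q_cells", non_negative = TRUE)
  check_number(q0, "q0", positive = TRUE)
  100 * (q_apical + q_basolateral + q_cells) / q0
}

#' Substrate and inhibition calls from efflux ratios
#'
#' A compound is an efflux substrate when its ER exceeds the cutoff (default
#' 2) with `Papp(B-A) > Papp(A-B)`; a co-incubated inhibitor is called
#' inhibiting when it brings the ER of a substrate below the cutoff.
#'
#' @param er Efflux ratio of the compound alone.
#' @param papp_ab,papp_ba Mean directional Papp values of the compound alone.
#' @param er_cutoff ER decision threshold (default 2).
#' @return `substrate_call()`: `"efflux_substrate"` or `"not_substrate"`.
#' @export
substrate_call <- function(er, papp_ab, papp_ba, er_cutoff = 2) {
  ifelse(er > er_cutoff & papp_ba > papp_ab, "efflux_substrate", "not_substrate")
}

#' @rdname substrate_call
#' @param er_with Efflux ratio in the presence of the inhibitor.
#' @param substrate Logical (or call string): is the compound an efflux
#'   substrate when tested alone?
#' @return `inhibition_call()`: `"inhibited"`, `"not_inhibited"`, or `"n/a"`
#'   when the compound is not a substrate to begin with.
#' @export
inhibition_call <- function(er_with, substrate, er_cutoff = 2) {
  is_sub <- if (is.character(substrate)) substrate == "efflux_substrate" else substrate
  n <- max(length(er_with), length(is_sub))
  er_with <- rep_len(er_with, n)
  is_sub <- rep_len(is_sub, n)
  ifelse(!is_sub | is.na(is_sub), "n/a",
    ifelse(er_with < er_cutoff, "inhibited", "not_inhibited")
  )
}

# mean of per-replicate B-A/A-B ratios over replicates with both directions
er_paired <- function(papp_ab, papp_ba) {
  ok <- !is.na(papp_ab) & !is.na(papp_ba) & papp_ab > 0
  if (!any(ok)) {
    return(NA_real_)
  }
  mean(papp_ba[ok] / papp_ab[ok])
}

normalize_direction <- function(x) {
  y <- toupper(gsub("[^A-Za-z]", "", x))
  out <- ifelse(y %in% c("AB", "ATOB"), "A_B", ifelse(y %in% c("BA", "BTOA"), "B_A", NA))
  if (anyNA(out)) {
    stop_schema("`direction` must be A-B or B-A.")
  }
  out
}

#' Analyze a bidirectional transwell dataset
#'
#' Computes per-replicate apparent permeability from the raw translocated
#' amounts, aggregates to mean +/- SEM per condition and direction, derives
#' the efflux ratio two ways (ratio of mean Papps, the display default, and
#' mean of per-replicate ratios, reported alongside), propagates ER
#' uncertainty to first order, computes recovery, and emits substrate and
#' inhibition calls (inhibitor arms are matched to the same compound,
#' concentration and incubation time tested alone).
#'
#' @param data Data frame with columns `compound`, `direction` (A-B/B-A),
#'   `conc_uM`, `time_min`, `dq_pmol`, `replicate`; optional `inhibitor`
#'   (`"none"`/`NA` for the compound alone), `area_cm2` (default 0.7),
#'   `q_apical`, `q_basolateral`, `q_cells`, `q0` (for recovery) and `qc_pass`
#'   (wells failing monolayer QC are excluded with a note).
#' @param er_cutoff ER decision threshold (default 2).
#' @param default_area Membrane area used when `area_cm2` is absent.
#' @return A tibble (one row per compound/inhibitor/concentration/time) with
#'   `papp_ab`, `papp_ba` (+ SEMs), `er` (ratio of means), `er_sem`
#'   (first-order propagation), `er_replicate` (mean of per-replicate ERs),
#'   `recovery_pct`, `substrate_call`, `inhibition_call`. The per-replicate
#'   detail table is attached as attribute `"detail"`.
#' @export
analyze_transwell <- function(data, er_cutoff = 2, default_area = 0.7) {
  df <- as_tibble(data)
  check_columns(
    df, c("compound", "direction", "conc_uM", "time_min", "dq_pmol", "replicate"),
    "transwell data"
  )
  if (!"inhibitor" %in% names(df)) df$inhibitor <- "none"
  df$inhibitor[is.na(df$inhibitor) | df$inhibitor == ""] <- "none"
  if (!"area_cm2" %in% names(df)) df$area_cm2 <- default_area
  if ("qc_pass" %in% names(df)) {
    n_fail <- sum(!df$qc_pass)
    if (n_fail > 0) {
      inform(sprintf("Excluding %d well(s) failing monolayer QC.", n_fail))
      df <- df[df$qc_pass, , drop = FALSE]
    }
  }
  df$direction <- normalize_direction(df$direction)
  df$papp <- papp(
    dq = df$dq_pmol, dt = df$time_min * 60,
    area = df$area_cm2, c0 = df$conc_uM * 1000 # 1 uM = 1000 pmol/cm^3
  )
  has_rec <- all(c("q_apical", "q_basolateral", "q_cells", "q0") %in% names(df))
  df$recovery_pct <- if (has_rec) {
    recovery(df$q_apical, df$q_basolateral, df$q_cells, df$q0)
  } else {
    NA_real_
  }

  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_

  wide <- df |>
    select(
      "compound", "inhibitor", "conc_uM", "time_min", "replicate",
      "direction", "papp", "recovery_pct"
    ) |>
    tidyr::pivot_wider(
      names_from = "direction", values_from = c("papp", "recovery_pct")
    )

  res <- wide |>
    group_by(.data$compound, .data$inhibitor, .data$conc_uM, .data$time_min) |>
    summarise(
      n = dplyr::n(),
      papp_ab = mean(.data$papp_A_B, na.rm = TRUE),
      papp_ab_sem = sem(.data$papp_A_B[!is.na(.data$papp_A_B)]),
      papp_ba = mean(.data$papp_B_A, na.rm = TRUE),
      papp_ba_sem = sem(.data$papp_B_A[!is.na(.data$papp_B_A)]),
      er_replicate = er_paired(.data$papp_A_B, .data$papp_B_A),
      recovery_pct = mean(c(.data$recovery_pct_A_B, .data$recovery_pct_B_A),
        na.rm = TRUE
      ),
      .groups = "drop"
    ) |>
    mutate(
      er = ifelse(
        is.finite(.data$papp_ab) & is.finite(.data$papp_ba),
        .data$papp_ba / pmax(.data$papp_ab, .Machine$double.xmin),
        NA_real_
      ),
      er_sem = .data$er * sqrt(
        (.data$papp_ab_sem / .data$papp_ab)^2 +
          (.data$papp_ba_sem / .data$papp_ba)^2
      ),
      recovery_pct = ifelse(is.nan(.data$recovery_pct), NA_real_, .data$recovery_pct)
    )

  alone <- res |>
    filter(.data$inhibitor == "none") |>
    mutate(
      substrate_call = substrate_call(
        .data$er, .data$papp_ab, .data$papp_ba, er_cutoff
      )
    )
  res <- res |>
    left_join(
      alone |>
        select("compound", "conc_uM", "time_min",
          alone_substrate = "substrate_call"
        ),
      by = c("compound", "conc_uM", "time_min")
    ) |>
    mutate(
      substrate_call = ifelse(
        .data$inhibitor == "none",
        substrate_call(.data$er, .data$papp_ab, .data$papp_ba, er_cutoff),
        NA_character_
      ),
      inhibition_call = ifelse(
        .data$inhibitor == "none",
        "n/a",
        inhibition_call(.data$er, .data$alone_substrate, er_cutoff)
      )
    ) |>
    select(-"alone_substrate") |>
    arrange(.data$compound, .data$time_min, dplyr::desc(.data$conc_uM), .data$inhibitor)

  attr(res, "detail") <- df
  res
}
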