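#' Log counts-per-million transformation
#'
#' `log2(1e6 * (count + pseudocount) / (library_size + 2 * pseudocount))`, a
#' simple variance-taming transform of a count matrix onto a comparable
#' per-sample scale. With `pseudocount = 0` the transform is exactly invariant
#' to proportional scaling of a sample's counts.
#'
#' @param counts Non-negative count matrix (genes in rows, samples in
#'   columns), or a data frame whose first column holds gene ids.
#' @param pseudocount Added to every count before the log (default 0.5).
#' @return Matrix of log2-CPM values with the input dimnames.
#' @export
log_cpm <- function(counts, pseudocount = 0.5) {
  counts <- as_count_matrix(counts)
  check_number(pseudocount, "pseudocount", non_negative = TRUE)
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop_domain("Every sample must have a positive library size.")
  }
  log2(1e6 * sweep(counts + pseudocount, 2, lib + 2 * pseudocount, "/"))
}

as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    gene_col <- names(counts)[1]
    if (!is.numeric(counts[[gene_col]])) {
      m <- as.matrix(counts[, -1, drop = FALSE])
      rownames(m) <- counts[[gene_col]]
      counts <- m
    } else {
      counts <- as.matrix(counts)
    }
  }
  if (any(counts < 0)) {
    stop_domain("Counts must be non-negative.")
  }
  if (anyDuplicated(rownames(counts))) {
    stop_schema("Duplicate gene ids in the count matrix.")
  }
  counts
}

#' Per-sample outlier statistics for an expression matrix
#'
#' Screens samples with four statistics: the sum of Euclidean distances to
#' all other samples; Hoeffding's D between the sample and a per-gene median
#' pseudo-reference; the mean Pearson correlation with every other sample;
#' and the two-sample Kolmogorov-Smirnov statistic between the sample's
#' expression distribution and the pooled distribution of the remaining
#' samples. A sample is flagged when any statistic departs from the
#' across-sample median by more than `flag_z` robust z-units (MAD scale), in
#' the adverse direction only: high distance, low D, low correlation, high KS.
#' Because the MAD of a dozen samples is itself noisy (and collapses when
#' replicates are tight), the fence has a minimum width per statistic
#' (`min_effect`): a departure must also be practically large to flag, which
#' keeps clean replicate designs flag-free while leaving genuine outliers
#' (whose statistics depart by an order of magnitude) unambiguous.
#'
#' @param logexpr Matrix of log-scale expression values (genes x samples),
#'   e.g. from [log_cpm()]; at least 3 samples.
#' @param flag_z Robust z threshold (default 3).
#' @param min_effect Minimum fence half-widths, named: `sum_euclidean`
#'   (relative to the median distance sum), `hoeffding_d`, `mean_pearson` and
#'   `ks_stat` (absolute).
#' @return A tibble with one row per sample: the four statistics, `flagged`,
#'   and a `reason` string naming the statistics that fired.
#' @export
outlier_stats <- function(logexpr, flag_z = 3,
                          min_effect = c(
                            sum_euclidean = 0.25, hoeffding_d = 0.1,
                            mean_pearson = 0.05, ks_stat = 0.05
                          )) {
  if (is.data.frame(logexpr)) logexpr <- as_count_matrix(logexpr)
  ns <- ncol(logexpr)
  if (is.null(ns) || ns < 3) {
    stop_domain("Outlier screening requires at least 3 samples.")
  }
  samples <- colnames(logexpr) %||% paste0("sample", seq_len(ns))

  dmat <- as.matrix(dist(t(logexpr)))
  sum_euclidean <- rowSums(dmat)

  ref <- apply(logexpr, 1, median) # per-gene median pseudo-reference
  hoeff <- vapply(
    seq_len(ns), function(j) hoeffding_d(logexpr[, j], ref), numeric(1)
  )

  mean_pearson <- mean_pairwise_cor(logexpr)

  ks_stat <- vapply(seq_len(ns), function(j) {
    pooled <- as.vector(logexpr[, -j, drop = FALSE])
    unname(suppressWarnings(ks.test(logexpr[, j], pooled)$statistic))
  }, numeric(1))

  flag_high <- function(s, floor) s > median(s) + max(flag_z * mad(s), floor)
  flag_low <- function(s, floor) s < median(s) - max(flag_z * mad(s), floor)
  fired <- cbind(
    sum_euclidean = flag_high(
      sum_euclidean, min_effect[["sum_euclidean"]] * median(sum_euclidean)
    ),
    hoeffding_d = flag_low(hoeff, min_effect[["hoeffding_d"]]),
    mean_pearson = flag_low(mean_pearson, min_effect[["mean_pearson"]]),
    ks_stat = flag_high(ks_stat, min_effect[["ks_stat"]])
  )
  reason <- apply(fired, 1, function(r) paste(colnames(fired)[r], collapse = ","))

  tibble(
    sample = samples,
    sum_euclidean = unname(sum_euclidean),
    hoeffding_d = hoeff,
    mean_pearson = unname(mean_pearson),
    ks_stat = ks_stat,
    flagged = unname(rowSums(fired) > 0),
    reason = unname(ifelse(reason == "", NA_character_, reason))
  )
}

# mean Pearson correlation of each sample with every other sample; pairs with
# a zero-variance member are 1 when the vectors are identical, otherwise
# dropped from the mean with a note
mean_pairwise_cor <- function(logexpr) {
  ns <- ncol(logexpr)
  sds <- apply(logexpr, 2, sd)
  cm <- suppressWarnings(cor(logexpr))
  dropped <- FALSE
  if (any(sds == 0)) {
    for (j in which(sds == 0)) {
      for (k in seq_len(ns)) {
        if (j == k) next
        if (identical(logexpr[, j], logexpr[, k])) {
          cm[j, k] <- cm[k, j] <- 1
        } else {
          dropped <- TRUE
        }
      }
    }
  }
  if (dropped) {
    inform("Zero-variance sample(s): undefined correlations dropped from the mean.")
  }
  diag(cm) <- NA
  rowMeans(cm, na.rm = TRUE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity, as
#' implemented by [stats::p.adjust()]; inputs are validated to lie in
#' \[0, 1\].
#'
#' @param pvalues Vector of p-values.
#' @return Adjusted q-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(pvalues) {
  check_number(pvalues, "pvalues")
  if (any(pvalues < 0 | pvalues > 1)) {
    stop_domain("p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Per-gene two-group Welch test on log-scale expression
#'
#' A deliberately simple stand-in for moderated count models: per-gene Welch
#' t-test on log2-CPM values, with the fold change taken as
#' `2^(mean difference)` relative to the reference group. Genes with
#' (near-)zero variance in both groups receive a small variance floor so the
#' statistic stays defined; identical groups give fold 1 and p about 1.
#'
#' @param logexpr Matrix of log2-scale expression (genes x samples).
#' @param groups Factor (or character) of length `ncol(logexpr)` with exactly
#'   two levels, each with at least 2 samples.
#' @param ref Reference (denominator) group; defaults to the first level.
#' @param var_floor Variance floor for degenerate genes.
#' @return Tibble with `gene`, `log2_fc`, `fold_change`, `p_value`.
#' @export
two_group_test <- function(logexpr, groups, ref = NULL, var_floor = 1e-8) {
  if (is.data.frame(logexpr)) logexpr <- as_count_matrix(logexpr)
  groups <- as.factor(groups)
  if (length(groups) != ncol(logexpr)) {
    stop_schema("`groups` must have one label per sample.")
  }
  if (nlevels(groups) != 2) {
    stop_schema("Exactly two groups are required.")
  }
  if (any(table(groups) < 2)) {
    stop_domain("At least 2 samples per group are required.")
  }
  ref <- ref %||% levels(groups)[1]
  if (!ref %in% levels(groups)) {
    stop_schema("`ref` is not one of the group labels.")
  }
  other <- setdiff(levels(groups), ref)

  x1 <- logexpr[, groups == ref, drop = FALSE]
  x2 <- logexpr[, groups == other, drop = FALSE]
  n1 <- ncol(x1)
  n2 <- ncol(x2)
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)

  floored <- v1 < var_floor & v2 < var_floor
  if (any(floored)) {
    inform(sprintf(
      "%d gene(s) with (near-)zero variance in both groups: variance floor applied.",
      sum(floored)
    ))
  }
  v1 <- pmax(v1, var_floor)
  v2 <- pmax(v2, var_floor)

  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)

  tibble(
    gene = rownames(logexpr) %||% as.character(seq_len(nrow(logexpr))),
    log2_fc = unname(m2 - m1),
    fold_change = unname(2^(m2 - m1)),
    p_value = unname(p)
  )
}

#' Differential-expression filter
#'
#' Flags genes as differentially expressed when the FDR-adjusted q-value is
#' below `fdr` AND the fold change is at least `fold` in either direction
#' (|log2 FC| >= log2(fold)).
#'
#' @param stats Data frame with `gene`, `log2_fc` and `p_value` (q-values are
#'   computed with [bh_adjust()] if a `q_value` column is absent).
#' @param fdr FDR threshold (default 0.05).
#' @param fold Fold-change threshold (default 2).
#' @return The input with `q_value` and logical `is_deg` columns, ordered by
#'   descending |log2 FC| among DEGs first.
#' @export
deg_filter <- function(stats, fdr = 0.05, fold = 2) {
  check_columns(stats, c("gene", "log2_fc", "p_value"), "DE statistics")
  out <- as_tibble(stats)
  if (!"q_value" %in% names(out)) {
    out$q_value <- bh_adjust(out$p_value)
  }
  if (!"fold_change" %in% names(out)) {
    out$fold_change <- 2^out$log2_fc
  }
  out$is_deg <- out$q_value < fdr & abs(out$log2_fc) >= log2(fold)
  out |>
    arrange(dplyr::desc(.data$is_deg), dplyr::desc(abs(.data$log2_fc)))
}

#' Count-matrix differential-expression screen
#'
#' Convenience chain: [log_cpm()] then [two_group_test()] then
#' [deg_filter()].
#'
#' @inheritParams log_cpm
#' @inheritParams two_group_test
#' @inheritParams deg_filter
#' @return A DEG table (see [deg_filter()]).
#' @export
deg_screen <- function(counts, groups, ref = NULL, pseudocount = 0.5,
                       fdr = 0.05, fold = 2) {
  lcpm <- log_cpm(counts, pseudocount = pseudocount)
  deg_filter(two_group_test(lcpm, groups, ref = ref), fdr = fdr, fold = fold)
}

#' Volcano plot of a DEG table
#'
#' @param deg_table Output of [deg_filter()] or [deg_screen()].
#' @param fdr,fold Thresholds drawn as guides.
#' @export
plot_deg_volcano <- function(deg_table, fdr = 0.05, fold = 2) {
  check_columns(deg_table, c("log2_fc", "q_value", "is_deg"), "DEG table")
  ggplot2::ggplot(
    deg_table,
    ggplot2::aes(
      x = .data$log2_fc, y = -log10(pmax(.data$q_value, 1e-300)),
      colour = .data$is_deg
    )
  ) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-log2(fold), log2(fold)), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(fdr), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "red3")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 q", colour = "DEG") +
    ggplot2::theme_minimal()
}
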