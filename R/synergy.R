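#' Bliss independence expectation for two drugs
#'
#' Under Bliss independence, the expected fraction unaffected by the
#' combination is the product of the single-agent fractions unaffected:
#' `E12 = E1 * E2`, with effects measured as treated-over-control (T/C)
#' fractions from the same plate.
#'
#' @param e1,e2 Single-agent T/C fractions, non-negative. Values above 1
#'   (stimulation) are used as-is so the multiplicative identity is preserved.
#' @return `e1 * e2`, vectorized.
#' @examples
#' bliss_neutral(0.9, 0.6) # 0.54
#' @export
bliss_neutral <- function(e1, e2) {
  check_number(e1, "e1", non_negative = TRUE)
  check_number(e2, "e2", non_negative = TRUE)
  e1 * e2
}

#' Bliss index of a combination condition
#'
#' The difference between the Bliss expectation and the observed combination
#' T/C: `BI = E12 - T/C(combination)`. Positive values mean stronger-than-
#' expected inhibition (synergy); negative values mean antagonism.
#'
#' @param neutral Bliss expectation (`E1 * E2`), non-negative.
#' @param tc_combo Observed combination T/C fraction, non-negative.
#' @return `neutral - tc_combo`, vectorized.
#' @examples
#' bliss_index(0.54, 0.30) # 0.24, synergy at the 0.15 threshold
#' @export
bliss_index <- function(neutral, tc_combo) {
  check_number(neutral, "neutral", non_negative = TRUE)
  check_number(tc_combo, "tc_combo", non_negative = TRUE)
  neutral - tc_combo
}

#' Modeled T/C of a condition
#'
#' The modeled T/C of a checkerboard condition is the arithmetic mean of its
#' replicate T/C measurements. The unclipped mean is what enters the Bliss
#' index; clipping to \[0, 1\] is only a heat-map display convention (see
#' `clip_tc()`).
#'
#' @param replicates Numeric vector of replicate T/C values (at least one).
#' @export
modeled_tc <- function(replicates) {
  if (length(replicates) < 1) {
    stop_domain("At least one replicate T/C value is required.")
  }
  check_number(replicates, "replicates")
  mean(replicates)
}

#' @rdname modeled_tc
#' @param x T/C values to clip to the \[0, 1\] display scale.
#' @export
clip_tc <- function(x) {
  pmin(pmax(x, 0), 1)
}

#' Build a checkerboard T/C matrix
#'
#' Assembles a `tc_matrix` (drug-A concentrations by drug-B concentrations,
#' both grids including 0) from either a long-format plate table or a
#' pre-normalized numeric grid. The zero/zero cell is 1 by construction
#' (controls normalize the plate); the zero row and column hold the
#' single-agent effects used as E1 and E2.
#'
#' @param x A data frame with columns `conc_a`, `conc_b`, `signal` (plus
#'   `is_control` rows or both concentrations zero for controls) or `tc`, and
#'   optionally `replicate`; or a numeric matrix of modeled T/C values whose
#'   rownames/colnames are drug-A/drug-B concentrations (including `"0"`).
#' @param meta Optional named list carried along (assay id, cell line, drugs).
#' @return A `tc_matrix`: list with `conc_a`, `conc_b`, `tc` (matrix of
#'   modeled T/C means), `replicates` (long tibble) and `meta`.
#' @export
as_tc_matrix <- function(x, meta = list()) {
  if (is.matrix(x)) {
    conc_a <- as.numeric(rownames(x))
    conc_b <- as.numeric(colnames(x))
    if (anyNA(conc_a) || anyNA(conc_b)) {
      stop_schema("Matrix input must have numeric concentration dimnames.")
    }
    ca <- rep(conc_a, times = length(conc_b))
    cb <- rep(conc_b, each = length(conc_a))
    long <- tibble(conc_a = ca, conc_b = cb, tc = as.vector(x))
    return(tc_matrix_from_long(long, meta))
  }
  df <- as_tibble(x)
  check_columns(df, c("conc_a", "conc_b"), "checkerboard data")
  for (m in intersect(c("assay_id", "cell_line", "drug_a", "drug_b"), names(df))) {
    v <- unique(df[[m]])
    if (length(v) == 1) meta[[m]] <- v
  }
  if (!"tc" %in% names(df)) {
    check_columns(df, "signal", "checkerboard data")
    is_ctrl <- if ("is_control" %in% names(df)) {
      df$is_control == 1
    } else {
      df$conc_a == 0 & df$conc_b == 0
    }
    if (!any(is_ctrl)) {
      abort("No untreated control wells found to normalize the plate.",
        class = "effluxr_error_invalid_plate"
      )
    }
    df$tc <- tc_fraction(df$signal, df$signal[is_ctrl])
    df <- df[!is_ctrl, , drop = FALSE]
  }
  tc_matrix_from_long(df, meta)
}

tc_matrix_from_long <- function(long, meta) {
  conc_a <- sort(unique(long$conc_a))
  conc_b <- sort(unique(long$conc_b))
  if (!0 %in% conc_a || !0 %in% conc_b) {
    stop_schema(paste(
      "Checkerboard is missing its single-agent margin:",
      "both concentration grids must include 0."
    ))
  }
  tc <- matrix(NA_real_,
    nrow = length(conc_a), ncol = length(conc_b),
    dimnames = list(
      format(conc_a, trim = TRUE, scientific = FALSE, digits = 15),
      format(conc_b, trim = TRUE, scientific = FALSE, digits = 15)
    )
  )
  means <- long |>
    filter(!is.na(.data$tc)) |>
    group_by(.data$conc_a, .data$conc_b) |>
    summarise(tc = modeled_tc(.data$tc), .groups = "drop")
  tc[cbind(
    match(means$conc_a, conc_a),
    match(means$conc_b, conc_b)
  )] <- means$tc
  tc[conc_a == 0, conc_b == 0] <- 1 # controls normalize to 1 by construction
  if (any(tc[!is.na(tc)] < 0)) {
    stop_domain("T/C values must be non-negative.")
  }
  structure(
    list(
      conc_a = conc_a, conc_b = conc_b, tc = tc,
      replicates = as_tibble(long[, intersect(
        c("conc_a", "conc_b", "replicate", "tc"), names(long)
      )]),
      meta = meta
    ),
    class = "tc_matrix"
  )
}

#' Bliss independence analysis of a checkerboard
#'
#' For every combination cell (both concentrations nonzero) the Bliss
#' expectation is the product of the measured single-agent effects from the
#' same plate's zero row/column, the Bliss index is expectation minus observed
#' modeled T/C, and cells are flagged synergy/neutral/antagonism against a
#' symmetric threshold (default |BI| >= 0.15, ties flagged). The assay-level
#' call generalizes the count rules used for 5 x 5 checkerboards (synergy when
#' more than 3/25 conditions are flagged, slight synergy at exactly 3/25,
#' additive when fewer than 3/25 are flagged in either direction) to any
#' matrix size via `k = ceiling(flag_fraction * n_total)`.
#'
#' @param x A `tc_matrix`, a long plate data frame, or a numeric T/C grid
#'   (see [as_tc_matrix()]).
#' @param bi_threshold Bliss-index flag threshold (default 0.15).
#' @param flag_fraction Fraction of the matrix defining the call thresholds
#'   (default 0.12; `ceiling(0.12 * 25) = 3` recovers the 5 x 5 rules).
#' @param meta Passed to [as_tc_matrix()] when coercing.
#' @return A `bliss_result`: list with matrices `tc`, `tc_display` (clipped),
#'   `neutral`, `index`, `flags`, plus `counts`, `call`, `thresholds`, `meta`.
#'   Has [tidy()], [glance()], [autoplot()] methods.
#' @examples
#' m <- matrix(1, 3, 3, dimnames = list(c(0, 1, 2), c(0, 1, 2)))
#' m[2:3, 2:3] <- outer(c(0.8, 0.4), c(0.9, 0.5)) # exactly multiplicative
#' m[2:3, 1] <- c(0.8, 0.4)
#' m[1, 2:3] <- c(0.9, 0.5)
#' glance(analyze_bliss(m))$call # "additive"
#' @export
analyze_bliss <- function(x, bi_threshold = 0.15, flag_fraction = 0.12,
                          meta = list()) {
  m <- if (inherits(x, "tc_matrix")) x else as_tc_matrix(x, meta = meta)
  ia <- which(m$conc_a > 0)
  ib <- which(m$conc_b > 0)
  i0 <- which(m$conc_a == 0)
  j0 <- which(m$conc_b == 0)

  e1 <- m$tc[, j0] # single-agent drug A (by conc_a), measured on this plate
  e2 <- m$tc[i0, ] # single-agent drug B (by conc_b)
  if (anyNA(e1[ia]) || anyNA(e2[ib])) {
    stop_schema("Single-agent margin of the checkerboard has missing cells.")
  }

  dims <- dimnames(m$tc)
  neutral <- matrix(NA_real_, nrow(m$tc), ncol(m$tc), dimnames = dims)
  neutral[ia, ib] <- outer(e1[ia], e2[ib], bliss_neutral)
  index <- neutral - m$tc # BI = E12 - observed modeled T/C
  flags <- matrix(NA_character_, nrow(m$tc), ncol(m$tc), dimnames = dims)
  flags[ia, ib] <- ifelse(
    is.na(index[ia, ib]), NA_character_,
    ifelse(index[ia, ib] >= bi_threshold, "synergy",
      ifelse(index[ia, ib] <= -bi_threshold, "antagonism", "neutral")
    )
  )

  cells <- flags[ia, ib]
  n_missing <- sum(is.na(cells))
  if (n_missing > 0) {
    inform(sprintf(
      "%d combination cell(s) without data excluded from the call.", n_missing
    ))
  }
  counts <- c(
    n_synergy = sum(cells == "synergy", na.rm = TRUE),
    n_antagonism = sum(cells == "antagonism", na.rm = TRUE),
    n_neutral = sum(cells == "neutral", na.rm = TRUE),
    n_total = sum(!is.na(cells))
  )
  call <- classify_combination(
    counts[["n_synergy"]], counts[["n_antagonism"]], counts[["n_total"]],
    flag_fraction = flag_fraction
  )

  structure(
    list(
      tc = m$tc, tc_display = clip_tc(m$tc), neutral = neutral, index = index,
      flags = flags, counts = counts, call = call,
      thresholds = list(bi_threshold = bi_threshold, flag_fraction = flag_fraction),
      conc_a = m$conc_a, conc_b = m$conc_b, meta = m$meta
    ),
    class = "bliss_result"
  )
}

#' Assay-level combination call from flagged-condition counts
#'
#' With `k = ceiling(flag_fraction * n_total)` (3 for a 5 x 5 checkerboard):
#' synergy when more than `k` conditions are synergy-flagged, slight synergy
#' at exactly `k`; symmetric for antagonism; `mixed` when both directions fire
#' (no precedence is assumed) and for split-flag edge cases where the total
#' number of flags reaches `k` without either direction doing so alone;
#' additive otherwise, i.e. when fewer than `k` conditions are flagged in
#' total.
#'
#' @param n_synergy,n_antagonism Flagged-condition counts.
#' @param n_total Number of evaluable combination conditions (> 0).
#' @param flag_fraction See [analyze_bliss()].
#' @return One of `"synergy"`, `"slight_synergy"`, `"additive"`,
#'   `"slight_antagonism"`, `"antagonism"`, `"mixed"`.
#' @examples
#' classify_combination(4, 0, 25) # "synergy"
#' classify_combination(3, 0, 25) # "slight_synergy"
#' classify_combination(0, 0, 25) # "additive"
#' @export
classify_combination <- function(n_synergy, n_antagonism, n_total,
                                 flag_fraction = 0.12) {
  if (n_total <= 0) {
    stop_domain("`n_total` must be positive.")
  }
  if (n_synergy + n_antagonism > n_total) {
    stop_domain("Flag counts exceed the number of conditions.")
  }
  k <- ceiling(flag_fraction * n_total)
  syn_fire <- n_synergy > k
  ant_fire <- n_antagonism > k
  if (syn_fire && ant_fire) {
    return("mixed")
  }
  if (syn_fire) {
    return("synergy")
  }
  if (ant_fire) {
    return("antagonism")
  }
  if (n_synergy == k && n_antagonism == k) {
    return("mixed")
  }
  if (n_synergy == k) {
    return("slight_synergy")
  }
  if (n_antagonism == k) {
    return("slight_antagonism")
  }
  "additive"
}

#' @export
print.bliss_result <- function(x, ...) {
  cat("Bliss independence analysis\n")
  if (length(x$meta)) {
    cat(" ", paste(unlist(x$meta), collapse = " / "), "\n")
  }
  cat(sprintf(
    "  %d x %d combination grid: %d synergy, %d antagonism, %d neutral (of %d)\n",
    sum(x$conc_a > 0), sum(x$conc_b > 0),
    x$counts[["n_synergy"]], x$counts[["n_antagonism"]],
    x$counts[["n_neutral"]], x$counts[["n_total"]]
  ))
  cat(sprintf(
    "  call: %s (|BI| >= %.2f)\n", x$call, x$thresholds$bi_threshold
  ))
  invisible(x)
}

#' @rdname analyze_bliss
#' @param x,object A `bliss_result`.
#' @param ... Unused.
#' @method tidy bliss_result
#' @export
tidy.bliss_result <- function(x, ...) {
  ia <- which(x$conc_a > 0)
  ib <- which(x$conc_b > 0)
  i0 <- which(x$conc_a == 0)
  j0 <- which(x$conc_b == 0)
  grid <- tidyr::expand_grid(conc_a = x$conc_a[ia], conc_b = x$conc_b[ib])
  ra <- match(grid$conc_a, x$conc_a)
  cb <- match(grid$conc_b, x$conc_b)
  grid |>
    mutate(
      e1 = x$tc[cbind(ra, j0)],
      e2 = x$tc[cbind(i0, cb)],
      tc = x$tc[cbind(ra, cb)],
      neutral = x$neutral[cbind(ra, cb)],
      index = x$index[cbind(ra, cb)],
      flag = x$flags[cbind(ra, cb)]
    )
}

#' @rdname analyze_bliss
#' @method glance bliss_result
#' @export
glance.bliss_result <- function(x, ...) {
  tibble(
    call = x$call,
    n_synergy = x$counts[["n_synergy"]],
    n_antagonism = x$counts[["n_antagonism"]],
    n_neutral = x$counts[["n_neutral"]],
    n_total = x$counts[["n_total"]],
    bi_threshold = x$thresholds$bi_threshold,
    flag_fraction = x$thresholds$flag_fraction
  )
}

#' @rdname analyze_bliss
#' @param what `"index"` for the Bliss-index heat map (blue = synergy,
#'   red = antagonism, white = neutral) or `"tc"` for the clipped modeled-T/C
#'   map on its 0-1 display scale.
#' @method autoplot bliss_result
#' @export
autoplot.bliss_result <- function(object, what = c("index", "tc"), ...) {
  what <- match.arg(what)
  long <- tidy(object) |>
    mutate(
      conc_a = factor(format(.data$conc_a, digits = 3)),
      conc_b = factor(format(.data$conc_b, digits = 3)),
      tc_display = clip_tc(.data$tc)
    )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$conc_b, y = .data$conc_a))
  if (what == "index") {
    p <- p +
      ggplot2::geom_tile(ggplot2::aes(fill = .data$index)) +
      ggplot2::scale_fill_gradient2(
        low = "red", mid = "white", high = "blue",
        midpoint = 0, limits = c(-1, 1), name = "Bliss index"
      )
  } else {
    p <- p +
      ggplot2::geom_tile(ggplot2::aes(fill = .data$tc_display)) +
      ggplot2::scale_fill_gradient(
        low = "grey10", high = "white", limits = c(0, 1), name = "Modeled T/C"
      )
  }
  p +
    ggplot2::labs(x = "Drug B concentration", y = "Drug A concentration") +
    ggplot2::theme_minimal()
}

#' Read/write modeled T/C grids as CSV
#'
#' The grid layout has drug-A concentrations in the first column (`conc_a`)
#' and drug-B concentrations as the remaining column headers. Values are
#' written with 17 significant digits, so write -> read -> analyze
#' reproduces Bliss index grids bit for bit.
#'
#' @param m A `tc_matrix` (or anything [as_tc_matrix()] accepts).
#' @param path File path.
#' @export
write_tc_matrix <- function(m, path) {
  if (!inherits(m, "tc_matrix")) m <- as_tc_matrix(m)
  # %.17g guarantees the shortest-parse double round-trips exactly
  df <- as.data.frame(apply(m$tc, 2, fmt17, simplify = FALSE))
  names(df) <- format(m$conc_b, trim = TRUE, scientific = FALSE, digits = 15)
  df <- cbind(conc_a = fmt17(m$conc_a), df)
  readr::write_csv(as_tibble(df), path)
  invisible(path)
}

fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' @rdname write_tc_matrix
#' @export
read_tc_matrix <- function(path) {
  # base read.csv parses doubles via strtod (correctly rounded), which the
  # bitwise round-trip guarantee relies on
  df <- utils::read.csv(path, check.names = FALSE)
  check_columns(df, "conc_a", "T/C grid file")
  tc <- as.matrix(df[, -1, drop = FALSE])
  rownames(tc) <- format(df$conc_a, trim = TRUE, scientific = FALSE, digits = 15)
  as_tc_matrix(tc)
}
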