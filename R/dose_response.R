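#' Four-parameter logistic concentration-response model
#'
#' Evaluates the sigmoid `bottom + (top - bottom) / (1 + (conc/ic50)^hill)`.
#' With `hill > 0` and `top > bottom` the curve decreases monotonically from
#' `top` (no drug) towards `bottom` (saturating drug), the usual shape of a
#' viability inhibition curve expressed as treated-over-control (T/C)
#' fractions. The relative IC50 is the inflection point, i.e. the
#' concentration giving a response halfway between the two plateaus.
#'
#' @param conc Concentration(s), molar, strictly positive.
#' @param top,bottom Upper and lower plateaus (T/C fractions).
#' @param ic50 Relative IC50, molar, positive.
#' @param hill Hill slope, finite and nonzero.
#' @return Numeric vector of T/C fractions, same length as `conc`.
#' @examples
#' four_pl(9e-9, top = 1, bottom = 0, ic50 = 1e-9, hill = 1) # 0.1
#' four_pl(1e-9, top = 1, bottom = 0, ic50 = 1e-9, hill = 2) # midpoint 0.5
#' @export
four_pl <- function(conc, top, bottom, ic50, hill) {
  check_number(conc, "conc", positive = TRUE)
  check_number(ic50, "ic50", positive = TRUE)
  check_number(hill, "hill")
  if (any(hill == 0)) {
    stop_domain("`hill` must be nonzero.")
  }
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

# four_pl extended to conc = 0 by its limit (top, for hill > 0); used by the
# simulators where the zero-dose margin is part of the design
four_pl0 <- function(conc, top, bottom, ic50, hill) {
  out <- rep(top, length(conc))
  nz <- conc > 0
  if (any(nz)) {
    out[nz] <- four_pl(conc[nz], top, bottom, ic50, hill)
  }
  out
}

#' Treated-over-control (T/C) fraction
#'
#' Normalizes a treated signal by the mean of untreated control wells from the
#' same plate. Values above 1 (apparent stimulation) are preserved; clipping
#' to \[0, 1\] is purely a display convention applied downstream.
#'
#' @param treated Treated signal(s), arbitrary units, non-negative.
#' @param controls Signals of untreated control wells (at least one).
#' @return `treated / mean(controls)`.
#' @examples
#' tc_fraction(450, c(500, 500)) # 0.9
#' @export
tc_fraction <- function(treated, controls) {
  check_number(treated, "treated", non_negative = TRUE)
  if (length(controls) < 1) {
    abort("At least one control well is required.",
      class = "effluxr_error_invalid_plate"
    )
  }
  check_number(controls, "controls")
  cm <- mean(controls)
  if (cm <= 0) {
    abort("Control mean must be strictly positive.",
      class = "effluxr_error_invalid_plate"
    )
  }
  treated / cm
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Unweighted least-squares fit of [four_pl()] in log10(concentration) space,
#' the standard parameterization for sigmoid dose-response data. Replicate
#' wells are averaged at the T/C level before fitting. Fitting is multi-start
#' over a grid of Hill slopes to avoid local minima, with box constraints that
#' keep the plateaus near the observed response range (preventing runaway
#' plateaus on partial curves). If the fitted inflection point lies outside
#' the tested concentration range the IC50 is censored at the range boundary
#' and reported with a comparator flag, mirroring the "> Cmax" convention used
#' for compounds inactive over the tested range.
#'
#' @param data Data frame with a `conc` column (molar, positive) and either a
#'   `tc` column of treated-over-control fractions or a `signal` column
#'   (normalized against `controls` or rows flagged `is_control == 1`).
#' @param controls Optional vector of control-well signals, used when `data`
#'   has `signal` but no control rows.
#' @param hill_starts Hill-slope starting values for the multi-start.
#' @param min_span Minimum observed response span (fraction of the maximum
#'   T/C) below which a non-converging curve is declared flat and censored
#'   rather than a fit failure.
#' @return An object of class `fourpl_fit` with elements `top`, `bottom`,
#'   `ic50_rel` (molar; the range boundary when censored), `hill`, `censored`
#'   (`"none"`, `"above_max"` or `"below_min"`), `rss`, and the averaged
#'   points used. Has [tidy()], [glance()], [predict()], [autoplot()] methods.
#' @examples
#' d <- tibble::tibble(
#'   conc = 10^seq(-10, -7, length.out = 8),
#'   tc = four_pl(conc, 1, 0, 2e-9, 1.5)
#' )
#' fit <- fit_dose_response(d)
#' glance(fit)
#' @export
fit_dose_response <- function(data, controls = NULL,
                              hill_starts = c(0.5, 1, 2, 4),
                              min_span = 0.1) {
  data <- as_tibble(data)
  if (!"conc" %in% names(data) && "conc_a" %in% names(data)) {
    # plate-style input: fit the single-agent series of drug A
    if ("conc_b" %in% names(data)) {
      data <- data[data$conc_b == 0 | data$is_control == 1, , drop = FALSE]
    }
    data$conc <- data$conc_a
  }
  check_columns(data, "conc", "dose-response data")

  if (!"tc" %in% names(data)) {
    check_columns(data, "signal", "dose-response data")
    if (is.null(controls) && "is_control" %in% names(data)) {
      controls <- data$signal[data$is_control == 1]
      data <- data[data$is_control != 1, , drop = FALSE]
    }
    if (is.null(controls)) {
      abort("Provide a `tc` column, `controls`, or rows with `is_control == 1`.",
        class = "effluxr_error_invalid_plate"
      )
    }
    data$tc <- tc_fraction(data$signal, controls)
  }
  data <- data[!(data$conc == 0 & !is.na(data$conc)), , drop = FALSE]
  check_number(data$conc, "conc", positive = TRUE)
  check_number(data$tc, "tc")

  # duplicates are averaged at the T/C level before fitting
  pts <- data |>
    group_by(conc = .data$conc) |>
    summarise(tc = mean(.data$tc), .groups = "drop") |>
    arrange(.data$conc)

  if (nrow(pts) < 4) {
    abort(sprintf(
      "At least 4 distinct concentrations are required (got %d).", nrow(pts)
    ), class = "effluxr_error_insufficient_data")
  }

  cmin <- min(pts$conc)
  cmax <- max(pts$conc)
  mx <- max(pts$tc)
  if (mx <= 0) {
    abort("All T/C values are non-positive; cannot fit.",
      class = "effluxr_error_fit_failure"
    )
  }
  span <- diff(range(pts$tc))

  lower <- c(top = 0.5 * mx, bottom = -0.1 * mx, l50 = log10(cmin) - 2, hill = 0.1)
  upper <- c(top = 1.2 * mx, bottom = 0.5 * mx, l50 = log10(cmax) + 2, hill = 10)

  top0 <- min(max(pts$tc), upper["top"])
  bottom0 <- min(max(min(pts$tc), lower["bottom"]), upper["bottom"])
  mid <- (top0 + bottom0) / 2
  l50_0 <- interpolate_crossing(log10(pts$conc), pts$tc, mid)
  l50_0 <- min(max(l50_0, lower["l50"]), upper["l50"])

  pts$lc <- log10(pts$conc)
  attempts <- character(0)
  best <- NULL
  for (h0 in hill_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        tc ~ bottom + (top - bottom) / (1 + 10^(hill * (lc - l50))),
        data = pts,
        start = list(top = top0, bottom = bottom0, l50 = l50_0, hill = h0),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      attempts <- c(attempts, conditionMessage(fit))
      next
    }
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }

  if (is.null(best)) {
    if (span < min_span * mx) {
      # flat curve: no inflection inside (or near) the tested range
      censored <- if (mean(pts$tc) > 0.5 * mx) "above_max" else "below_min"
      return(new_fourpl_fit(
        top = max(pts$tc), bottom = min(pts$tc),
        ic50_rel = if (censored == "above_max") cmax else cmin,
        hill = 1, censored = censored,
        rss = sum((pts$tc - mean(pts$tc))^2),
        points = pts, conc_range = c(cmin, cmax), converged = FALSE
      ))
    }
    abort("4PL fit did not converge from any start.",
      class = "effluxr_error_fit_failure",
      diagnostics = attempts
    )
  }

  p <- coef(best$fit)
  ic50 <- 10^p[["l50"]]
  censored <- "none"
  ic50_rel <- ic50
  if (ic50 > cmax) {
    censored <- "above_max"
    ic50_rel <- cmax
  } else if (ic50 < cmin) {
    censored <- "below_min"
    ic50_rel <- cmin
  }

  new_fourpl_fit(
    top = p[["top"]], bottom = p[["bottom"]], ic50_rel = ic50_rel,
    hill = p[["hill"]], censored = censored, rss = best$rss,
    points = pts, conc_range = c(cmin, cmax), converged = TRUE,
    ic50_unconstrained = ic50
  )
}

new_fourpl_fit <- function(top, bottom, ic50_rel, hill, censored, rss, points,
                           conc_range, converged, ic50_unconstrained = NA_real_) {
  structure(
    list(
      top = top, bottom = bottom, ic50_rel = ic50_rel, hill = hill,
      censored = censored, rss = rss, points = points,
      conc_range = conc_range, converged = converged,
      ic50_unconstrained = ic50_unconstrained
    ),
    class = "fourpl_fit"
  )
}

# first crossing of `target` by linear interpolation of y over x (sorted by x);
# falls back to the midpoint of the x range when no crossing exists
interpolate_crossing <- function(x, y, target) {
  d <- y - target
  idx <- which(d[-length(d)] * d[-1] <= 0)
  if (length(idx) == 0) {
    return(mean(range(x)))
  }
  i <- idx[1]
  if (d[i + 1] == d[i]) {
    return(x[i])
  }
  x[i] + (x[i + 1] - x[i]) * (0 - d[i]) / (d[i + 1] - d[i])
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("Four-parameter logistic fit\n")
  cat(sprintf(
    "  top %.3f, bottom %.3f, hill %.2f\n", x$top, x$bottom, x$hill
  ))
  cat(sprintf("  relative IC50: %s\n", format_ic50(x, unit = "nM")))
  cat(sprintf("  rss %.4g over %d concentrations\n", x$rss, nrow(x$points)))
  invisible(x)
}

#' @export
predict.fourpl_fit <- function(object, conc, ...) {
  ic50 <- if (object$censored == "none") object$ic50_rel else object$ic50_unconstrained
  if (is.na(ic50)) ic50 <- object$ic50_rel
  four_pl(conc, object$top, object$bottom, ic50, object$hill)
}

#' @rdname fit_dose_response
#' @param x,object A `fourpl_fit`.
#' @param ... Unused.
#' @method tidy fourpl_fit
#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble(
    term = c("top", "bottom", "ic50_rel", "hill"),
    estimate = c(x$top, x$bottom, x$ic50_rel, x$hill)
  )
}

#' @rdname fit_dose_response
#' @method glance fourpl_fit
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble(
    top = x$top, bottom = x$bottom, ic50_rel = x$ic50_rel,
    ic50_rel_nM = x$ic50_rel * 1e9, hill = x$hill,
    censored = x$censored, rss = x$rss, n_conc = nrow(x$points),
    converged = x$converged
  )
}

#' Format a relative IC50 with its censoring comparator
#'
#' Censored fits print as a bound at the tested range limit ("> 30.0000"
#' style) rather than an extrapolated value.
#'
#' @param fit A `fourpl_fit`.
#' @param unit One of `"M"`, `"uM"`, `"nM"`.
#' @param digits Decimal places.
#' @export
format_ic50 <- function(fit, unit = c("nM", "uM", "M"), digits = 4) {
  unit <- match.arg(unit)
  scale <- c(nM = 1e9, uM = 1e6, M = 1)[[unit]]
  val <- formatC(fit$ic50_rel * scale, format = "f", digits = digits)
  prefix <- switch(fit$censored, none = "", above_max = "> ", below_min = "< ")
  paste0(prefix, val, " ", unit)
}

#' Relative resistance (or fold-sensitization) ratio of two IC50s
#'
#' The relative resistance of a derived line is its IC50 divided by the
#' parental line's IC50; the same ratio with and without a co-administered
#' inhibitor measures fold-sensitization. Conventionally reported at one
#' decimal place.
#'
#' @param ic50_num,ic50_den IC50 values (molar or any common unit), positive;
#'   `fourpl_fit` objects are accepted and must be uncensored.
#' @return A one-row tibble with `numerator_ic50`, `denominator_ic50` and the
#'   exact `fold`; round to one decimal for reporting.
#' @examples
#' ic50_ratio(54.6, 1.3)$fold # 42.0
#' @export
ic50_ratio <- function(ic50_num, ic50_den) {
  as_value <- function(x, name) {
    if (inherits(x, "fourpl_fit")) {
      if (x$censored != "none") {
        stop_domain(paste0(
          "`", name, "` is a censored fit; report a bound (e.g. via ",
          "format_ic50()) instead of a ratio."
        ))
      }
      x <- x$ic50_rel
    }
    check_number(x, name, positive = TRUE)
    x
  }
  num <- as_value(ic50_num, "ic50_num")
  den <- as_value(ic50_den, "ic50_den")
  tibble(
    numerator_ic50 = num, denominator_ic50 = den, fold = num / den
  )
}

#' @rdname fit_dose_response
#' @method autoplot fourpl_fit
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  pts <- object$points
  grid <- tibble(
    conc = 10^seq(log10(min(pts$conc)), log10(max(pts$conc)), length.out = 200)
  )
  grid$tc <- predict(object, grid$conc)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$conc, y = .data$tc)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Concentration (M)", y = "T/C fraction",
      subtitle = paste("relative IC50", format_ic50(object))
    ) +
    ggplot2::theme_minimal()
}
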