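test_that("four_pl evaluates the sigmoid and its limits correctly", {
  # inflection midpoint: the definition of the relative IC50
  expect_equal(four_pl(2e-9, 1, 0, 2e-9, 1.7), 0.5)
  expect_equal(four_pl(5e-9, 0.9, 0.1, 5e-9, 3), 0.5)
  # direct evaluation 1/(1 + 9)
  expect_equal(four_pl(9e-9, 1, 0, 1e-9, 1), 0.1)
  # low-concentration limit approaches the top plateau
  expect_equal(four_pl(1e-18, 1, 0, 1e-9, 1), 1, tolerance = 1e-8)
  expect_error(four_pl(0, 1, 0, 1e-9, 1), class = "effluxr_error_domain")
  expect_error(four_pl(-1e-9, 1, 0, 1e-9, 1), class = "effluxr_error_domain")
  expect_error(four_pl(1e-9, 1, 0, 1e-9, 0), class = "effluxr_error_domain")
})

test_that("four_pl is monotone non-increasing for positive hill", {
  withr::with_seed(42, {
    for (i in 1:20) {
      top <- runif(1, 0.8, 1.2)
      bottom <- runif(1, -0.1, 0.3)
      ic50 <- 10^runif(1, -10, -5)
      hill <- runif(1, 0.2, 6)
      conc <- sort(10^runif(30, -12, -3))
      y <- four_pl(conc, top, bottom, ic50, hill)
      expect_true(all(diff(y) <= 1e-12))
    }
  })
})

test_that("tc_fraction normalizes against the control mean", {
  expect_equal(tc_fraction(500, c(500, 500)), 1)
  expect_equal(tc_fraction(0, c(500, 500)), 0)
  expect_equal(tc_fraction(450, c(500, 500)), 0.9)
  expect_equal(tc_fraction(c(100, 600), 500), c(0.2, 1.2)) # > 1 preserved
  expect_error(tc_fraction(450, c(0, 0)), class = "effluxr_error_invalid_plate")
  expect_error(tc_fraction(450, numeric(0)), class = "effluxr_error_invalid_plate")
})

test_that("noiseless 4PL data is recovered within 1% on all four parameters", {
  truth <- list(top = 1, bottom = 0, ic50 = 2e-9, hill = 1.5)
  plate <- gen_viability_plate(
    viability_truth(ic50 = truth$ic50, hill = truth$hill, noise_cv = 0),
    conc_a = 10^seq(-10.5, -6.5, length.out = 10)
  )
  fit <- fit_dose_response(plate)
  expect_equal(fit$censored, "none")
  expect_equal(fit$ic50_rel, truth$ic50, tolerance = 0.01)
  expect_equal(fit$hill, truth$hill, tolerance = 0.01)
  expect_equal(fit$top, truth$top, tolerance = 0.01)
  # truth bottom is 0: 1% of the top-bottom range as absolute tolerance
  expect_lt(abs(fit$bottom - truth$bottom), 0.01)
})

test_that("fit is invariant to rescaling the raw signal", {
  plate <- gen_viability_plate(
    viability_truth(ic50 = 3e-9, hill = 2),
    conc_a = 10^seq(-10, -7, length.out = 8), seed = 11
  )
  f1 <- fit_dose_response(plate)
  plate2 <- plate
  plate2$signal <- plate2$signal * 1e4
  f2 <- fit_dose_response(plate2)
  expect_equal(f1$ic50_rel, f2$ic50_rel, tolerance = 1e-8)
  expect_equal(f1$hill, f2$hill, tolerance = 1e-8)
})

test_that("degenerate and under-determined inputs error or censor, never a fake IC50", {
  expect_error(
    fit_dose_response(tibble::tibble(conc = c(1, 2, 3) * 1e-9, tc = c(1, 0.5, 0))),
    class = "effluxr_error_insufficient_data"
  )
  # all-identical response: no finite inflection can be claimed
  flat <- tibble::tibble(conc = 10^seq(-9, -5, length.out = 6), tc = 1)
  fit <- tryCatch(fit_dose_response(flat), error = function(e) e)
  if (inherits(fit, "error")) {
    expect_s3_class(fit, "effluxr_error_fit_failure")
  } else {
    expect_true(fit$censored != "none")
  }
})

test_that("inactive-compound curves are censored at the top of the range", {
  # inhibitor-like compound with true IC50 far above the 30 uM test ceiling
  plate <- gen_viability_plate(
    viability_truth(ic50 = 3e-4, hill = 1, noise_cv = 0),
    conc_a = c(0.3, 0.949, 3, 9.49, 30) * 1e-6
  )
  fit <- fit_dose_response(plate)
  expect_equal(fit$censored, "above_max")
  expect_equal(fit$ic50_rel, 30e-6)
  expect_equal(format_ic50(fit, unit = "uM"), "> 30.0000 uM")
  expect_error(ic50_ratio(fit, 1e-9), class = "effluxr_error_domain")
})

test_that("replicates are averaged at the T/C level before fitting", {
  conc <- 10^seq(-10, -7, length.out = 6)
  tc <- four_pl(conc, 1, 0, 2e-9, 1)
  dup <- tibble::tibble(
    conc = rep(conc, 2),
    tc = c(tc + 0.05, tc - 0.05) # duplicates symmetric about the true curve
  )
  fit <- fit_dose_response(dup)
  expect_equal(fit$ic50_rel, 2e-9, tolerance = 0.01)
})

test_that("ic50_ratio reproduces printed relative-resistance values", {
  pairs <- readr::read_csv(ref_path("reference_ic50_pairs.csv"),
    show_col_types = FALSE
  )
  fold <- purrr::map2_dbl(
    pairs$numerator_ic50_nM, pairs$denominator_ic50_nM,
    \(a, b) ic50_ratio(a, b)$fold
  )
  expect_equal(round(fold, 1), pairs$reported_fold)
})

test_that("ic50_ratio identities hold", {
  expect_equal(ic50_ratio(3.7e-9, 3.7e-9)$fold, 1)
  expect_equal(ic50_ratio(54.6, 1.3)$fold * ic50_ratio(1.3, 54.6)$fold, 1)
  expect_error(ic50_ratio(-1, 2), class = "effluxr_error_domain")
})

test_that("tidy/glance/predict methods are coherent", {
  plate <- gen_viability_plate(
    viability_truth(noise_cv = 0), conc_a = 10^seq(-10, -7, length.out = 8)
  )
  fit <- fit_dose_response(plate)
  td <- tidy(fit)
  expect_equal(td$term, c("top", "bottom", "ic50_rel", "hill"))
  gl <- glance(fit)
  expect_equal(gl$ic50_rel_nM, fit$ic50_rel * 1e9)
  expect_equal(predict(fit, fit$ic50_rel), (fit$top + fit$bottom) / 2,
    tolerance = 1e-6
  )
})
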