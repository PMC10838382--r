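test_that("bliss_neutral multiplies fractions unaffected", {
  expect_equal(bliss_neutral(0.5, 0.5), 0.25)
  expect_equal(bliss_neutral(1.0, 0.37), 0.37) # inactive partner
  expect_equal(bliss_neutral(0.9, 0.6), 0.54)
  expect_error(bliss_neutral(-0.1, 0.5), class = "effluxr_error_domain")
})

test_that("bliss_index is expectation minus observation", {
  expect_equal(bliss_index(0.42, 0.42), 0) # exactly multiplicative
  expect_equal(bliss_index(0.54, 0.30), 0.24)
  expect_equal(bliss_index(0.54, 0.80), -0.26)
})

test_that("modeled_tc averages replicates; clipping is display-only", {
  expect_equal(modeled_tc(c(0.4, 0.6)), 0.5)
  expect_equal(modeled_tc(c(0.32, 0.28, 0.30)), 0.30)
  expect_equal(modeled_tc(1.1), 1.1) # stimulation retained
  expect_equal(clip_tc(1.1), 1.0) # ... but clipped for display
  expect_error(modeled_tc(numeric(0)), class = "effluxr_error_domain")
})

make_grid <- function(e1, e2, combo) {
  m <- matrix(NA_real_, length(e1) + 1, length(e2) + 1,
    dimnames = list(c(0, seq_along(e1)), c(0, seq_along(e2)))
  )
  m[1, 1] <- 1
  m[-1, 1] <- e1
  m[1, -1] <- e2
  m[-1, -1] <- combo
  m
}

test_that("an exactly multiplicative checkerboard scores BI = 0 and additive", {
  e1 <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  e2 <- c(0.95, 0.8, 0.6, 0.45, 0.3)
  res <- analyze_bliss(make_grid(e1, e2, outer(e1, e2)))
  expect_true(all(res$index[-1, -1] == 0))
  expect_equal(res$call, "additive")
  expect_equal(res$counts[["n_total"]], 25)
  expect_equal(res$counts[["n_neutral"]], 25)
})

test_that("flag counts drive the assay call, with >= ties flagged", {
  e1 <- rep(0.8, 5)
  e2 <- rep(0.8, 5)
  combo <- outer(e1, e2)
  combo[1, 1:3] <- combo[1, 1:3] - 0.15 # exactly at threshold: flagged
  res <- analyze_bliss(make_grid(e1, e2, combo))
  expect_equal(res$counts[["n_synergy"]], 3)
  expect_equal(res$call, "slight_synergy")

  combo[1, 4] <- combo[1, 4] - 0.2
  expect_equal(analyze_bliss(make_grid(e1, e2, combo))$call, "synergy")

  combo2 <- outer(e1, e2)
  combo2[2, 1:4] <- combo2[2, 1:4] + 0.3
  expect_equal(analyze_bliss(make_grid(e1, e2, combo2))$call, "antagonism")
})

test_that("classify_combination implements the generalized count rules", {
  expect_equal(classify_combination(4, 0, 25), "synergy")
  expect_equal(classify_combination(3, 0, 25), "slight_synergy")
  expect_equal(classify_combination(0, 4, 25), "antagonism")
  expect_equal(classify_combination(0, 3, 25), "slight_antagonism")
  expect_equal(classify_combination(0, 0, 25), "additive")
  expect_equal(classify_combination(2, 2, 25), "additive")
  expect_equal(classify_combination(4, 4, 25), "mixed")
  expect_equal(classify_combination(3, 3, 25), "mixed")
  # 8 x 2 grids: k = ceiling(0.12 * 16) = 2
  expect_equal(classify_combination(3, 0, 16), "synergy")
  expect_equal(classify_combination(2, 0, 16), "slight_synergy")
  expect_equal(classify_combination(1, 1, 16), "additive")
  expect_error(classify_combination(0, 0, 0), class = "effluxr_error_domain")
  expect_error(classify_combination(20, 10, 25), class = "effluxr_error_domain")
})

test_that("analysis is invariant to transposing the checkerboard", {
  plate <- gen_viability_plate(
    viability_truth(efflux_e = 30, ki = 5e-6, noise_cv = 0.05),
    conc_a = doc_grid_m, conc_b = rit_grid_m, seed = 77
  )
  res <- analyze_bliss(plate)
  res_t <- analyze_bliss(t(res$tc))
  expect_equal(res_t$index, t(res$index))
  expect_equal(res_t$counts, res$counts)
  expect_equal(res_t$call, res$call)
})

test_that("a checkerboard without its single-agent margin is a structural error", {
  m <- matrix(0.5, 3, 3, dimnames = list(c(1, 2, 3), c(0, 1, 2)))
  expect_error(analyze_bliss(m), class = "effluxr_error_schema")
})

test_that("T/C grids round-trip through CSV with bitwise-identical BI", {
  plate <- gen_viability_plate(
    viability_truth(efflux_e = 21.3, noise_cv = 0.1),
    conc_a = doc_grid_m, conc_b = rit_grid_m, seed = 3
  )
  res <- analyze_bliss(plate)
  m <- effluxr:::as_tc_matrix_from_result(res)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tc_matrix(m, path)
  res2 <- analyze_bliss(read_tc_matrix(path))
  expect_identical(res2$index, res$index)
  expect_identical(res2$call, res$call)
})

test_that("stimulation above 1 enters the expectation unclipped", {
  e1 <- c(1.1, 0.5)
  e2 <- c(0.9, 0.4)
  combo <- outer(e1, e2)
  res <- analyze_bliss(make_grid(e1, e2, combo))
  expect_equal(res$neutral["1", "1"], 1.1 * 0.9)
  expect_true(all(res$index[-1, -1] == 0))
  expect_equal(max(res$tc_display), 1)
})

test_that("tidy and glance expose the grid and the call", {
  plate <- gen_viability_plate(
    viability_truth(efflux_e = 30, noise_cv = 0.05),
    conc_a = doc_grid_m, conc_b = rit_grid_m, seed = 5
  )
  res <- analyze_bliss(plate)
  td <- tidy(res)
  expect_equal(nrow(td), 25)
  expect_equal(td$index, td$e1 * td$e2 - td$tc)
  gl <- glance(res)
  expect_equal(
    gl$n_synergy + gl$n_antagonism + gl$n_neutral, gl$n_total
  )
})
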