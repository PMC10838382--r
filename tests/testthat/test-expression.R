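test_that("log_cpm matches its closed form and scale behavior", {
  counts <- matrix(c(100, 900, 200, 1800), nrow = 2,
    dimnames = list(c("g1", "g2"), c("s1", "s2"))
  )
  lc <- log_cpm(counts, pseudocount = 0.5)
  expect_equal(lc["g1", "s1"], log2(1e6 * 100.5 / 1001))
  # proportional samples are identical columns at pseudocount 0
  lc0 <- log_cpm(counts, pseudocount = 0)
  expect_equal(lc0[, "s1"], lc0[, "s2"])
  expect_error(
    log_cpm(matrix(0, 2, 2)), class = "effluxr_error_domain"
  )
  expect_error(
    log_cpm(matrix(-1, 2, 2)), class = "effluxr_error_domain"
  )
})

test_that("bh_adjust is the BH step-up with monotonicity", {
  expect_equal(bh_adjust(0.031), 0.031)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "effluxr_error_domain")
  withr::with_seed(1, {
    p <- runif(200)
    q <- bh_adjust(p)
    expect_true(all(q >= p)) # q >= p gene-wise under BH
    expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in sorted order
    # a fully flattened adjustment is a fixed point
    expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
  })
})

test_that("two_group_test agrees with the per-gene Welch oracle", {
  withr::with_seed(7, {
    x <- matrix(rnorm(40 * 6), nrow = 40)
    rownames(x) <- paste0("g", 1:40)
    groups <- rep(c("a", "b"), each = 3)
    res <- two_group_test(x, groups)
    for (i in c(1, 13, 40)) {
      tt <- t.test(x[i, 4:6], x[i, 1:3]) # Welch by default
      expect_equal(res$p_value[i], tt$p.value)
      expect_equal(res$log2_fc[i], unname(diff(rev(tt$estimate))))
    }
  })
})

test_that("identical groups give fold 1 and p near 1", {
  x <- matrix(rep(c(5, 6, 7, 5, 6, 7), times = 3), nrow = 3, byrow = TRUE)
  res <- two_group_test(x, rep(c("a", "b"), each = 3))
  expect_equal(res$fold_change, rep(1, 3))
  expect_true(all(res$p_value > 0.99))
  # genes constant within both groups get the variance floor, with a note
  xc <- matrix(5, nrow = 2, ncol = 6)
  expect_message(
    resc <- two_group_test(xc, rep(c("a", "b"), each = 3)),
    "variance floor"
  )
  expect_equal(resc$p_value, rep(1, 2))
})

test_that("deg_filter applies the fold AND FDR conjunction", {
  stats <- tibble::tibble(
    gene = c("ABCB1", "nearmiss_fold", "nearmiss_fdr", "down"),
    log2_fc = c(log2(3287), log2(1.9), 2, -3),
    p_value = c(1e-12, 0.001, 0.06, 1e-4)
  )
  out <- deg_filter(stats |> dplyr::mutate(q_value = p_value))
  expect_true(out$is_deg[out$gene == "ABCB1"])
  expect_false(out$is_deg[out$gene == "nearmiss_fold"]) # fold threshold
  expect_false(out$is_deg[out$gene == "nearmiss_fdr"]) # FDR threshold
  expect_true(out$is_deg[out$gene == "down"]) # symmetric for down-regulation
  expect_equal(out$gene[1], "ABCB1") # DEGs ordered by |fold|
  expect_error(
    deg_filter(tibble::tibble(gene = "g")), class = "effluxr_error_schema"
  )
})

test_that("Welch power at the DEG thresholds is >= 95% for an 8-fold shift", {
  # per-gene power simulation: 3 vs 3 counts, NB dispersion 0.05, true 8-fold
  hits <- vapply(1:200, function(s) {
    withr::with_seed(1000 + s, {
      x <- matrix(
        log2(1 + rnbinom(6, mu = rep(c(200, 1600), each = 3), size = 1 / 0.05)),
        nrow = 1
      )
      r <- two_group_test(x, rep(c("ctrl", "case"), each = 3))
      r$p_value < 0.05 && abs(r$log2_fc) >= 1
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("outlier statistics behave on degenerate identical samples", {
  x <- matrix(rep(c(1, 5, 9, 2, 7, 3), times = 4), nrow = 6,
    dimnames = list(NULL, paste0("s", 1:4))
  )
  res <- outlier_stats(x)
  expect_equal(res$sum_euclidean, rep(0, 4))
  expect_equal(res$mean_pearson, rep(1, 4))
  expect_equal(res$ks_stat, rep(0, 4))
  expect_false(any(res$flagged))
  expect_error(outlier_stats(x[, 1:2]), class = "effluxr_error_domain")
})

test_that("a clean triplicate study design yields zero outlier flags", {
  for (s in c(101, 202, 303)) {
    cnt <- gen_counts(
      counts_truth(),
      groups = rep(c("lineA_parental", "lineA_resistant",
                     "lineB_parental", "lineB_resistant"), each = 3),
      seed = s
    )
    qc <- outlier_stats(log_cpm(cnt))
    expect_equal(sum(qc$flagged), 0)
  }
})

test_that("a permuted sample is flagged by correlation and Hoeffding criteria", {
  cnt <- gen_counts(counts_truth(), seed = 31)
  lc <- log_cpm(cnt)
  lc[, 4] <- withr::with_seed(99, sample(lc[, 4]))
  qc <- outlier_stats(lc)
  expect_true(qc$flagged[4])
  expect_match(qc$reason[4], "mean_pearson")
  expect_match(qc$reason[4], "hoeffding_d")
  expect_equal(sum(qc$flagged), 1)
})

test_that("outlier flags are invariant to gene and sample reordering", {
  cnt <- gen_counts(counts_truth(), seed = 13)
  lc <- log_cpm(cnt)
  lc[, 2] <- withr::with_seed(5, sample(lc[, 2]))
  qc <- outlier_stats(lc)
  withr::with_seed(8, {
    gperm <- sample(nrow(lc))
    sperm <- sample(ncol(lc))
  })
  qc_g <- outlier_stats(lc[gperm, ])
  expect_equal(qc_g$flagged, qc$flagged)
  expect_equal(qc_g$sum_euclidean, qc$sum_euclidean)
  qc_s <- outlier_stats(lc[, sperm])
  expect_equal(qc_s$flagged[order(sperm)], qc$flagged)
})

test_that("null data produce (almost) no DEGs", {
  for (s in 1:10) {
    cnt <- gen_counts(counts_truth(de = tibble::tibble()), seed = 4000 + s)
    deg <- deg_screen(cnt, groups = sub("_[0-9]+$", "", sample_sheet(cnt)$sample))
    expect_lte(mean(deg$is_deg), 0.05)
  }
})

test_that("the transporter-like gene is the top-fold DEG across seeds", {
  for (s in 1:10) {
    cnt <- gen_counts(counts_truth(), seed = 600 + s)
    deg <- deg_screen(cnt, groups = sub("_[0-9]+$", "", sample_sheet(cnt)$sample))
    expect_true(deg$is_deg[deg$gene == "ABCB1like"])
    expect_equal(deg$gene[1], "ABCB1like")
    degs <- deg[deg$is_deg, ]
    expect_equal(degs$gene[which.max(abs(degs$log2_fc))], "ABCB1like")
  }
})
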