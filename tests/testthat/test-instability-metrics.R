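test_that("GC correction removes planted bias and normalizes length", {
  # bias-free, equal-length bins: correction is a near-no-op
  bp <- make_cohort(seed = 61, n_bins = 60, gc_bias = 0, dispersion = 0.01)
  raw <- bp$counts[, 1]
  corr <- gc_correct_and_normalize(bp$panel, raw)
  expect_lt(stats::median(abs(corr - raw) / raw), 0.1)

  # bins of length 100 and 200 with identical per-base coverage equalize
  panel <- generate_panel(n_bins = 10, bin_length = 100, seed = 62)
  panel$bins$end <- panel$bins$start + rep(c(100L, 200L), 5)
  panel$exonic_base_total <- sum(panel$bins$end - panel$bins$start)
  counts <- (panel$bins$end - panel$bins$start) * 3 # 3 reads per base
  corr2 <- gc_correct_and_normalize(panel, counts)
  expect_equal(stats::sd(corr2), 0, tolerance = 1e-9)

  # planted GC bias: the GC association shrinks
  bp3 <- make_cohort(seed = 63, n_bins = 80, gc_bias = 4, dispersion = 0.01)
  raw3 <- bp3$counts[, 1]
  corr3 <- gc_correct_and_normalize(bp3$panel, raw3)
  rho_raw <- abs(stats::cor(raw3, bp3$panel$bins$gc_fraction, method = "spearman"))
  rho_corr <- abs(stats::cor(corr3, bp3$panel$bins$gc_fraction, method = "spearman"))
  expect_lt(rho_corr, rho_raw)

  expect_error(gc_correct_and_normalize(bp$panel, rep(0, 60)), "all-zero")
  small <- generate_panel(n_bins = 5, bin_length = 100, seed = 1)
  expect_error(gc_correct_and_normalize(small, 1:5), "8 bins")
})

test_that("log2 ratios behave as the identity/doubling/quartering arithmetic", {
  base <- rep(1, 10)
  expect_equal(as.vector(compute_log2_ratios(rep(5, 10), base, center = FALSE)) -
                 log2(5), rep(0, 10))
  expect_equal(as.vector(compute_log2_ratios(base, base, center = FALSE)),
               rep(0, 10))
  x <- base; x[3] <- 2
  expect_equal(compute_log2_ratios(x, base, center = FALSE)[3], 1)
  x[3] <- 1 / 4
  expect_equal(compute_log2_ratios(x, base, center = FALSE)[3], -2)

  # zero baseline bins are masked and reported
  b2 <- base; b2[c(2, 7)] <- 0
  expect_warning(r <- compute_log2_ratios(x, b2, center = FALSE), "masked")
  expect_identical(attr(r, "masked_bins"), c(2L, 7L))
  expect_true(all(is.na(r[c(2, 7)])))
})

test_that("compute_cni matches the brute-force oracle to 1e-9", {
  for (seed in 1:4) {
    set.seed(seed)
    n_bins <- 20; n_base <- 10
    baseline <- matrix(rnorm(n_bins * n_base, 0, 0.2), n_bins)
    sample_r <- rnorm(n_bins, 0, 0.2)
    sample_r[1:3] <- sample_r[1:3] + 2 # supra-threshold gains
    got <- compute_cni(sample_r, baseline)
    want <- brute_cni(sample_r, baseline)
    expect_equal(got$cni, want$cni, tolerance = 1e-9)
    expect_identical(got$unstable_bins, want$unstable)
    expect_equal(got$threshold, want$threshold, tolerance = 1e-9)
    expect_equal(got$z_scores, want$z, tolerance = 1e-9)
  }
})

test_that("CNI is ~0 on null samples and monotone in added unstable bins", {
  bp <- make_cohort(seed = 71, n_bins = 40, n_baseline = 10, n_test = 0,
                    dispersion = 0.01)
  corrected <- gc_correct_and_normalize(bp$panel, bp$counts)
  ref <- baseline_reference(corrected)
  ratios <- vapply(seq_len(ncol(corrected)),
                   function(j) compute_log2_ratios(corrected[, j], ref),
                   numeric(40))
  # held-out-like null samples: median CNI over the baseline cohort below T
  cnis <- vapply(seq_len(ncol(ratios)), function(j) {
    compute_cni(ratios[, j], ratios[, -j])$cni
  }, numeric(1))
  thr <- compute_cni(ratios[, 1], ratios[, -1])$threshold
  expect_lt(stats::median(cnis), thr)

  # adding a second amplified bin never decreases CNI
  r <- ratios[, 1]
  base <- ratios[, -1]
  one <- r; one[5] <- 10
  two <- one; two[9] <- 10
  expect_gte(compute_cni(two, base)$cni, compute_cni(one, base)$cni)
  # and an injected z = 10 bin contributes ~10 when alone above threshold
  z5 <- compute_cni(one, base)
  if (length(z5$unstable_bins) == 1L) {
    expect_equal(z5$cni, z5$z_scores[5], tolerance = 1e-9)
  }
})

test_that("degenerate baseline bins are masked with a warning", {
  baseline <- matrix(rnorm(40, 0, 0.1), 10)
  baseline[4, ] <- 0.3 # zero SD row
  expect_warning(res <- compute_cni(rnorm(10), baseline), "masked")
  expect_true(4L %in% res$masked_bins)
  expect_true(is.na(res$z_scores[4]))
})

test_that("MATH follows the printed formula, inclusion window and conventions", {
  expect_identical(compute_math(c(0.2, 0.2, 0.2)), 0)
  # median 0.2, MAD 0.1 -> 0.5 under the literal convention
  expect_equal(compute_math(c(0.10, 0.20, 0.40)), 0.5)
  # 1.5% VAF excluded by the 2% floor: same result
  expect_equal(compute_math(c(0.015, 0.10, 0.20, 0.40)), 0.5)
  # consistency-constant convention of the MATH literature
  expect_equal(compute_math(c(0.10, 0.20, 0.40), convention = "mroz"),
               100 * 1.4826 * 0.5)
  # scale invariance for c within (0, 1/max]
  v <- c(0.04, 0.1, 0.3, 0.5)
  expect_equal(compute_math(v), compute_math(v * 1.8))
  # no VAF in window: undefined, not zero
  expect_warning(res <- compute_math(c(0.001, 0.005)), "undefined")
  expect_true(is.na(res))
  expect_error(compute_math(c(0.5, 1.2)), "VAFs")
})

test_that("TMB is the exact linear formula", {
  expect_identical(compute_tmb(30, 1.5e6), 20)
  expect_identical(compute_tmb(0, 123), 0)
  expect_identical(compute_tmb(7, 1e6), 7)
  # linear in count, inverse in panel size
  expect_identical(compute_tmb(14, 1e6), 2 * compute_tmb(7, 1e6))
  expect_identical(compute_tmb(7, 2e6), compute_tmb(7, 1e6) / 2)
  expect_error(compute_tmb(5, 0), "exonic_base_total")
})

test_that("Mann-Whitney wrapper matches exact enumeration and flags direction", {
  r <- compare_groups_mannwhitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(unname(r$u), 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$p, enum_mannwhitney_p(c(1, 2, 3), c(4, 5, 6)))
  expect_identical(r$larger, "b")

  same <- compare_groups_mannwhitney(c(1, 2), c(1, 2))
  expect_equal(same$p, 1, tolerance = 1e-6)
  expect_identical(same$larger, "tie")

  # shifting one group up cannot decrease its rank-sum (U of a grows)
  a <- c(2, 5, 9); b <- c(1, 4, 7)
  u1 <- compare_groups_mannwhitney(a, b)$u
  u2 <- compare_groups_mannwhitney(a + 10, b)$u
  expect_gte(u2, u1)
  expect_error(compare_groups_mannwhitney(numeric(0), 1), "non-empty")
})

test_that("CNI separates event-carrying samples from event-free ones", {
  # 8 "better" samples with recurrent multi-bin gains vs 8 "poor" without
  n_rep <- 100
  hits <- vapply(seq_len(n_rep), function(i) {
    panel <- generate_panel(n_bins = 40, bin_length = 200, seed = i)
    ev <- do.call(rbind, lapply(1:8, function(k) {
      data.frame(sample = sprintf("test_%02d", k), chrom = "chr1",
                 start = panel$bins$start[10], end = panel$bins$end[15],
                 multiplier = 2)
    }))
    bp <- generate_bin_counts(panel, n_baseline = 8, n_test = 16,
                              cnv_events = ev, depth_mean = 300,
                              dispersion = 0.02, seed = i + 5000L)
    met <- suppressWarnings(compute_instability_metrics(bp))
    p <- compare_groups_mannwhitney(met$cni[1:8], met$cni[9:16])$p
    p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
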