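# Fixtures and independent oracles used across test files.

# The six-call toy set: one violation of each elimination rule plus one
# clean plasma call (the only survivor under hand application of the rules).
toy_calls <- function() {
  data.frame(
    sample = "s1",
    sample_type = c("tumor", "tumor", "plasma", "plasma", "tumor", "plasma"),
    chrom = "chr1", pos = 1:6, ref = "A", alt = "T", gene = paste0("G", 1:6),
    functional_class = c("synonymous", "nonsynonymous", "nonsynonymous",
                         "nonsynonymous", "nonsynonymous", "nonsynonymous"),
    region_class = c("exonic", "intronic", "exonic", "exonic", "exonic", "exonic"),
    vaf = c(0.2, 0.2, 0.2, 0.2, 0.04, 0.02),
    support_reads = c(50L, 50L, 50L, 4L, 50L, 10L),
    population_af = c(0, 0, 0.003, 0, 0, 0),
    strand_bias = FALSE,
    stringsAsFactors = FALSE
  )
}

# Brute-force CNI oracle: direct enumeration of the per-bin baseline
# moments, the pooled-Z threshold and the unstable-bin sum. Shares no code
# with compute_cni().
brute_cni <- function(sample_ratios, baseline_ratios, percentile = 0.95,
                      sd_mult = 2) {
  n_bins <- length(sample_ratios)
  mu <- sdv <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    row <- baseline_ratios[b, ]
    mu[b] <- sum(row) / length(row)
    sdv[b] <- sqrt(sum((row - mu[b])^2) / (length(row) - 1))
  }
  z <- (sample_ratios - mu) / sdv
  pool <- c()
  for (j in seq_len(ncol(baseline_ratios))) {
    pool <- c(pool, (baseline_ratios[, j] - mu) / sdv)
  }
  thr <- as.numeric(stats::quantile(pool, percentile)) + sd_mult * stats::sd(pool)
  unstable <- which(z > thr)
  list(cni = if (length(unstable)) sum(z[unstable]) else 0,
       unstable = unstable, threshold = thr, z = z)
}

# Exact Mann-Whitney two-sided p by enumeration of all labelings (small n,
# no ties); used to validate the wrapped rank-sum test.
enum_mannwhitney_p <- function(a, b) {
  x <- c(a, b)
  n <- length(x); na <- length(a)
  u_of <- function(idx) {
    aa <- x[idx]; bb <- x[-idx]
    sum(outer(aa, bb, ">"))
  }
  obs <- u_of(seq_len(na))
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, u_of)
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(obs - mu))
}

# Eigen-decomposition PCA oracle on the sample covariance; independent of
# prcomp's SVD route.
eigen_pca_scores <- function(x, k = 2) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  vec <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  list(scores = xc %*% vec, values = ev$values[seq_len(k)], vectors = vec)
}

# Small seeded cohort helper used by several property tests.
make_cohort <- function(seed, n_bins = 40, n_baseline = 8, n_test = 4,
                        events = NULL, gc_bias = 0, depth = 300,
                        dispersion = 0.02) {
  panel <- generate_panel(n_bins = n_bins, bin_length = 200, seed = seed)
  generate_bin_counts(panel, n_baseline, n_test, cnv_events = events,
                      gc_bias_strength = gc_bias, depth_mean = depth,
                      dispersion = dispersion, seed = seed + 1000L)
}
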