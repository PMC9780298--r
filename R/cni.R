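#' Per-bin baseline reference level from corrected baseline counts
#'
#' Each baseline sample is median-centered (divided by its own median
#' corrected count, so total depth cancels) and the reference level of a bin
#' is the mean of the centered values across baseline samples.
#'
#' @param corrected_baseline Bins x baseline-samples matrix of corrected
#'   counts (>= 2 columns).
#' @return Numeric vector of per-bin reference levels.
#' @export
baseline_reference <- function(corrected_baseline) {
  corrected_baseline <- as.matrix(corrected_baseline)
  if (ncol(corrected_baseline) < 2L) {
    stop("the baseline cohort needs at least 2 samples", call. = FALSE)
  }
  centered <- sweep(corrected_baseline, 2,
                    apply(corrected_baseline, 2, stats::median), "/")
  rowMeans(centered)
}

#' Transform corrected counts into log2 copy ratios against a baseline
#'
#' The sample is median-centered (divided by its median corrected count) and
#' each bin's ratio is `log2(centered / baseline)`. A sample identical to
#' the baseline therefore gives ratios of 0 everywhere. Bins whose baseline
#' level is zero (or not finite) are masked as `NA` and reported in the
#' `masked_bins` attribute.
#'
#' @param corrected Numeric vector of corrected counts for one sample.
#' @param baseline Per-bin reference level, e.g. from [baseline_reference()].
#' @param center Median-center the sample first (default TRUE).
#' @return Numeric vector of log2 ratios with attribute `masked_bins`.
#' @export
compute_log2_ratios <- function(corrected, baseline, center = TRUE) {
  if (length(corrected) != length(baseline)) {
    stop("sample and baseline vectors are not congruent", call. = FALSE)
  }
  x <- if (center) corrected / stats::median(corrected) else corrected
  masked <- which(!is.finite(baseline) | baseline <= 0)
  ratio <- rep(NA_real_, length(x))
  ok <- setdiff(seq_along(x), masked)
  ratio[ok] <- log2(x[ok] / baseline[ok])
  if (length(masked) > 0L) {
    warning(length(masked), " bin(s) masked: zero or undefined baseline level",
            call. = FALSE)
  }
  attr(ratio, "masked_bins") <- masked
  ratio
}

#' Copy-number instability (CNI) score of one sample
#'
#' Each bin's log2 ratio is standardized against the baseline cohort
#' (`z(b) = (ratio(b) - mean_b) / sd_b`, with mean and SD taken over the
#' baseline samples' ratios at that bin). The unstable-region threshold is
#' derived from the pooled baseline Z distribution:
#' `T = quantile(pool, percentile) + sd_mult * sd(pool)` (default the 95th
#' percentile plus twice the standard deviation). Bins with `z > T` are the
#' unstable regions and the CNI score is the sum of their Z-scores (0 when
#' the set is empty, so CNI is always >= 0 under the one-sided default).
#'
#' @param sample_ratios Log2-ratio vector of the test sample.
#' @param baseline_ratios Bins x baseline-samples matrix of log2 ratios
#'   (>= 2 columns).
#' @param percentile Pool quantile used by the threshold (default 0.95).
#' @param sd_mult Multiplier of the pool SD (default 2).
#' @param two_sided If TRUE, bins with `|z| > T` count and `|z|` is summed;
#'   the one-sided (gain) rule is the default.
#' @param threshold_scope `"baseline_pool"` (default) computes T from the
#'   pooled baseline Z values; `"per_sample"` from the test sample's own Z
#'   vector.
#' @return A list: `cni`, `unstable_bins` (integer indices), `z_scores`,
#'   `threshold`, and `masked_bins` (bins with degenerate baseline SD,
#'   dropped with a warning).
#' @export
compute_cni <- function(sample_ratios, baseline_ratios, percentile = 0.95,
                        sd_mult = 2, two_sided = FALSE,
                        threshold_scope = c("baseline_pool", "per_sample")) {
  threshold_scope <- match.arg(threshold_scope)
  baseline_ratios <- as.matrix(baseline_ratios)
  if (ncol(baseline_ratios) < 2L) {
    stop("the baseline cohort needs at least 2 samples", call. = FALSE)
  }
  if (length(sample_ratios) != nrow(baseline_ratios)) {
    stop("sample and baseline bin vectors are not congruent", call. = FALSE)
  }
  mu <- rowMeans(baseline_ratios)
  sd_b <- apply(baseline_ratios, 1, stats::sd)
  masked <- which(!is.finite(sd_b) | sd_b == 0 | !is.finite(mu) |
                    !is.finite(sample_ratios))
  if (length(masked) > 0L) {
    warning(length(masked),
            " bin(s) masked in CNI: degenerate baseline (zero/undefined SD)",
            call. = FALSE)
  }
  ok <- setdiff(seq_along(sample_ratios), masked)
  z <- rep(NA_real_, length(sample_ratios))
  z[ok] <- (sample_ratios[ok] - mu[ok]) / sd_b[ok]

  pool <- if (threshold_scope == "baseline_pool") {
    zb <- (baseline_ratios[ok, , drop = FALSE] - mu[ok]) / sd_b[ok]
    as.vector(zb)
  } else {
    z[ok]
  }
  threshold <- stats::quantile(pool, percentile, names = FALSE) +
    sd_mult * stats::sd(pool)

  crit <- if (two_sided) abs(z) else z
  unstable <- which(!is.na(crit) & crit > threshold)
  cni <- if (length(unstable) == 0L) 0 else sum(crit[unstable])

  list(cni = cni, unstable_bins = unstable, z_scores = z,
       threshold = threshold, masked_bins = masked)
}
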