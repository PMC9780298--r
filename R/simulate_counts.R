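#' Simulate per-bin read counts for a baseline cohort and test samples
#'
#' Per sample and bin, the expected count is
#' `depth_mean * length_factor * gc_bias * copy_ratio`, where the length
#' factor is `bin length / mean bin length`, the GC bias is a smooth unimodal
#' curve peaking at GC = 0.5 (`exp(-gc_bias_strength * (gc - 0.5)^2)`), and
#' the copy ratio is the multiplier of any injected CNV event covering the
#' bin (1 when none). Counts are drawn from a negative binomial with the
#' given dispersion; `dispersion = 0` selects Poisson. Baseline samples never
#' carry events.
#'
#' @param panel A `panel_design` from [generate_panel()].
#' @param n_baseline Number of baseline (reference) samples; must be >= 2
#'   because the CNI Z-transformation needs a baseline cohort.
#' @param n_test Number of test samples.
#' @param cnv_events `NULL` or a data.frame with columns `sample`, `chrom`,
#'   `start`, `end`, `multiplier` (> 0; 1 encodes no event). Events must hit
#'   test samples and overlap panel bins; others are ignored with a warning
#'   and recorded in the truth.
#' @param gc_bias_strength Non-negative strength of the GC bias curve
#'   (0 disables it).
#' @param depth_mean Expected count for an average-length, unbiased,
#'   copy-neutral bin.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson.
#' @param seed Integer seed.
#'
#' @return A list of class `bin_profile_set`: `counts` (bins x samples integer
#'   matrix), `sample_info` (data.frame `sample`, `role` in
#'   \{baseline, test\}), `panel`, and `truth` (class `cohort_truth`) holding
#'   the applied `cnv_events`, ignored events, `expected` mean matrix and the
#'   seed.
#' @export
generate_bin_counts <- function(panel, n_baseline, n_test, cnv_events = NULL,
                                gc_bias_strength = 0, depth_mean = 200,
                                dispersion = 0.02, seed = 1L) {
  validate_panel(panel)
  assert_scalar_number(n_baseline, "n_baseline", lower = 2)
  assert_scalar_number(n_test, "n_test", lower = 0)
  assert_scalar_number(gc_bias_strength, "gc_bias_strength", lower = 0)
  assert_scalar_number(depth_mean, "depth_mean", lower = 0, strict_lower = TRUE)
  assert_scalar_number(dispersion, "dispersion", lower = 0)

  bins <- panel$bins
  n_bins <- nrow(bins)
  samples <- c(sprintf("baseline_%02d", seq_len(n_baseline)),
               sprintf("test_%02d", seq_len(n_test)))
  role <- rep(c("baseline", "test"), c(n_baseline, n_test))

  len <- bins$end - bins$start
  length_factor <- len / mean(len)
  gc_factor <- exp(-gc_bias_strength * (bins$gc_fraction - 0.5)^2)

  mult <- matrix(1, n_bins, length(samples), dimnames = list(NULL, samples))
  applied <- ignored <- NULL
  if (!is.null(cnv_events) && nrow(cnv_events) > 0L) {
    need <- c("sample", "chrom", "start", "end", "multiplier")
    if (!all(need %in% names(cnv_events))) {
      stop("cnv_events needs columns: ", paste(need, collapse = ", "), call. = FALSE)
    }
    if (any(cnv_events$multiplier <= 0)) {
      stop("cnv_events$multiplier must be > 0", call. = FALSE)
    }
    ok <- logical(nrow(cnv_events))
    for (i in seq_len(nrow(cnv_events))) {
      ev <- cnv_events[i, ]
      hit <- which(bins$chrom == ev$chrom & bins$start < ev$end & bins$end > ev$start)
      if (!ev$sample %in% samples[role == "test"] || length(hit) == 0L) {
        warning(sprintf("CNV event %d (%s:%s-%s in %s) is off-panel or targets a non-test sample; ignored",
                        i, ev$chrom, ev$start, ev$end, ev$sample), call. = FALSE)
        next
      }
      mult[hit, ev$sample] <- mult[hit, ev$sample] * ev$multiplier
      ok[i] <- TRUE
    }
    applied <- cnv_events[ok, , drop = FALSE]
    ignored <- cnv_events[!ok, , drop = FALSE]
  }

  mu <- (depth_mean * length_factor * gc_factor) * mult
  counts <- with_seed(seed, {
    if (dispersion == 0) {
      matrix(stats::rpois(length(mu), lambda = mu), n_bins)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion), n_bins)
    }
  })
  dimnames(counts) <- list(NULL, samples)

  truth <- structure(
    list(cnv_events = applied, ignored_events = ignored, expected = mu,
         gc_bias_strength = gc_bias_strength, depth_mean = depth_mean,
         dispersion = dispersion, seed = seed),
    class = "cohort_truth"
  )
  structure(
    list(counts = counts,
         sample_info = data.frame(sample = samples, role = role,
                                  stringsAsFactors = FALSE),
         panel = panel, truth = truth),
    class = "bin_profile_set"
  )
}

#' @export
print.bin_profile_set <- function(x, ...) {
  cat(sprintf("<bin_profile_set> %d bins x %d samples (%d baseline, %d test)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$sample_info$role == "baseline"),
              sum(x$sample_info$role == "test")))
  invisible(x)
}
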