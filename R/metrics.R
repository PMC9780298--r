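#' Mutant-allele tumor heterogeneity (MATH)
#'
#' VAFs are restricted to the inclusion window \[`lower`, `upper`\] (default
#' 2% to 100%, both bounds inclusive) and MATH is the median absolute
#' deviation of the included VAFs divided by their median. The default
#' convention is the literal ratio (`MAD/median`, with MAD the plain median
#' of absolute deviations); `convention = "mroz"` applies the 1.4826
#' Gaussian-consistency constant and the x100 percentage scale of the MATH
#' literature.
#'
#' @param vafs Numeric vector of variant allele frequencies in \[0, 1\].
#' @param convention `"literal"` (default) or `"mroz"`.
#' @param lower,upper Inclusion bounds on VAF (defaults 0.02 and 1).
#' @return MATH value (>= 0), or `NA_real_` with a warning when no VAF
#'   survives inclusion (undefined, not 0).
#' @export
#' @examples
#' compute_math(c(0.10, 0.20, 0.40)) # 0.5
compute_math <- function(vafs, convention = c("literal", "mroz"),
                         lower = 0.02, upper = 1) {
  convention <- match.arg(convention)
  if (any(vafs < 0 | vafs > 1, na.rm = TRUE)) {
    stop("VAFs must lie in [0, 1]", call. = FALSE)
  }
  v <- vafs[!is.na(vafs) & vafs >= lower & vafs <= upper]
  if (length(v) == 0L) {
    warning("no VAF inside the inclusion window; MATH undefined", call. = FALSE)
    return(NA_real_)
  }
  med <- stats::median(v)
  mad0 <- stats::median(abs(v - med))
  scale <- if (convention == "mroz") 1.4826 * 100 else 1
  scale * mad0 / med
}

#' Tumor mutational burden (TMB)
#'
#' `TMB = mutation_count * 1e6 / exonic_base_total`, in mutations per
#' megabase of the sequenced panel. The numerator is the post-filter somatic
#' mutation count.
#'
#' @param mutation_count Non-negative integer count of somatic mutations.
#' @param exonic_base_total Positive panel size in bases.
#' @return TMB in mutations/Mb.
#' @export
#' @examples
#' compute_tmb(30, 1.5e6) # 20
compute_tmb <- function(mutation_count, exonic_base_total) {
  assert_scalar_number(mutation_count, "mutation_count", lower = 0)
  assert_scalar_number(exonic_base_total, "exonic_base_total",
                       lower = 0, strict_lower = TRUE)
  mutation_count * 1e6 / exonic_base_total
}

#' Mann-Whitney U comparison of a metric between two groups
#'
#' Wraps the two-sided Wilcoxon rank-sum test: exact enumeration when both
#' groups are small and tie-free, normal approximation with tie correction
#' otherwise.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return A list: `u` (the U statistic of group A), `p` (two-sided),
#'   `larger` ("a", "b" or "tie" by mean rank).
#' @export
compare_groups_mannwhitney <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- any(duplicated(c(values_a, values_b)))
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = !ties, correct = ties)
  )
  ra <- mean(rank(c(values_a, values_b))[seq_along(values_a)])
  rb <- mean(rank(c(values_a, values_b))[-seq_along(values_a)])
  list(u = unname(wt$statistic), p = wt$p.value,
       larger = if (ra > rb) "a" else if (rb > ra) "b" else "tie")
}

#' Per-sample instability metrics for a cohort
#'
#' Convenience wrapper running the full CNI/MATH/TMB pipeline on a
#' `bin_profile_set` and a filtered variant table: GC correction and length
#' normalization, baseline reference and log2 ratios, per-sample CNI against
#' the baseline cohort, and MATH/TMB from each sample's retained calls.
#'
#' @param profiles A `bin_profile_set` (e.g. from [generate_bin_counts()]).
#' @param retained_calls Data.frame of retained variant calls (the
#'   `retained` element of a [filter_somatic()] report); may be empty.
#' @param window_frac Passed to [gc_correct_and_normalize()].
#' @param ... Passed to [compute_cni()].
#' @return A data.frame with one row per test sample: `sample`, `cni`,
#'   `n_unstable_bins`, `mutation_count`, `tmb`, `math`; the per-sample CNI
#'   details (Z traces, threshold) are attached as attribute `cni_details`.
#' @export
compute_instability_metrics <- function(profiles, retained_calls = NULL,
                                        window_frac = 0.3, ...) {
  stopifnot(inherits(profiles, "bin_profile_set"))
  info <- profiles$sample_info
  corrected <- gc_correct_and_normalize(profiles$panel, profiles$counts,
                                        window_frac = window_frac)
  base_cols <- info$sample[info$role == "baseline"]
  test_cols <- info$sample[info$role == "test"]
  ref <- baseline_reference(corrected[, base_cols, drop = FALSE])
  base_ratios <- vapply(base_cols, function(s) {
    compute_log2_ratios(corrected[, s], ref)
  }, numeric(nrow(corrected)))

  details <- list()
  rows <- lapply(test_cols, function(s) {
    lr <- compute_log2_ratios(corrected[, s], ref)
    cni <- compute_cni(lr, base_ratios, ...)
    details[[s]] <<- cni
    sv <- if (is.null(retained_calls) || nrow(retained_calls) == 0L) {
      data.frame(vaf = numeric(0))
    } else {
      retained_calls[retained_calls$sample == s, , drop = FALSE]
    }
    math <- if (nrow(sv) > 0L) suppressWarnings(compute_math(sv$vaf)) else NA_real_
    data.frame(
      sample = s, cni = cni$cni, n_unstable_bins = length(cni$unstable_bins),
      mutation_count = nrow(sv),
      tmb = compute_tmb(nrow(sv), profiles$panel$exonic_base_total),
      math = math, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cni_details") <- details
  out
}
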