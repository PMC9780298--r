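#' GC-content correction and target-length normalization of bin counts
#'
#' Raw per-bin read counts are divided by two multiplicative factors: a
#' target-length factor (`bin length / median bin length`) and a GC trend.
#' The trend is a rolling-median fit of count versus GC fraction (bins
#' ordered by GC, window a fraction of the bin count), rescaled to mean 1,
#' so the corrected counts keep the sample's depth scale while losing the
#' monotone/unimodal association with GC.
#'
#' @param panel A `panel_design`.
#' @param counts Numeric vector (one sample) or bins x samples matrix of raw
#'   counts, congruent with `panel$bins`.
#' @param window_frac Rolling-median window as a fraction of the number of
#'   bins (default 0.3).
#' @return Corrected counts with the same shape as `counts`.
#' @export
gc_correct_and_normalize <- function(panel, counts, window_frac = 0.3) {
  validate_panel(panel)
  bins <- panel$bins
  vec_in <- is.null(dim(counts))
  m <- if (vec_in) matrix(counts, ncol = 1) else as.matrix(counts)
  if (nrow(m) != nrow(bins)) {
    stop("counts are not congruent with the panel bin list", call. = FALSE)
  }
  if (nrow(bins) < 8L) stop("need at least 8 bins to fit the GC trend", call. = FALSE)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)

  k <- odd_window(nrow(bins), window_frac)
  if (k > nrow(bins)) {
    stop("fewer bins than the smoother window; reduce `window_frac`", call. = FALSE)
  }
  len <- bins$end - bins$start
  length_factor <- len / stats::median(len)
  ord <- order(bins$gc_fraction)

  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (all(x == 0)) stop("all-zero counts for sample column ", j, call. = FALSE)
    per_base <- x / length_factor
    trend <- numeric(length(x))
    trend[ord] <- stats::runmed(per_base[ord], k, endrule = "median")
    trend <- trend / mean(trend)
    # guard flat/zero stretches so division stays finite
    trend <- pmax(trend, 0.05)
    out[, j] <- per_base / trend
  }
  if (vec_in) drop(out) else out
}
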