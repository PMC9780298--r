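#' Generate a synthetic capture-panel design
#'
#' Emulates the target regions of a hybrid-capture gene panel: an ordered set
#' of non-overlapping exonic bins, each with a GC fraction and a gene label.
#' Coordinates are 0-based half-open, as in BED.
#'
#' @param n_bins Number of target bins (>= 1).
#' @param bin_length Length of each bin in bases (> 0).
#' @param gc_range Length-2 numeric interval within \[0, 1\] from which each
#'   bin's GC fraction is drawn uniformly.
#' @param bins_per_gene How many consecutive bins share a gene label
#'   (default 1: one gene per bin).
#' @param gap Fixed gap between consecutive bins, in bases.
#' @param seed Integer seed; identical seeds give identical panels.
#'
#' @return An object of class `panel_design`: a list with `bins` (data.frame
#'   with columns `chrom`, `start`, `end`, `gene`, `gc_fraction`) and
#'   `exonic_base_total` (sum of bin lengths, the denominator of TMB).
#' @export
#' @examples
#' p <- generate_panel(n_bins = 10, bin_length = 200, seed = 1)
#' p$exonic_base_total # 2000
generate_panel <- function(n_bins, bin_length = 200, gc_range = c(0.3, 0.7),
                           bins_per_gene = 1L, gap = 100L, seed = 1L) {
  assert_scalar_number(n_bins, "n_bins", lower = 1)
  assert_scalar_number(bin_length, "bin_length", lower = 0, strict_lower = TRUE)
  assert_scalar_number(bins_per_gene, "bins_per_gene", lower = 1)
  if (!is.numeric(gc_range) || length(gc_range) != 2L ||
      gc_range[1] > gc_range[2] || gc_range[1] < 0 || gc_range[2] > 1) {
    stop("`gc_range` must be an ordered interval within [0, 1]", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  bin_length <- as.integer(bin_length)

  gc <- with_seed(seed, stats::runif(n_bins, gc_range[1], gc_range[2]))
  start <- (seq_len(n_bins) - 1L) * (bin_length + as.integer(gap))
  gene_idx <- ceiling(seq_len(n_bins) / bins_per_gene)
  bins <- data.frame(
    chrom = "chr1",
    start = start,
    end = start + bin_length,
    gene = sprintf("G%03d", gene_idx),
    gc_fraction = gc,
    stringsAsFactors = FALSE
  )
  structure(
    list(bins = bins, exonic_base_total = sum(bins$end - bins$start)),
    class = "panel_design"
  )
}

#' Validate a panel design
#'
#' Checks the structural invariants of a `panel_design`: positive bin widths,
#' sorted non-overlapping bins per chromosome, GC fractions in \[0, 1\], and an
#' `exonic_base_total` equal to the summed bin lengths.
#'
#' @param panel A `panel_design`.
#' @return `panel` invisibly; stops on violation.
#' @export
validate_panel <- function(panel) {
  if (!inherits(panel, "panel_design")) stop("not a panel_design", call. = FALSE)
  b <- panel$bins
  if (any(b$start >= b$end)) stop("panel bins must satisfy start < end", call. = FALSE)
  if (any(b$gc_fraction < 0 | b$gc_fraction > 1)) {
    stop("gc_fraction must lie in [0, 1]", call. = FALSE)
  }
  for (ch in unique(b$chrom)) {
    sub <- b[b$chrom == ch, ]
    if (is.unsorted(sub$start)) stop("bins must be sorted by (chrom, start)", call. = FALSE)
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stop("bins must not overlap on a chromosome", call. = FALSE)
    }
  }
  if (panel$exonic_base_total != sum(b$end - b$start)) {
    stop("exonic_base_total does not equal the summed bin lengths", call. = FALSE)
  }
  invisible(panel)
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf("<panel_design> %d bins, %d exonic bases, %d genes\n",
              nrow(x$bins), x$exonic_base_total, length(unique(x$bins$gene))))
  invisible(x)
}

#' Write a panel (with optional count columns) as BED-like TSV
#'
#' @param panel A `panel_design`.
#' @param path Output path.
#' @param counts Optional bins-by-samples count matrix appended as columns.
#' @return `path` invisibly.
#' @export
write_panel_tsv <- function(panel, path, counts = NULL) {
  out <- panel$bins
  if (!is.null(counts)) {
    stopifnot(nrow(counts) == nrow(out))
    out <- cbind(out, as.data.frame(counts))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
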