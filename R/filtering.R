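#' Apply the three-step somatic-mutation elimination rules
#'
#' Variant calls are screened in a fixed order and each removal is attributed
#' to the first rule it violates:
#' \describe{
#'   \item{R1_annotation}{synonymous SNVs, or calls in intergenic/intronic
#'     regions.}
#'   \item{R2_population_af}{population allele frequency (max of ExAC/gnomAD
#'     fields) at or above `pop_af_max` (default 0.002).}
#'   \item{R3_quality}{strand bias, support reads below `min_support`
#'     (default 5), or VAF below the sample-type floor — `vaf_floor_tumor`
#'     (default 0.05) for tumor, `vaf_floor_plasma` (default 0.01) for
#'     plasma. Equality survives: the floors are strict `<` comparisons.}
#' }
#' Missing `population_af` is treated as 0 (absent from the population
#' databases means presumed rare).
#'
#' @param calls Data.frame of variant calls with the columns of
#'   [read_variant_table()]'s TSV dialect.
#' @param pop_af_max,min_support,vaf_floor_tumor,vaf_floor_plasma Rule
#'   thresholds (defaults as above).
#' @return An object of class `filter_report`: list with `retained` and
#'   `removed` data.frames (removed carries a `rule` column), and `counts`,
#'   a named integer vector of removals per rule.
#' @export
#' @examples
#' v <- data.frame(sample = "s1", sample_type = "tumor", chrom = "chr1",
#'                 pos = 100, ref = "A", alt = "T", gene = "TP53",
#'                 functional_class = "synonymous", region_class = "exonic",
#'                 vaf = 0.2, support_reads = 50, population_af = 0,
#'                 strand_bias = FALSE)
#' filter_somatic(v)$counts
filter_somatic <- function(calls, pop_af_max = 0.002, min_support = 5,
                           vaf_floor_tumor = 0.05, vaf_floor_plasma = 0.01) {
  calls <- validate_variant_calls(calls)

  floor_vaf <- ifelse(calls$sample_type == "tumor", vaf_floor_tumor, vaf_floor_plasma)
  pop_af <- ifelse(is.na(calls$population_af), 0, calls$population_af)

  r1 <- calls$region_class %in% c("intergenic", "intronic") |
    calls$functional_class == "synonymous"
  r2 <- !r1 & pop_af >= pop_af_max
  r3 <- !r1 & !r2 &
    (calls$strand_bias | calls$support_reads < min_support | calls$vaf < floor_vaf)

  rule <- rep(NA_character_, nrow(calls))
  rule[r3] <- "R3_quality"
  rule[r2] <- "R2_population_af"
  rule[r1] <- "R1_annotation"

  removed <- calls[!is.na(rule), , drop = FALSE]
  removed$rule <- rule[!is.na(rule)]
  retained <- calls[is.na(rule), , drop = FALSE]
  rownames(removed) <- rownames(retained) <- NULL

  counts <- vapply(c("R1_annotation", "R2_population_af", "R3_quality"),
                   function(r) sum(removed$rule == r), integer(1))
  structure(
    list(retained = retained, removed = removed, counts = counts,
         thresholds = list(pop_af_max = pop_af_max, min_support = min_support,
                           vaf_floor_tumor = vaf_floor_tumor,
                           vaf_floor_plasma = vaf_floor_plasma)),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d retained, %d removed (R1 %d, R2 %d, R3 %d)\n",
              nrow(x$retained), nrow(x$removed),
              x$counts[["R1_annotation"]], x$counts[["R2_population_af"]],
              x$counts[["R3_quality"]]))
  invisible(x)
}

#' Validate a variant-call table against the dialect schema
#' @noRd
validate_variant_calls <- function(calls) {
  if (!is.data.frame(calls)) stop("`calls` must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(variant_columns(), names(calls))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  calls <- calls[variant_columns()]
  bad_type <- !calls$sample_type %in% c("tumor", "plasma")
  if (any(bad_type)) {
    i <- which(bad_type)[1L]
    stop(sprintf("unknown sample_type '%s' (record %d, sample %s, %s:%s)",
                 calls$sample_type[i], i, calls$sample[i], calls$chrom[i],
                 calls$pos[i]), call. = FALSE)
  }
  bad_vaf <- !is.na(calls$vaf) & (calls$vaf < 0 | calls$vaf > 1)
  if (any(bad_vaf)) {
    stop(sprintf("vaf out of [0, 1] at record %d", which(bad_vaf)[1L]), call. = FALSE)
  }
  if (any(calls$pos < 1, na.rm = TRUE)) stop("pos must be >= 1", call. = FALSE)
  if (any(calls$support_reads < 0, na.rm = TRUE)) {
    stop("support_reads must be >= 0", call. = FALSE)
  }
  calls$strand_bias <- as.logical(calls$strand_bias)
  calls
}
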