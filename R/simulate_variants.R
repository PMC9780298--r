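#' Column order of the somatic variant TSV dialect
#' @noRd
variant_columns <- function() {
  c("sample", "sample_type", "chrom", "pos", "ref", "alt", "gene",
    "functional_class", "region_class", "vaf", "support_reads",
    "population_af", "strand_bias")
}

#' Simulate somatic variant calls with optional planted filter violations
#'
#' Each sample receives `round(mutation_rate_per_mb * exonic_base_total /
#' 1e6)` true somatic calls placed on panel bins, with VAFs drawn from a
#' Beta law (truncated below at the sample-type VAF floor so every true call
#' passes the somatic filter). A `contamination_fraction` of additional
#' records is planted, each violating exactly one filtering rule —
#' synonymous/intronic annotation, population allele frequency >= 0.002,
#' support reads < 5, sub-floor VAF, or strand bias — with the planted rule
#' recorded in the returned truth so per-rule filter behaviour is
#' attributable in tests.
#'
#' @param panel A `panel_design`.
#' @param samples Character vector of sample names.
#' @param mutation_rate_per_mb True somatic mutation rate per megabase;
#'   scalar or one value per sample.
#' @param vaf_shape Length-2 positive shape parameters of the Beta VAF law.
#' @param contamination_fraction Fraction (of the true count) of planted
#'   rule-violating records, in \[0, 1\].
#' @param sample_type `"plasma"` or `"tumor"`; sets which VAF floor applies.
#' @param seed Integer seed.
#'
#' @return A list: `variants` (data.frame in the TSV dialect column order)
#'   and `truth` (class `cohort_truth`) with `true_mutation_counts` (named
#'   integer vector) and `contaminants` (data.frame `sample`, `chrom`, `pos`,
#'   `rule` with rule in R1_annotation/R2_population_af/R3_quality plus the
#'   specific planted defect).
#' @export
generate_variants <- function(panel, samples, mutation_rate_per_mb = 20,
                              vaf_shape = c(2, 8), contamination_fraction = 0,
                              sample_type = c("plasma", "tumor"), seed = 1L) {
  validate_panel(panel)
  sample_type <- match.arg(sample_type)
  if (any(mutation_rate_per_mb < 0)) stop("mutation rate must be >= 0", call. = FALSE)
  if (length(vaf_shape) != 2L || any(vaf_shape <= 0)) {
    stop("`vaf_shape` must be two positive Beta shapes", call. = FALSE)
  }
  assert_scalar_number(contamination_fraction, "contamination_fraction", 0, 1)
  rate <- rep_len(mutation_rate_per_mb, length(samples))
  floor_vaf <- if (sample_type == "tumor") 0.05 else 0.01
  bins <- panel$bins

  # planted defects: each violates exactly the named rule, nothing else
  defects <- c("R1_synonymous", "R1_intronic", "R2_population_af",
               "R3_low_support", "R3_low_vaf", "R3_strand_bias")
  defect_rule <- c(R1_synonymous = "R1_annotation", R1_intronic = "R1_annotation",
                   R2_population_af = "R2_population_af", R3_low_support = "R3_quality",
                   R3_low_vaf = "R3_quality", R3_strand_bias = "R3_quality")

  res <- with_seed(seed, {
    rows <- list()
    contam <- list()
    true_counts <- integer(length(samples))
    names(true_counts) <- samples
    pos_counter <- 0L
    draw_vaf <- function(n, lo) {
      v <- stats::rbeta(n, vaf_shape[1], vaf_shape[2])
      while (any(bad <- v < lo)) v[bad] <- stats::rbeta(sum(bad), vaf_shape[1], vaf_shape[2])
      v
    }
    base_call <- function(s, n) {
      b <- sample.int(nrow(bins), n, replace = TRUE)
      # one unique locus per call (sequential offsets within the hit bin keep
      # truth records unambiguous when matched back by sample/chrom/pos)
      pos <- bins$start[b] + 1L + pos_counter + seq_len(n)
      data.frame(
        sample = s, sample_type = sample_type, chrom = bins$chrom[b],
        pos = pos, ref = sample(c("A", "C", "G", "T"), n, TRUE),
        alt = sample(c("A", "C", "G", "T"), n, TRUE), gene = bins$gene[b],
        functional_class = sample(c("nonsynonymous", "stopgain", "frameshift_deletion"),
                                  n, TRUE, prob = c(0.7, 0.15, 0.15)),
        region_class = "exonic", vaf = draw_vaf(n, floor_vaf),
        support_reads = 5L + stats::rpois(n, 25),
        population_af = 0, strand_bias = FALSE, stringsAsFactors = FALSE
      )
    }
    for (i in seq_along(samples)) {
      s <- samples[i]
      n_true <- as.integer(round(rate[i] * panel$exonic_base_total / 1e6))
      true_counts[s] <- n_true
      if (n_true > 0L) {
        rows[[length(rows) + 1L]] <- base_call(s, n_true)
        pos_counter <- pos_counter + 10000L
      }
      n_cont <- as.integer(round(contamination_fraction * n_true))
      if (n_cont > 0L) {
        cc <- base_call(s, n_cont)
        pos_counter <- pos_counter + 10000L
        kind <- defects[(seq_len(n_cont) - 1L) %% length(defects) + 1L]
        for (j in seq_len(n_cont)) {
          cc[j, ] <- switch(kind[j],
            R1_synonymous    = { cc$functional_class[j] <- "synonymous"; cc[j, ] },
            R1_intronic      = { cc$region_class[j] <- "intronic"; cc[j, ] },
            R2_population_af = { cc$population_af[j] <- 0.002 + stats::runif(1, 0, 0.05); cc[j, ] },
            R3_low_support   = { cc$support_reads[j] <- sample(0:4, 1); cc[j, ] },
            R3_low_vaf       = { cc$vaf[j] <- stats::runif(1, 0, floor_vaf * 0.9); cc[j, ] },
            R3_strand_bias   = { cc$strand_bias[j] <- TRUE; cc[j, ] }
          )
        }
        rows[[length(rows) + 1L]] <- cc
        contam[[length(contam) + 1L]] <- data.frame(
          sample = s, chrom = cc$chrom, pos = cc$pos,
          rule = unname(defect_rule[kind]), defect = kind,
          stringsAsFactors = FALSE
        )
      }
    }
    list(variants = do.call(rbind, rows) %||% data.frame(),
         contaminants = do.call(rbind, contam),
         true_counts = true_counts)
  })

  variants <- res$variants
  if (nrow(variants) > 0L) {
    variants <- variants[variant_columns()]
    rownames(variants) <- NULL
  }
  truth <- structure(
    list(true_mutation_counts = res$true_counts,
         contaminants = res$contaminants %||%
           data.frame(sample = character(), chrom = character(),
                      pos = integer(), rule = character(), defect = character()),
         vaf_shape = vaf_shape, seed = seed),
    class = "cohort_truth"
  )
  list(variants = variants, truth = truth)
}
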