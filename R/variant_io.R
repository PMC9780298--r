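#' Read a somatic variant table
#'
#' Two dialects are accepted. `"tsv"` is the package's native 13-column
#' tab-separated dialect (exact order): sample, sample_type, chrom, pos, ref,
#' alt, gene, functional_class, region_class, vaf, support_reads,
#' population_af, strand_bias. `"vcf"` is read-only: one record per variant,
#' with the non-VCF fields carried in INFO under the tag mapping
#' `SAMPLE, STYPE, GENE, FCLASS, RCLASS, VAF, SR, PAF, SB` (SB present means
#' strand bias true).
#'
#' @param path Path to an existing file.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @return A validated data.frame of variant calls (TSV dialect columns).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  calls <- switch(dialect,
    tsv = read_variant_tsv(path),
    vcf = read_variant_vcf(path)
  )
  validate_variant_calls(calls)
}

#' @noRd
read_variant_tsv <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(pos = "integer", vaf = "numeric",
                                     support_reads = "integer",
                                     population_af = "numeric",
                                     strand_bias = "logical")),
    error = function(e) stop("malformed variant TSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  missing_cols <- setdiff(variant_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error in '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' @noRd
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info1 <- function(tag) vcfR::extract.info(v, element = tag)
  data.frame(
    sample = info1("SAMPLE"),
    sample_type = info1("STYPE"),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = info1("GENE"),
    functional_class = info1("FCLASS"),
    region_class = info1("RCLASS"),
    vaf = as.numeric(info1("VAF")),
    support_reads = as.integer(info1("SR")),
    population_af = as.numeric(info1("PAF")),
    # SB is a Flag (no '=value'), so it is detected on the raw INFO string
    strand_bias = grepl("(^|;)SB(;|$)", vcfR::getINFO(v)),
    stringsAsFactors = FALSE
  )
}

#' Write a somatic variant table in the native TSV dialect
#'
#' Round-trips with [read_variant_table()].
#'
#' @param calls Data.frame of variant calls.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_variant_table <- function(calls, path) {
  calls <- validate_variant_calls(calls)
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
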