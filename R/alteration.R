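#' Collapse CR/PR/SD/PD response grades into better/poor groups
#'
#' Complete and partial responders form the "better" group; stable and
#' progressive disease the "poor" group. Labels already equal to
#' "better"/"poor" pass through.
#'
#' @param response Character vector of grades.
#' @return Character vector of "better"/"poor".
#' @export
collapse_response_groups <- function(response) {
  out <- ifelse(response %in% c("CR", "PR", "better"), "better",
         ifelse(response %in% c("SD", "PD", "poor"), "poor", NA_character_))
  if (anyNA(out)) {
    stop("unrecognized response grade(s): ",
         paste(unique(response[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Build a gene x sample alteration matrix
#'
#' For `kind = "snv_binary"`, `x` is a table of retained variant calls and
#' the matrix entry is 1 iff the sample has at least one call in the gene.
#' For `kind = "cnv_level"`, `x` is a long table with columns `gene`,
#' `sample`, `value` (signed copy-number levels or integer states). Genes
#' are ordered by descending alteration frequency (non-zero entries), the
#' ordering of the mutation heatmaps of panel studies. Genes constant across
#' all samples carry no discrimination signal and are dropped with a message.
#'
#' @param x Input table (see above).
#' @param kind `"snv_binary"` or `"cnv_level"`.
#' @param group Named character vector mapping every sample to
#'   "better"/"poor" (CR/PR/SD/PD accepted and collapsed).
#' @return An object of class `alteration_matrix`: list with `values`
#'   (gene x sample matrix), `kind`, `genes`, `samples`, `group`,
#'   `dropped_genes`.
#' @export
build_alteration_matrix <- function(x, kind = c("snv_binary", "cnv_level"),
                                    group) {
  kind <- match.arg(kind)
  if (is.null(x) || nrow(x) == 0L) {
    stop("empty input: no calls/values to build an alteration matrix from",
         call. = FALSE)
  }
  if (kind == "snv_binary") {
    stopifnot(all(c("sample", "gene") %in% names(x)))
    samples <- sort(unique(x$sample))
    genes <- sort(unique(x$gene))
    m <- matrix(0, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(match(x$gene, genes), match(x$sample, samples))] <- 1
  } else {
    stopifnot(all(c("sample", "gene", "value") %in% names(x)))
    samples <- sort(unique(x$sample))
    genes <- sort(unique(x$gene))
    m <- matrix(0, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(match(x$gene, genes), match(x$sample, samples))] <- x$value
  }
  if (!all(samples %in% names(group))) {
    stop("sample(s) without a group label: ",
         paste(setdiff(samples, names(group)), collapse = ", "), call. = FALSE)
  }
  grp <- stats::setNames(collapse_response_groups(group[samples]), samples)

  constant <- apply(m, 1, function(r) length(unique(r)) == 1L)
  dropped <- rownames(m)[constant]
  if (length(dropped) > 0L) {
    message("dropping ", length(dropped), " constant gene row(s): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
    m <- m[!constant, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("no informative genes remain", call. = FALSE)

  freq <- rowMeans(m != 0)
  ord <- order(-freq, rownames(m))
  m <- m[ord, , drop = FALSE]

  structure(
    list(values = m, kind = kind, genes = rownames(m), samples = samples,
         group = grp, dropped_genes = dropped),
    class = "alteration_matrix"
  )
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat(sprintf("<alteration_matrix> kind=%s, %d genes x %d samples (%d better / %d poor)\n",
              x$kind, nrow(x$values), ncol(x$values),
              sum(x$group == "better"), sum(x$group == "poor")))
  invisible(x)
}
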