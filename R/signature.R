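#' nCTPS: two-component PCA gene-signature score
#'
#' PCA is run on the column-centered expression submatrix of the
#' therapeutic-relevant gene list (samples as observations), and each
#' sample's score is the sum of its component-1 and component-2 scores:
#' `nCTPS(s) = PC1(s) + PC2(s)`. Genes absent from the matrix are logged
#' and skipped; at least two usable genes and three samples are required.
#' Centering only by default; `scale. = TRUE` standardizes genes first.
#'
#' @param expression Gene x sample numeric matrix with dimnames.
#' @param gene_list Character vector of signature genes.
#' @param scale. Unit-variance scaling of genes before PCA (default FALSE).
#' @return An object of class `signature_model`: `gene_list` (genes used),
#'   `missing_genes`, `loadings` (components 1-2), `explained_fraction`,
#'   `nctps` (named per-sample score), `scores` (the two components);
#'   `cutoff` and `high_low` are `NULL` until [stratify_by_signature()].
#' @export
compute_nctps <- function(expression, gene_list, scale. = FALSE) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stop("`expression` needs gene rownames and sample colnames", call. = FALSE)
  }
  used <- intersect(gene_list, rownames(expression))
  missing_genes <- setdiff(gene_list, used)
  if (length(missing_genes) > 0L) {
    message(length(missing_genes), " signature gene(s) absent from the matrix: ",
            paste(utils::head(missing_genes, 5), collapse = ", "),
            if (length(missing_genes) > 5) ", ...")
  }
  if (length(used) < 2L) {
    stop("fewer than 2 signature genes present in the expression matrix",
         call. = FALSE)
  }
  if (ncol(expression) < 3L) stop("need at least 3 samples", call. = FALSE)

  x <- t(expression[used, , drop = FALSE])
  n_comp <- min(2L, nrow(x) - 1L, ncol(x))
  pca <- fit_pca(x, n_components = n_comp, scale. = scale.)
  sc <- pca$scores
  nctps <- sc[, 1] + if (ncol(sc) >= 2L) sc[, 2] else 0
  structure(
    list(gene_list = used, missing_genes = missing_genes,
         loadings = pca$loadings, explained_fraction = pca$explained_fraction,
         scores = sc, nctps = stats::setNames(nctps, colnames(expression)),
         cutoff = NULL, high_low = NULL),
    class = "signature_model"
  )
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d genes, %d samples%s\n",
              length(x$gene_list), length(x$nctps),
              if (!is.null(x$cutoff)) sprintf(", cutoff %.4g (%d high / %d low)",
                                              x$cutoff, sum(x$high_low == "high"),
                                              sum(x$high_low == "low")) else ""))
  invisible(x)
}

#' Dichotomize a signature by the maximally selected survival cutoff
#'
#' Finds the nCTPS cutoff via [maxstat_cutoff()] on the clinical data,
#' labels samples high (`nctps > cutoff`) or low, and runs the two-group
#' log-rank test.
#'
#' @param model A `signature_model` from [compute_nctps()].
#' @param clinical Data.frame with columns `sample`, `time`, `event`
#'   covering the scored samples.
#' @param ... Passed to [maxstat_cutoff()].
#' @return The model with `cutoff`, `high_low`, `cutpoint` (full
#'   [maxstat_cutoff()] result) and `survival` (a `survival_result`) filled.
#' @export
stratify_by_signature <- function(model, clinical, ...) {
  stopifnot(inherits(model, "signature_model"))
  stopifnot(all(c("sample", "time", "event") %in% names(clinical)))
  idx <- match(names(model$nctps), clinical$sample)
  if (anyNA(idx)) {
    stop("clinical table lacks sample(s): ",
         paste(names(model$nctps)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  cl <- clinical[idx, ]
  cut <- maxstat_cutoff(model$nctps, cl$time, cl$event, ...)
  model$cutoff <- cut$cutoff
  model$cutpoint <- cut
  model$high_low <- stats::setNames(
    ifelse(model$nctps > cut$cutoff, "high", "low"), names(model$nctps))
  model$survival <- logrank_test(model$high_low, cl$time, cl$event)
  model
}
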