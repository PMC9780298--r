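#' Chi-square screen of gene CNV states between tumor and normal samples
#'
#' For each gene a condition x alteration contingency table is formed —
#' by default the 2 x 2 collapse \{altered (state != 0), neutral (state =
#' 0)\} — and Pearson's chi-square without continuity correction is applied.
#' Genes whose table has a zero marginal are reported untestable (NA), not
#' significant. P-values are Benjamini-Hochberg adjusted across the
#' testable genes.
#'
#' @param states Gene x sample integer matrix with states in
#'   \{-2, -1, 0, 1, 2\} and dimnames.
#' @param condition Per-sample labels, both "tumor" and "normal" present.
#' @param collapse `"binary"` (default, altered vs neutral) or `"full"`
#'   (all five states as table columns).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return Data.frame per gene: `gene`, `chi2`, `p`, `p_adj`, `testable`,
#'   `significant`.
#' @export
cnv_chisquare_screen <- function(states, condition,
                                 collapse = c("binary", "full"), alpha = 0.05) {
  collapse <- match.arg(collapse)
  states <- as.matrix(states)
  condition <- as.character(condition)
  stopifnot(ncol(states) == length(condition))
  if (!all(c("tumor", "normal") %in% condition)) {
    stop("both 'tumor' and 'normal' conditions are required", call. = FALSE)
  }
  res <- lapply(rownames(states), function(g) {
    st <- states[g, ]
    col <- if (collapse == "binary") ifelse(st != 0, "altered", "neutral")
           else factor(st, levels = -2:2)
    tab <- table(condition, col)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || ncol(tab) < 2L) {
      return(data.frame(gene = g, chi2 = NA_real_, p = NA_real_,
                        testable = FALSE))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(gene = g, chi2 = unname(ct$statistic), p = ct$p.value,
               testable = TRUE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  out$p_adj[out$testable] <- stats::p.adjust(out$p[out$testable], method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Copy-number dosage association of one gene's expression
#'
#' Samples are grouped by CNV state into deletion (-2 and -1 merged),
#' normal (0), single gain (1) and amplification (2); groups with fewer
#' than `min_group_n` samples are dropped. Exactly two usable groups are
#' compared by the two-sided Wilcoxon rank-sum test; more than two by
#' Kruskal-Wallis (both with tie correction). Fewer than two usable groups
#' makes the gene untestable.
#'
#' @param expression Numeric expression values (one gene, all samples).
#' @param states Matching integer CNV states in \{-2, ..., 2\}.
#' @param min_group_n Minimum samples per used group (default 2).
#' @return A list: `test` ("wilcoxon", "kruskal" or "untestable"),
#'   `statistic`, `p`, `groups_used`.
#' @export
dosage_association <- function(expression, states, min_group_n = 2L) {
  stopifnot(length(expression) == length(states))
  grp <- ifelse(states <= -1, "deletion",
         ifelse(states == 0, "normal",
         ifelse(states == 1, "gain", "amplification")))
  keep_lv <- names(which(table(grp) >= min_group_n))
  keep <- grp %in% keep_lv
  if (length(keep_lv) < 2L) {
    return(list(test = "untestable", statistic = NA_real_, p = NA_real_,
                groups_used = keep_lv))
  }
  e <- expression[keep]; g <- factor(grp[keep])
  if (stats::sd(e) == 0) {
    # complete ties: the rank tests are 0/0; the null is trivially retained
    return(list(test = if (nlevels(g) == 2L) "wilcoxon" else "kruskal",
                statistic = 0, p = 1, groups_used = levels(g)))
  }
  if (nlevels(g) == 2L) {
    sp <- split(e, g)
    wt <- suppressWarnings(stats::wilcox.test(sp[[1]], sp[[2]]))
    list(test = "wilcoxon", statistic = unname(wt$statistic), p = wt$p.value,
         groups_used = levels(g))
  } else {
    kt <- stats::kruskal.test(e, g)
    list(test = "kruskal", statistic = unname(kt$statistic), p = kt$p.value,
         groups_used = levels(g))
  }
}

#' Dosage association across all genes of an expression/state matrix pair
#'
#' @param expression,states Congruent gene x sample matrices.
#' @param alpha Significance level (default 0.05, on the raw p as in
#'   four-group dosage analyses; an adjusted column is also provided).
#' @param ... Passed to [dosage_association()].
#' @return Data.frame per gene: `gene`, `test`, `statistic`, `p`, `p_adj`,
#'   `significant`.
#' @export
dosage_screen <- function(expression, states, alpha = 0.05, ...) {
  stopifnot(all(dim(expression) == dim(states)),
            identical(rownames(expression), rownames(states)))
  rows <- lapply(rownames(expression), function(g) {
    r <- dosage_association(expression[g, ], states[g, ], ...)
    data.frame(gene = g, test = r$test, statistic = r$statistic, p = r$p)
  })
  out <- do.call(rbind, rows)
  ok <- out$test != "untestable"
  out$p_adj <- NA_real_
  out$p_adj[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$significant <- ok & !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out
}

#' Intersect the gene sets from the three screens
#'
#' Reports all seven Venn regions of sets A (CNV tumor-vs-normal
#' significant), B (dosage-associated) and C (response-discriminating),
#' with sorted, case-normalized memberships.
#'
#' @param set_a,set_b,set_c Character vectors of gene labels (empty
#'   allowed).
#' @return A list of class `venn_report`: `counts` (named integer vector
#'   over the 7 regions), `members` (named list), `core` (the triple
#'   intersection).
#' @export
intersect_screens <- function(set_a, set_b, set_c) {
  norm <- function(x) sort(unique(toupper(as.character(x))))
  a <- norm(set_a); b <- norm(set_b); c <- norm(set_c)
  members <- list(
    A_only = setdiff(a, union(b, c)),
    B_only = setdiff(b, union(a, c)),
    C_only = setdiff(c, union(a, b)),
    AB_not_C = setdiff(intersect(a, b), c),
    AC_not_B = setdiff(intersect(a, c), b),
    BC_not_A = setdiff(intersect(b, c), a),
    ABC = Reduce(intersect, list(a, b, c))
  )
  structure(
    list(counts = vapply(members, length, integer(1)), members = members,
         core = members$ABC, sizes = c(A = length(a), B = length(b), C = length(c))),
    class = "venn_report"
  )
}

#' @export
print.venn_report <- function(x, ...) {
  cat("<venn_report> |A|=", x$sizes["A"], " |B|=", x$sizes["B"],
      " |C|=", x$sizes["C"], "; core (A∩B∩C): ",
      if (length(x$core)) paste(x$core, collapse = ", ") else "(empty)", "\n",
      sep = "")
  invisible(x)
}

#' Expression versus drug-sensitivity correlation across cell lines
#'
#' For every (gene, drug) pair sharing at least `min_lines` cell lines,
#' the correlation between expression and drug response is computed
#' (Pearson by default, Spearman optional) with the two-sided p-value from
#' the t transform, and BH adjustment across all tested pairs. Positive r
#' means higher expression goes with a higher response score; whether that
#' score encodes sensitivity or resistance depends on the source's sign
#' convention, stated by `higher_is_sensitive`.
#'
#' @param expression Gene x cell-line matrix.
#' @param response Drug x cell-line matrix.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_lines Minimum shared cell lines per pair (default 3).
#' @param higher_is_sensitive Logical documenting the response score's
#'   orientation (recorded in the output, not used in computation).
#' @return Data.frame per pair: `gene`, `drug`, `n`, `r`, `p`, `p_adj`,
#'   `testable`; attribute `higher_is_sensitive`.
#' @export
drug_sensitivity_correlation <- function(expression, response,
                                         method = c("pearson", "spearman"),
                                         min_lines = 3L,
                                         higher_is_sensitive = TRUE) {
  method <- match.arg(method)
  expression <- as.matrix(expression); response <- as.matrix(response)
  shared <- intersect(colnames(expression), colnames(response))
  if (length(shared) == 0L) stop("no shared cell lines", call. = FALSE)
  rows <- list()
  for (g in rownames(expression)) {
    for (d in rownames(response)) {
      e <- expression[g, shared]; r <- response[d, shared]
      ok <- is.finite(e) & is.finite(r)
      n <- sum(ok)
      if (n < min_lines || stats::sd(e[ok]) == 0 || stats::sd(r[ok]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, drug = d, n = n, r = NA_real_, p = NA_real_, testable = FALSE)
        next
      }
      ct <- suppressWarnings(stats::cor.test(e[ok], r[ok], method = method))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, drug = d, n = n, r = unname(ct$estimate), p = ct$p.value,
        testable = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  out$p_adj[out$testable] <- stats::p.adjust(out$p[out$testable], method = "BH")
  rownames(out) <- NULL
  attr(out, "higher_is_sensitive") <- higher_is_sensitive
  out
}
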