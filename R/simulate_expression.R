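#' Simulate dosage-coupled expression and exponential survival
#'
#' Expression follows a linear copy-number dosage model:
#' `expr(g, s) = baseline(g) + dosage_slope * state(g, s) + N(0, noise_sd)`,
#' with integer CNV states in \{-2, -1, 0, 1, 2\}. Survival times are
#' exponential with hazard `baseline_hazard * hazard_ratio^[group == "poor"]`;
#' censoring is independent: each subject is censored with probability
#' `censor_rate`, at a uniform fraction of its latent event time.
#'
#' @param gene_cnv_states Integer gene x sample matrix with states in
#'   \{-2, -1, 0, 1, 2\} (dimnames required).
#' @param dosage_slope Expression units per CNV state unit.
#' @param noise_sd Positive Gaussian noise SD.
#' @param baseline_hazard Positive hazard of the reference ("better") group.
#' @param hazard_ratio Positive hazard ratio of the "poor" group versus
#'   "better"; 1 makes the two survival laws identical.
#' @param censor_rate Probability of independent right-censoring, in \[0, 1\].
#' @param group Optional character vector (one per sample) with values
#'   "better"/"poor"; defaults to a balanced split in sample order.
#' @param baseline_mean,baseline_sd Per-gene baseline expression law
#'   (fixed per gene, drawn once).
#' @param seed Integer seed.
#'
#' @return A list: `expression` (gene x sample matrix), `clinical`
#'   (data.frame `sample`, `group`, `time`, `event`), and `truth`
#'   (class `cohort_truth`) holding `dosage_slope`, `hazard_ratio`,
#'   `group_labels`, and the seed.
#' @export
generate_expression_survival <- function(gene_cnv_states, dosage_slope = 1,
                                         noise_sd = 0.5, baseline_hazard = 0.1,
                                         hazard_ratio = 2, censor_rate = 0.2,
                                         group = NULL, baseline_mean = 8,
                                         baseline_sd = 1, seed = 1L) {
  if (!is.matrix(gene_cnv_states) || is.null(rownames(gene_cnv_states)) ||
      is.null(colnames(gene_cnv_states))) {
    stop("`gene_cnv_states` must be a gene x sample matrix with dimnames", call. = FALSE)
  }
  if (!all(gene_cnv_states %in% -2:2)) {
    stop("CNV states must lie in {-2, -1, 0, 1, 2}", call. = FALSE)
  }
  assert_scalar_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  assert_scalar_number(baseline_hazard, "baseline_hazard", lower = 0, strict_lower = TRUE)
  assert_scalar_number(hazard_ratio, "hazard_ratio", lower = 0, strict_lower = TRUE)
  assert_scalar_number(censor_rate, "censor_rate", 0, 1)

  samples <- colnames(gene_cnv_states)
  n <- length(samples)
  if (is.null(group)) {
    group <- rep(c("better", "poor"), length.out = n)
  }
  if (length(group) != n || !all(group %in% c("better", "poor"))) {
    stop("`group` must assign 'better' or 'poor' to every sample", call. = FALSE)
  }

  out <- with_seed(seed, {
    g_base <- stats::rnorm(nrow(gene_cnv_states), baseline_mean, baseline_sd)
    expr <- g_base + dosage_slope * gene_cnv_states +
      matrix(stats::rnorm(length(gene_cnv_states), 0, noise_sd),
             nrow(gene_cnv_states))
    hz <- baseline_hazard * hazard_ratio^(group == "poor")
    latent <- stats::rexp(n, rate = hz)
    event <- as.integer(stats::runif(n) >= censor_rate)
    time <- ifelse(event == 1L, latent, latent * stats::runif(n))
    list(expr = expr, time = time, event = event)
  })
  dimnames(out$expr) <- dimnames(gene_cnv_states)

  clinical <- data.frame(sample = samples, group = group,
                         time = out$time, event = out$event,
                         stringsAsFactors = FALSE)
  truth <- structure(
    list(dosage_slope = dosage_slope, hazard_ratio = hazard_ratio,
         baseline_hazard = baseline_hazard, censor_rate = censor_rate,
         group_labels = stats::setNames(group, samples), seed = seed),
    class = "cohort_truth"
  )
  list(expression = out$expr, clinical = clinical, truth = truth)
}

#' Simulate a gene x sample CNV state matrix
#'
#' States are drawn i.i.d. from the five-level copy-number alphabet with the
#' given probabilities; optionally a subset of genes receives group-biased
#' states (gains enriched in one group) to plant a recoverable signal.
#'
#' @param n_genes,samples Matrix dimensions; `samples` is a character vector.
#' @param state_probs Probabilities for states (-2, -1, 0, 1, 2).
#' @param biased_genes Optional character vector of gene names (subset of the
#'   generated `G###` labels) whose states are shifted upward in `group ==
#'   "better"` samples by `bias_shift`.
#' @param group Optional per-sample "better"/"poor" labels (needed when
#'   `biased_genes` is given).
#' @param bias_shift Integer state shift applied to biased genes in the
#'   "better" group (clipped to \[-2, 2\]).
#' @param seed Integer seed.
#' @return Integer gene x sample matrix with dimnames.
#' @export
generate_cnv_states <- function(n_genes, samples,
                                state_probs = c(0.05, 0.15, 0.6, 0.15, 0.05),
                                biased_genes = NULL, group = NULL,
                                bias_shift = 2L, seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  stopifnot(length(state_probs) == 5L, all(state_probs >= 0))
  genes <- sprintf("G%03d", seq_len(n_genes))
  m <- with_seed(seed, {
    s <- matrix(sample(-2:2, n_genes * length(samples), TRUE, prob = state_probs),
                n_genes, dimnames = list(genes, samples))
    if (!is.null(biased_genes)) {
      if (is.null(group) || length(group) != length(samples)) {
        stop("`group` labels are required with `biased_genes`", call. = FALSE)
      }
      hit <- intersect(biased_genes, genes)
      up <- samples[group == "better"]
      s[hit, up] <- pmin(2L, pmax(-2L, s[hit, up] + as.integer(bias_shift)))
    }
    s
  })
  storage.mode(m) <- "integer"
  m
}
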