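#' Build a pipeline configuration
#'
#' One flat configuration covering every stage of the synthetic demo
#' pipeline: simulate -> filter -> metrics -> discriminate -> signature ->
#' screen. Defaults mirror the published thresholds where the method states
#' them (population AF 0.002, 5 support reads, VAF floors 0.05 tumor / 0.01
#' plasma, MATH window 2%-100%, CNI threshold P95 + 2 SD, alpha 0.05) and
#' the package's own documented choices elsewhere. Configurations
#' round-trip losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param seed Integer master seed for all stages.
#' @param stages Character vector of enabled stages (dependency-checked by
#'   [run_pipeline()]).
#' @param ... Overrides for any default parameter listed in the function
#'   body (unknown names are an error).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L,
                            stages = c("simulate", "filter", "metrics",
                                       "discriminate", "signature", "screen"),
                            ...) {
  cfg <- list(
    seed = as.integer(seed),
    stages = stages,
    # simulate
    n_bins = 120L, bin_length = 200L, bins_per_gene = 2L,
    n_baseline = 12L, n_test = 16L, n_better = 8L,
    depth_mean = 200, gc_bias_strength = 2, dispersion = 0.02,
    event_multiplier = 2, event_bins = 6L, events_per_better = 2L,
    # the demo panel is scaled down to 24 kb; rates are scaled up so samples
    # still carry realistic per-sample call counts (~8 better / ~16 poor,
    # mirroring the higher mutational burden of non-responders)
    mutation_rate_better = 350, mutation_rate_poor = 650,
    contamination_fraction = 0.3,
    vaf_shape = c(2, 8),
    expr_n_samples = 150L, expr_n_genes = 60L,
    dosage_slope = 1, noise_sd = 0.5,
    baseline_hazard = 0.1, hazard_ratio = 3, censor_rate = 0.2,
    # filter
    pop_af_max = 0.002, min_support = 5,
    vaf_floor_tumor = 0.05, vaf_floor_plasma = 0.01,
    # metrics
    cni_percentile = 0.95, cni_sd_mult = 2, cni_two_sided = FALSE,
    math_convention = "literal", gc_window_frac = 0.3,
    # discriminate
    n_components = 2L, loading_quantile = 0.75,
    # signature / survival
    maxstat_window = c(0.1, 0.9),
    # screen
    alpha = 0.05
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `path` invisibly / the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config,
          c(list(seed = raw$seed, stages = raw$stages),
            raw[setdiff(names(raw), c("seed", "stages"))]))
}

#' Run the ctDNA chemo-score pipeline end-to-end
#'
#' Executes the enabled stages in dependency order on a synthetic cohort,
#' writing each stage's outputs as plain-text files under `out_dir` and a
#' JSON manifest (parameters, per-stage summaries, output file MD5 hashes).
#' Identical configurations produce byte-identical primary outputs and
#' therefore identical manifest hashes.
#'
#' Stage dependencies: filter needs simulate; metrics needs simulate +
#' filter; discriminate needs metrics; signature needs discriminate;
#' screen needs signature. A missing dependency is a configuration error
#' raised before any stage runs.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if absent).
#' @return The run manifest (list), invisibly also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("ctdna_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  deps <- list(filter = "simulate", metrics = c("simulate", "filter"),
               discriminate = "metrics", signature = "discriminate",
               screen = "signature")
  for (s in stages) {
    miss <- setdiff(deps[[s]] %||% character(), stages)
    if (length(miss) > 0L) {
      stop(sprintf("stage '%s' requires disabled stage(s): %s",
                   s, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = unclass(config), stages = list())
  env <- new.env(parent = emptyenv())

  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }

  if ("simulate" %in% stages) {
    panel <- generate_panel(config$n_bins, config$bin_length,
                            bins_per_gene = config$bins_per_gene,
                            seed = config$seed)
    test_samples <- sprintf("test_%02d", seq_len(config$n_test))
    better <- test_samples[seq_len(config$n_better)]
    group <- stats::setNames(
      ifelse(test_samples %in% better, "better", "poor"), test_samples)
    # recurrent multi-bin gain events shared by the better group (higher
    # copy-number instability in responders, at common loci so the signal is
    # recoverable at the gene level)
    n_reg <- config$events_per_better
    region_starts <- floor(seq(1L, config$n_bins - config$event_bins,
                               length.out = n_reg + 2L))[2:(n_reg + 1L)]
    ev <- do.call(rbind, lapply(names(group)[group == "better"], function(s) {
      do.call(rbind, lapply(region_starts, function(b0) {
        data.frame(sample = s, chrom = "chr1",
                   start = panel$bins$start[b0],
                   end = panel$bins$end[min(b0 + config$event_bins - 1L,
                                            config$n_bins)],
                   multiplier = config$event_multiplier)
      }))
    }))
    profiles <- generate_bin_counts(panel, config$n_baseline, config$n_test,
                                    cnv_events = ev,
                                    gc_bias_strength = config$gc_bias_strength,
                                    depth_mean = config$depth_mean,
                                    dispersion = config$dispersion,
                                    seed = config$seed + 1L)
    base_rate <- ifelse(group == "better", config$mutation_rate_better,
                        config$mutation_rate_poor)
    rates <- with_seed(config$seed + 7L,
                       base_rate * stats::rgamma(length(group), 20, 20))
    vars <- generate_variants(panel, test_samples,
                              mutation_rate_per_mb = rates,
                              vaf_shape = config$vaf_shape,
                              contamination_fraction = config$contamination_fraction,
                              seed = config$seed + 2L)
    env$panel <- panel; env$profiles <- profiles; env$variants <- vars
    env$group <- group
    files <- c(bins = write_panel_tsv(panel, file.path(out_dir, "bins.tsv"),
                                      counts = profiles$counts),
               variants = tsv(vars$variants, "variants.tsv"),
               groups = tsv(data.frame(sample = names(group), group = group),
                            "groups.tsv"))
    manifest$stages$simulate <- list(
      files = files,
      n_variants = nrow(vars$variants),
      n_events = nrow(profiles$truth$cnv_events))
  }

  if ("filter" %in% stages) {
    rep <- filter_somatic(env$variants$variants,
                          pop_af_max = config$pop_af_max,
                          min_support = config$min_support,
                          vaf_floor_tumor = config$vaf_floor_tumor,
                          vaf_floor_plasma = config$vaf_floor_plasma)
    env$filter_report <- rep
    files <- c(retained = tsv(rep$retained, "retained.tsv"),
               removed = tsv(rep$removed, "removed.tsv"))
    manifest$stages$filter <- list(files = files,
                                   counts = as.list(rep$counts),
                                   n_retained = nrow(rep$retained))
  }

  if ("metrics" %in% stages) {
    met <- compute_instability_metrics(env$profiles, env$filter_report$retained,
                                       window_frac = config$gc_window_frac,
                                       percentile = config$cni_percentile,
                                       sd_mult = config$cni_sd_mult,
                                       two_sided = config$cni_two_sided)
    met$group <- env$group[met$sample]
    env$metrics <- met
    cmp <- lapply(c(cni = "cni", tmb = "tmb", math = "math"), function(v) {
      ok <- !is.na(met[[v]])
      compare_groups_mannwhitney(met[[v]][ok & met$group == "better"],
                                 met[[v]][ok & met$group == "poor"])
    })
    files <- c(metrics = tsv(met, "metrics.tsv"))
    manifest$stages$metrics <- list(
      files = files,
      mannwhitney_p = lapply(cmp, function(x) x$p),
      higher_group = lapply(cmp, function(x) x$larger))
  }

  if ("discriminate" %in% stages) {
    # per-gene CNV level: mean log2 ratio over the gene's bins
    corrected <- gc_correct_and_normalize(env$panel, env$profiles$counts,
                                          window_frac = config$gc_window_frac)
    info <- env$profiles$sample_info
    ref <- baseline_reference(
      corrected[, info$sample[info$role == "baseline"], drop = FALSE])
    test_cols <- info$sample[info$role == "test"]
    lr <- vapply(test_cols, function(s) compute_log2_ratios(corrected[, s], ref),
                 numeric(nrow(corrected)))
    gene_lr <- rowsum(lr, env$panel$bins$gene) /
      as.vector(table(env$panel$bins$gene)[sort(unique(env$panel$bins$gene))])
    long <- data.frame(
      gene = rep(rownames(gene_lr), ncol(gene_lr)),
      sample = rep(colnames(gene_lr), each = nrow(gene_lr)),
      value = as.vector(gene_lr))
    am <- build_alteration_matrix(long, kind = "cnv_level", group = env$group)
    pca <- fit_pca(am, n_components = config$n_components,
                   loading_quantile = config$loading_quantile)
    auc <- discrimination_auc(pca$scores[, 1], am$group[rownames(pca$scores)])
    cl <- cluster_samples(pca$scores[, 1:2, drop = FALSE],
                          am$group[rownames(pca$scores)])
    env$pca <- pca; env$pc_genes <- unique(unlist(pca$pc_genes))
    files <- c(scores = tsv(data.frame(sample = rownames(pca$scores),
                                       pca$scores), "pca_scores.tsv"),
               roc = tsv(roc_points(pca$scores[, 1],
                                    am$group[rownames(pca$scores)]),
                         "roc_points.tsv"))
    manifest$stages$discriminate <- list(
      files = files, auc_pc1 = auc,
      cluster_agreement = cl$agreement,
      n_pc_genes = length(env$pc_genes))
  }

  if ("signature" %in% stages) {
    sig_genes <- env$pc_genes
    n_expr_genes <- max(config$expr_n_genes, length(sig_genes))
    expr_samples <- sprintf("tcga_%03d", seq_len(config$expr_n_samples))
    expr_group <- rep(c("better", "poor"), length.out = config$expr_n_samples)
    states <- generate_cnv_states(n_expr_genes, expr_samples,
                                  biased_genes = sig_genes, group = expr_group,
                                  bias_shift = 2L, seed = config$seed + 3L)
    sim <- generate_expression_survival(states, dosage_slope = config$dosage_slope,
                                        noise_sd = config$noise_sd,
                                        baseline_hazard = config$baseline_hazard,
                                        hazard_ratio = config$hazard_ratio,
                                        censor_rate = config$censor_rate,
                                        group = expr_group,
                                        seed = config$seed + 4L)
    model <- compute_nctps(sim$expression, sig_genes)
    model <- stratify_by_signature(model, sim$clinical,
                                   quantile_window = config$maxstat_window)
    # TMB-stratified prognosis on simulated per-sample burdens
    tmb_vals <- with_seed(config$seed + 5L,
                          stats::rgamma(config$expr_n_samples, 4, 0.5))
    strat <- stratified_prognosis(model$high_low[sim$clinical$sample], tmb_vals,
                                  sim$clinical$time, sim$clinical$event)
    env$expression <- sim$expression; env$expr_states <- states
    env$expr_clinical <- sim$clinical; env$signature <- model
    files <- c(expression = tsv(data.frame(gene = rownames(sim$expression),
                                           sim$expression), "expression.tsv"),
               clinical = tsv(sim$clinical, "clinical.tsv"),
               nctps = tsv(data.frame(sample = names(model$nctps),
                                      nctps = model$nctps,
                                      group = model$high_low), "nctps.tsv"))
    manifest$stages$signature <- list(
      files = files, cutoff = model$cutoff,
      logrank_p = model$survival$p,
      stratified_p = strat$p)
  }

  if ("screen" %in% stages) {
    # tumor cohort = the expression cohort; add matched synthetic normals
    n_norm <- ceiling(config$expr_n_samples / 2)
    normal_states <- generate_cnv_states(
      nrow(env$expr_states), sprintf("normal_%03d", seq_len(n_norm)),
      state_probs = c(0.01, 0.04, 0.9, 0.04, 0.01), seed = config$seed + 6L)
    all_states <- cbind(env$expr_states, normal_states)
    condition <- rep(c("tumor", "normal"),
                     c(ncol(env$expr_states), n_norm))
    chi <- cnv_chisquare_screen(all_states, condition, alpha = config$alpha)
    dos <- dosage_screen(env$expression, env$expr_states, alpha = config$alpha)
    venn <- intersect_screens(chi$gene[chi$significant],
                              dos$gene[dos$significant],
                              env$pc_genes)
    files <- c(chisq = tsv(chi, "screen_chisq.tsv"),
               dosage = tsv(dos, "screen_dosage.tsv"))
    jsonlite::write_json(venn$members, file.path(out_dir, "venn.json"),
                         auto_unbox = FALSE, pretty = TRUE)
    manifest$stages$screen <- list(
      files = c(files, venn = file.path(out_dir, "venn.json")),
      n_chisq_significant = sum(chi$significant),
      n_dosage_significant = sum(dos$significant),
      venn_counts = as.list(venn$counts))
  }

  all_files <- unlist(lapply(manifest$stages, `[[`, "files"))
  manifest$file_md5 <- as.list(tools::md5sum(all_files))
  names(manifest$file_md5) <- basename(names(manifest$file_md5))
  manifest$out_dir <- out_dir
  jsonlite::write_json(manifest[setdiff(names(manifest), "out_dir")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
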