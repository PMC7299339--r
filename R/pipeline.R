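# End-to-end orchestration from a single YAML (or list) configuration:
# synthetic generation or file ingestion, expression filtering,
# normalization, differential expression, pairwise correlation with
# permutation null and stratified comparison, optional GSEA association
# matrix, network assembly with topology statistics and power-law fit,
# and optional cohort / delta-delta-Ct stages. Every intermediate table
# is written to the output directory; the summary JSON is a pure
# function of (config, seed).

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file with optional sections `synthetic`, `inputs`,
#'   `de`, `correlation`, `gsea`, `network`, `cohort`, `ddct`, `output`,
#'   and a master `seed`.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_format("configuration must be a YAML mapping")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full network-inference pipeline
#'
#' Executes: expression filtering, normalization, differential
#' expression, all-pairs correlation + permutation null + stratified
#' distribution test, optional miRNA x gene-set association matrix,
#' network assembly, topology summary with power-law fits, hub and
#' subnetwork extraction, and optional cohort scoring and delta-delta-Ct
#' stages. Identical config + seed produces byte-identical summary JSON.
#'
#' @param config configuration list (see [read_run_config()]); either a
#'   `synthetic` section or an `inputs` section with file paths must be
#'   present.
#' @param out_dir output directory (created if missing); overrides
#'   `config$output$dir`.
#' @return Invisibly, the path of the output directory. Side effects:
#'   intermediate TSVs, network files, `summary.json`, `manifest.json`,
#'   `log.txt`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- out_dir %||% config$output$dir %||%
    stop_config("no output directory configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(fmt, ...) cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                                         sprintf(fmt, ...)),
                                 file = log_path, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, sproutnet_error = function(e) {
      logf("stage %s failed: %s", name, conditionMessage(e))
      stop(errorCondition(sprintf("stage '%s': %s", name, conditionMessage(e)),
                          class = class(e)))
    })
  }
  summary <- list(seed = seed)

  # ---- inputs -------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    sc$seed <- sc$seed %||% split_seed(seed, "synthetic")
    cfg <- do.call(synthetic_config, sc)
    logf("generating synthetic experiment (seed %d)", cfg$seed)
    exp <- stage("synthetic", generate_experiment(cfg))
    mirs_raw <- exp$mirna; genes_raw <- exp$gene
    predictions <- exp$predictions; genesets <- exp$genesets
    truth <- exp$truth
    write_counts(mirs_raw, file.path(out_dir, "mirna_counts.tsv"))
    write_counts(genes_raw, file.path(out_dir, "gene_counts.tsv"))
    write_predictions(predictions, file.path(out_dir, "predictions.tsv"))
    write_gmt(genesets, file.path(out_dir, "genesets.gmt"))
    utils::write.table(truth$planted_edges,
                       file.path(out_dir, "truth_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    cmap <- unlist(inp$condition_map)
    mirs_raw <- stage("io", read_counts(inp$mirna_counts, cmap, kind = "mirna"))
    genes_raw <- stage("io", read_counts(inp$gene_counts, cmap, kind = "gene"))
    predictions <- stage("io", read_predictions(
      inp$predictions,
      conserved_min_pct = inp$conserved_min_pct %||% 50,
      nonconserved_min_pct = inp$nonconserved_min_pct %||% 90))
    genesets <- if (!is.null(inp$gmt)) stage("io", read_gmt(inp$gmt)) else NULL
  } else stop_config("config needs either a 'synthetic' or an 'inputs' section")

  # ---- filter / normalize / DE -------------------------------------------
  de_cfg <- config$de %||% list()
  min_raw <- de_cfg$min_raw %||% 5
  lfc_thr <- de_cfg$lfc_threshold %||% 0.5
  fdr_cut <- de_cfg$fdr_cutoff %||% 0.05
  mirs_f <- stage("filter", filter_expressed(mirs_raw, min_raw))
  genes_f <- stage("filter", filter_expressed(genes_raw, min_raw))
  logf("expressed features: %d miRNAs, %d genes", nrow(mirs_f$values),
       nrow(genes_f$values))
  mirs_n <- stage("normalize", normalize_counts(mirs_f))
  genes_n <- stage("normalize", normalize_counts(genes_f))
  de_mir <- if (!is.null(de_cfg$mirna_table))
    stage("de", ingest_de_table(de_cfg$mirna_table, lfc_thr, fdr_cut))
  else stage("de", differential_expression(mirs_n, lfc_thr, fdr_cut))
  de_gene <- if (!is.null(de_cfg$gene_table))
    stage("de", ingest_de_table(de_cfg$gene_table, lfc_thr, fdr_cut))
  else stage("de", differential_expression(genes_n, lfc_thr, fdr_cut))
  write_de_table(de_mir, file.path(out_dir, "de_mirna.tsv"))
  write_de_table(de_gene, file.path(out_dir, "de_gene.tsv"))
  summary$n_mirna_expressed <- nrow(mirs_f$values)
  summary$n_gene_expressed <- nrow(genes_f$values)
  summary$n_mirna_de <- sum(de_mir$direction != "ns")
  summary$n_gene_de <- sum(de_gene$direction != "ns")

  # ---- correlation + permutation null ------------------------------------
  cor_cfg <- config$correlation %||% list()
  n_perm <- cor_cfg$n_perm %||% 1000
  ct <- stage("correlation", pairwise_correlation(mirs_n, genes_n))
  null <- stage("correlation", permutation_null(
    mirs_n, genes_n, n_perm = n_perm, seed = split_seed(seed, "permnull")))
  ct <- empirical_pvalues(ct, null)
  write_correlations(ct, file.path(out_dir, "correlations.tsv"))
  summary$null_mean_r <- mean(null$samples)
  summary$null_n_pooled <- length(null$samples)
  strat <- tryCatch(
    stage("correlation", stratified_distribution_test(ct, predictions, "conserved")),
    sproutnet_contract_error = function(e) NULL)
  if (!is.null(strat)) {
    summary$conserved_ks_d <- strat$D
    summary$conserved_ks_p_one_sided <- strat$p_one_sided
    summary$conserved_mean_shift <- strat$mean_shift
  }
  jsonlite::write_json(
    list(n_permutations = null$n_permutations, n_pairs = null$n_pairs,
         mean_r = mean(null$samples), sd_r = stats::sd(null$samples),
         subsampled = null$subsampled),
    file.path(out_dir, "null_summary.json"), auto_unbox = TRUE, digits = 10)

  # ---- GSEA association matrix (optional) --------------------------------
  gsea_cfg <- config$gsea %||% list()
  if (isTRUE(gsea_cfg$enabled %||% FALSE) && !is.null(genesets)) {
    am <- stage("gsea", mirna_association_matrix(
      mirs_n, genes_n, genesets,
      n_perm = gsea_cfg$n_perm %||% 1000,
      seed = split_seed(seed, "gsea"),
      fdr_cutoff = gsea_cfg$fdr_cutoff %||% 0.05))
    utils::write.table(data.frame(set = rownames(am$nes), am$nes,
                                  check.names = FALSE),
                       file.path(out_dir, "association_nes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(set = rownames(am$fdr), am$fdr,
                                  check.names = FALSE),
                       file.path(out_dir, "association_fdr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_significant_associations <- sum(am$masked != 0)
  }

  # ---- network ------------------------------------------------------------
  net_cfg <- config$network %||% list()
  net <- stage("network", build_network(
    de_mir, de_gene, ct, predictions,
    p_threshold = net_cfg$p_threshold %||% 0.05,
    conservation_mode = net_cfg$conservation_mode %||% "conserved_only",
    p_kind = net_cfg$p_kind %||% "analytic"))
  write_network(net, file.path(out_dir, "network.graphml"), "graphml")
  write_network(net, file.path(out_dir, "network_edges.tsv"), "edge_tsv")
  ns <- network_summary(net, n_hubs = net_cfg$n_hubs %||% 10)
  summary$network <- list(
    n_mirna = ns$n_mirna, n_gene = ns$n_gene, n_edges = ns$n_edges,
    n_components = ns$n_components,
    component_sizes = ns$component_sizes,
    hubs = ns$hubs)
  if (length(ns$out_degree) >= 10 && length(unique(ns$out_degree)) > 1) {
    fit <- stage("powerlaw", fit_power_law(
      ns$out_degree, n_bootstrap = net_cfg$n_bootstrap %||% 200,
      seed = split_seed(seed, "plfit")))
    summary$power_law <- list(alpha = fit$alpha, xmin = fit$xmin,
                              ks_d = fit$ks_d, p_gof = fit$p_gof,
                              n_tail = fit$n_tail)
  }
  if (!is.null(truth) && nrow(truth$planted_edges)) {
    pr <- edge_recovery(net, truth)
    summary$edge_precision <- pr$precision
    summary$edge_recall <- pr$recall
    summary$n_true_edges <- pr$n_true
  }
  if (!is.null(net_cfg$subnetwork_seeds)) {
    sub <- stage("network", extract_subnetwork(net,
                                               unlist(net_cfg$subnetwork_seeds)))
    write_network(sub, file.path(out_dir, "subnetwork.graphml"), "graphml")
    sns <- network_summary(sub)
    summary$subnetwork <- list(n_mirna = sns$n_mirna, n_gene = sns$n_gene,
                               n_edges = sns$n_edges)
  }

  # ---- cohort (optional) --------------------------------------------------
  coh_cfg <- config$cohort
  if (!is.null(coh_cfg)) {
    coh <- stage("cohort", generate_cohort(
      n_samples = coh_cfg$n_samples %||% 100L,
      signature_genes = sprintf("sig%02d", 1:35),
      module_genes = coh_cfg$module_genes %||%
        (if (!is.null(truth)) truth$module_sets$module_up else
           stop_config("cohort stage needs module_genes")),
      beta = coh_cfg$beta %||% 0.5,
      noise_sd = coh_cfg$noise_sd %||% 1,
      responder_effect = coh_cfg$responder_effect %||% 1,
      seed = split_seed(seed, "cohort")))
    scores <- stage("cohort", endothelial_score(coh$cohort, coh$signature))
    msc <- stage("cohort", module_score_correlation(
      coh$cohort, coh$truth$module_sets$module, scores))
    utils::write.table(data.frame(sample = names(scores), score = scores),
                       file.path(out_dir, "endothelial_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$cohort <- list(module_score_r = msc$r, module_score_p = msc$p,
                           n_samples = msc$n)
  }

  # ---- delta-delta-Ct (optional) -----------------------------------------
  ddct_cfg <- config$ddct
  if (!is.null(ddct_cfg)) {
    card <- stage("ddct", generate_ct_card(
      n_mirna = ddct_cfg$n_mirna %||% 48L,
      shifted_ids = unlist(ddct_cfg$shifted_ids %||% character(0)),
      shift_ddct = ddct_cfg$shift_ddct %||% 0,
      seed = split_seed(seed, "ddct"),
      noise_sd = ddct_cfg$noise_sd %||% 0))
    dd <- stage("ddct", ddct_analysis(card$ct_table,
                                      threshold = ddct_cfg$threshold %||% 2))
    utils::write.table(as.data.frame(dd), file.path(out_dir, "ddct.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$ddct <- list(n_altered = sum(dd$passes_threshold),
                         altered = sort(unique(dd$assay[dd$passes_threshold])))
  }

  # ---- outputs ------------------------------------------------------------
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns")
  manifest <- list(
    package_version = as.character(utils::packageVersion("sproutnet")),
    seed = seed,
    config = config,
    outputs = sort(setdiff(list.files(out_dir), c("manifest.json", "log.txt"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  logf("pipeline complete: %d edges", summary$network$n_edges)
  invisible(out_dir)
}

#' Precision and recall of network edges against planted truth
#'
#' @param net a `RegulatoryNetwork`.
#' @param truth a `SyntheticTruth` with `planted_edges`.
#' @return list with `precision`, `recall`, `n_called`, `n_true`.
#' @export
edge_recovery <- function(net, truth) {
  e <- network_edges(net)
  key <- function(m, g) paste(m, g, sep = "\r")
  called <- key(e$mirna, e$gene)
  planted <- key(truth$planted_edges$mirna, truth$planted_edges$gene)
  tp <- sum(called %in% planted)
  list(precision = if (length(called)) tp / length(called) else NA_real_,
       recall = if (length(planted)) tp / length(planted) else NA_real_,
       n_called = length(called), n_true = length(planted))
}
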