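# Synthetic two-condition miRNA/mRNA experiments with planted
# post-transcriptional structure: negative-binomial counts, up/down
# regulator miRNAs whose predicted targets shift in the opposite
# direction, power-law out-degrees, decoy predictions, module-aligned
# gene sets, and a ground-truth key for every recovery test. One RNG
# stream per generated artifact is split from the master seed so adding
# one output never perturbs another.

#' Configuration for a synthetic two-condition experiment
#'
#' Defaults emulate a 3 + 3 replicate spheroid-style design: ~25% of
#' miRNAs act as regulators, planted out-degrees follow a discrete power
#' law, and each regulator draws its targets from a direction-specific
#' module pool so that target sharing concentrates regulation on a small
#' gene module (as in real miRNA networks).
#'
#' @param n_mirna,n_gene feature counts.
#' @param n_regulator_up,n_regulator_down numbers of up-/down-regulated
#'   regulator miRNAs.
#' @param out_degree_alpha power-law exponent of planted out-degrees (> 1).
#' @param out_degree_min power-law lower bound (xmin) of out-degrees.
#' @param module_size per-direction target-pool size; out-degrees are
#'   truncated at this pool size.
#' @param effect_lfc planted |log2 fold change| of regulators/targets.
#' @param nb_dispersion negative-binomial dispersion d in
#'   `var = mu + d * mu^2` (0 gives Poisson counts).
#' @param baseline_log2_mean,baseline_log2_sd log2-scale distribution of
#'   baseline feature means.
#' @param replicates_per_condition replicates per condition (>= 2).
#' @param decoy_prediction_ratio decoy predictions per planted edge, per
#'   conservation class.
#' @param n_decoy_predictions explicit decoy count overriding the ratio
#'   (per class); lets a null experiment carry a non-empty stratum.
#' @param size_factor_spread library-size multipliers drawn uniformly in
#'   `1 +- spread`.
#' @param n_random_sets,random_set_size decoy gene sets in the collection.
#' @param seed master seed.
#' @return A validated `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_mirna = 40L, n_gene = 400L,
                             n_regulator_up = 10L, n_regulator_down = 10L,
                             out_degree_alpha = 2.5, out_degree_min = 8L,
                             module_size = 60L, effect_lfc = 2,
                             nb_dispersion = 0.05,
                             baseline_log2_mean = 9, baseline_log2_sd = 1,
                             replicates_per_condition = 3L,
                             decoy_prediction_ratio = 3,
                             n_decoy_predictions = NULL,
                             size_factor_spread = 0.2,
                             n_random_sets = 8L, random_set_size = 20L,
                             seed = 1L) {
  cfg <- list(n_mirna = as.integer(n_mirna), n_gene = as.integer(n_gene),
              n_regulator_up = as.integer(n_regulator_up),
              n_regulator_down = as.integer(n_regulator_down),
              out_degree_alpha = out_degree_alpha,
              out_degree_min = as.integer(out_degree_min),
              module_size = as.integer(module_size),
              effect_lfc = effect_lfc, nb_dispersion = nb_dispersion,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              replicates_per_condition = as.integer(replicates_per_condition),
              decoy_prediction_ratio = decoy_prediction_ratio,
              n_decoy_predictions = n_decoy_predictions,
              size_factor_spread = size_factor_spread,
              n_random_sets = as.integer(n_random_sets),
              random_set_size = as.integer(random_set_size),
              seed = as.integer(seed))
  with(cfg, {
    if (n_regulator_up + n_regulator_down > n_mirna)
      stop_config("regulator counts exceed n_mirna")
    if (out_degree_alpha <= 1) stop_config("out_degree_alpha must exceed 1")
    if (nb_dispersion < 0) stop_config("nb_dispersion must be >= 0")
    if (replicates_per_condition < 2L)
      stop_config("need >= 2 replicates per condition")
    if (effect_lfc < 0) stop_config("effect_lfc must be >= 0")
    if (decoy_prediction_ratio < 0) stop_config("decoy ratio must be >= 0")
    if (2L * module_size > n_gene)
      stop_config("module pools exceed gene count")
    if ((n_regulator_up + n_regulator_down) > 0 && out_degree_min > module_size)
      stop_config("infeasible out-degree demand: out_degree_min exceeds the target pool")
  })
  structure(cfg, class = "SyntheticConfig")
}

nb_counts <- function(mu, dispersion) {
  if (dispersion == 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

count_matrix_from_mu <- function(base_mu, shift_dir, effect_lfc, cfg, ids) {
  R <- cfg$replicates_per_condition
  samples <- c(paste0("ctrl_", seq_len(R)), paste0("trt_", seq_len(R)))
  condition <- stats::setNames(rep(c("control", "treated"), each = R), samples)
  sf <- stats::runif(2L * R, 1 - cfg$size_factor_spread,
                     1 + cfg$size_factor_spread)
  mult <- ifelse(shift_dir == "up", 2^cfg$effect_lfc,
                 ifelse(shift_dir == "down", 2^(-cfg$effect_lfc), 1))
  m <- matrix(0, length(base_mu), 2L * R, dimnames = list(ids, samples))
  for (j in seq_len(2L * R)) {
    mu_j <- base_mu * sf[j]
    if (condition[j] == "treated") mu_j <- mu_j * mult
    m[, j] <- nb_counts(mu_j, cfg$nb_dispersion)
  }
  list(values = m, condition = condition)
}

#' Generate a synthetic two-condition experiment with planted structure
#'
#' Counts are drawn negative-binomially around condition means; regulator
#' miRNAs shift by `+-effect_lfc` in the treated condition; each regulator
#' receives an out-degree from a discrete power law (truncated at the
#' module pool size) and its targets shift in the opposite direction. All
#' planted edges appear in the prediction table as conserved records with
#' percentile in (50, 100]; decoy predictions over non-planted pairs are
#' added per conservation class (conserved in (50, 100], non-conserved in
#' (90, 100]). The gene-set collection holds one set per planted module
#' plus random sets.
#'
#' @param config a [synthetic_config()].
#' @return list with `mirna` and `gene` [expression_matrix()]s,
#'   `predictions` ([prediction_table()]), `genesets`
#'   ([gene_set_collection()]), and `truth` (`SyntheticTruth`: planted
#'   edge data.frame, direction maps, module sets, out-degrees).
#' @export
generate_experiment <- function(config) {
  cfg <- config
  mirna_ids <- sprintf("mir%03d", seq_len(cfg$n_mirna))
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_gene))

  st <- with_seed(split_seed(cfg$seed, "structure"), {
    regs <- sample(mirna_ids, cfg$n_regulator_up + cfg$n_regulator_down)
    up_regs <- regs[seq_len(cfg$n_regulator_up)]
    down_regs <- setdiff(regs, up_regs)
    pools <- sample(gene_ids, 2L * cfg$module_size)
    down_pool <- pools[seq_len(cfg$module_size)]     # targets of up regulators
    up_pool <- setdiff(pools, down_pool)             # targets of down regulators
    edges <- list()
    out_deg <- integer(0)
    for (m in c(up_regs, down_regs)) {
      pool <- if (m %in% up_regs) down_pool else up_pool
      d <- min(rpldis(1L, cfg$out_degree_alpha, cfg$out_degree_min),
               length(pool))
      tg <- sample(pool, d)
      edges[[m]] <- data.frame(mirna = m, gene = tg, stringsAsFactors = FALSE)
      out_deg[m] <- d
    }
    planted <- if (length(edges)) do.call(rbind, edges) else
      data.frame(mirna = character(0), gene = character(0))
    rownames(planted) <- NULL
    mirna_dir <- stats::setNames(rep("null", cfg$n_mirna), mirna_ids)
    mirna_dir[up_regs] <- "up"; mirna_dir[down_regs] <- "down"
    gene_dir <- stats::setNames(rep("null", cfg$n_gene), gene_ids)
    gene_dir[unique(planted$gene[planted$mirna %in% up_regs])] <- "down"
    gene_dir[unique(planted$gene[planted$mirna %in% down_regs])] <- "up"
    list(planted = planted, mirna_dir = mirna_dir, gene_dir = gene_dir,
         out_deg = out_deg)
  })

  mir_mu <- with_seed(split_seed(cfg$seed, "mirna_mu"),
    2^stats::rnorm(cfg$n_mirna, cfg$baseline_log2_mean, cfg$baseline_log2_sd))
  gene_mu <- with_seed(split_seed(cfg$seed, "gene_mu"),
    2^stats::rnorm(cfg$n_gene, cfg$baseline_log2_mean, cfg$baseline_log2_sd))

  mir_cm <- with_seed(split_seed(cfg$seed, "mirna_counts"),
    count_matrix_from_mu(mir_mu, st$mirna_dir, cfg$effect_lfc, cfg, mirna_ids))
  gene_cm <- with_seed(split_seed(cfg$seed, "gene_counts"),
    count_matrix_from_mu(gene_mu, st$gene_dir, cfg$effect_lfc, cfg, gene_ids))

  mirs <- expression_matrix(mir_cm$values, mir_cm$condition, kind = "mirna")
  genes <- expression_matrix(gene_cm$values, gene_cm$condition, kind = "gene")

  n_planted <- nrow(st$planted)
  n_decoy_total <- if (!is.null(cfg$n_decoy_predictions))
    as.integer(cfg$n_decoy_predictions)
  else as.integer(round(cfg$decoy_prediction_ratio * n_planted))
  # the decoy budget is split evenly across the two conservation classes
  n_cons_decoy <- n_decoy_total %/% 2L
  n_noncons_decoy <- n_decoy_total - n_cons_decoy

  pred <- with_seed(split_seed(cfg$seed, "predictions"), {
    pair_id <- function(m, g)
      (match(m, mirna_ids) - 1) * cfg$n_gene + match(g, gene_ids)
    planted_idx <- if (n_planted) pair_id(st$planted$mirna, st$planted$gene)
    else integer(0)
    draw_decoys <- function(n) {
      if (n <= 0) return(integer(0))
      avail <- setdiff(seq_len(cfg$n_mirna * cfg$n_gene), planted_idx)
      sample(avail, min(n, length(avail)))
    }
    cons_idx <- draw_decoys(n_cons_decoy)
    noncons_idx <- draw_decoys(n_noncons_decoy)
    idx_mir <- function(i) mirna_ids[(i - 1) %/% cfg$n_gene + 1]
    idx_gene <- function(i) gene_ids[(i - 1) %% cfg$n_gene + 1]
    prediction_table(
      mirna = c(st$planted$mirna, idx_mir(cons_idx), idx_mir(noncons_idx)),
      gene = c(st$planted$gene, idx_gene(cons_idx), idx_gene(noncons_idx)),
      conservation = c(rep("conserved", n_planted + length(cons_idx)),
                       rep("nonconserved", length(noncons_idx))),
      percentile = c(stats::runif(n_planted + length(cons_idx), 50, 100),
                     stats::runif(length(noncons_idx), 90, 100)))
  })

  module_sets <- list(
    module_down = sort(names(st$gene_dir)[st$gene_dir == "down"]),
    module_up = sort(names(st$gene_dir)[st$gene_dir == "up"]))
  module_sets <- module_sets[lengths(module_sets) > 0]
  gsc <- with_seed(split_seed(cfg$seed, "genesets"), {
    rand <- lapply(seq_len(cfg$n_random_sets), function(i)
      sample(gene_ids, cfg$random_set_size))
    names(rand) <- sprintf("random_set_%02d", seq_len(cfg$n_random_sets))
    gene_set_collection(c(module_sets, rand),
                        description = c(rep("planted module", length(module_sets)),
                                        rep("random decoy set", cfg$n_random_sets)))
  })

  truth <- structure(list(planted_edges = st$planted,
                          mirna_direction = st$mirna_dir,
                          gene_direction = st$gene_dir,
                          module_sets = module_sets,
                          out_degrees = st$out_deg,
                          cohort_beta = NA_real_),
                     class = "SyntheticTruth")
  list(mirna = mirs, gene = genes, predictions = pred, genesets = gsc,
       truth = truth, config = cfg)
}

#' Generate a synthetic tumor cohort with a latent endothelial score
#'
#' Each sample carries a latent score `z ~ N(0, 1)`. Signature genes
#' follow `a * z + noise`, module genes `beta * z + noise`; responders
#' (labelled `treated` in the condition map) additionally receive
#' `responder_effect` on module genes. Background genes are pure noise.
#'
#' @param n_samples cohort size (>= 10).
#' @param signature_genes,module_genes gene id vectors (may overlap).
#' @param beta latent-score loading of module genes.
#' @param noise_sd residual standard deviation (> 0).
#' @param responder_effect shift added to module genes in responders.
#' @param seed integer seed.
#' @param n_background number of noise-only genes.
#' @param signature_strength latent loading `a` of signature genes.
#' @param responder_frac fraction of responder samples.
#' @return list with `cohort` (an [expression_matrix()], `normalized`),
#'   `signature`, `response` (named 0/1 vector), and `truth` (latent
#'   scores and `cohort_beta`).
#' @export
generate_cohort <- function(n_samples = 100L, signature_genes, module_genes,
                            beta = 0.5, noise_sd = 1, responder_effect = 1,
                            seed = 1L, n_background = 200L,
                            signature_strength = 1, responder_frac = 0.5) {
  if (noise_sd <= 0) stop_config("noise_sd must be > 0")
  if (n_samples < 10L) stop_config("n_samples must be >= 10")
  samples <- sprintf("s%03d", seq_len(n_samples))
  bg_genes <- sprintf("bg%04d", seq_len(n_background))
  all_genes <- unique(c(signature_genes, module_genes, bg_genes))
  with_seed(seed, {
    z <- stats::rnorm(n_samples)
    resp <- as.integer(sample(n_samples) <= round(responder_frac * n_samples))
    m <- matrix(stats::rnorm(length(all_genes) * n_samples, sd = noise_sd),
                length(all_genes), n_samples,
                dimnames = list(all_genes, samples))
    m[signature_genes, ] <- m[signature_genes, , drop = FALSE] +
      rep(signature_strength * z, each = length(signature_genes))
    m[module_genes, ] <- m[module_genes, , drop = FALSE] +
      rep(beta * z, each = length(module_genes)) +
      rep(responder_effect * resp, each = length(module_genes))
    condition <- stats::setNames(ifelse(resp == 1, "treated", "control"),
                                 samples)
    cohort <- expression_matrix(m, condition, kind = "gene", normalized = TRUE)
    truth <- structure(list(latent_score = stats::setNames(z, samples),
                            response = stats::setNames(resp, samples),
                            module_sets = list(module = module_genes),
                            cohort_beta = beta),
                       class = "SyntheticTruth")
    list(cohort = cohort, signature = signature_genes,
         response = stats::setNames(resp, samples), truth = truth)
  })
}

#' Generate a synthetic qPCR miRNA card
#'
#' Ct values for control and treated conditions, run in duplicate. After
#' global-mean normalization, miRNAs in `shifted_ids` carry a
#' delta-delta-Ct offset of `shift_ddct` (up to the small global-mean
#' compensation `shift_ddct * m / n`); all others are null.
#'
#' @param n_mirna number of assays on the card.
#' @param shifted_ids assay ids to shift (subset of the generated ids
#'   `card_mir_01` ...).
#' @param shift_ddct planted Ct offset in the treated condition.
#' @param seed integer seed.
#' @param noise_sd technical Ct noise (0 for exact recovery).
#' @param n_replicates duplicates per condition.
#' @return list with `ct_table` (data.frame assay/condition/replicate/ct)
#'   and `truth` (shifted ids and planted shift).
#' @export
generate_ct_card <- function(n_mirna = 48L, shifted_ids = character(0),
                             shift_ddct = 0, seed = 1L, noise_sd = 0,
                             n_replicates = 2L) {
  if (!is.finite(shift_ddct)) stop_config("shift magnitude must be finite")
  ids <- sprintf("card_mir_%02d", seq_len(n_mirna))
  unknown <- setdiff(shifted_ids, ids)
  if (length(unknown))
    stop_config("shifted ids not on the card: %s", paste(unknown, collapse = ", "))
  with_seed(seed, {
    base <- stats::runif(n_mirna, 20, 30)
    grid <- expand.grid(assay = ids, condition = c("control", "treated"),
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    ct <- base[match(grid$assay, ids)] +
      ifelse(grid$condition == "treated" & grid$assay %in% shifted_ids,
             shift_ddct, 0) +
      stats::rnorm(nrow(grid), sd = noise_sd)
    list(ct_table = data.frame(grid, ct = ct, stringsAsFactors = FALSE),
         truth = structure(list(shifted_ids = shifted_ids,
                                shift_ddct = shift_ddct),
                           class = "SyntheticTruth"))
  })
}
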