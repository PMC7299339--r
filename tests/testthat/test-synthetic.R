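# Synthetic-data generator: determinism, planted effects, noise model.

test_that("identical seeds give identical experiments", {
  a <- generate_experiment(small_config(seed = 12))
  b <- generate_experiment(small_config(seed = 12))
  expect_identical(a$mirna$values, b$mirna$values)
  expect_identical(a$gene$values, b$gene$values)
  expect_identical(as.data.frame(a$predictions), as.data.frame(b$predictions))
  expect_identical(a$genesets$sets, b$genesets$sets)
  expect_identical(a$truth$planted_edges, b$truth$planted_edges)

  c <- generate_experiment(small_config(seed = 13))
  expect_false(identical(a$mirna$values, c$mirna$values))
})

test_that("planted edges join regulators and targets of opposite direction", {
  exp <- generate_experiment(small_config(seed = 4))
  tr <- exp$truth
  md <- tr$mirna_direction[tr$planted_edges$mirna]
  gd <- tr$gene_direction[tr$planted_edges$gene]
  expect_true(all(md %in% c("up", "down")))
  expect_true(all(ifelse(md == "up", "down", "up") == gd))
  # every planted edge appears as a conserved prediction above percentile 50
  key <- function(m, g) paste(m, g)
  cons <- exp$predictions[exp$predictions$conservation == "conserved", ]
  expect_true(all(key(tr$planted_edges$mirna, tr$planted_edges$gene) %in%
                    key(cons$mirna, cons$gene)))
  expect_true(all(exp$predictions$percentile > 50 |
                    exp$predictions$conservation == "nonconserved"))
})

test_that("null effect size leaves regulator fold changes centred at zero", {
  lfcs <- unlist(lapply(1:25, function(s) {
    exp <- generate_experiment(small_config(seed = s, effect_lfc = 0))
    de <- differential_expression(normalize_counts(exp$mirna),
                                  lfc_threshold = 0, fdr_cutoff = 1)
    regs <- names(exp$truth$mirna_direction)[exp$truth$mirna_direction != "null"]
    de$log2fc[match(regs, de$feature_id)]
  }))
  expect_lt(abs(mean(lfcs)), 0.1)
})

test_that("planted targets realize the configured fold change", {
  cfg <- synthetic_config(seed = 21)       # 400 genes, ~300 planted edges
  exp <- generate_experiment(cfg)
  de <- differential_expression(normalize_counts(exp$gene),
                                lfc_threshold = 0, fdr_cutoff = 1)
  down <- names(exp$truth$gene_direction)[exp$truth$gene_direction == "down"]
  up <- names(exp$truth$gene_direction)[exp$truth$gene_direction == "up"]
  expect_lt(abs(mean(de$log2fc[match(down, de$feature_id)]) + cfg$effect_lfc), 0.3)
  expect_lt(abs(mean(de$log2fc[match(up, de$feature_id)]) - cfg$effect_lfc), 0.3)
})

test_that("counts are overdispersed when the NB dispersion is positive", {
  exp <- generate_experiment(small_config(seed = 2, nb_dispersion = 0.3,
                                          size_factor_spread = 0))
  v <- exp$gene$values[, exp$gene$condition == "control"]
  rv <- apply(v, 1, var); rm_ <- rowMeans(v)
  expect_gt(mean(rv - rm_), 0)           # pooled variance exceeds the mean
  expect_gt(mean(rv / rm_ > 1), 0.8)     # and does so for most features
})

test_that("infeasible out-degree demand raises a configuration error", {
  expect_error(synthetic_config(out_degree_min = 50L, module_size = 30L),
               class = "sproutnet_config_error")
  expect_error(synthetic_config(n_regulator_up = 30L, n_regulator_down = 30L,
                                n_mirna = 40L),
               class = "sproutnet_config_error")
  expect_error(synthetic_config(nb_dispersion = -1),
               class = "sproutnet_config_error")
})

test_that("power-law out-degree sampler recovers the configured exponent", {
  set.seed(31)
  x <- rpldis(6000, 2.5, 1)
  fit <- fit_power_law(x, n_bootstrap = 0)
  expect_lt(abs(fit$alpha - 2.5), 0.2)
})

test_that("cohort generator plants a recoverable latent score", {
  a <- generate_cohort(n_samples = 60, signature_genes = sprintf("sig%02d", 1:35),
                       module_genes = sprintf("mod%02d", 1:20),
                       beta = 2, noise_sd = 0.3, seed = 5)
  b <- generate_cohort(n_samples = 60, signature_genes = sprintf("sig%02d", 1:35),
                       module_genes = sprintf("mod%02d", 1:20),
                       beta = 2, noise_sd = 0.3, seed = 5)
  expect_identical(a$cohort$values, b$cohort$values)

  # strong coupling, weak noise: module mean tracks the latent score
  mm <- colMeans(a$cohort$values[sprintf("mod%02d", 1:20), ])
  expect_gt(cor(mm, a$truth$latent_score), 0.95)

  # beta = 0: correlation stays inside the null band most of the time
  rs <- vapply(1:40, function(s) {
    g <- generate_cohort(n_samples = 64, signature_genes = sprintf("sig%02d", 1:10),
                         module_genes = sprintf("mod%02d", 1:10),
                         beta = 0, noise_sd = 1, responder_effect = 0, seed = s)
    mm <- colMeans(g$cohort$values[sprintf("mod%02d", 1:10), ])
    cor(mm, g$truth$latent_score)
  }, numeric(1))
  expect_gte(mean(abs(rs) < 2 / sqrt(64)), 0.8)

  expect_error(generate_cohort(60, "a", "b", noise_sd = 0),
               class = "sproutnet_config_error")
  expect_error(generate_cohort(5, "a", "b"),
               class = "sproutnet_config_error")
})

test_that("ct card planting is exact at zero noise and robust at low noise", {
  shifted <- sprintf("card_mir_%02d", 1:5)
  card <- generate_ct_card(48, shifted, shift_ddct = 3, seed = 1, noise_sd = 0)
  dd <- ddct_analysis(card$ct_table)
  expect_setequal(dd$assay[dd$passes_threshold], shifted)

  null_card <- generate_ct_card(48, shifted, shift_ddct = 0, seed = 1,
                                noise_sd = 0)
  dd0 <- ddct_analysis(null_card$ct_table)
  expect_equal(sum(dd0$passes_threshold), 0L)

  # duplicate determinism
  card2 <- generate_ct_card(48, shifted, shift_ddct = 3, seed = 1, noise_sd = 0)
  expect_identical(card$ct_table, card2$ct_table)

  # noisy recovery, pooled over seeds
  rec <- vapply(1:40, function(s) {
    cd <- generate_ct_card(48, shifted, shift_ddct = 3, seed = s,
                           noise_sd = 0.3)
    dd <- ddct_analysis(cd$ct_table)
    mean(shifted %in% dd$assay[dd$passes_threshold])
  }, numeric(1))
  expect_gte(mean(rec), 0.9)
})
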