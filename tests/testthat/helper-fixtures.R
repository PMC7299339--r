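# Shared fixtures, built in code at test time.

cond6 <- function() {
  stats::setNames(rep(c("control", "treated"), each = 3),
                  c(paste0("c", 1:3), paste0("t", 1:3)))
}

# small raw-count matrix with named features/samples
toy_counts <- function(nf = 6, seed = 1, kind = "gene") {
  set.seed(seed)
  m <- matrix(rpois(nf * 6, lambda = 50), nf, 6,
              dimnames = list(sprintf("f%02d", seq_len(nf)), names(cond6())))
  expression_matrix(m, cond6(), kind = kind)
}

# the hand-enumerated toy tables used for edge-calling checks:
# m1 up, m2 down; g1 down, g2 up, g3 down; conserved predictions
# (m1,g1,60), (m1,g2,70), (m2,g2,55); correlations r(m1,g1) = -0.95
# p = 0.004, r(m1,g2) = -0.20 p = 0.70, r(m2,g2) = -0.92 p = 0.01.
toy_network_tables <- function() {
  de_mir <- de_table(c("m1", "m2"), base_mean = c(100, 100),
                     log2fc = c(1.2, -1.1), p = c(1e-4, 2e-4),
                     fdr = c(1e-3, 2e-3))
  de_gene <- de_table(c("g1", "g2", "g3"), base_mean = c(50, 50, 50),
                      log2fc = c(-0.9, 0.8, -0.7), p = rep(1e-4, 3),
                      fdr = rep(1e-3, 3))
  pt <- prediction_table(mirna = c("m1", "m1", "m2"),
                         gene = c("g1", "g2", "g2"),
                         conservation = rep("conserved", 3),
                         percentile = c(60, 70, 55))
  ct <- correlation_table(mirna = c("m1", "m1", "m2"),
                          gene = c("g1", "g2", "g2"),
                          r = c(-0.95, -0.20, -0.92),
                          p_analytic = c(0.004, 0.70, 0.01),
                          n_samples = 6)
  list(de_mir = de_mir, de_gene = de_gene, pt = pt, ct = ct)
}

toy_network <- function(...) {
  tb <- toy_network_tables()
  build_network(tb$de_mir, tb$de_gene, tb$ct, tb$pt, ...)
}

# sorted (mirna, gene) edge keys of a network
edge_keys <- function(net) {
  e <- network_edges(net)
  sort(paste(e$mirna, e$gene))
}

# independent naive enrichment-score walk (test oracle, kept deliberately
# simple and quadratic)
naive_es <- function(genes_ranked, metrics, set, weight = 1) {
  N <- length(genes_ranked)
  hit <- genes_ranked %in% set
  nh <- sum(hit)
  denom <- sum(abs(metrics[hit])^weight)
  run <- numeric(N)
  s <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      s <- s + (if (denom > 0) abs(metrics[i])^weight / denom else 1 / nh)
    } else {
      s <- s - 1 / (N - nh)
    }
    run[i] <- s
  }
  run[which.max(abs(run))]
}

# independent quadratic two-sample KS statistic (max ECDF gap)
naive_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

# small synthetic configuration for fast end-to-end tests
small_config <- function(seed = 1, ...) {
  args <- list(n_mirna = 16L, n_gene = 120L, n_regulator_up = 4L,
               n_regulator_down = 4L, out_degree_min = 4L,
               module_size = 25L, n_random_sets = 3L,
               random_set_size = 10L, seed = seed)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

run_small_network <- function(seed = 1, ...) {
  exp <- generate_experiment(small_config(seed = seed, ...))
  mir <- normalize_counts(filter_expressed(exp$mirna))
  gen <- normalize_counts(filter_expressed(exp$gene))
  de_m <- differential_expression(mir)
  de_g <- differential_expression(gen)
  ct <- pairwise_correlation(mir, gen)
  net <- suppressWarnings(build_network(de_m, de_g, ct, exp$predictions))
  list(exp = exp, mir = mir, gen = gen, de_m = de_m, de_g = de_g,
       ct = ct, net = net)
}
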