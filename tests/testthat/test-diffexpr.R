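# Expression filter, median-of-ratios normalization, Welch-t DE stage.

test_that("filter_expressed keeps features with mean strictly above cutoff", {
  m <- matrix(c(rep(5, 6),            # mean exactly 5: dropped
                c(0, 0, 0, 0, 0, 36), # mean 6: kept
                rep(0, 6), rep(4, 6), rep(100, 6)),
              nrow = 5, byrow = TRUE,
              dimnames = list(paste0("f", 1:5), names(cond6())))
  em <- expression_matrix(m, cond6())
  kept <- filter_expressed(em)
  expect_setequal(rownames(kept$values), c("f2", "f5"))

  means <- c(0, 4, 5, 6, 100)
  expect_equal(nrow(kept$values), sum(means > 5))
  expect_error(filter_expressed(normalize_counts(toy_counts())),
               class = "sproutnet_contract_error")
})

test_that("size factors match the hand-computed median of ratios", {
  m <- matrix(c(2, 4, 8, 16, 2, 8), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  em <- expression_matrix(m, c(s1 = "control", s2 = "control"))
  sf <- size_factors(em)
  # geometric means: sqrt(8), sqrt(128), 4; ratio medians: 1/sqrt(2), sqrt(2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # sample2 = 2 x sample1: normalized values equal across samples
  m2 <- cbind(s1 = c(3, 7, 11), s2 = c(6, 14, 22))
  rownames(m2) <- c("a", "b", "c")
  em2 <- expression_matrix(m2, c(s1 = "control", s2 = "control"))
  nm <- normalize_counts(em2)
  expect_equal(nm$values[, 1], nm$values[, 2], tolerance = 1e-12)
  expect_true(nm$normalized)

  # identical samples: all size factors equal
  m3 <- cbind(s1 = c(3, 9), s2 = c(3, 9))
  rownames(m3) <- c("a", "b")
  em3 <- expression_matrix(m3, c(s1 = "control", s2 = "control"))
  expect_equal(diff(unname(size_factors(em3))), 0)

  # every feature contains a zero: size-factor error
  m4 <- cbind(s1 = c(0, 5), s2 = c(5, 0))
  rownames(m4) <- c("a", "b")
  expect_error(size_factors(expression_matrix(m4, c(s1 = "control", s2 = "control"))),
               class = "sproutnet_contract_error")
})

test_that("differential expression nulls constant features and checks design", {
  m <- toy_counts(nf = 10, seed = 2)
  # constant feature on the normalized scale: build the matrix directly
  nm <- m$values
  nm[1, ] <- 42
  em <- expression_matrix(nm, m$condition, normalized = TRUE)
  de <- differential_expression(em)
  expect_equal(de$log2fc[de$feature_id == "f01"], 0)
  expect_equal(de$p[de$feature_id == "f01"], 1)
  expect_equal(de$direction[de$feature_id == "f01"], "ns")

  # a design with a missing condition is a contract error
  ctrl_only <- expression_matrix(
    m$values[, c("c1", "c2", "c3")],
    c(c1 = "control", c2 = "control", c3 = "control"), normalized = TRUE)
  expect_error(differential_expression(ctrl_only),
               class = "sproutnet_contract_error")
  expect_error(differential_expression(m),   # raw counts refused
               class = "sproutnet_contract_error")
})

test_that("DE fdr equals a quadratic-time BH reference", {
  run <- run_small_network(seed = 5)
  de <- run$de_g
  # reference: step-up BH computed the slow way
  bh_ref <- function(p) {
    n <- length(p)
    ord <- order(p)
    q <- rep(NA_real_, n)
    running_min <- Inf
    for (i in rev(seq_len(n))) {
      val <- p[ord[i]] * n / i
      running_min <- min(running_min, val)
      q[ord[i]] <- min(1, running_min)
    }
    q
  }
  expect_equal(de$fdr, bh_ref(de$p), tolerance = 1e-12)
})

test_that("direction is a pure function of (log2fc, fdr, thresholds)", {
  tab <- de_table(feature_id = c("g1", "g2", "g3", "g4"),
                  base_mean = 10, log2fc = c(0.6, 0.6, -0.5, -0.8),
                  p = 1e-4, fdr = c(1e-3, 0.2, 1e-3, 1e-3))
  expect_equal(tab$direction, c("up", "ns", "ns", "down"))
  # |lfc| exactly at the threshold fails the strict rule
  strict <- de_table("x", 1, log2fc = 0.5, p = 1e-5, fdr = 1e-4)
  expect_equal(strict$direction, "ns")
})

test_that("ingest_de_table recomputes directions from thresholds", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\tlog2fc\tp\tfdr",
               "g1\t0.6\t1e-4\t1e-3",
               "g2\t0.6\t1e-4\t0.2",
               "g3\t-0.5\t1e-4\t1e-3"), tf)
  de <- ingest_de_table(tf)
  expect_equal(de$direction, c("up", "ns", "ns"))
  expect_equal(attr(de, "origin"), "external")

  writeLines(c("feature\tlog2fc\tp", "g1\t0.6\t1e-4"), tf)
  expect_error(ingest_de_table(tf), class = "sproutnet_format_error")
})

test_that("DE on null data stays near the nominal FDR level", {
  fracs <- vapply(1:30, function(s) {
    exp <- generate_experiment(small_config(
      seed = s, n_regulator_up = 0L, n_regulator_down = 0L, effect_lfc = 0))
    de <- differential_expression(normalize_counts(filter_expressed(exp$gene)))
    mean(de$fdr < 0.05)
  }, numeric(1))
  expect_lte(mean(fracs), 0.07)
})

test_that("planted regulators and targets are recovered in a dense design", {
  # dense-signal regime: most genes carry planted effects, so the BH
  # threshold adapts upward and the 3+3 Welch t has the power to call
  # nearly all planted features
  cfg <- synthetic_config(n_mirna = 40L, n_gene = 150L, module_size = 60L,
                          out_degree_min = 8L, seed = 11)
  exp <- generate_experiment(cfg)
  de_m <- differential_expression(normalize_counts(filter_expressed(exp$mirna)))
  de_g <- differential_expression(normalize_counts(filter_expressed(exp$gene)))
  tm <- exp$truth$mirna_direction[exp$truth$mirna_direction != "null"]
  tg <- exp$truth$gene_direction[exp$truth$gene_direction != "null"]
  called_m <- de_m$direction[match(names(tm), de_m$feature_id)]
  called_g <- de_g$direction[match(names(tg), de_g$feature_id)]
  hit <- c(called_m == unname(tm), called_g == unname(tg))
  expect_gte(mean(hit), 0.9)
})
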