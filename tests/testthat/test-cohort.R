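# Hypergeometric over-representation, signature scoring, delta-delta-Ct.

test_that("hypergeometric tail matches hand-enumerated values", {
  expect_equal(hypergeometric_test(0, 5, 5, 10)$p_upper, 1)
  expect_equal(hypergeometric_test(5, 5, 5, 10)$p_upper, 1 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeometric_test(1, 2, 2, 4)$p_upper, 5 / 6,
               tolerance = 1e-12)
  expect_error(hypergeometric_test(6, 5, 5, 10),
               class = "sproutnet_contract_error")
  expect_error(hypergeometric_test(1, 5, 11, 10),
               class = "sproutnet_contract_error")
})

test_that("hypergeometric tail equals literal draw enumeration for small N", {
  # enumerate every n-subset of a labelled universe and count overlaps
  for (N in c(6, 8)) {
    for (K in c(2, 4)) {
      for (n in c(3, 5)) {
        marked <- seq_len(K)
        draws <- utils::combn(N, n)
        for (k in 0:min(K, n)) {
          p_enum <- mean(apply(draws, 2, function(d)
            sum(d %in% marked) >= k))
          expect_equal(hypergeometric_test(k, K, n, N)$p_upper, p_enum,
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("endothelial score ranks a dominating sample first", {
  set.seed(6)
  sig <- sprintf("sig%02d", 1:10)
  v <- matrix(rnorm(12 * 10), 12, 10,
              dimnames = list(c(sig, "other1", "other2"), sprintf("s%02d", 1:10)))
  v[sig, "s03"] <- v[sig, "s03"] + 10
  cond <- stats::setNames(rep(c("control", "treated"), each = 5),
                          sprintf("s%02d", 1:10))
  coh <- expression_matrix(v, cond, normalized = TRUE)
  sc <- endothelial_score(coh, sig)
  expect_equal(names(sc)[1], "s03")
  expect_equal(sort(names(sc)), sort(colnames(v)))

  # constant signature gene excluded with a warning
  v2 <- v; v2["sig01", ] <- 3
  coh2 <- expression_matrix(v2, cond, normalized = TRUE)
  expect_warning(sc2 <- endothelial_score(coh2, sig), "constant")
  expect_equal(length(sc2), 10L)

  expect_error(endothelial_score(coh, c("nope1", "nope2")),
               class = "sproutnet_contract_error")
})

test_that("endothelial score is invariant to per-gene affine rescaling", {
  set.seed(8)
  sig <- sprintf("sig%02d", 1:8)
  v <- matrix(rnorm(8 * 12), 8, 12,
              dimnames = list(sig, sprintf("s%02d", 1:12)))
  cond <- stats::setNames(rep(c("control", "treated"), each = 6),
                          colnames(v))
  sc1 <- endothelial_score(expression_matrix(v, cond, normalized = TRUE), sig)
  a <- runif(8, 0.5, 4); b <- rnorm(8, sd = 10)
  v2 <- v * a + b
  sc2 <- endothelial_score(expression_matrix(v2, cond, normalized = TRUE), sig)
  expect_equal(sc1, sc2[names(sc1)], tolerance = 1e-12)
})

test_that("module-score correlation is exact for module == signature", {
  g <- generate_cohort(n_samples = 50, signature_genes = sprintf("sig%02d", 1:10),
                       module_genes = sprintf("mod%02d", 1:10),
                       beta = 1, noise_sd = 1, seed = 2)
  sc <- endothelial_score(g$cohort, g$signature)
  self <- module_score_correlation(g$cohort, g$signature, sc)
  expect_equal(self$r, 1, tolerance = 1e-9)

  msc <- module_score_correlation(g$cohort, sprintf("mod%02d", 1:10), sc)
  expect_true(is.finite(msc$p))
  expect_error(module_score_correlation(g$cohort, "mod01", sc),
               class = "sproutnet_contract_error")
})

test_that("ddct analysis reproduces the comparative-Ct arithmetic", {
  # target Ct 25 vs reference 20 (treated), dCt_control = 3:
  # ddct = 2, rq = 0.25, fails the strict > 2 rule
  ct_table <- data.frame(
    assay = rep(c("t1", "ref"), each = 2),
    condition = rep(c("control", "treated"), 2),
    replicate = 1L,
    ct = c(23, 25, 20, 20))
  dd <- ddct_analysis(ct_table, reference_assays = "ref")
  row <- dd[dd$assay == "t1", ]
  expect_equal(row$dct_control, 3)
  expect_equal(row$dct_treated, 5)
  expect_equal(row$ddct, 2)
  expect_equal(row$rq, 0.25)
  expect_false(row$passes_threshold)

  # ddct = -3 gives rq = 8 and passes
  ct_table2 <- ct_table
  ct_table2$ct <- c(23, 20, 20, 20)
  dd2 <- ddct_analysis(ct_table2, reference_assays = "ref")
  row2 <- dd2[dd2$assay == "t1", ]
  expect_equal(row2$ddct, -3)
  expect_equal(row2$rq, 8)
  expect_true(row2$passes_threshold)

  # rq * 2^ddct = 1 for every row, on a random card
  card <- generate_ct_card(20, sprintf("card_mir_%02d", 1:4), 2.5,
                           seed = 9, noise_sd = 0.4)
  dd3 <- ddct_analysis(card$ct_table)
  expect_equal(dd3$rq * 2^dd3$ddct, rep(1, nrow(dd3)), tolerance = 1e-12)

  # an assay missing a condition is a contract error
  broken <- card$ct_table[!(card$ct_table$assay == "card_mir_01" &
                              card$ct_table$condition == "treated"), ]
  expect_error(ddct_analysis(broken), class = "sproutnet_contract_error")
})

test_that("ddct heat-map ordering clusters only the passing assays", {
  shifted <- sprintf("card_mir_%02d", 1:6)
  card <- generate_ct_card(30, shifted, shift_ddct = 4, seed = 3,
                           noise_sd = 0.1)
  dd <- ddct_analysis(card$ct_table)
  kept <- attr(dd, "kept_assays")
  expect_setequal(kept, shifted)
  expect_true(all(abs(dd$ddct[match(kept, dd$assay)]) > 2))
})
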