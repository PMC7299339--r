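# All-pairs miRNA-gene Pearson correlation (the "correlator"), a
# permutation null obtained by sample-label randomization, and the
# stratified distribution comparison that detects the enrichment of
# negative correlations among predicted conserved interactions.

#' All-pairs miRNA-gene Pearson correlation
#'
#' Correlations are computed on `log2(x + 1)`-transformed values (set
#' `log = FALSE` if the matrices are already on log scale). The analytic
#' two-sided p-value uses the t transform with n - 2 degrees of freedom.
#' Zero-variance features yield records flagged `undefined` (r = NA) that
#' downstream stages exclude.
#'
#' @param mirs,genes [expression_matrix()]s sharing the same sample
#'   ordering (>= 4 samples).
#' @param log apply `log2(x + 1)` before correlating (default TRUE).
#' @return A [correlation_table()] with one row per (miRNA, gene) pair.
#' @export
pairwise_correlation <- function(mirs, genes, log = TRUE) {
  if (!identical(sample_ids(mirs), sample_ids(genes)))
    stop_contract("miRNA and gene matrices must share sample ordering")
  n <- ncol(mirs$values)
  if (n < 4L) stop_contract("need >= 4 common samples")
  a <- if (log) log2p1(mirs$values) else mirs$values
  b <- if (log) log2p1(genes$values) else genes$values
  sd_a <- apply(a, 1L, stats::sd); sd_b <- apply(b, 1L, stats::sd)
  suppressWarnings(rmat <- stats::cor(t(a), t(b)))
  rmat[sd_a == 0, ] <- NA_real_
  rmat[, sd_b == 0] <- NA_real_
  r <- as.vector(rmat)                         # column-major: gene varies slowest
  pair_mir <- rep(rownames(a), times = ncol(rmat))
  pair_gene <- rep(colnames(rmat), each = nrow(rmat))
  rc <- pmin(pmax(r, -1), 1)
  tstat <- rc * sqrt((n - 2) / pmax(1 - rc^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[!is.na(rc) & abs(rc) >= 1] <- 0
  correlation_table(pair_mir, pair_gene, r, p, n_samples = n)
}

#' Permutation null of the correlator by sample randomization
#'
#' For each permutation the sample labels of the miRNA matrix are
#' shuffled (one shuffle per permutation, keeping the null joint across
#' all pairs) and all pairwise correlations are recomputed. The pooled
#' null distribution is returned; with 6 samples the 720 distinct
#' orderings are fewer than 1000, so shuffles are drawn with replacement.
#'
#' @inheritParams pairwise_correlation
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param max_pooled cap on the pooled null size; larger pools are
#'   subsampled (recorded in the result).
#' @return A `NullDistribution`: list with `samples` (pooled null r),
#'   `n_permutations`, `n_pairs`, `subsampled`.
#' @export
permutation_null <- function(mirs, genes, n_perm = 1000, seed = 1L,
                             log = TRUE, max_pooled = 2e7) {
  if (n_perm < 1) stop_config("n_perm must be >= 1")
  if (!identical(sample_ids(mirs), sample_ids(genes)))
    stop_contract("miRNA and gene matrices must share sample ordering")
  n <- ncol(mirs$values)
  a <- if (log) log2p1(mirs$values) else mirs$values
  b <- if (log) log2p1(genes$values) else genes$values
  keep_a <- apply(a, 1L, stats::sd) > 0
  keep_b <- apply(b, 1L, stats::sd) > 0
  a <- a[keep_a, , drop = FALSE]; tb <- t(b[keep_b, , drop = FALSE])
  n_pairs <- nrow(a) * ncol(tb)
  per_perm <- n_pairs
  sub_rate <- min(1, max_pooled / (as.numeric(n_perm) * n_pairs))
  pooled <- with_seed(seed, {
    out <- vector("list", n_perm)
    for (i in seq_len(n_perm)) {
      perm <- sample.int(n)
      rm_i <- as.vector(stats::cor(t(a[, perm, drop = FALSE]), tb))
      if (sub_rate < 1)
        rm_i <- rm_i[stats::runif(length(rm_i)) < sub_rate]
      out[[i]] <- rm_i
    }
    unlist(out)
  })
  structure(list(samples = pooled, n_permutations = as.integer(n_perm),
                 n_pairs = n_pairs, subsampled = sub_rate < 1),
            class = "NullDistribution")
}

#' @export
print.NullDistribution <- function(x, ...) {
  cat(sprintf("NullDistribution: %d permutations x %d pairs, %d pooled draws%s\n",
              x$n_permutations, x$n_pairs, length(x$samples),
              if (x$subsampled) " (subsampled)" else ""))
  invisible(x)
}

#' Attach empirical p-values from a permutation null
#'
#' `p_empirical = (1 + #\{null |r| >= |r_obs|\}) / (1 + N_null)` with the
#' pooled null.
#'
#' @param ct a [correlation_table()].
#' @param null a `NullDistribution` from [permutation_null()].
#' @return The table with its `p_empirical` column filled in.
#' @export
empirical_pvalues <- function(ct, null) {
  sorted <- sort(abs(null$samples))
  N <- length(sorted)
  robs <- abs(ct$r)
  n_ge <- N - findInterval(robs - 1e-12, sorted)
  ct$p_empirical <- ifelse(is.na(robs), NA_real_, (1 + n_ge) / (1 + N))
  ct
}

#' Compare the correlator distribution of a prediction stratum with all pairs
#'
#' Tests whether the correlations of pairs carrying a predicted
#' interaction of the given conservation class are shifted toward
#' negative values relative to the full pair set: returns histogram
#' summaries, the two-sample Kolmogorov-Smirnov statistic D, and a
#' one-sided p-value for stochastic ordering toward negative r.
#'
#' @param ct a [correlation_table()].
#' @param pt a [prediction_table()].
#' @param stratum `"conserved"` or `"nonconserved"`.
#' @param breaks histogram breaks passed to [hist()].
#' @return list with `D`, `p_one_sided`, `n_stratum`, `n_all`,
#'   `mean_shift` (stratum mean r minus all-pairs mean r) and the two
#'   histograms.
#' @export
stratified_distribution_test <- function(ct, pt,
                                         stratum = c("conserved", "nonconserved"),
                                         breaks = seq(-1, 1, by = 0.05)) {
  stratum <- match.arg(stratum)
  ok <- !ct$undefined
  r_all <- ct$r[ok]
  key <- function(a, b) paste(a, b, sep = "\r")
  sel <- pt[pt$conservation == stratum, , drop = FALSE]
  in_str <- key(ct$mirna, ct$gene) %in% key(sel$mirna, sel$gene)
  r_str <- ct$r[ok & in_str]
  if (!length(r_str)) stop_contract("empty %s stratum", stratum)
  two <- suppressWarnings(stats::ks.test(r_str, r_all))
  # alternative = "greater": the CDF of x lies above that of y, i.e. the
  # stratum is stochastically smaller (shifted toward negative r)
  one <- suppressWarnings(stats::ks.test(r_str, r_all, alternative = "greater"))
  list(D = unname(two$statistic), p_one_sided = one$p.value,
       n_stratum = length(r_str), n_all = length(r_all),
       mean_shift = mean(r_str) - mean(r_all),
       hist_all = graphics::hist(r_all, breaks = breaks, plot = FALSE),
       hist_stratum = graphics::hist(r_str, breaks = breaks, plot = FALSE))
}

#' Write a correlation table to TSV
#'
#' @param ct a [correlation_table()].
#' @param path destination file.
#' @export
write_correlations <- function(ct, path) {
  utils::write.table(as.data.frame(ct), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
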