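# Downstream statistics: hypergeometric over-representation of a gene
# subset among differentially expressed genes, endothelial-signature
# cohort scoring with module-score correlation, and delta-delta-Ct qPCR
# card processing.

#' Hypergeometric over-representation test (upper tail)
#'
#' `p_upper = P(X >= k)` for X hypergeometric with `K` marked elements in
#' a universe of `N`, drawing `n`. Computed by log-space summation of the
#' exact binomial-coefficient terms.
#'
#' @param k observed overlap.
#' @param K marked elements in the universe (e.g. pathway size).
#' @param n draw size (e.g. number of DE genes).
#' @param N universe size; always explicit, never inferred.
#' @return A `HypergeomResult` list: `k`, `K`, `n`, `N`, `p_upper`.
#' @export
hypergeometric_test <- function(k, K, n, N) {
  k <- as.integer(k); K <- as.integer(K); n <- as.integer(n); N <- as.integer(N)
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop_contract("infeasible hypergeometric parameters (k=%d K=%d n=%d N=%d)",
                  k, K, n, N)
  i <- k:min(K, n)
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logp)
  p <- exp(m) * sum(exp(logp - m))
  structure(list(k = k, K = K, n = n, N = N, p_upper = min(1, p)),
            class = "HypergeomResult")
}

#' @export
print.HypergeomResult <- function(x, ...) {
  cat(sprintf("Hypergeometric: k=%d of K=%d marked, n=%d drawn from N=%d; P(X>=k) = %.4g\n",
              x$k, x$K, x$n, x$N, x$p_upper))
  invisible(x)
}

#' Endothelial (signature) score per sample
#'
#' Score = mean over the present signature genes of the per-gene z-scored
#' expression. Constant (zero-variance) signature genes are excluded with
#' a warning; a warning is also raised when fewer than 80% of the
#' signature genes are present in the matrix.
#'
#' @param cohort an [expression_matrix()].
#' @param signature character vector of signature gene ids.
#' @return named numeric vector of per-sample scores, sorted descending.
#' @export
endothelial_score <- function(cohort, signature) {
  present <- intersect(signature, feature_ids(cohort))
  if (!length(present))
    stop_contract("no signature gene present in the cohort matrix")
  if (length(present) < 0.8 * length(signature))
    warning(sprintf("only %d/%d signature genes present in the cohort",
                    length(present), length(signature)))
  v <- cohort$values[present, , drop = FALSE]
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d constant signature gene(s)", sum(sds == 0)))
    v <- v[sds > 0, , drop = FALSE]
    if (!nrow(v)) stop_contract("all present signature genes are constant")
  }
  z <- t(scale(t(v)))
  scores <- colMeans(z)
  sort(scores, decreasing = TRUE)
}

#' Correlation between a gene module and per-sample scores
#'
#' Pearson correlation between the per-sample mean of the z-scored module
#' gene expression and the supplied scores, with the analytic two-sided
#' p-value.
#'
#' @param cohort an [expression_matrix()].
#' @param module character vector of module gene ids (>= 2 present).
#' @param scores named per-sample scores (e.g. from
#'   [endothelial_score()]); matched to the cohort samples by name.
#' @return list with `r`, `p`, `n`, and the per-sample `module_mean`.
#' @export
module_score_correlation <- function(cohort, module, scores) {
  present <- intersect(module, feature_ids(cohort))
  if (length(present) < 2L)
    stop_contract("fewer than 2 module genes present in the cohort")
  v <- cohort$values[present, , drop = FALSE]
  sds <- apply(v, 1L, stats::sd)
  v <- v[sds > 0, , drop = FALSE]
  if (nrow(v) < 2L) stop_contract("module variance is degenerate")
  mm <- colMeans(t(scale(t(v))))
  s <- scores[sample_ids(cohort)]
  if (anyNA(s)) stop_contract("scores missing for some cohort samples")
  if (stats::sd(mm) == 0 || stats::sd(s) == 0)
    stop_contract("degenerate variance in module mean or scores")
  ct <- stats::cor.test(mm, s)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(s),
       module_mean = mm)
}

#' Delta-delta-Ct analysis of a qPCR card
#'
#' Per sample (condition x replicate), Ct values are normalized by
#' subtracting the mean Ct of the reference assays (global mean over all
#' assays when `reference_assays` is empty). Delta-Ct values are averaged
#' across replicates on the Ct scale; `ddct = dct_treated - dct_control`
#' against `control_condition`, and `rq = 2^(-ddct)`. Rows failing the
#' strict `|ddct| > threshold` filter (in every treated condition) are
#' dropped from the heat-map ordering, which clusters the surviving
#' assays on `-ddct` (Euclidean distance, complete linkage).
#'
#' @param ct_table data.frame with columns `assay`, `condition`,
#'   `replicate`, `ct`.
#' @param reference_assays reference assay ids (empty = global-mean
#'   normalization).
#' @param control_condition the baseline condition label.
#' @param threshold strict |ddct| cutoff (default 2).
#' @return A `DdctTable`: data.frame (assay, condition, dct_control,
#'   dct_treated, ddct, rq, passes_threshold), plus attributes
#'   `kept_assays` (clustered ordering) and `ddct_matrix`.
#' @export
ddct_analysis <- function(ct_table, reference_assays = character(0),
                          control_condition = "control", threshold = 2) {
  need <- c("assay", "condition", "replicate", "ct")
  miss <- setdiff(need, names(ct_table))
  if (length(miss))
    stop_format("ct_table missing column(s): %s", paste(miss, collapse = ", "))
  conds <- unique(ct_table$condition)
  if (!control_condition %in% conds)
    stop_contract("control condition '%s' absent", control_condition)
  treated_conds <- setdiff(conds, control_condition)
  if (!length(treated_conds)) stop_contract("no treated condition present")
  assays <- sort(unique(ct_table$assay))
  cross <- table(ct_table$assay, ct_table$condition)
  if (any(cross == 0))
    stop_contract("assay missing a condition: %s",
                  paste(rownames(cross)[rowSums(cross == 0) > 0], collapse = ", "))
  if (length(reference_assays)) {
    missing_ref <- setdiff(reference_assays, assays)
    if (length(missing_ref))
      stop_contract("reference assay(s) absent: %s",
                    paste(missing_ref, collapse = ", "))
  }

  # per (condition, replicate) sample: subtract the reference mean Ct
  ct_table$sample <- paste(ct_table$condition, ct_table$replicate, sep = "|")
  ref_rows <- if (length(reference_assays))
    ct_table$assay %in% reference_assays else rep(TRUE, nrow(ct_table))
  ref_mean <- tapply(ct_table$ct[ref_rows], ct_table$sample[ref_rows], mean)
  dct <- ct_table$ct - ref_mean[ct_table$sample]
  # replicate-averaged delta-Ct per (assay, condition)
  dct_ac <- tapply(dct, list(ct_table$assay, ct_table$condition), mean)

  rows <- expand.grid(assay = assays, condition = treated_conds,
                      stringsAsFactors = FALSE)
  rows$dct_control <- dct_ac[cbind(rows$assay, control_condition)]
  rows$dct_treated <- dct_ac[cbind(rows$assay, rows$condition)]
  rows$ddct <- rows$dct_treated - rows$dct_control
  rows$rq <- 2^(-rows$ddct)
  rows$passes_threshold <- abs(rows$ddct) > threshold

  # heat-map ordering: cluster assays passing in any condition on -ddct
  dmat <- matrix(rows$ddct, nrow = length(assays),
                 dimnames = list(assays, treated_conds))
  pass_any <- rowSums(matrix(rows$passes_threshold,
                             nrow = length(assays))) > 0
  kept <- assays[pass_any]
  if (length(kept) >= 2L) {
    hc <- stats::hclust(stats::dist(-dmat[kept, , drop = FALSE],
                                    method = "euclidean"),
                        method = "complete")
    kept <- kept[hc$order]
  }
  out <- rows
  attr(out, "kept_assays") <- kept
  attr(out, "ddct_matrix") <- dmat
  attr(out, "threshold") <- threshold
  class(out) <- c("DdctTable", "data.frame")
  out
}
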