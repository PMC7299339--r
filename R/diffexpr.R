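# Expression filtering, median-of-ratios normalization and a simple
# two-condition differential-expression stage (Welch's t on log2(x+1) with
# Benjamini-Hochberg FDR). This stage deliberately mirrors only the
# thresholding semantics of a full count-model DE analysis: modulated
# features satisfy |log2FC| > 0.5 and FDR < 0.05 by default.

#' Filter features by minimum expression
#'
#' Keeps features whose mean raw count across all samples is strictly
#' greater than `min_raw` (default 5). Row order is preserved.
#'
#' @param m a raw-count [expression_matrix()].
#' @param min_raw strict mean-count cutoff.
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_expressed <- function(m, min_raw = 5) {
  if (m$normalized)
    stop_contract("filter_expressed expects raw counts, not normalized values")
  keep <- rowMeans(m$values) > min_raw
  expression_matrix(m$values[keep, , drop = FALSE], m$condition,
                    kind = m$kind, normalized = FALSE)
}

#' Size factors by median of ratios
#'
#' For each sample, the size factor is the median over features (with a
#' nonzero geometric mean across samples) of count / geometric mean.
#'
#' @param m a raw-count [expression_matrix()].
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors <- function(m) {
  v <- m$values
  log_gm <- rowMeans(log(v))
  use <- is.finite(log_gm)            # rows with any zero drop out
  if (!any(use))
    stop_contract("size-factor error: every feature contains a zero count")
  sf <- apply(v[use, , drop = FALSE], 2L, function(col)
    stats::median(exp(log(col) - log_gm[use])))
  sf
}

#' Normalize counts by median-of-ratios size factors
#'
#' @param m a raw-count [expression_matrix()].
#' @return An `ExpressionMatrix` flagged `normalized = TRUE`.
#' @export
normalize_counts <- function(m) {
  if (m$normalized) stop_contract("matrix is already normalized")
  sf <- size_factors(m)
  expression_matrix(sweep(m$values, 2L, sf, `/`), m$condition,
                    kind = m$kind, normalized = TRUE)
}

#' Two-condition differential expression (Welch's t on log2 counts)
#'
#' log2 fold change is `log2((mean_treated + 1)/(mean_control + 1))` on
#' normalized counts; the p-value comes from Welch's t-test on
#' `log2(x + 1)` values; FDR is Benjamini-Hochberg across all features.
#' Features with zero pooled variance and zero difference get p = 1.
#'
#' @param m a normalized [expression_matrix()] with both conditions.
#' @param lfc_threshold strict |log2FC| threshold for calling modulation.
#' @param fdr_cutoff strict FDR cutoff.
#' @return A [de_table()].
#' @export
differential_expression <- function(m, lfc_threshold = 0.5,
                                    fdr_cutoff = 0.05) {
  if (!m$normalized)
    stop_contract("differential_expression expects a normalized matrix")
  trt <- m$condition == "treated"
  if (sum(trt) < 2L || sum(!trt) < 2L)
    stop_contract("each condition needs >= 2 samples")
  v <- m$values
  lv <- log2p1(v)
  mt <- rowMeans(lv[, trt, drop = FALSE])
  mc <- rowMeans(lv[, !trt, drop = FALSE])
  vt <- apply(lv[, trt, drop = FALSE], 1L, stats::var)
  vc <- apply(lv[, !trt, drop = FALSE], 1L, stats::var)
  nt <- sum(trt); nc <- sum(!trt)
  se2 <- vt / nt + vc / nc
  tstat <- (mt - mc) / sqrt(se2)
  df <- se2^2 / ((vt / nt)^2 / (nt - 1) + (vc / nc)^2 / (nc - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0 & (mt - mc) == 0] <- 1
  p[se2 == 0 & (mt - mc) != 0] <- 0
  fdr <- stats::p.adjust(p, method = "BH")
  log2fc <- log2((rowMeans(v[, trt, drop = FALSE]) + 1) /
                   (rowMeans(v[, !trt, drop = FALSE]) + 1))
  de_table(rownames(v), rowMeans(v), log2fc, p, fdr,
           lfc_threshold = lfc_threshold, fdr_cutoff = fdr_cutoff)
}

#' Ingest an externally computed differential-expression table
#'
#' Reads a TSV with columns `feature`, `log2fc`, `p`, `fdr` (an optional
#' `base_mean` is carried through) and recomputes directions from the
#' thresholds, so that external DE results (e.g. from a count-model tool
#' run on the original accessions) can replace the internal stage.
#'
#' @param path file path.
#' @param lfc_threshold,fdr_cutoff modulation thresholds.
#' @return A [de_table()] with `attr(,"origin") = "external"`.
#' @export
ingest_de_table <- function(path, lfc_threshold = 0.5, fdr_cutoff = 0.05) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("feature", "log2fc", "p", "fdr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("DE table missing column(s): %s", paste(miss, collapse = ", "))
  bm <- if ("base_mean" %in% names(df)) df$base_mean else NA_real_
  out <- de_table(df$feature, bm, df$log2fc, df$p, df$fdr,
                  lfc_threshold = lfc_threshold, fdr_cutoff = fdr_cutoff)
  attr(out, "origin") <- "external"
  out
}

#' Write a DE table to TSV
#'
#' @param de a [de_table()].
#' @param path destination file.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
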