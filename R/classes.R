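# Domain containers shared across the pipeline. All are light S3 wrappers
# around base matrices / data.frames so that standard tools (subsetting,
# write.table, str) keep working.

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sproutnet_format_error", "sproutnet_error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sproutnet_config_error", "sproutnet_error")))
}

stop_contract <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sproutnet_contract_error", "sproutnet_error")))
}

#' Construct an expression matrix with condition labels
#'
#' The central data container: a features x samples numeric matrix together
#' with a two-level condition assignment per sample (`control` / `treated`)
#' and a kind tag (`mirna` or `gene`). Raw-count matrices must be
#' non-negative and finite; normalized matrices carry `normalized = TRUE` so
#' downstream stages can enforce their scale contracts.
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   have unique row and column names.
#' @param condition named character vector mapping every sample id to
#'   `"control"` or `"treated"`. Each condition must have at least two
#'   samples.
#' @param kind `"mirna"` or `"gene"`.
#' @param normalized logical; `TRUE` once size-factor normalization has been
#'   applied.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, condition, kind = c("gene", "mirna"),
                              normalized = FALSE) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop_format("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_format("values must have feature (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop_format("duplicate feature identifiers: %s",
                paste(unique(rownames(values)[duplicated(rownames(values))]),
                      collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_format("duplicate sample identifiers")
  if (any(!is.finite(values)))
    stop_format("values must be finite")
  if (!normalized && any(values < 0))
    stop_format("raw counts must be non-negative")
  samples <- colnames(values)
  missing <- setdiff(samples, names(condition))
  if (length(missing))
    stop_config("samples missing from condition map: %s",
                paste(missing, collapse = ", "))
  condition <- condition[samples]
  if (!all(condition %in% c("control", "treated")))
    stop_config("condition labels must be 'control' or 'treated'")
  tab <- table(condition)
  if (any(tab < 2L))
    stop_config("each condition present needs at least 2 samples")
  structure(list(values = values, condition = condition, kind = kind,
                 normalized = normalized),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix <%s%s>: %d features x %d samples (%s)\n",
              x$kind, if (x$normalized) ", normalized" else ", raw",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

sample_ids <- function(m) colnames(m$values)
feature_ids <- function(m) rownames(m$values)

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (set name -> member genes).
#' @param description optional character vector of per-set descriptions.
#' @return A `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (!length(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_format("sets must be a non-empty uniquely named list")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L))
    stop_format("empty gene set")
  if (is.null(description)) description <- rep("", length(sets))
  structure(list(sets = sets, description = stats::setNames(description, names(sets))),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, sizes %d-%d\n", length(x$sets),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Construct a target-prediction table
#'
#' One row per predicted (miRNA, gene, conservation class) interaction with
#' its weighted context++ score percentile.
#'
#' @param mirna,gene character vectors of interaction endpoints.
#' @param conservation `"conserved"` or `"nonconserved"` per record.
#' @param percentile numeric in \[0, 100\].
#' @return A `PredictionTable` (also a data.frame).
#' @export
prediction_table <- function(mirna, gene, conservation, percentile) {
  mirna <- trimws(as.character(mirna)); gene <- trimws(as.character(gene))
  conservation <- as.character(conservation)
  bad <- setdiff(unique(conservation), c("conserved", "nonconserved"))
  if (length(bad))
    stop_format("unknown conservation flag: %s", paste(bad, collapse = ", "))
  percentile <- as.numeric(percentile)
  if (any(!is.finite(percentile)) || any(percentile < 0 | percentile > 100))
    stop_format("percentile must lie in [0, 100]")
  df <- data.frame(mirna = mirna, gene = gene, conservation = conservation,
                   percentile = percentile, stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("mirna", "gene", "conservation")]))
    stop_format("duplicate (mirna, gene, conservation) records")
  class(df) <- c("PredictionTable", "data.frame")
  df
}

#' Construct a differential-expression table
#'
#' Direction is always recomputed from the thresholds so it is a pure
#' function of (log2fc, fdr, lfc_threshold, fdr_cutoff): `up` iff
#' log2fc > lfc_threshold and fdr < fdr_cutoff, `down` symmetric, else `ns`.
#'
#' @param feature_id,base_mean,log2fc,p,fdr parallel vectors.
#' @param lfc_threshold,fdr_cutoff modulation thresholds (strict `>` on
#'   |log2fc|, strict `<` on fdr).
#' @return A `DETable` (also a data.frame) with a `direction` column.
#' @export
de_table <- function(feature_id, base_mean, log2fc, p, fdr,
                     lfc_threshold = 0.5, fdr_cutoff = 0.05) {
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id)) stop_format("duplicate feature ids")
  p <- as.numeric(p); fdr <- as.numeric(fdr)
  if (any(stats::na.omit(c(p, fdr)) < 0) || any(stats::na.omit(c(p, fdr)) > 1))
    stop_format("p and fdr must lie in [0, 1]")
  direction <- assign_direction(log2fc, fdr, lfc_threshold, fdr_cutoff)
  df <- data.frame(feature_id = feature_id, base_mean = as.numeric(base_mean),
                   log2fc = as.numeric(log2fc), p = p, fdr = fdr,
                   direction = direction, stringsAsFactors = FALSE)
  attr(df, "lfc_threshold") <- lfc_threshold
  attr(df, "fdr_cutoff") <- fdr_cutoff
  class(df) <- c("DETable", "data.frame")
  df
}

assign_direction <- function(log2fc, fdr, lfc_threshold, fdr_cutoff) {
  d <- rep("ns", length(log2fc))
  sig <- !is.na(fdr) & fdr < fdr_cutoff & !is.na(log2fc)
  d[sig & log2fc > lfc_threshold] <- "up"
  d[sig & log2fc < -lfc_threshold] <- "down"
  d
}

#' Construct a correlation table
#'
#' @param mirna,gene pair endpoints.
#' @param r Pearson correlation per pair (NA for zero-variance pairs).
#' @param p_analytic two-sided p from the t transform with n - 2 df.
#' @param p_empirical empirical p from the permutation null (NA until
#'   attached).
#' @param n_samples number of samples the correlations were computed on.
#' @return A `CorrelationTable` (also a data.frame) with an `undefined`
#'   flag column for zero-variance pairs.
#' @export
correlation_table <- function(mirna, gene, r, p_analytic,
                              p_empirical = NA_real_, n_samples) {
  r <- as.numeric(r)
  if (any(abs(stats::na.omit(r)) > 1 + 1e-12)) stop_format("|r| must be <= 1")
  df <- data.frame(mirna = as.character(mirna), gene = as.character(gene),
                   r = r, p_analytic = as.numeric(p_analytic),
                   p_empirical = as.numeric(p_empirical),
                   undefined = is.na(r), stringsAsFactors = FALSE)
  attr(df, "n_samples") <- as.integer(n_samples)
  class(df) <- c("CorrelationTable", "data.frame")
  df
}
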