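# A from-scratch gene set enrichment analysis engine: two-class
# (signal-to-noise) and continuous (Pearson-correlation) phenotype
# rankings, the weighted Kolmogorov-Smirnov-like running-sum enrichment
# score, permutation significance with sign-stratified NES normalization
# and FDR, leading-edge ("core enrichment") extraction, and the
# miRNA x gene-set association matrix with hierarchical clustering.

#' Rank genes against a phenotype
#'
#' Continuous phenotype: the ranking metric is the Pearson correlation of
#' each gene's profile with the phenotype profile (zero-variance genes
#' get metric 0 and are flagged). Two-class phenotype: signal-to-noise
#' `(mu1 - mu2) / (sd1 + sd2)` with each sd floored at
#' `max(0.2 * |mu|, 0.2)`. Genes are ordered by metric descending, ties
#' broken lexicographically by id.
#'
#' @param genes an [expression_matrix()].
#' @param phenotype numeric vector (continuous profile, same sample
#'   ordering as `genes`) or character/factor of two class labels.
#' @param positive for two-class phenotypes, the class whose mean enters
#'   with positive sign; defaults to `"treated"` when present, else the
#'   last factor level.
#' @return A `RankedList`: data.frame (gene, metric) sorted descending,
#'   with attributes `phenotype_type` and `flagged` (zero-variance genes).
#' @export
rank_genes <- function(genes, phenotype, positive = NULL) {
  v <- genes$values
  if (is.numeric(phenotype)) {
    if (length(phenotype) != ncol(v))
      stop_contract("phenotype length must match sample count")
    sds <- apply(v, 1L, stats::sd)
    if (stats::sd(phenotype) == 0)
      stop_contract("constant continuous phenotype")
    suppressWarnings(metric <- as.vector(stats::cor(t(v), phenotype)))
    flagged <- rownames(v)[sds == 0]
    metric[sds == 0] <- 0
    type <- "continuous"
  } else {
    cls <- as.factor(phenotype)
    if (nlevels(cls) != 2L) stop_contract("two-class phenotype needs 2 levels")
    if (any(table(cls) < 2L)) stop_contract("each class needs >= 2 samples")
    if (is.null(positive))
      positive <- if ("treated" %in% levels(cls)) "treated" else
        levels(cls)[nlevels(cls)]
    pos <- cls == positive
    mu1 <- rowMeans(v[, pos, drop = FALSE])
    mu2 <- rowMeans(v[, !pos, drop = FALSE])
    s1 <- apply(v[, pos, drop = FALSE], 1L, stats::sd)
    s2 <- apply(v[, !pos, drop = FALSE], 1L, stats::sd)
    s1 <- pmax(s1, pmax(0.2 * abs(mu1), 0.2))
    s2 <- pmax(s2, pmax(0.2 * abs(mu2), 0.2))
    metric <- (mu1 - mu2) / (s1 + s2)
    flagged <- character(0)
    type <- "two_class"
  }
  ord <- order(-metric, rownames(v))
  rl <- data.frame(gene = rownames(v)[ord], metric = metric[ord],
                   stringsAsFactors = FALSE)
  attr(rl, "phenotype_type") <- type
  attr(rl, "flagged") <- flagged
  class(rl) <- c("RankedList", "data.frame")
  rl
}

# ES from sorted hit positions; the workhorse shared by the observed
# statistic and the permutation null. absw = |metric|^weight along the
# full list.
es_from_positions <- function(pos, absw, N) {
  k <- length(pos)
  w <- absw[pos]
  W <- sum(w)
  cw <- if (W > 0) cumsum(w) / W else seq_len(k) / k
  if (N == k) return(list(es = 1, extremum = k, cw = cw))
  miss <- (pos - seq_len(k)) / (N - k)
  after <- cw - miss
  before <- c(0, cw[-k]) - miss
  # interleave in walk order (before each hit, then after it) so exact
  # |max| = |min| ties resolve to the first extremum along the list,
  # matching the running-sum walk
  cand <- as.vector(rbind(before, after))
  i <- which.max(abs(cand))
  hit_i <- (i + 1L) %/% 2L
  list(es = cand[i], extremum = pos[hit_i], cw = cw)
}

#' Running-sum enrichment score of a gene set
#'
#' Walking the ranked list, set members ("hits") add
#' `|metric|^weight / sum_set |metric|^weight` and non-members subtract
#' `1 / (N - N_hits)`; the enrichment score is the signed maximum
#' deviation of this running sum from zero. The leading edge contains the
#' set members at or before the extremum (at or after it, for negative
#' scores).
#'
#' @param rl a `RankedList` from [rank_genes()] (or any data.frame with
#'   `gene` and `metric` columns in ranked order).
#' @param set character vector of member genes.
#' @param weight exponent on |metric| for hit increments (default 1).
#' @return list with `es`, `running` (length-N running sum),
#'   `leading_edge`, `n_hits`, and `undefined` (TRUE when the set does
#'   not overlap the list).
#' @export
enrichment_score <- function(rl, set, weight = 1) {
  N <- nrow(rl)
  hit <- rl$gene %in% set
  k <- sum(hit)
  if (k == 0L)
    return(list(es = NA_real_, running = rep(NA_real_, N),
                leading_edge = character(0), n_hits = 0L, undefined = TRUE))
  absw <- abs(rl$metric)^weight
  steps <- numeric(N)
  W <- sum(absw[hit])
  steps[hit] <- if (W > 0) absw[hit] / W else 1 / k
  if (k < N) steps[!hit] <- -1 / (N - k)
  running <- cumsum(steps)
  i <- which.max(abs(running))
  es <- running[i]
  le <- if (es >= 0) rl$gene[hit & seq_len(N) <= i] else rl$gene[hit & seq_len(N) >= i]
  list(es = es, running = running, leading_edge = le, n_hits = k,
       undefined = FALSE)
}

# Geneset-permutation GSEA on a pre-ranked list. Null member sets are
# random gene subsets of equal size; exhaustive = TRUE enumerates all
# C(N, k) subsets instead of sampling.
gsea_preranked <- function(rl, collection, n_perm = 1000, seed = 1L,
                           weight = 1, exhaustive = FALSE) {
  N <- nrow(rl)
  absw <- abs(rl$metric)^weight
  sets <- collection$sets
  obs <- lapply(sets, function(s) enrichment_score(rl, s, weight))
  ks <- vapply(obs, function(o) o$n_hits, integer(1))
  if (any(ks > N)) stop_contract("gene set larger than ranked universe")
  usable <- ks > 0L

  null_by_size <- list()
  for (k in sort(unique(ks[usable]))) {
    if (exhaustive) {
      combos <- utils::combn(N, k)
      null_by_size[[as.character(k)]] <- apply(combos, 2L, function(p)
        es_from_positions(p, absw, N)$es)
    } else {
      null_by_size[[as.character(k)]] <- with_seed(split_seed(seed, paste0("k", k)),
        vapply(seq_len(n_perm), function(b)
          es_from_positions(sort(sample.int(N, k)), absw, N)$es, numeric(1)))
    }
  }

  # tail counts use a 1e-12 tolerance so that exact ties (e.g. the observed
  # set re-appearing in an exhaustive enumeration) are not lost to
  # floating-point noise
  norm_one <- function(es, null) {
    pos <- null[null >= 0]; neg <- null[null < 0]
    if (es >= 0) {
      nes <- if (length(pos)) es / mean(pos) else NA_real_
      p <- if (exhaustive) {
        if (length(pos)) sum(pos >= es - 1e-12) / length(pos) else NA_real_
      } else if (length(pos)) (1 + sum(pos >= es - 1e-12)) / (1 + length(pos))
      else 1 / (1 + length(null))
    } else {
      nes <- if (length(neg)) -es / mean(neg) else NA_real_
      p <- if (exhaustive) {
        if (length(neg)) sum(neg <= es + 1e-12) / length(neg) else NA_real_
      } else if (length(neg)) (1 + sum(neg <= es + 1e-12)) / (1 + length(neg))
      else 1 / (1 + length(null))
    }
    c(nes = nes, p = p)
  }

  nes <- p_perm <- rep(NA_real_, length(sets))
  null_nes <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    if (!usable[i]) next
    null <- null_by_size[[as.character(ks[i])]]
    np <- norm_one(obs[[i]]$es, null)
    nes[i] <- np["nes"]; p_perm[i] <- np["p"]
    pos <- null[null >= 0]; neg <- null[null < 0]
    nn <- numeric(length(null))
    nn[null >= 0] <- if (length(pos)) null[null >= 0] / mean(pos) else NA_real_
    nn[null < 0] <- if (length(neg)) -null[null < 0] / mean(neg) else NA_real_
    null_nes[[i]] <- nn
  }

  # sign-stratified FDR: ratio of the null and observed NES tail fractions
  pooled <- unlist(null_nes[usable])
  pooled <- pooled[is.finite(pooled)]
  obs_nes <- nes[usable & is.finite(nes)]
  fdr_q <- rep(NA_real_, length(sets))
  for (i in seq_along(sets)) {
    if (!usable[i] || !is.finite(nes[i])) next
    v <- nes[i]
    if (v >= 0) {
      denom_null <- sum(pooled >= 0); denom_obs <- sum(obs_nes >= 0)
      num_null <- sum(pooled >= v); num_obs <- sum(obs_nes >= v)
    } else {
      denom_null <- sum(pooled < 0); denom_obs <- sum(obs_nes < 0)
      num_null <- sum(pooled <= v); num_obs <- sum(obs_nes <= v)
    }
    if (denom_null == 0 || denom_obs == 0 || num_obs == 0) { fdr_q[i] <- 1; next }
    fdr_q[i] <- min(1, (num_null / denom_null) / (num_obs / denom_obs))
  }

  res <- data.frame(
    set_name = names(sets),
    es = vapply(obs, function(o) o$es, numeric(1)),
    nes = nes, p_perm = p_perm, fdr_q = fdr_q,
    n_hits = ks,
    leading_edge = vapply(obs, function(o)
      paste(o$leading_edge, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "leading_edges") <- lapply(obs, function(o) o$leading_edge)
  attr(res, "n_perm") <- if (exhaustive) NA_integer_ else as.integer(n_perm)
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Gene set enrichment analysis with permutation significance
#'
#' Ranks the genes against the phenotype ([rank_genes()]), scores every
#' set ([enrichment_score()]), and assesses significance by permutation:
#' `perm_type = "geneset"` (default) draws random member sets of equal
#' size; `perm_type = "phenotype"` shuffles the phenotype and re-ranks.
#' NES normalizes by the sign-matched null mean; FDR follows the
#' sign-stratified NES-ratio procedure.
#'
#' @inheritParams rank_genes
#' @param collection a [gene_set_collection()].
#' @param n_perm number of permutations (default 1000).
#' @param perm_type `"geneset"` or `"phenotype"`.
#' @param seed integer seed.
#' @param weight ES weight exponent (default 1).
#' @param exhaustive with `perm_type = "geneset"`, enumerate all
#'   equal-size member sets instead of sampling (small universes only).
#' @return An `EnrichmentResult` data.frame: set_name, es, nes, p_perm,
#'   fdr_q, n_hits, leading_edge.
#' @export
run_gsea <- function(genes, phenotype, collection, n_perm = 1000,
                     perm_type = c("geneset", "phenotype"), seed = 1L,
                     weight = 1, positive = NULL, exhaustive = FALSE) {
  perm_type <- match.arg(perm_type)
  if (!length(collection$sets)) stop_contract("empty gene-set collection")
  rl <- rank_genes(genes, phenotype, positive = positive)
  if (perm_type == "geneset" || exhaustive)
    return(gsea_preranked(rl, collection, n_perm, seed, weight, exhaustive))

  # phenotype permutation: shuffle the phenotype, re-rank, re-score
  sets <- collection$sets
  obs <- lapply(sets, function(s) enrichment_score(rl, s, weight))
  null_es <- with_seed(split_seed(seed, "phen"), {
    sapply(seq_len(n_perm), function(b) {
      ph <- sample(phenotype)
      rlb <- rank_genes(genes, ph, positive = positive)
      vapply(sets, function(s) enrichment_score(rlb, s, weight)$es, numeric(1))
    })
  })
  if (is.null(dim(null_es))) null_es <- matrix(null_es, nrow = 1L)
  nes <- p_perm <- fdr_q <- rep(NA_real_, length(sets))
  null_nes <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    if (obs[[i]]$undefined) next
    null <- null_es[i, ]
    pos <- null[null >= 0]; neg <- null[null < 0]
    es <- obs[[i]]$es
    if (es >= 0) {
      nes[i] <- if (length(pos)) es / mean(pos) else NA_real_
      p_perm[i] <- if (length(pos)) (1 + sum(pos >= es)) / (1 + length(pos))
      else 1 / (1 + length(null))
    } else {
      nes[i] <- if (length(neg)) -es / mean(neg) else NA_real_
      p_perm[i] <- if (length(neg)) (1 + sum(neg <= es)) / (1 + length(neg))
      else 1 / (1 + length(null))
    }
    nn <- numeric(length(null))
    nn[null >= 0] <- if (length(pos)) null[null >= 0] / mean(pos) else NA_real_
    nn[null < 0] <- if (length(neg)) -null[null < 0] / mean(neg) else NA_real_
    null_nes[[i]] <- nn
  }
  pooled <- unlist(null_nes); pooled <- pooled[is.finite(pooled)]
  obs_nes <- nes[is.finite(nes)]
  for (i in seq_along(sets)) {
    if (!is.finite(nes[i])) next
    v <- nes[i]
    if (v >= 0) {
      dn <- sum(pooled >= 0); do_ <- sum(obs_nes >= 0)
      nn_ <- sum(pooled >= v); no_ <- sum(obs_nes >= v)
    } else {
      dn <- sum(pooled < 0); do_ <- sum(obs_nes < 0)
      nn_ <- sum(pooled <= v); no_ <- sum(obs_nes <= v)
    }
    fdr_q[i] <- if (dn == 0 || do_ == 0 || no_ == 0) 1
    else min(1, (nn_ / dn) / (no_ / do_))
  }
  res <- data.frame(
    set_name = names(sets),
    es = vapply(obs, function(o) o$es, numeric(1)),
    nes = nes, p_perm = p_perm, fdr_q = fdr_q,
    n_hits = vapply(obs, function(o) o$n_hits, integer(1)),
    leading_edge = vapply(obs, function(o)
      paste(o$leading_edge, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "leading_edges") <- lapply(obs, function(o) o$leading_edge)
  attr(res, "n_perm") <- as.integer(n_perm)
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' miRNA x gene-set association matrix
#'
#' Runs one continuous-phenotype GSEA per miRNA, using the miRNA's
#' `log2(normalized + 1)` profile as the phenotype to rank the genes, with
#' geneset permutation. Returns NES and FDR matrices (sets x miRNAs), the
#' sign-masked NES rendering (NES where FDR < `fdr_cutoff`, 0 elsewhere),
#' hierarchical clustering of the significant rows/columns (Euclidean
#' distance, complete linkage on the masked NES), and the per-row-cluster
#' leading-edge gene unions ("core enrichment").
#'
#' @param mirs,genes [expression_matrix()]s sharing sample ordering.
#' @param collection a [gene_set_collection()].
#' @param n_perm permutations per miRNA run (default 1000).
#' @param seed integer seed.
#' @param fdr_cutoff significance mask (default 0.05, applied within each
#'   miRNA's run).
#' @param n_clusters number of row clusters cut from the dendrogram.
#' @param log apply `log2(x + 1)` to both matrices (default TRUE).
#' @return An `AssociationMatrix` list: `nes`, `fdr`, `masked`,
#'   `row_order`, `col_order`, `row_cluster`, `core_enrichment`,
#'   `results` (per-miRNA `EnrichmentResult`s).
#' @export
mirna_association_matrix <- function(mirs, genes, collection, n_perm = 1000,
                                     seed = 1L, fdr_cutoff = 0.05,
                                     n_clusters = 5L, log = TRUE) {
  if (!identical(sample_ids(mirs), sample_ids(genes)))
    stop_contract("miRNA and gene matrices must share sample ordering")
  gv <- if (log) log2p1(genes$values) else genes$values
  mv <- if (log) log2p1(mirs$values) else mirs$values
  gm <- expression_matrix(gv, genes$condition, kind = "gene", normalized = TRUE)
  set_names <- names(collection$sets)
  mirna_ids <- rownames(mv)
  nes <- fdr <- matrix(NA_real_, length(set_names), length(mirna_ids),
                       dimnames = list(set_names, mirna_ids))
  results <- vector("list", length(mirna_ids))
  names(results) <- mirna_ids
  les <- list()
  for (j in seq_along(mirna_ids)) {
    ph <- mv[j, ]
    if (stats::sd(ph) == 0) next    # constant miRNA: column stays NA
    # one shared null seed: duplicate miRNA profiles yield identical columns
    res <- run_gsea(gm, ph, collection, n_perm = n_perm,
                    perm_type = "geneset",
                    seed = split_seed(seed, "gsea_null"))
    nes[res$set_name, j] <- res$nes
    fdr[res$set_name, j] <- res$fdr_q
    les[[mirna_ids[j]]] <- attr(res, "leading_edges")
    results[[j]] <- res
  }
  masked <- ifelse(!is.na(fdr) & fdr < fdr_cutoff, nes, 0)
  masked[is.na(masked)] <- 0

  sig_rows <- rowSums(masked != 0) > 0
  sig_cols <- colSums(masked != 0) > 0
  row_order <- seq_len(nrow(masked)); col_order <- seq_len(ncol(masked))
  row_cluster <- stats::setNames(rep(NA_integer_, nrow(masked)), set_names)
  if (sum(sig_rows) >= 2L) {
    hr <- stats::hclust(stats::dist(masked[sig_rows, , drop = FALSE],
                                    method = "euclidean"),
                        method = "complete")
    row_order <- c(which(sig_rows)[hr$order], which(!sig_rows))
    row_cluster[sig_rows] <- stats::cutree(hr, k = min(n_clusters, sum(sig_rows)))
  }
  if (sum(sig_cols) >= 2L) {
    hc <- stats::hclust(stats::dist(t(masked[, sig_cols, drop = FALSE]),
                                    method = "euclidean"),
                        method = "complete")
    col_order <- c(which(sig_cols)[hc$order], which(!sig_cols))
  }

  # core enrichment: union of leading edges of significant cells per row cluster
  core <- list()
  for (cl in sort(unique(stats::na.omit(row_cluster)))) {
    rows <- names(row_cluster)[!is.na(row_cluster) & row_cluster == cl]
    genes_cl <- character(0)
    for (s in rows) {
      i <- match(s, set_names)
      for (m in mirna_ids) {
        j <- match(m, mirna_ids)
        if (!is.na(fdr[i, j]) && fdr[i, j] < fdr_cutoff)
          genes_cl <- union(genes_cl, les[[m]][[i]])
      }
    }
    core[[as.character(cl)]] <- sort(genes_cl)
  }

  structure(list(nes = nes, fdr = fdr, masked = masked,
                 row_order = row_order, col_order = col_order,
                 row_cluster = row_cluster, core_enrichment = core,
                 results = results, fdr_cutoff = fdr_cutoff),
            class = "AssociationMatrix")
}

#' @export
print.AssociationMatrix <- function(x, ...) {
  cat(sprintf("AssociationMatrix: %d gene sets x %d miRNAs, %d significant cells (FDR < %g)\n",
              nrow(x$nes), ncol(x$nes), sum(x$masked != 0), x$fdr_cutoff))
  invisible(x)
}
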