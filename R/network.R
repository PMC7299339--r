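# Assembly and interrogation of the signed bipartite miRNA-target network:
# an edge requires (i) a predicted direct interaction, (ii) a negative
# Pearson correlation significant at the configured threshold, and, by
# default, (iii) both endpoints differentially expressed in opposite
# directions.

as_regulatory_network <- function(g) {
  structure(list(graph = g), class = "RegulatoryNetwork")
}

empty_regulatory_network <- function() {
  g <- igraph::make_empty_graph(directed = FALSE)
  as_regulatory_network(g)
}

network_from_edges <- function(e) {
  if (!nrow(e)) return(empty_regulatory_network())
  mirs <- unique(e$mirna); genes <- unique(e$gene)
  vattr <- data.frame(name = c(mirs, genes),
                      node_type = c(rep("mirna", length(mirs)),
                                    rep("gene", length(genes))),
                      type = c(rep(TRUE, length(mirs)),
                               rep(FALSE, length(genes))),
                      direction = c(e$mirna_direction[match(mirs, e$mirna)],
                                    e$gene_direction[match(genes, e$gene)]),
                      log2fc = c(e$mirna_log2fc[match(mirs, e$mirna)],
                                 e$gene_log2fc[match(genes, e$gene)]),
                      stringsAsFactors = FALSE)
  eattr <- e[c("mirna", "gene", "r", "p", "conservation", "percentile")]
  names(eattr)[1:2] <- c("from", "to")
  g <- igraph::graph_from_data_frame(eattr, directed = FALSE, vertices = vattr)
  as_regulatory_network(g)
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  g <- x$graph
  nt <- if (igraph::vcount(g)) table(igraph::V(g)$node_type) else c(mirna = 0, gene = 0)
  cat(sprintf("RegulatoryNetwork: %d miRNAs, %d genes, %d edges\n",
              sum(nt[names(nt) == "mirna"]), sum(nt[names(nt) == "gene"]),
              igraph::ecount(g)))
  invisible(x)
}

#' Assemble the signed bipartite miRNA-target regulatory network
#'
#' An edge (m, g) is kept iff the pair has a retained target prediction
#' (per `conservation_mode`), a negative correlation (`r < 0`) significant
#' at `p_threshold`, and -- with `require_de = TRUE`, the default -- both
#' endpoints are differentially expressed with opposite directions.
#' Isolated nodes are dropped.
#'
#' @param de_mir,de_gene [de_table()]s for miRNAs and genes.
#' @param ct a [correlation_table()].
#' @param pt a [prediction_table()] (already percentile-filtered).
#' @param p_threshold pair significance threshold (default 0.05).
#' @param conservation_mode `"conserved_only"` (default: only conserved
#'   predictions seed edges) or `"both"`.
#' @param p_kind which pair p-value gates edges: `"analytic"` (default)
#'   or `"empirical"` (requires the permutation null to be attached).
#' @param require_de if `FALSE`, edges are defined by prediction plus
#'   significant negative correlation only (no direction constraint).
#' @return A `RegulatoryNetwork`.
#' @export
build_network <- function(de_mir, de_gene, ct, pt, p_threshold = 0.05,
                          conservation_mode = c("conserved_only", "both"),
                          p_kind = c("analytic", "empirical"),
                          require_de = TRUE) {
  conservation_mode <- match.arg(conservation_mode)
  p_kind <- match.arg(p_kind)
  if (conservation_mode == "conserved_only")
    pt <- pt[pt$conservation == "conserved", , drop = FALSE]
  pairs <- unique(pt[c("mirna", "gene", "conservation", "percentile")])
  # collapse duplicate (mirna, gene) across classes: keep best percentile
  ord <- order(pairs$mirna, pairs$gene, -pairs$percentile)
  pairs <- pairs[ord, , drop = FALSE]
  pairs <- pairs[!duplicated(pairs[c("mirna", "gene")]), , drop = FALSE]

  key <- function(a, b) paste(a, b, sep = "\r")
  idx <- match(key(pairs$mirna, pairs$gene), key(ct$mirna, ct$gene))
  pairs$r <- ct$r[idx]
  pairs$p <- if (p_kind == "analytic") ct$p_analytic[idx] else ct$p_empirical[idx]
  if (p_kind == "empirical" && all(is.na(pairs$p)) && nrow(pairs))
    stop_contract("empirical p-values not attached; run empirical_pvalues() first")

  md <- de_mir$direction[match(pairs$mirna, de_mir$feature_id)]
  gd <- de_gene$direction[match(pairs$gene, de_gene$feature_id)]
  keep <- !is.na(pairs$r) & pairs$r < 0 & !is.na(pairs$p) & pairs$p < p_threshold
  if (require_de) {
    keep <- keep & !is.na(md) & !is.na(gd) & md != "ns" & gd != "ns" & md != gd
  }
  pairs <- pairs[keep, , drop = FALSE]
  md <- md[keep]; gd <- gd[keep]
  if (!nrow(pairs)) {
    warning("network is empty: no pair passed all edge filters")
    return(empty_regulatory_network())
  }
  e <- data.frame(mirna = pairs$mirna, gene = pairs$gene, r = pairs$r,
                  p = pairs$p, conservation = pairs$conservation,
                  percentile = pairs$percentile,
                  mirna_direction = ifelse(is.na(md), "ns", md),
                  gene_direction = ifelse(is.na(gd), "ns", gd),
                  mirna_log2fc = de_mir$log2fc[match(pairs$mirna, de_mir$feature_id)],
                  gene_log2fc = de_gene$log2fc[match(pairs$gene, de_gene$feature_id)],
                  stringsAsFactors = FALSE)
  network_from_edges(e)
}

#' Topology summary of a regulatory network
#'
#' @param net a `RegulatoryNetwork`.
#' @param n_hubs number of top out-degree miRNAs to report (ties broken
#'   lexicographically).
#' @return list with node/edge counts, connected components and sizes,
#'   miRNA out-degree and gene in-degree sequences, and the hub table.
#' @export
network_summary <- function(net, n_hubs = 10) {
  g <- net$graph
  if (igraph::vcount(g) == 0L) {
    return(list(n_mirna = 0L, n_gene = 0L, n_edges = 0L, n_components = 0L,
                component_sizes = integer(0), out_degree = integer(0),
                in_degree = integer(0),
                hubs = data.frame(mirna = character(0), out_degree = integer(0))))
  }
  is_mir <- igraph::V(g)$node_type == "mirna"
  deg <- igraph::degree(g)
  outd <- deg[is_mir]; ind <- deg[!is_mir]
  comp <- igraph::components(g)
  ord <- order(-outd, names(outd))
  hubs <- data.frame(mirna = names(outd)[ord], out_degree = as.integer(outd[ord]),
                     stringsAsFactors = FALSE)[seq_len(min(n_hubs, length(outd))), ,
                                               drop = FALSE]
  rownames(hubs) <- NULL
  list(n_mirna = sum(is_mir), n_gene = sum(!is_mir),
       n_edges = igraph::ecount(g), n_components = comp$no,
       component_sizes = sort(as.integer(comp$csize), decreasing = TRUE),
       out_degree = outd, in_degree = ind, hubs = hubs)
}

#' Extract a seed-anchored subnetwork
#'
#' Gene seeds pull in the seed genes plus all their miRNA neighbors;
#' miRNA seeds pull in the seed miRNAs plus all their target genes. Edge
#' and node attributes are preserved.
#'
#' @param net a `RegulatoryNetwork`.
#' @param seeds character vector of node ids (all of one type).
#' @return A `RegulatoryNetwork` (possibly empty, with a warning).
#' @export
extract_subnetwork <- function(net, seeds) {
  if (!length(seeds)) stop_contract("seeds must be non-empty")
  g <- net$graph
  present <- intersect(seeds, igraph::V(g)$name)
  if (!length(present)) {
    warning("no seed node present in the network")
    return(empty_regulatory_network())
  }
  nb <- unique(unlist(lapply(present, function(v)
    igraph::neighbors(g, v)$name)))
  keep <- union(present, nb)
  sg <- igraph::induced_subgraph(g, keep)
  sg <- igraph::delete_vertices(sg, igraph::V(sg)[igraph::degree(sg) == 0])
  if (igraph::vcount(sg) == 0L) {
    warning("seed nodes are isolated; subnetwork is empty")
    return(empty_regulatory_network())
  }
  as_regulatory_network(sg)
}

#' miRNAs sharing target genes with a hub
#'
#' @param net a `RegulatoryNetwork`.
#' @param hub miRNA id present in the network.
#' @param candidates miRNA ids to screen.
#' @return data.frame (mirna, shared_targets) for candidates sharing at
#'   least one target with the hub, sorted by shared count then id.
#' @export
shared_target_mirnas <- function(net, hub, candidates) {
  g <- net$graph
  if (!hub %in% igraph::V(g)$name) stop_contract("hub '%s' not in network", hub)
  hub_t <- igraph::neighbors(g, hub)$name
  candidates <- setdiff(intersect(candidates, igraph::V(g)$name), hub)
  shared <- vapply(candidates, function(m)
    length(intersect(igraph::neighbors(g, m)$name, hub_t)), integer(1))
  out <- data.frame(mirna = candidates, shared_targets = shared,
                    stringsAsFactors = FALSE)
  out <- out[out$shared_targets > 0L, , drop = FALSE]
  out <- out[order(-out$shared_targets, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}
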