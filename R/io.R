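# Readers and writers for every external representation: counts TSV, GMT
# gene-set collections, TargetScan-style prediction TSVs, and network
# exports (GraphML / SIF / edge TSV). TSV dialect: tab-separated, UTF-8,
# "." decimal, no quoting; the first header cell of a counts file is
# ignored.

#' Read a counts matrix from TSV
#'
#' Expects a header row of sample ids (first cell ignored) and feature ids
#' in the first column. Row order is preserved.
#'
#' @param path file path.
#' @param condition_map named character vector sample id -> `"control"` /
#'   `"treated"`.
#' @param kind `"mirna"` or `"gene"`.
#' @param normalized logical, whether the file holds normalized values.
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path, condition_map, kind = c("gene", "mirna"),
                        normalized = FALSE) {
  kind <- match.arg(kind)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = NA, comment.char = "")
  if (ncol(raw) < 2L) stop_format("counts file needs >= 1 sample column")
  ids <- trimws(as.character(raw[[1L]]))
  if (anyDuplicated(ids))
    stop_format("duplicate feature id in %s: %s", path,
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- raw[-1L]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !all(is.na(v)))
        stop_format("non-numeric cell in column '%s'", names(vals)[j])
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  colnames(m) <- trimws(names(vals))
  expression_matrix(m, condition_map, kind = kind, normalized = normalized)
}

#' Write an expression matrix to TSV
#'
#' @param m an [expression_matrix()].
#' @param path destination file.
#' @export
write_counts <- function(m, path) {
  df <- data.frame(feature = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: set name, description, then member genes, tab-separated.
#' Duplicate genes within one line are collapsed; lines with fewer than
#' three fields are format errors.
#'
#' @param path file path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_format("empty GMT file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop_format("GMT line %d has fewer than 3 fields", short[1L])
  names <- vapply(parts, function(p) trimws(p[1L]), character(1))
  desc <- vapply(parts, function(p) trimws(p[2L]), character(1))
  sets <- lapply(parts, function(p) unique(trimws(p[-(1:2)])))
  sets <- lapply(sets, function(g) g[nzchar(g)])
  names(sets) <- names
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection to GMT
#'
#' @param gsc a [gene_set_collection()].
#' @param path destination file.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$description[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a target-prediction table with percentile filtering
#'
#' Expects columns `mirna`, `gene`, `conservation`, `percentile`. Only
#' records strictly above the class-specific weighted context++ score
#' percentile cutoff are retained: conserved interactions above
#' `conserved_min_pct`, non-conserved above `nonconserved_min_pct`. The
#' thresholds are recorded as attributes for provenance.
#'
#' @param path file path.
#' @param conserved_min_pct strict lower percentile cutoff for conserved
#'   records (default 50).
#' @param nonconserved_min_pct strict lower cutoff for non-conserved
#'   records (default 90).
#' @return A filtered [prediction_table()].
#' @export
read_predictions <- function(path, conserved_min_pct = 50,
                             nonconserved_min_pct = 90) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("mirna", "gene", "conservation", "percentile")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("prediction table missing column(s): %s",
                paste(miss, collapse = ", "))
  pt <- prediction_table(df$mirna, df$gene, df$conservation, df$percentile)
  filter_predictions(pt, conserved_min_pct, nonconserved_min_pct)
}

#' Apply class-specific percentile cutoffs to a prediction table
#'
#' @inheritParams read_predictions
#' @param pt a [prediction_table()].
#' @return The filtered table, cutoffs recorded in attributes.
#' @export
filter_predictions <- function(pt, conserved_min_pct = 50,
                               nonconserved_min_pct = 90) {
  keep <- (pt$conservation == "conserved" & pt$percentile > conserved_min_pct) |
    (pt$conservation == "nonconserved" & pt$percentile > nonconserved_min_pct)
  out <- pt[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conserved_min_pct") <- conserved_min_pct
  attr(out, "nonconserved_min_pct") <- nonconserved_min_pct
  class(out) <- c("PredictionTable", "data.frame")
  out
}

#' Write a prediction table to TSV
#'
#' @param pt a [prediction_table()].
#' @param path destination file.
#' @export
write_predictions <- function(pt, path) {
  utils::write.table(as.data.frame(pt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a regulatory network to disk
#'
#' `graphml` and `edge_tsv` preserve node attributes (type, direction,
#' log2fc) and edge attributes (r, p, conservation, percentile); `sif`
#' keeps topology only (one `mirna targets gene` line per edge).
#'
#' @param net a `RegulatoryNetwork` from [build_network()].
#' @param path destination file.
#' @param format one of `"graphml"`, `"edge_tsv"`, `"sif"`.
#' @export
write_network <- function(net, path, format = c("graphml", "edge_tsv", "sif")) {
  if (!inherits(net, "RegulatoryNetwork"))
    stop_contract("net must be a RegulatoryNetwork")
  if (!is.character(format) || length(format) != 1L ||
      !format %in% c("graphml", "edge_tsv", "sif"))
    stop_config("unknown network format: %s",
                paste(format, collapse = ","))
  g <- net$graph
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edge_tsv") {
    utils::write.table(network_edges(net), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    e <- network_edges(net)
    lines <- if (nrow(e)) sprintf("%s\ttargets\t%s", e$mirna, e$gene) else character(0)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a regulatory network written by [write_network()]
#'
#' @param path file path.
#' @param format the format it was written in.
#' @return A `RegulatoryNetwork`.
#' @export
read_network <- function(path, format = c("graphml", "edge_tsv", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    # igraph's graphml writer stores logicals as strings; retype
    if ("type" %in% igraph::vertex_attr_names(g) &&
        !is.logical(igraph::V(g)$type))
      g <- igraph::set_vertex_attr(g, "type",
                                   value = as.logical(igraph::V(g)$type))
    return(as_regulatory_network(g))
  }
  if (format == "edge_tsv") {
    e <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
    return(network_from_edges(e))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_regulatory_network())
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  e <- data.frame(mirna = parts[, 1L], gene = parts[, 3L],
                  r = NA_real_, p = NA_real_, conservation = NA_character_,
                  percentile = NA_real_,
                  mirna_direction = NA_character_, gene_direction = NA_character_,
                  mirna_log2fc = NA_real_, gene_log2fc = NA_real_,
                  stringsAsFactors = FALSE)
  network_from_edges(e)
}

#' Edge table of a regulatory network
#'
#' @param net a `RegulatoryNetwork`.
#' @return data.frame with one row per edge and all node/edge attributes.
#' @export
network_edges <- function(net) {
  g <- net$graph
  if (igraph::ecount(g) == 0L) {
    return(data.frame(mirna = character(0), gene = character(0),
                      r = numeric(0), p = numeric(0),
                      conservation = character(0), percentile = numeric(0),
                      mirna_direction = character(0), gene_direction = character(0),
                      mirna_log2fc = numeric(0), gene_log2fc = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ends <- igraph::as_edgelist(g)
  # orient every edge as (mirna, gene) using the node_type attribute
  is_mir1 <- igraph::V(g)[ends[, 1L]]$node_type == "mirna"
  mir <- ifelse(is_mir1, ends[, 1L], ends[, 2L])
  gene <- ifelse(is_mir1, ends[, 2L], ends[, 1L])
  vt <- function(attr, ids) igraph::vertex_attr(g, attr, ids)
  data.frame(mirna = mir, gene = gene,
             r = igraph::E(g)$r, p = igraph::E(g)$p,
             conservation = igraph::E(g)$conservation,
             percentile = igraph::E(g)$percentile,
             mirna_direction = vt("direction", mir),
             gene_direction = vt("direction", gene),
             mirna_log2fc = vt("log2fc", mir),
             gene_log2fc = vt("log2fc", gene),
             stringsAsFactors = FALSE)
}
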