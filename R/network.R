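## Methylation-dependent TF regulatory network: backbone construction from
## two evidence sources, DEG filtering, direct/indirect node classification,
## out-degree ranking and Fisher-exact TF activity scoring.

#' Build the TF-target network backbone from two evidence sources
#'
#' Source B (evidence-labelled, ChEA3-style) contributes an edge only when
#' the edge appears in at least one coexpression set AND at least one
#' ChIP-seq set; that intersection is unioned with source A (curated,
#' TRRUST-style). Duplicates are collapsed with provenance.
#'
#' @param edges_a data frame (tf, target).
#' @param edges_b data frame (tf, target, evidence_class) with classes
#'   `"coexpression"`/`"chipseq"` (an optional `set` column is ignored).
#' @return Data frame (tf, target, sources) with `sources` in
#'   `"A"`, `"B"`, `"A,B"`.
#' @export
build_backbone <- function(edges_a, edges_b) {
  key <- function(d) paste(d$tf, d$target, sep = "\r")
  ka <- unique(key(edges_a))
  co <- unique(key(edges_b[edges_b$evidence_class == "coexpression", ,
                           drop = FALSE]))
  ch <- unique(key(edges_b[edges_b$evidence_class == "chipseq", ,
                           drop = FALSE]))
  kb <- intersect(co, ch)
  all_k <- sort(union(ka, kb))
  parts <- strsplit(all_k, "\r", fixed = TRUE)
  data.frame(tf = vapply(parts, `[`, character(1), 1),
             target = vapply(parts, `[`, character(1), 2),
             sources = paste0(ifelse(all_k %in% ka, "A", ""),
                              ifelse(all_k %in% ka & all_k %in% kb, ",", ""),
                              ifelse(all_k %in% kb, "B", "")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter the backbone to differentially expressed genes
#'
#' Keeps edges whose both endpoints are DEGs; isolated nodes are dropped.
#'
#' @param edges backbone data frame (tf, target, ...).
#' @param deg_set character vector of DEGs (time-course set).
#' @param tfs character vector naming which nodes are TFs.
#' @return A `regnet` object: list with `edges` and `nodes` (node table with
#'   `is_tf`).
#' @export
filter_to_degs <- function(edges, deg_set, tfs) {
  keep <- edges$tf %in% deg_set & edges$target %in% deg_set
  e <- edges[keep, , drop = FALSE]
  rownames(e) <- NULL
  if (nrow(e) == 0) warning("no edges survive the DEG filter")
  nodes <- data.frame(node = sort(unique(c(e$tf, e$target))),
                      stringsAsFactors = FALSE)
  nodes$is_tf <- nodes$node %in% tfs
  structure(list(edges = e, nodes = nodes), class = "regnet")
}

#' @export
print.regnet <- function(x, ...) {
  cat("regulatory network:", nrow(x$edges), "edges,", nrow(x$nodes),
      "nodes (", sum(x$nodes$is_tf), "TFs )\n")
  if (!is.null(x$nodes$class))
    print(table(x$nodes$class))
  invisible(x)
}

#' Classify network nodes as direct/indirect/target
#'
#' A TF is `direct` iff all three evidence flags hold: upregulated in the
#' KO, downregulated on methyltransferase re-expression, and associated to
#' at least one KO-hypomethylated DMR overlapping a regulatory region.
#' TFs missing any flag are `indirect`; non-TF nodes are `target`.
#'
#' @param net a `regnet`.
#' @param evidence data frame keyed by `gene` with logical columns
#'   `up_in_ko`, `down_in_rescue`, `has_hypo_regulatory_dmr`; genes absent
#'   from the table count as all-FALSE.
#' @return The network with node `class` and the three flag columns.
#' @export
classify_nodes <- function(net, evidence) {
  stopifnot(inherits(net, "regnet"))
  flags <- c("up_in_ko", "down_in_rescue", "has_hypo_regulatory_dmr")
  stopifnot(all(flags %in% names(evidence)))
  i <- match(net$nodes$node, evidence$gene)
  for (f in flags)
    net$nodes[[f]] <- !is.na(i) & evidence[[f]][i] %in% TRUE
  direct <- net$nodes$is_tf & net$nodes$up_in_ko &
    net$nodes$down_in_rescue & net$nodes$has_hypo_regulatory_dmr
  net$nodes$class <- ifelse(!net$nodes$is_tf, "target",
                            ifelse(direct, "direct", "indirect"))
  net
}

## igraph view of a regnet (nodes kept in table order)
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("tf", "target")],
                                directed = TRUE,
                                vertices = net$nodes$node)
}

#' Rank TFs by out-degree centrality
#'
#' TFs sorted by out-degree (number of regulated genes) descending, ties
#' broken lexicographically by id. The top `ceiling(percentile% x N)` nodes
#' over ALL network nodes are flagged.
#'
#' @param net a `regnet`.
#' @param percentile top percentile to flag (default 1).
#' @return The network with `out_degree`, `rank` (over TFs; NA for
#'   non-TFs) and `top_percentile` node columns, plus a `ranking` data
#'   frame of TFs in rank order.
#' @export
rank_by_out_degree <- function(net, percentile = 1) {
  g <- as_igraph(net)
  deg <- igraph::degree(g, mode = "out")
  net$nodes$out_degree <- as.integer(deg[net$nodes$node])
  n_top <- ceiling(percentile / 100 * nrow(net$nodes))
  ord_all <- order(-net$nodes$out_degree, net$nodes$node)
  net$nodes$top_percentile <- FALSE
  net$nodes$top_percentile[ord_all[seq_len(n_top)]] <- TRUE
  tf <- net$nodes[net$nodes$is_tf, , drop = FALSE]
  tf <- tf[order(-tf$out_degree, tf$node), , drop = FALSE]
  net$nodes$rank <- NA_integer_
  net$nodes$rank[match(tf$node, net$nodes$node)] <- seq_len(nrow(tf))
  net$ranking <- data.frame(tf = tf$node, out_degree = tf$out_degree,
                            rank = seq_len(nrow(tf)),
                            top_percentile = tf$top_percentile,
                            stringsAsFactors = FALSE, row.names = NULL)
  net
}

#' TF activity as target enrichment among DEGs
#'
#' For each TF, a one-sided (greater) Fisher's exact test on the 2x2 table
#' of target-of-TF x DEG membership over the gene universe; TFs are
#' returned sorted by decreasing `-log10(p)`. BH-adjusted values are
#' reported alongside raw p. TFs with no target in the universe are
#' skipped.
#'
#' @param net a `regnet` (edges define TF target sets).
#' @param deg_set DEG gene set (e.g. union of KO-vs-WT contrasts).
#' @param universe all genes in the expression analysis.
#' @return Data frame (tf, n_targets, n_deg_targets, odds_ratio, p,
#'   neg_log10_p, fdr).
#' @export
tf_activity_enrichment <- function(net, deg_set, universe) {
  deg_set <- intersect(deg_set, universe)
  tfs <- net$nodes$node[net$nodes$is_tf]
  rows <- lapply(tfs, function(tf) {
    tgt <- intersect(unique(net$edges$target[net$edges$tf == tf]), universe)
    if (length(tgt) == 0) return(NULL)
    a <- length(intersect(tgt, deg_set))
    b <- length(tgt) - a
    c <- length(deg_set) - a
    d <- length(universe) - a - b - c
    ft <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                      alternative = "greater")
    data.frame(tf = tf, n_targets = length(tgt), n_deg_targets = a,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(tf = character(), n_targets = integer(),
                                      n_deg_targets = integer(),
                                      odds_ratio = numeric(), p = numeric(),
                                      neg_log10_p = numeric(),
                                      fdr = numeric()))
  out$neg_log10_p <- -log10(out$p)
  out$fdr <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a network to edge/node TSVs and GraphML
#'
#' @param net a `regnet`.
#' @param prefix file path prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>_nodes.tsv` and `<prefix>.graphml`.
#' @param config_hash optional provenance hash for the TSV headers.
#' @return Invisibly, the written paths.
#' @export
write_network <- function(net, prefix, config_hash = NULL) {
  pe <- paste0(prefix, "_edges.tsv")
  pn <- paste0(prefix, "_nodes.tsv")
  pg <- paste0(prefix, ".graphml")
  write_tsv(net$edges, pe, config_hash)
  write_tsv(net$nodes, pn, config_hash)
  g <- as_igraph(net)
  for (cl in setdiff(names(net$nodes), "node"))
    g <- igraph::set_vertex_attr(g, cl, value = net$nodes[[cl]])
  igraph::write_graph(g, pg, format = "graphml")
  invisible(c(pe, pn, pg))
}

#' Read a network written by [write_network()]
#'
#' @param prefix file path prefix used at write time.
#' @return A `regnet`.
#' @export
read_network <- function(prefix) {
  e <- read_tsv(paste0(prefix, "_edges.tsv"))
  n <- read_tsv(paste0(prefix, "_nodes.tsv"))
  for (cl in intersect(names(n), c("is_tf", "top_percentile", "up_in_ko",
                                   "down_in_rescue",
                                   "has_hypo_regulatory_dmr")))
    n[[cl]] <- as.logical(n[[cl]])
  structure(list(edges = e, nodes = n), class = "regnet")
}
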