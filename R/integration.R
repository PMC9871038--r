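## Multi-omics joins: target-gene calling (the three-criterion definition),
## early/medium/late timing groups, multi-block factor analysis, and the
## single-cell cluster-abundance Fisher test.

#' Call methyltransferase target genes
#'
#' A gene is called iff (i) it has at least one associated KO-hypomethylated
#' DMR within the association window of its TSS, (ii) that DMR overlaps a
#' putative regulatory region (promoter/enhancer/super-enhancer active at
#' any stage), and (iii) the gene is upregulated in the KO (passes the
#' pairwise thresholds with positive log2FC in at least one post-ESC
#' contrast). The call is the exact conjunction of the three predicates;
#' per-call provenance (supporting DMRs, regulatory class, contrast
#' evidence) is recorded.
#'
#' @param hypo_dmrs KO-hypomethylated DMR data frame with `region_id` and
#'   the `regulatory`/`regulatory_class` flags from
#'   [overlap_dmrs_with_regions()].
#' @param dmr_gene_map association table (region_id, gene) from
#'   [associate_regions_to_genes()].
#' @param ko_contrasts named list of pairwise KO-vs-WT [pairwise_contrast()]
#'   results (names = stage labels).
#' @return Data frame (gene, dmrs, regulatory_class, stages, n_dmrs).
#' @export
call_target_genes <- function(hypo_dmrs, dmr_gene_map, ko_contrasts) {
  if (is.null(ko_contrasts) || length(ko_contrasts) == 0)
    stop("missing upstream table: KO-vs-WT pairwise contrasts")
  if (is.null(hypo_dmrs$regulatory))
    stop("missing upstream table: regulatory flags on hypo DMRs")
  up_by_stage <- lapply(ko_contrasts, function(ct)
    ct$gene[ct$pass & ct$logfc > 0])
  up <- unique(unlist(up_by_stage))
  reg_dmrs <- hypo_dmrs[hypo_dmrs$regulatory, , drop = FALSE]
  map <- dmr_gene_map[dmr_gene_map$region_id %in% reg_dmrs$region_id, ,
                      drop = FALSE]
  map <- map[map$gene %in% up, , drop = FALSE]
  if (nrow(map) == 0)
    return(data.frame(gene = character(), dmrs = character(),
                      regulatory_class = character(), stages = character(),
                      n_dmrs = integer(), stringsAsFactors = FALSE))
  cls <- setNames(reg_dmrs$regulatory_class, reg_dmrs$region_id)
  calls <- do.call(rbind, lapply(split(map$region_id, map$gene),
                                 function(r) {
    data.frame(dmrs = paste(sort(unique(r)), collapse = ","),
               regulatory_class = paste(sort(unique(cls[r])), collapse = ","),
               n_dmrs = length(unique(r)), stringsAsFactors = FALSE)
  }))
  calls$gene <- rownames(calls)
  calls$stages <- vapply(calls$gene, function(g)
    paste(names(up_by_stage)[vapply(up_by_stage, function(s) g %in% s,
                                    logical(1))], collapse = ","),
    character(1))
  rownames(calls) <- NULL
  calls[order(calls$gene),
        c("gene", "dmrs", "regulatory_class", "stages", "n_dmrs")]
}

#' Assign early/medium/late timing groups to target genes
#'
#' The timing group is the post-ESC stage at which the KO-WT expression
#' difference (log2 scale by default) is largest: first, second and third
#' post-ESC stage map to early, medium and late. Ties break toward the
#' earlier stage.
#'
#' @param genes character vector of target genes.
#' @param rpkm abundance matrix.
#' @param samples sample metadata (sample, condition, stage).
#' @param stages ordered post-ESC stage labels (length 3).
#' @param log_scale compute differences on `log2(rpkm + 1)` (default TRUE).
#' @return Data frame (gene, timing, stage, diff).
#' @export
assign_timing_groups <- function(genes, rpkm, samples,
                                 stages = c("EpiLC", "ME24", "ME48"),
                                 log_scale = TRUE) {
  stopifnot(length(stages) == 3)
  x <- if (log_scale) log2(rpkm + 1) else rpkm
  diffs <- vapply(stages, function(st) {
    ko <- samples$sample[samples$condition == "KO" & samples$stage == st]
    wt <- samples$sample[samples$condition == "WT" & samples$stage == st]
    rowMeans(x[genes, ko, drop = FALSE]) -
      rowMeans(x[genes, wt, drop = FALSE])
  }, numeric(length(genes)))
  diffs <- matrix(diffs, ncol = 3, dimnames = list(genes, stages))
  imax <- apply(diffs, 1, which.max)      # ties -> earliest (which.max)
  data.frame(gene = genes,
             timing = c("early", "medium", "late")[imax],
             stage = stages[imax],
             diff = diffs[cbind(seq_along(genes), imax)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Multi-block factor analysis (MFA-style)
#'
#' Each block (samples x features) is column-standardised, divided by its
#' first singular value (so every block contributes unit top variance), the
#' weighted blocks are concatenated and a global PCA is run. Per-sample
#' scores and per-block contributions to each component are returned.
#'
#' @param blocks named list of samples x features matrices sharing rows.
#' @param n_components components to keep (default 5).
#' @return List with `scores` (samples x components), `block_weights`
#'   (first singular value per block), `block_contrib` (blocks x
#'   components, columns sum to 1), and `sdev`.
#' @export
multiblock_factor_analysis <- function(blocks, n_components = 5) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  ns <- vapply(blocks, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("blocks must share samples (rows)")
  prep <- lapply(names(blocks), function(b) {
    x <- as.matrix(blocks[[b]])
    sds <- apply(x, 2, sd)
    if (all(sds == 0)) stop("block '", b, "' has zero variance")
    x <- x[, sds > 0, drop = FALSE]
    x <- scale(x)
    d1 <- svd(x, nu = 0, nv = 0)$d[1]
    list(x = x / d1, d1 = d1)
  })
  names(prep) <- names(blocks)
  concat <- do.call(cbind, lapply(prep, `[[`, "x"))
  pc <- prcomp(concat, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  block_id <- rep(names(blocks),
                  vapply(prep, function(p) ncol(p$x), integer(1)))
  contrib <- apply(pc$rotation[, seq_len(k), drop = FALSE]^2, 2, function(l)
    tapply(l, block_id, sum) / sum(l))
  contrib <- matrix(contrib, nrow = length(blocks),
                    dimnames = list(unique(block_id), colnames(pc$x)[seq_len(k)]))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       block_weights = vapply(prep, `[[`, numeric(1), "d1"),
       block_contrib = contrib,
       sdev = pc$sdev[seq_len(k)])
}

#' Per-cluster differential abundance between genotypes
#'
#' For each cell cluster and each mutant genotype, tests whether mutant
#' cells are enriched (one-sided Fisher, greater) or depleted (one-sided,
#' less) in the cluster relative to the reference genotype, on the 2x2
#' genotype x in/out-of-cluster table. Status uses the p < 1e-4 convention.
#'
#' @param cluster per-cell cluster labels.
#' @param genotype per-cell genotype labels.
#' @param reference the reference genotype (default `"WT"`).
#' @return Data frame (cluster, genotype, mut_in, mut_out, ref_in, ref_out,
#'   odds_ratio, p_enriched, p_depleted, status). Clusters with zero cells
#'   overall are skipped.
#' @export
cluster_abundance_test <- function(cluster, genotype, reference = "WT") {
  stopifnot(length(cluster) == length(genotype))
  if (!reference %in% genotype) stop("no cells with reference genotype")
  muts <- setdiff(unique(genotype), reference)
  out <- list()
  for (cl in sort(unique(cluster))) {
    for (m in muts) {
      a <- sum(genotype == m & cluster == cl)
      b <- sum(genotype == m & cluster != cl)
      c <- sum(genotype == reference & cluster == cl)
      d <- sum(genotype == reference & cluster != cl)
      tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
      pe <- fisher.test(tab, alternative = "greater")$p.value
      pd <- fisher.test(tab, alternative = "less")$p.value
      out[[length(out) + 1]] <- data.frame(
        cluster = cl, genotype = m, mut_in = a, mut_out = b,
        ref_in = c, ref_out = d,
        odds_ratio = ifelse(b * c > 0, (a * d) / (b * c), NA_real_),
        p_enriched = pe, p_depleted = pd,
        status = if (pe < 1e-4) "enriched" else if (pd < 1e-4) "depleted"
                 else "ns",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
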