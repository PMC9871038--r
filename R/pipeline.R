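## End-to-end orchestration. Stages communicate strictly through plain-text
## files in the run directory, so a rerun after deleting an intermediate
## recomputes only that stage and everything downstream, and a fresh rerun
## with the same configuration is bit-identical (the manifest records md5s
## of every output).

PIPELINE_STAGES <- c("simulate", "methylome", "transcriptome", "regions",
                     "integration", "network")

stage_files <- function(stage, run_dir, cfg) {
  f <- switch(stage,
    simulate = c("inputs/counts.tsv", "inputs/gene_model.tsv",
                 "inputs/samples_expr.tsv", "inputs/samples_cpg.tsv",
                 "inputs/peaks.tsv", "inputs/edges_a.tsv",
                 "inputs/edges_b.tsv", "truth/regions.tsv",
                 "truth/genes.tsv", "truth/tf_edges.tsv"),
    methylome = c("methylome/wt_dmrs.tsv", "methylome/ko_dmrs.tsv",
                  "methylome/dmr_stage_meth.tsv"),
    transcriptome = c("transcriptome/rpkm.tsv", "transcriptome/timecourse.tsv",
                      "transcriptome/clusters.tsv",
                      "transcriptome/rescue_overlap.tsv",
                      paste0("transcriptome/pairwise_",
                             cfg$sim$stages[-1], ".tsv"),
                      paste0("transcriptome/rescue_",
                             cfg$sim$stages[-1], ".tsv")),
    regions = c("regions/enhancers.tsv", "regions/promoters.tsv",
                "regions/hypo_dmr_flags.tsv", "regions/associations.tsv",
                "regions/enrichment.tsv"),
    integration = c("integration/target_genes.tsv", "integration/timing.tsv",
                    "integration/mfa_scores.tsv"),
    network = c("network/backbone.tsv", "network/net_edges.tsv",
                "network/net_nodes.tsv", "network/ranking.tsv",
                "network/activity.tsv")
  )
  file.path(run_dir, f)
}

cpg_report_paths <- function(run_dir, samples) {
  setNames(file.path(run_dir, "inputs", "cpg",
                     paste0(samples$sample, ".cpg.tsv")), samples$sample)
}

load_cpg <- function(run_dir) {
  samples <- read_tsv(file.path(run_dir, "inputs/samples_cpg.tsv"))
  read_cpg_reports(cpg_report_paths(run_dir, samples), samples)
}

load_expr <- function(run_dir) {
  counts <- as.matrix(read_tsv(file.path(run_dir, "inputs/counts.tsv"),
                               row.names = 1))
  list(counts = counts,
       samples = read_tsv(file.path(run_dir, "inputs/samples_expr.tsv")),
       gene_model = read_tsv(file.path(run_dir, "inputs/gene_model.tsv")))
}

run_stage_simulate <- function(cfg, run_dir, hash) {
  sim <- simulate_all(cfg$sim)
  dir.create(file.path(run_dir, "truth"), showWarnings = FALSE)
  write_cpg_reports(sim$cpg, file.path(run_dir, "inputs", "cpg"))
  cts <- data.frame(gene = rownames(sim$expr$counts), sim$expr$counts,
                    check.names = FALSE)
  write_tsv(cts, file.path(run_dir, "inputs/counts.tsv"), hash)
  write_tsv(sim$expr$gene_model, file.path(run_dir, "inputs/gene_model.tsv"),
            hash)
  write_tsv(sim$expr$samples, file.path(run_dir, "inputs/samples_expr.tsv"),
            hash)
  write_tsv(sim$cpg$samples, file.path(run_dir, "inputs/samples_cpg.tsv"),
            hash)
  write_tsv(sim$peaks, file.path(run_dir, "inputs/peaks.tsv"), hash)
  write_tsv(sim$edges_a, file.path(run_dir, "inputs/edges_a.tsv"), hash)
  write_tsv(sim$edges_b, file.path(run_dir, "inputs/edges_b.tsv"), hash)
  write_tsv(sim$truth$regions, file.path(run_dir, "truth/regions.tsv"), hash)
  write_tsv(sim$truth$genes, file.path(run_dir, "truth/genes.tsv"), hash)
  write_tsv(sim$truth$edges, file.path(run_dir, "truth/tf_edges.tsv"), hash)
}

run_stage_methylome <- function(cfg, run_dir, hash, verbose = FALSE) {
  cpg <- load_cpg(run_dir)
  stages <- cfg$sim$stages
  dcfg <- cfg$dmr
  ## WT differentiation dynamics: all pairwise stage comparisons
  pairs <- utils::combn(stages, 2, simplify = FALSE)
  wt_lists <- lapply(pairs, function(pr)
    call_dmrs(cpg, cpg_samples(cpg, "WT", pr[2]),
              cpg_samples(cpg, "WT", pr[1]), dcfg,
              comparison = paste0("WT_", pr[2], "_vs_", pr[1])))
  wt_dmrs <- combine_dmr_sets(wt_lists)
  wt_dmrs <- filter_by_coverage(wt_dmrs, cpg, dcfg)
  stage_log(verbose, "methylome: %d WT time-course DMRs after filters",
            nrow(wt_dmrs))
  wt_groups <- setNames(lapply(stages, function(st)
    cpg_samples(cpg, "WT", st)), stages)
  traj <- dmr_methylation(wt_dmrs, cpg, wt_groups, dcfg)
  cl <- cluster_dmr_trajectories(traj, k = cfg$dmr_k,
                                 seed = derive_seed(cfg$sim$seed, "kmeans_dmr"))
  wt_dmrs$cluster <- cl$labels
  ## KO vs WT at matching stages
  ko_lists <- lapply(stages, function(st)
    call_dmrs(cpg, cpg_samples(cpg, "KO", st), cpg_samples(cpg, "WT", st),
              dcfg, comparison = paste0("KO_vs_WT_", st)))
  ko_dmrs <- combine_dmr_sets(ko_lists)
  ko_dmrs <- filter_by_coverage(ko_dmrs, cpg, dcfg)
  grp <- list(KO = cpg_samples(cpg, "KO"), WT = cpg_samples(cpg, "WT"))
  mm <- dmr_methylation(ko_dmrs, cpg, grp, dcfg)
  ko_dmrs <- classify_ko_dmrs(ko_dmrs, wt_dmrs, mm[, "KO"], mm[, "WT"])
  ko_dmrs$meth_ko <- mm[, "KO"]; ko_dmrs$meth_wt <- mm[, "WT"]
  ko_dmrs$region_id <- sprintf("koDMR%05d", seq_len(max(nrow(ko_dmrs), 0)))
  stage_log(verbose, "methylome: %d KO-vs-WT DMRs (%d hypo)",
            nrow(ko_dmrs), sum(ko_dmrs$direction == "hypo"))
  traj_df <- data.frame(wt_dmrs[, c("chrom", "start", "end", "cluster")],
                        traj, check.names = FALSE)
  write_tsv(wt_dmrs, file.path(run_dir, "methylome/wt_dmrs.tsv"), hash)
  write_tsv(ko_dmrs, file.path(run_dir, "methylome/ko_dmrs.tsv"), hash)
  write_tsv(traj_df, file.path(run_dir, "methylome/dmr_stage_meth.tsv"), hash)
}

run_stage_transcriptome <- function(cfg, run_dir, hash, verbose = FALSE) {
  ex <- load_expr(run_dir)
  norm <- normalize_expression(ex$counts,
                               ex$gene_model$length[
                                 match(rownames(ex$counts),
                                       ex$gene_model$gene)])
  rpkm <- norm$rpkm[norm$expressed, , drop = FALSE]
  s <- ex$samples
  main <- s$sample[s$condition %in% c("WT", "KO")]
  groups <- paste(s$condition, s$stage, sep = "_")[match(main, s$sample)]
  tc <- timecourse_anova(rpkm[, main, drop = FALSE], groups,
                         baseline = paste0("WT_", cfg$sim$stages[1]))
  stage_log(verbose, "transcriptome: %d/%d genes expressed, %d time-course DEGs",
            sum(norm$expressed), nrow(ex$counts), sum(tc$pass))
  for (st in cfg$sim$stages[-1]) {
    pw <- pairwise_contrast(rpkm, s$sample[s$condition == "KO" & s$stage == st],
                            s$sample[s$condition == "WT" & s$stage == st],
                            class = "pairwise")
    write_tsv(pw, file.path(run_dir, sprintf("transcriptome/pairwise_%s.tsv",
                                             st)), hash)
    rs <- pairwise_contrast(rpkm,
                            s$sample[s$condition == "KO_3B" & s$stage == st],
                            s$sample[s$condition == "KO_empty" & s$stage == st],
                            class = "rescue")
    write_tsv(rs, file.path(run_dir, sprintf("transcriptome/rescue_%s.tsv",
                                             st)), hash)
  }
  degs <- tc$gene[tc$pass]
  cl <- cluster_expression_profiles(
    log2(rpkm[degs, main, drop = FALSE] + 1), k = cfg$expr_k,
    seed = derive_seed(cfg$sim$seed, "kmeans_expr"))
  ## rescue overlap: up in KO at any stage vs down on re-expression
  up_ko <- down_resc <- character()
  for (st in cfg$sim$stages[-1]) {
    pw <- read_tsv(file.path(run_dir, sprintf("transcriptome/pairwise_%s.tsv",
                                              st)))
    rs <- read_tsv(file.path(run_dir, sprintf("transcriptome/rescue_%s.tsv",
                                              st)))
    up_ko <- union(up_ko, pw$gene[pw$pass & pw$logfc > 0])
    down_resc <- union(down_resc, rs$gene[rs$pass & rs$logfc < 0])
  }
  ro <- rescue_overlap_test(up_ko, down_resc, rownames(rpkm))
  rpkm_df <- data.frame(gene = rownames(rpkm), rpkm, check.names = FALSE)
  write_tsv(rpkm_df, file.path(run_dir, "transcriptome/rpkm.tsv"), hash)
  write_tsv(tc, file.path(run_dir, "transcriptome/timecourse.tsv"), hash)
  write_tsv(data.frame(gene = degs, cluster = cl$cluster[degs]),
            file.path(run_dir, "transcriptome/clusters.tsv"), hash)
  write_tsv(data.frame(fraction_rescued = ro$fraction,
                       odds_ratio = ro$odds_ratio, p = ro$p,
                       n_up_in_ko = length(up_ko),
                       n_down_in_rescue = length(down_resc)),
            file.path(run_dir, "transcriptome/rescue_overlap.tsv"), hash)
}

run_stage_regions <- function(cfg, run_dir, hash, verbose = FALSE) {
  peaks <- read_tsv(file.path(run_dir, "inputs/peaks.tsv"))
  gene_model <- read_tsv(file.path(run_dir, "inputs/gene_model.tsv"))
  ko_dmrs <- read_tsv(file.path(run_dir, "methylome/ko_dmrs.tsv"))
  hypo <- ko_dmrs[ko_dmrs$direction == "hypo", , drop = FALSE]
  enh <- stitch_and_rank_enhancers(peaks, cfg$stitch_bp, gene_model,
                                   cfg$tss_exclusion_bp)
  prom <- define_promoters(gene_model, cfg$promoter_window_bp, peaks)
  flags <- overlap_dmrs_with_regions(hypo, enh, prom)
  assoc <- associate_regions_to_genes(flags, gene_model, rule = "window",
                                      window_kb = cfg$association_window_kb)
  stage_log(verbose,
            "regions: %d enhancers (%d super), %d/%d hypo DMRs regulatory",
            nrow(enh), sum(enh$class == "super_enhancer"), sum(flags$regulatory),
            nrow(flags))
  ## annotation enrichment of hypo DMRs vs region classes
  workspace <- setNames(rep(cfg$sim$chrom_length_bp, cfg$sim$n_chromosomes),
                        paste0("chr", seq_len(cfg$sim$n_chromosomes)))
  ann <- list(
    typical_enhancer = enh[enh$class == "typical_enhancer", , drop = FALSE],
    super_enhancer = enh[enh$class == "super_enhancer", , drop = FALSE],
    promoter = prom)
  enr <- if (nrow(hypo) > 0)
    randomized_annotation_enrichment(hypo, ann, workspace,
                                     n_samplings = cfg$n_samplings,
                                     seed = derive_seed(cfg$sim$seed,
                                                        "enrichment"))
  else data.frame(feature = names(ann), observed_bp = NA, expected_bp = NA,
                  log2_ratio = NA, p = NA, q = NA, status = NA)
  write_tsv(enh, file.path(run_dir, "regions/enhancers.tsv"), hash)
  write_tsv(prom, file.path(run_dir, "regions/promoters.tsv"), hash)
  write_tsv(flags, file.path(run_dir, "regions/hypo_dmr_flags.tsv"), hash)
  write_tsv(assoc, file.path(run_dir, "regions/associations.tsv"), hash)
  write_tsv(enr, file.path(run_dir, "regions/enrichment.tsv"), hash)
}

run_stage_integration <- function(cfg, run_dir, hash, verbose = FALSE) {
  flags <- read_tsv(file.path(run_dir, "regions/hypo_dmr_flags.tsv"))
  assoc <- read_tsv(file.path(run_dir, "regions/associations.tsv"))
  rpkm_df <- read_tsv(file.path(run_dir, "transcriptome/rpkm.tsv"))
  rpkm <- as.matrix(rpkm_df[, -1]); rownames(rpkm) <- rpkm_df$gene
  s <- read_tsv(file.path(run_dir, "inputs/samples_expr.tsv"))
  kc <- setNames(lapply(cfg$sim$stages[-1], function(st)
    read_tsv(file.path(run_dir, sprintf("transcriptome/pairwise_%s.tsv", st)))),
    cfg$sim$stages[-1])
  flags$regulatory <- as.logical(flags$regulatory)
  targets <- call_target_genes(flags, assoc, kc)
  timing <- if (nrow(targets) > 0)
    assign_timing_groups(targets$gene, rpkm, s,
                         stages = cfg$sim$stages[2:4])
  else data.frame(gene = character(), timing = character(),
                  stage = character(), diff = numeric())
  stage_log(verbose, "integration: %d target genes called", nrow(targets))
  ## MFA on matched expression / DMR-methylation blocks (WT + KO samples)
  main <- s$sample[s$condition %in% c("WT", "KO")]
  meth_df <- read_tsv(file.path(run_dir, "methylome/ko_dmrs.tsv"))
  cpg <- load_cpg(run_dir)
  grp <- setNames(lapply(main, function(x) x), main)
  mblock <- t(dmr_methylation(meth_df, cpg, grp, cfg$dmr))
  mblock[is.na(mblock)] <- 50
  eblock <- t(log2(rpkm[, main, drop = FALSE] + 1))
  mfa <- multiblock_factor_analysis(list(expression = eblock,
                                         methylation = mblock),
                                    n_components = 4)
  mfa_df <- data.frame(sample = rownames(mfa$scores), mfa$scores,
                       check.names = FALSE)
  write_tsv(targets, file.path(run_dir, "integration/target_genes.tsv"), hash)
  write_tsv(timing, file.path(run_dir, "integration/timing.tsv"), hash)
  write_tsv(mfa_df, file.path(run_dir, "integration/mfa_scores.tsv"), hash)
}

run_stage_network <- function(cfg, run_dir, hash, verbose = FALSE) {
  edges_a <- read_tsv(file.path(run_dir, "inputs/edges_a.tsv"))
  edges_b <- read_tsv(file.path(run_dir, "inputs/edges_b.tsv"))
  tc <- read_tsv(file.path(run_dir, "transcriptome/timecourse.tsv"))
  flags <- read_tsv(file.path(run_dir, "regions/hypo_dmr_flags.tsv"))
  assoc <- read_tsv(file.path(run_dir, "regions/associations.tsv"))
  rpkm_genes <- read_tsv(file.path(run_dir, "transcriptome/rpkm.tsv"))$gene
  up_ko <- down_resc <- deg_ko <- character()
  for (st in cfg$sim$stages[-1]) {
    pw <- read_tsv(file.path(run_dir, sprintf("transcriptome/pairwise_%s.tsv",
                                              st)))
    rs <- read_tsv(file.path(run_dir, sprintf("transcriptome/rescue_%s.tsv",
                                              st)))
    up_ko <- union(up_ko, pw$gene[pw$pass & pw$logfc > 0])
    down_resc <- union(down_resc, rs$gene[rs$pass & rs$logfc < 0])
    deg_ko <- union(deg_ko, pw$gene[pw$pass])
  }
  hypo_reg <- flags$region_id[as.logical(flags$regulatory)]
  genes_with_dmr <- unique(assoc$gene[assoc$region_id %in% hypo_reg])
  backbone <- build_backbone(edges_a, edges_b)
  tfs <- unique(backbone$tf)
  net <- filter_to_degs(backbone, tc$gene[tc$pass], tfs)
  evidence <- data.frame(gene = net$nodes$node, stringsAsFactors = FALSE)
  evidence$up_in_ko <- evidence$gene %in% up_ko
  evidence$down_in_rescue <- evidence$gene %in% down_resc
  evidence$has_hypo_regulatory_dmr <- evidence$gene %in% genes_with_dmr
  net <- classify_nodes(net, evidence)
  net <- rank_by_out_degree(net, cfg$top_percentile)
  act <- tf_activity_enrichment(net, deg_ko, rpkm_genes)
  stage_log(verbose, "network: %d edges, %d nodes (%d TFs, %d direct)",
            nrow(net$edges), nrow(net$nodes), sum(net$nodes$is_tf),
            sum(net$nodes$class == "direct"))
  write_tsv(backbone, file.path(run_dir, "network/backbone.tsv"), hash)
  write_network(net, file.path(run_dir, "network/net"), hash)
  write_tsv(net$ranking, file.path(run_dir, "network/ranking.tsv"), hash)
  write_tsv(act, file.path(run_dir, "network/activity.tsv"), hash)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order (simulate, methylome,
#' transcriptome, regions, integration, network), each reading its inputs
#' from and writing its outputs to `run_dir`. A stage whose outputs already
#' exist under a matching configuration hash is skipped, so deleting an
#' intermediate and rerunning recomputes only that stage and everything
#' downstream. The resolved configuration, and a manifest with the md5 of
#' every output file, are written alongside the outputs.
#'
#' @param cfg an [analysis_config()].
#' @param run_dir output directory (created if missing).
#' @param verbose log record counts per stage.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg = analysis_config(), run_dir,
                         verbose = FALSE) {
  stopifnot(inherits(cfg, "analysis_config"))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("inputs", "methylome", "transcriptome", "regions",
              "integration", "network"))
    dir.create(file.path(run_dir, d), showWarnings = FALSE)
  hash <- hash_object(unclass_deep(cfg))
  jsonlite::write_json(unclass_deep(cfg),
                       file.path(run_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  status <- character()
  upstream_recomputed <- FALSE
  for (stage in PIPELINE_STAGES) {
    files <- stage_files(stage, run_dir, cfg)
    hash_file <- file.path(run_dir, paste0(".", stage, ".hash"))
    up_to_date <- !upstream_recomputed && all(file.exists(files)) &&
      file.exists(hash_file) &&
      identical(readLines(hash_file, warn = FALSE), as.character(hash))
    if (up_to_date) {
      status[stage] <- "skipped"
      stage_log(verbose, "%s: up to date, skipped", stage)
      next
    }
    switch(stage,
      simulate = run_stage_simulate(cfg, run_dir, hash),
      methylome = run_stage_methylome(cfg, run_dir, hash, verbose),
      transcriptome = run_stage_transcriptome(cfg, run_dir, hash, verbose),
      regions = run_stage_regions(cfg, run_dir, hash, verbose),
      integration = run_stage_integration(cfg, run_dir, hash, verbose),
      network = run_stage_network(cfg, run_dir, hash, verbose))
    writeLines(as.character(hash), hash_file)
    status[stage] <- "computed"
    upstream_recomputed <- TRUE
  }
  all_files <- unlist(lapply(PIPELINE_STAGES, stage_files, run_dir, cfg))
  rel <- sub(paste0("^", run_dir, "/?"), "", all_files)
  ## stage status is logged, not put in the manifest: the manifest must be
  ## bit-identical for identical config+inputs regardless of resume state
  stage_log(verbose, "stages: %s",
            paste(names(status), status, sep = "=", collapse = ", "))
  manifest <- list(
    config_hash = as.character(hash),
    version = cfg$version,
    seed = cfg$sim$seed,
    files = as.list(setNames(as.character(tools::md5sum(all_files)), rel))
  )
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, status = status))
}

## strip S3 classes recursively so hashing/serialisation sees plain lists
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
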