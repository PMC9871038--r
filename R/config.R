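#' Simulation configuration for the synthetic differentiation time course
#'
#' Defines the study conditions the generator emulates: a WT versus
#' de-novo-methyltransferase-knockout (KO) embryonic stem cell line taken
#' through a two-step differentiation (ESC -> EpiLC -> meso-endoderm at 24 h
#' and 48 h), profiled by per-CpG bisulfite counts, expression counts (with a
#' KO rescue arm), active-chromatin peaks and a TF-target edge catalogue.
#'
#' Region dynamics classes and their stage means (methylation fraction):
#' `stableLow` 0.10 throughout; `stableHigh` 0.85 throughout; `gainMedium`
#' 0.10 at ESC then 0.70 from EpiLC; `gainHigh` 0.10 then 0.90 from EpiLC;
#' `demethylated` 0.80 at ESC then 0.20 from EpiLC. A fraction
#' `ko_fail_fraction` of the gain regions fail to methylate in the KO (their
#' KO means stay frozen at the ESC level); each such region carries one
#' planted target gene whose TSS lies within the association window.
#'
#' @param seed integer; fully determines every generated dataset.
#' @param n_chromosomes,chrom_length_bp synthetic genome geometry.
#' @param n_cpg total CpGs (region CpGs plus background).
#' @param n_regions number of planted methylation regions.
#' @param region_cluster_fractions named proportions over the five dynamics
#'   classes; must sum to 1.
#' @param ko_fail_fraction fraction of gain regions that fail to gain
#'   methylation in the KO.
#' @param n_genes total genes in the expression model.
#' @param n_deg_per_cluster genes planted per expression archetype (four
#'   archetypes: down at pluripotency exit, up at exit, WT-specific
#'   meso-endoderm induction, KO-upregulated).
#' @param stages ordered stage labels.
#' @param n_replicates biological replicates per condition and stage.
#' @param coverage_mean expected bisulfite read depth per CpG (Poisson).
#' @param rho beta-binomial overdispersion of per-CpG methylation.
#' @param nb_size negative-binomial size (1/dispersion) for expression counts.
#' @param expr_meanlog,expr_sdlog log-normal baseline expression means.
#' @param target_logfc KO-derepression effect (log2) planted on target genes
#'   at and after their timing stage.
#' @param n_tfs,n_direct_tfs,edges_per_tf TF-network geometry. Direct TFs are
#'   drawn from the planted target genes; the first direct TF is the planted
#'   hub (highest out-degree, the structural analogue of Sox2).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 4e6,
                       n_cpg = 12000L,
                       n_regions = 300L,
                       region_cluster_fractions = c(
                         stableLow = 0.30, stableHigh = 0.20,
                         gainMedium = 0.20, gainHigh = 0.20,
                         demethylated = 0.10
                       ),
                       ko_fail_fraction = 0.5,
                       n_genes = 1200L,
                       n_deg_per_cluster = 75L,
                       stages = c("ESC", "EpiLC", "ME24", "ME48"),
                       n_replicates = 2L,
                       coverage_mean = 15,
                       rho = 0.02,
                       nb_size = 100,
                       expr_meanlog = log(150),
                       expr_sdlog = 1,
                       target_logfc = 4,
                       n_tfs = 30L,
                       n_direct_tfs = 3L,
                       edges_per_tf = 40L) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp, n_cpg = as.integer(n_cpg),
    n_regions = as.integer(n_regions),
    region_cluster_fractions = region_cluster_fractions,
    ko_fail_fraction = ko_fail_fraction, n_genes = as.integer(n_genes),
    n_deg_per_cluster = as.integer(n_deg_per_cluster), stages = stages,
    n_replicates = as.integer(n_replicates), coverage_mean = coverage_mean,
    rho = rho, nb_size = nb_size, expr_meanlog = expr_meanlog,
    expr_sdlog = expr_sdlog, target_logfc = target_logfc,
    n_tfs = as.integer(n_tfs), n_direct_tfs = as.integer(n_direct_tfs),
    edges_per_tf = as.integer(edges_per_tf)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- cfg$region_cluster_fractions
  need <- c("stableLow", "stableHigh", "gainMedium", "gainHigh", "demethylated")
  if (!setequal(names(fr), need))
    stop("region_cluster_fractions must be named over: ",
         paste(need, collapse = ", "))
  if (abs(sum(fr) - 1) > 1e-8) stop("region_cluster_fractions must sum to 1")
  if (cfg$ko_fail_fraction < 0 || cfg$ko_fail_fraction > 1)
    stop("ko_fail_fraction must be in [0,1]")
  if (length(cfg$stages) < 2) stop("need at least two ordered stages")
  if (anyDuplicated(cfg$stages)) stop("stages must be unique")
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1")
  if (cfg$coverage_mean <= 0) stop("coverage_mean must be positive")
  if (cfg$rho <= 0 || cfg$rho >= 1) stop("rho must be in (0,1)")
  if (cfg$n_direct_tfs > cfg$n_tfs) stop("n_direct_tfs must be <= n_tfs")
  if (cfg$seed >= 2^31 || cfg$seed < 0) stop("seed must be a 31-bit integer")
  invisible(cfg)
}

#' DMR-calling configuration
#'
#' Houses the thresholds of the differential-methylation stage: per-CpG call
#' thresholds, region segmentation parameters, coverage filters and the tile
#' width used for genome-wide summaries. Defaults follow the published
#' analysis: per-CpG delta 0.1 at p 0.001; region delta 0.2 at p 0.05 with at
#' least 5 CpGs merged across gaps up to 100 bp; smoothing window 500 bp;
#' CpGs kept at >= 5x and regions at >= 10x mean coverage in every sample;
#' 400 bp tiles. All thresholds are inclusive.
#'
#' @param delta_site,p_site per-CpG methylation-difference and p thresholds.
#' @param delta_region,p_region region-level thresholds.
#' @param min_cg minimum candidate CpGs per region.
#' @param dis_merge maximum gap (bp) between candidate CpGs within a region.
#' @param smoothing_span boxcar smoothing window width (bp).
#' @param cpg_min_cov,dmr_min_cov coverage filters (x).
#' @param tile_bp tile width for genome-wide methylation summaries.
#' @return A list of class `dmr_call_config`.
#' @export
dmr_call_config <- function(delta_site = 0.1, p_site = 0.001,
                            delta_region = 0.2, p_region = 0.05,
                            min_cg = 5L, dis_merge = 100L,
                            smoothing_span = 500L,
                            cpg_min_cov = 5L, dmr_min_cov = 10L,
                            tile_bp = 400L) {
  cfg <- list(delta_site = delta_site, p_site = p_site,
              delta_region = delta_region, p_region = p_region,
              min_cg = as.integer(min_cg), dis_merge = as.integer(dis_merge),
              smoothing_span = as.integer(smoothing_span),
              cpg_min_cov = as.integer(cpg_min_cov),
              dmr_min_cov = as.integer(dmr_min_cov),
              tile_bp = as.integer(tile_bp))
  stopifnot(cfg$delta_site > 0, cfg$delta_site < 1,
            cfg$delta_region > 0, cfg$delta_region < 1,
            cfg$p_site > 0, cfg$p_region > 0, cfg$min_cg >= 1,
            cfg$dis_merge >= 1, cfg$smoothing_span >= 1,
            cfg$cpg_min_cov >= 1, cfg$dmr_min_cov >= 1, cfg$tile_bp >= 1)
  structure(cfg, class = "dmr_call_config")
}

## Differential-expression threshold classes (|log2FC|, BH-FDR), inclusive.
DEG_THRESHOLDS <- list(
  timecourse = c(lfc = 1.5, fdr = 0.001),
  pairwise   = c(lfc = 1.0, fdr = 0.05),
  rescue     = c(lfc = 0.5, fdr = 0.05)
)

#' Full analysis configuration
#'
#' Bundles every numeric parameter of the pipeline in one serialisable,
#' human-readable object; `run_pipeline()` writes the resolved configuration
#' (plus its hash) next to its outputs so any run can be reproduced exactly.
#'
#' @param sim a [sim_config()].
#' @param dmr a [dmr_call_config()].
#' @param deg_thresholds named list of `c(lfc=, fdr=)` threshold classes.
#' @param association_window_kb TSS association window for target calling.
#' @param stitch_bp enhancer stitching distance.
#' @param tss_exclusion_bp promoter-proximal exclusion around TSS for
#'   enhancer stitching.
#' @param promoter_window_bp promoter half-window around the TSS.
#' @param top_percentile out-degree percentile flagged in network ranking.
#' @param n_samplings randomisations for annotation enrichment.
#' @param dmr_k,expr_k cluster counts for region dynamics and expression
#'   profiles.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(sim = sim_config(),
                            dmr = dmr_call_config(),
                            deg_thresholds = DEG_THRESHOLDS,
                            association_window_kb = 100,
                            stitch_bp = 12500L,
                            tss_exclusion_bp = 2500L,
                            promoter_window_bp = 2000L,
                            top_percentile = 1,
                            n_samplings = 1000L,
                            dmr_k = 3L,
                            expr_k = 4L) {
  cfg <- list(sim = sim, dmr = dmr, deg_thresholds = deg_thresholds,
              association_window_kb = association_window_kb,
              stitch_bp = as.integer(stitch_bp),
              tss_exclusion_bp = as.integer(tss_exclusion_bp),
              promoter_window_bp = as.integer(promoter_window_bp),
              top_percentile = top_percentile,
              n_samplings = as.integer(n_samplings),
              dmr_k = as.integer(dmr_k), expr_k = as.integer(expr_k),
              version = as.character(utils::packageVersion("epiprime")))
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("epiprime analysis configuration (v", x$version, ")\n", sep = "")
  cat("  seed:", x$sim$seed, " stages:", paste(x$sim$stages, collapse = " > "),
      "\n")
  cat("  DMR: delta", x$dmr$delta_region, "p", x$dmr$p_region,
      "minCG", x$dmr$min_cg, "dis.merge", x$dmr$dis_merge, "bp\n")
  cat("  DEG classes:",
      paste(names(x$deg_thresholds), collapse = ", "), "\n")
  cat("  association window:", x$association_window_kb, "kb;",
      "top percentile:", x$top_percentile, "%\n")
  invisible(x)
}
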