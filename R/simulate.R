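## Synthetic multi-omics generator with planted ground truth.
##
## Emulates the statistical structure of a WT vs de-novo-methyltransferase
## knockout (KO) differentiation time course (ESC -> EpiLC -> ME24 -> ME48):
## stage-wise global methylation gain, a KO that fails to gain methylation at
## a planted subset of regions, expression archetypes with stage-specific
## induction plus KO-derepressed target genes reverted in a rescue arm,
## enhancer peaks with a heavy-tailed super-enhancer signal component, and a
## TF-target edge catalogue with a planted high-out-degree direct TF.
## All stage means are generator conventions chosen to be realistic for this
## system, not published values.

CPG_PER_REGION <- 10L
CPG_SPACING <- 40L
REGION_GAP <- 2400L
REGION_ZONE_START <- 10000L

REGION_LABELS <- c("stableLow", "stableHigh", "gainMedium", "gainHigh",
                   "demethylated")

## stage-mean lookup: ESC value then post-ESC plateau
region_stage_means <- function(label, n_stages) {
  base <- switch(label,
    stableLow    = c(0.10, 0.10),
    stableHigh   = c(0.85, 0.85),
    gainMedium   = c(0.10, 0.70),
    gainHigh     = c(0.10, 0.90),
    demethylated = c(0.80, 0.20),
    background   = c(0.70, 0.70)
  )
  c(base[1], rep(base[2], n_stages - 1L))
}

## deterministic genome layout: planted regions + background CpG grid
sim_layout <- function(cfg) {
  n_per_chrom <- diff(round(seq(0, cfg$n_regions,
                                length.out = cfg$n_chromosomes + 1)))
  regions <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(c) {
    n <- n_per_chrom[c]
    if (n == 0) return(NULL)
    starts <- REGION_ZONE_START + (seq_len(n) - 1L) * REGION_GAP
    data.frame(chrom = paste0("chr", c), start = starts,
               end = starts + (CPG_PER_REGION - 1L) * CPG_SPACING + 2L,
               stringsAsFactors = FALSE)
  }))
  regions$region_id <- sprintf("region%04d", seq_len(nrow(regions)))
  ## dynamics labels in fixed proportions, interleaved for spatial balance
  fr <- cfg$region_cluster_fractions[REGION_LABELS]
  counts <- diff(round(cumsum(c(0, fr)) * nrow(regions)))
  labels <- rep(REGION_LABELS, counts)
  length(labels) <- nrow(regions)
  labels[is.na(labels)] <- "stableLow"
  regions$label <- labels[order(seq_along(labels) %% 5, seq_along(labels))]
  ## KO failure planted on a deterministic subset of gain regions
  gain <- which(regions$label %in% c("gainMedium", "gainHigh"))
  n_fail <- round(cfg$ko_fail_fraction * length(gain))
  regions$ko_hypo <- FALSE
  if (n_fail > 0)
    regions$ko_hypo[gain[seq(1, length(gain), length.out = n_fail)]] <- TRUE

  ## CpG grid: region CpGs + evenly spaced background CpGs per chromosome
  cpg_list <- lapply(seq_len(nrow(regions)), function(i) {
    data.frame(chrom = regions$chrom[i],
               pos = regions$start[i] + (seq_len(CPG_PER_REGION) - 1L) *
                 CPG_SPACING,
               region_id = regions$region_id[i], stringsAsFactors = FALSE)
  })
  n_bg <- max(cfg$n_cpg - nrow(regions) * CPG_PER_REGION, 0L)
  if (n_bg > 0) {
    bg_per_chrom <- diff(round(seq(0, n_bg, length.out = cfg$n_chromosomes + 1)))
    zone_end <- vapply(seq_len(cfg$n_chromosomes), function(c) {
      r <- regions[regions$chrom == paste0("chr", c), ]
      if (nrow(r)) max(r$end) else REGION_ZONE_START
    }, numeric(1))
    cpg_list <- c(cpg_list, lapply(seq_len(cfg$n_chromosomes), function(c) {
      n <- bg_per_chrom[c]
      if (n == 0) return(NULL)
      lo <- zone_end[c] + 5000
      hi <- cfg$chrom_length_bp - 1000
      data.frame(chrom = paste0("chr", c),
                 pos = round(seq(lo, hi, length.out = n)),
                 region_id = NA_character_, stringsAsFactors = FALSE)
    }))
  }
  cpgs <- do.call(rbind, cpg_list)
  cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), ]
  rownames(cpgs) <- NULL
  list(regions = regions, cpgs = cpgs)
}

#' Simulate a WT/KO bisulfite methylome time course
#'
#' Per-CpG methylated counts are beta-binomial around the region's
#' stage/condition mean (overdispersion `cfg$rho`), with Poisson coverage.
#' Regions planted as KO-failing keep their ESC-level mean in the KO at every
#' stage; all other regions share WT means across conditions.
#'
#' @param cfg a [sim_config()].
#' @return A list with `cpg` (a `cpg_table`: chrom/pos vectors, `meth` and
#'   `total` count matrices with one column per sample, and a `samples`
#'   data frame) and `truth` (the planted region table).
#' @export
simulate_methylome <- function(cfg) {
  validate_sim_config(cfg)
  lay <- sim_layout(cfg)
  n_stages <- length(cfg$stages)
  labels <- c(lay$regions$label[match(lay$cpgs$region_id,
                                      lay$regions$region_id)])
  labels[is.na(labels)] <- "background"
  ko_hypo_cpg <- lay$regions$ko_hypo[match(lay$cpgs$region_id,
                                           lay$regions$region_id)]
  ko_hypo_cpg[is.na(ko_hypo_cpg)] <- FALSE

  mean_tbl <- vapply(unique(labels), region_stage_means,
                     numeric(n_stages), n_stages = n_stages)
  samples <- expand.grid(replicate = seq_len(cfg$n_replicates),
                         stage = cfg$stages, condition = c("WT", "KO"),
                         stringsAsFactors = FALSE)
  samples <- samples[, c("condition", "stage", "replicate")]
  samples$sample <- with(samples, paste(condition, stage, replicate, sep = "_"))

  n_cpg <- nrow(lay$cpgs)
  a_scale <- (1 - cfg$rho) / cfg$rho
  meth <- total <- matrix(0L, n_cpg, nrow(samples),
                          dimnames = list(NULL, samples$sample))
  with_seed(derive_seed(cfg$seed, "methylome"), {
    for (j in seq_len(nrow(samples))) {
      st <- match(samples$stage[j], cfg$stages)
      mu <- mean_tbl[st, match(labels, colnames(mean_tbl))]
      if (samples$condition[j] == "KO" && any(ko_hypo_cpg)) {
        esc <- mean_tbl[1L, match(labels, colnames(mean_tbl))]
        mu[ko_hypo_cpg] <- esc[ko_hypo_cpg]
      }
      cov <- rpois(n_cpg, cfg$coverage_mean)
      p <- rbeta(n_cpg, mu * a_scale, (1 - mu) * a_scale)
      meth[, j] <- rbinom(n_cpg, cov, p)
      total[, j] <- cov
    }
  })
  cpg <- structure(list(chrom = lay$cpgs$chrom, pos = lay$cpgs$pos,
                        region_id = lay$cpgs$region_id,
                        meth = meth, total = total, samples = samples),
                   class = "cpg_table")
  list(cpg = cpg, truth = lay$regions)
}

## KO-vs-WT log2 expression offsets per stage for a target gene, by timing.
## Effects persist after onset (priming-style derepression); the maximum
## always falls on the nominal timing stage.
target_offsets <- function(timing, L, n_stages) {
  off <- switch(timing,
    early  = c(0, L, L - 1, L - 1.5),
    medium = c(0, 0.5, L, L - 1),
    late   = c(0, 0, 1, L + 0.5)
  )
  off[seq_len(n_stages)]
}

## archetype offsets (log2, relative to baseline) per condition
archetype_offsets <- function(cluster, condition, n_stages) {
  wt <- switch(cluster,
    I   = c(2, 0, 0, 0),
    II  = c(0, 2, 2.5, 2.5),
    III = c(0, 0.5, 2.5, 3),
    IV  = c(0, 0, 0, 0)
  )
  ko <- switch(cluster,
    I   = wt, II = wt,
    III = c(0, 0.5, 0.5, 0.5),
    IV  = c(3, 3, 3, 3)
  )
  (if (condition == "WT") wt else ko)[seq_len(n_stages)]
}

#' Simulate the expression time course with a KO rescue arm
#'
#' Negative-binomial counts for four conditions (WT, KO, KO with the
#' methyltransferase re-expressed `KO_3B`, KO with empty vector `KO_empty`)
#' across the configured stages. Four expression archetypes are planted
#' (down at pluripotency exit; up at exit; WT-specific meso-endoderm
#' induction impaired in KO; constitutively KO-upregulated), plus one planted
#' target gene per KO-failing methylation region: silent in WT, derepressed
#' in KO from its timing stage onward, and reverted by the rescue. Target
#' gene TSSs are placed within the association window of their region; all
#' other genes are placed far (> 110 kb) from every planted region.
#'
#' @param cfg a [sim_config()].
#' @param gt the `truth` region table from [simulate_methylome()].
#' @return A list with `expr` (an `expr_set`: counts matrix, samples data
#'   frame, gene model with TSS/length) and `truth` (per-gene ground truth).
#' @export
simulate_expression <- function(cfg, gt) {
  n_stages <- length(cfg$stages)
  hypo <- gt[gt$ko_hypo, , drop = FALSE]
  n_targets <- nrow(hypo)
  n_arch <- 4L * cfg$n_deg_per_cluster
  if (n_targets + n_arch > cfg$n_genes)
    stop("n_genes too small for the planted archetypes and target genes")

  genes <- data.frame(gene = sprintf("g%04d", seq_len(cfg$n_genes)),
                      stringsAsFactors = FALSE)
  genes$deg_cluster <- NA_character_
  if (cfg$n_deg_per_cluster > 0)
    genes$deg_cluster[seq_len(n_arch)] <-
      rep(c("I", "II", "III", "IV"), each = cfg$n_deg_per_cluster)
  genes$is_target <- FALSE
  genes$region_id <- NA_character_
  genes$timing <- NA_character_
  if (n_targets > 0) {
    idx <- n_arch + seq_len(n_targets)
    genes$is_target[idx] <- TRUE
    genes$region_id[idx] <- hypo$region_id
    genes$timing[idx] <- rep_len(c("early", "medium", "late"), n_targets)
  }

  with_seed(derive_seed(cfg$seed, "expression"), {
    ## gene model geometry
    genes$chrom <- NA_character_
    genes$tss <- NA_real_
    if (n_targets > 0) {
      idx <- which(genes$is_target)
      mid <- (hypo$start + hypo$end) / 2
      genes$chrom[idx] <- hypo$chrom
      genes$tss[idx] <- pmax(1000, pmin(cfg$chrom_length_bp - 1000,
                                        round(mid + runif(n_targets, -5e4, 5e4))))
    }
    other <- which(!genes$is_target)
    zone_start <- vapply(paste0("chr", seq_len(cfg$n_chromosomes)),
                         function(ch) {
      r <- gt[gt$chrom == ch, ]
      (if (nrow(r)) max(r$end) else REGION_ZONE_START) + 120000
    }, numeric(1))
    chrom_of <- rep_len(paste0("chr", seq_len(cfg$n_chromosomes)),
                        length(other))
    genes$chrom[other] <- chrom_of
    for (ch in unique(chrom_of)) {
      sel <- other[chrom_of == ch]
      genes$tss[sel] <- round(seq(zone_start[ch], cfg$chrom_length_bp - 5000,
                                  length.out = length(sel)))
    }
    genes$strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    genes$length <- round(exp(rnorm(cfg$n_genes, log(2000), 0.4)))
    baseline <- exp(rnorm(cfg$n_genes, cfg$expr_meanlog, cfg$expr_sdlog))

    samples <- expand.grid(replicate = seq_len(cfg$n_replicates),
                           stage = cfg$stages,
                           condition = c("WT", "KO", "KO_3B", "KO_empty"),
                           stringsAsFactors = FALSE)
    samples <- samples[, c("condition", "stage", "replicate")]
    samples$sample <- with(samples,
                           paste(condition, stage, replicate, sep = "_"))

    counts <- matrix(0L, cfg$n_genes, nrow(samples),
                     dimnames = list(genes$gene, samples$sample))
    for (j in seq_len(nrow(samples))) {
      st <- match(samples$stage[j], cfg$stages)
      cond <- samples$condition[j]
      off <- numeric(cfg$n_genes)
      for (cl in c("I", "II", "III", "IV")) {
        sel <- which(genes$deg_cluster %in% cl)
        ## re-expression restores the WT program: the rescue arm reverts the
        ## KO-dependent archetypes as well as the planted targets
        if (length(sel))
          off[sel] <- archetype_offsets(
            cl, if (cond %in% c("WT", "KO_3B")) "WT" else "KO", n_stages)[st]
      }
      if (n_targets > 0) {
        tsel <- which(genes$is_target)
        if (cond %in% c("KO", "KO_empty")) {
          off[tsel] <- vapply(genes$timing[tsel], function(tm)
            target_offsets(tm, cfg$target_logfc, n_stages)[st], numeric(1))
        } ## WT and KO_3B (rescued): silent baseline
      }
      mu <- baseline * 2^off
      counts[, j] <- rnbinom(cfg$n_genes, mu = mu, size = cfg$nb_size)
    }
  })
  expr <- structure(list(counts = counts, samples = samples,
                         gene_model = genes[, c("gene", "chrom", "tss",
                                                "strand", "length")]),
                    class = "expr_set")
  list(expr = expr, truth = genes)
}

#' Simulate enhancer peaks and a TF-target edge catalogue
#'
#' Peaks cover every planted gain/demethylated region (so KO-failing regions
#' overlap an active regulatory region by construction) plus background
#' intervals; signal is log-normal with a Pareto-tailed super-enhancer
#' component on a small subset. Two edge sources are produced: a curated-style
#' list (source A) and an evidence-labelled list (source B, classes
#' `coexpression`/`chipseq`). Planted edges are routed so that the
#' intersection rule on source B retains them, and decoy edges occur only
#' in coexpression sets so the rule drops them. The first direct TF is the
#' planted hub: most of its edges point at KO-upregulated genes.
#'
#' @param cfg a [sim_config()].
#' @param gt list with `regions` and `genes` ground-truth tables (from the
#'   methylome and expression generators).
#' @return A list with `peaks` (BED-like with `signal` and `stage`),
#'   `edges_a`, `edges_b` (with `evidence_class` and `set` columns), and
#'   `truth` (TF table and planted-edge table with a `in_backbone` flag).
#' @export
simulate_peaks_and_network <- function(cfg, gt) {
  regions <- gt$regions
  genes <- gt$genes
  n_stages_active <- setdiff(cfg$stages, cfg$stages[1])

  with_seed(derive_seed(cfg$seed, "peaks"), {
    act <- regions[regions$label %in%
                     c("gainMedium", "gainHigh", "demethylated"), ]
    peak_list <- list()
    if (nrow(act)) {
      peak_list$planted <- data.frame(
        chrom = act$chrom, start = pmax(0, act$start - 200),
        end = act$end + 200,
        signal = exp(rnorm(nrow(act), log(10), 0.5)),
        stage = sample(n_stages_active, nrow(act), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    ## background peaks in the gene zone
    n_bg <- max(50L, round(cfg$n_regions / 3))
    bg_chrom <- paste0("chr", sample.int(cfg$n_chromosomes, n_bg,
                                         replace = TRUE))
    zone_start <- vapply(bg_chrom, function(ch) {
      r <- regions[regions$chrom == ch, ]
      (if (nrow(r)) max(r$end) else REGION_ZONE_START) + 130000
    }, numeric(1))
    bg_start <- round(runif(n_bg, zone_start, cfg$chrom_length_bp - 3000))
    peak_list$background <- data.frame(
      chrom = bg_chrom, start = bg_start,
      end = bg_start + round(runif(n_bg, 400, 1500)),
      signal = exp(rnorm(n_bg, log(8), 0.6)),
      stage = sample(n_stages_active, n_bg, replace = TRUE),
      stringsAsFactors = FALSE)
    peaks <- do.call(rbind, peak_list)
    rownames(peaks) <- NULL
    ## heavy-tailed super-enhancer component on ~4% of peaks
    n_super <- max(2L, round(0.04 * nrow(peaks)))
    sup <- sample.int(nrow(peaks), n_super)
    peaks$signal[sup] <- peaks$signal[sup] + 100 / runif(n_super)^(1 / 1.2)
    peaks <- peaks[order(peaks$chrom, peaks$start), ]
    rownames(peaks) <- NULL
  })

  ## ---- TF-target edges ----
  target_genes <- genes$gene[genes$is_target]
  ko_up <- c(target_genes, genes$gene[genes$deg_cluster %in% "IV"])
  tc_deg <- genes$gene[!is.na(genes$deg_cluster)]
  non_deg <- setdiff(genes$gene, union(tc_deg, target_genes))
  n_direct <- min(cfg$n_direct_tfs, length(target_genes))
  direct_tfs <- head(target_genes, n_direct)
  other_pool <- setdiff(tc_deg, direct_tfs)
  n_other <- min(cfg$n_tfs - n_direct, length(other_pool))

  with_seed(derive_seed(cfg$seed, "network"), {
    other_tfs <- if (n_other > 0) sample(other_pool, n_other) else character(0)
    tfs <- c(direct_tfs, other_tfs)
    edge_list <- list()
    for (i in seq_along(tfs)) {
      tf <- tfs[i]
      if (i == 1 && n_direct > 0) {      # planted hub
        n_e <- round(cfg$edges_per_tf * 1.5)
        n_deg_e <- round(0.9 * n_e)
        pool_deg <- setdiff(ko_up, tf)
      } else if (i <= n_direct) {
        n_e <- cfg$edges_per_tf
        n_deg_e <- round(0.6 * n_e)
        pool_deg <- setdiff(ko_up, tf)
      } else {
        n_e <- sample(seq(10, cfg$edges_per_tf), 1)
        n_deg_e <- round(0.4 * n_e)
        pool_deg <- setdiff(tc_deg, tf)
      }
      tgt <- c(sample(pool_deg, min(n_deg_e, length(pool_deg))),
               sample(non_deg, min(n_e - n_deg_e, length(non_deg))))
      edge_list[[tf]] <- data.frame(tf = tf, target = unique(tgt),
                                    stringsAsFactors = FALSE)
    }
    empty_edges <- data.frame(tf = character(), target = character(),
                              stringsAsFactors = FALSE)
    if (length(edge_list) > 0) {
      edges <- do.call(rbind, edge_list)
      rownames(edges) <- NULL
      ## route each planted edge through the sources
      route <- sample(c("A", "B", "AB"), nrow(edges), replace = TRUE,
                      prob = c(0.3, 0.5, 0.2))
      edges$in_backbone <- TRUE
      edges_a <- edges[route %in% c("A", "AB"), c("tf", "target")]
      b_real <- edges[route %in% c("B", "AB"), c("tf", "target")]
      edges_b <- rbind(
        transform(b_real, evidence_class = "coexpression",
                  set = "ARCHS4_Coexpression"),
        transform(b_real, evidence_class = "chipseq", set = "ReMap_ChIPseq")
      )
      ## decoys: coexpression-only edges the intersection rule must drop
      n_decoy <- max(20L, round(0.2 * nrow(edges)))
      decoy <- data.frame(tf = sample(tfs, n_decoy, replace = TRUE),
                          target = sample(genes$gene, n_decoy, replace = TRUE),
                          stringsAsFactors = FALSE)
      key <- function(d) paste(d$tf, d$target)
      decoy <- decoy[!key(decoy) %in% key(edges), , drop = FALSE]
      decoy <- decoy[!duplicated(key(decoy)), , drop = FALSE]
      edges_b <- rbind(edges_b,
                       transform(decoy, evidence_class = "coexpression",
                                 set = "GTEx_Coexpression"))
      rownames(edges_a) <- rownames(edges_b) <- NULL
    } else {
      edges <- cbind(empty_edges, in_backbone = logical(0))
      edges_a <- empty_edges
      edges_b <- cbind(empty_edges, evidence_class = character(0),
                       set = character(0))
    }
  })
  tf_truth <- data.frame(tf = tfs,
                         direct = tfs %in% direct_tfs,
                         hub = seq_along(tfs) == 1 & n_direct > 0,
                         stringsAsFactors = FALSE)
  list(peaks = peaks, edges_a = edges_a, edges_b = edges_b,
       truth = list(tfs = tf_truth, edges = edges))
}

#' Generate every pipeline input with consolidated ground truth
#'
#' @param cfg a [sim_config()].
#' @return A list with `cpg`, `expr`, `peaks`, `edges_a`, `edges_b` and
#'   `truth` (regions, genes, target_genes, ko_hypo_regions, deg_labels,
#'   direct_tfs, hub_tf, edges).
#' @export
simulate_all <- function(cfg = sim_config()) {
  met <- simulate_methylome(cfg)
  exp <- simulate_expression(cfg, met$truth)
  net <- simulate_peaks_and_network(cfg, list(regions = met$truth,
                                              genes = exp$truth))
  truth <- list(
    regions = met$truth,
    genes = exp$truth,
    ko_hypo_regions = met$truth$region_id[met$truth$ko_hypo],
    target_genes = exp$truth$gene[exp$truth$is_target],
    deg_labels = setNames(exp$truth$deg_cluster, exp$truth$gene),
    direct_tfs = net$truth$tfs$tf[net$truth$tfs$direct],
    hub_tf = if (any(net$truth$tfs$hub)) net$truth$tfs$tf[net$truth$tfs$hub]
             else NA_character_,
    edges = net$truth$edges,
    tfs = net$truth$tfs$tf
  )
  list(cpg = met$cpg, expr = exp$expr, peaks = net$peaks,
       edges_a = net$edges_a, edges_b = net$edges_b, truth = truth)
}
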