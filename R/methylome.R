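## Differential methylation: smoothing, per-CpG testing, run-based DMR
## segmentation with the published parameters, set combination, coverage
## filtering, trajectory clustering and KO-vs-WT classification.
##
## The per-CpG test is a deliberate stand-in for a beta-binomial shrinkage
## model: a coverage-weighted boxcar smoother followed by a pooled
## two-proportion z-test with continuity correction, with region p-values
## from a Stouffer combination of member-CpG z-scores. The segmentation
## layer on top uses the published thresholds verbatim and is inclusive
## (>= / <=) at every boundary.

## ---- helpers on cpg_table ----

cpg_samples <- function(cpg, condition = NULL, stage = NULL) {
  s <- cpg$samples
  keep <- rep(TRUE, nrow(s))
  if (!is.null(condition)) keep <- keep & s$condition %in% condition
  if (!is.null(stage)) keep <- keep & s$stage %in% stage
  s$sample[keep]
}

## pooled counts across a sample group
pool_counts <- function(cpg, samples) {
  j <- match(samples, colnames(cpg$meth))
  if (anyNA(j)) stop("unknown samples: ",
                     paste(samples[is.na(j)], collapse = ", "))
  list(meth = rowSums(cpg$meth[, j, drop = FALSE]),
       total = rowSums(cpg$total[, j, drop = FALSE]))
}

#' Boxcar-smooth methylation fractions
#'
#' Each CpG's value becomes the coverage-weighted mean of raw methylation
#' fractions over all CpGs within +/- `span_bp/2`, computed independently per
#' chromosome. The CpG itself is always in its own window, so values are
#' defined wherever total coverage is positive.
#'
#' @param chrom,pos CpG coordinates (0-based, sorted within chromosome).
#' @param meth,total methylated and total counts (vectors or single-column).
#' @param span_bp full window width in bp (default 500).
#' @return Numeric vector of smoothed fractions in `[0,1]` (NA where the
#'   window has zero coverage).
#' @export
smooth_methylation <- function(chrom, pos, meth, total, span_bp = 500) {
  stopifnot(length(chrom) == length(pos), length(meth) == length(pos),
            length(total) == length(pos))
  h <- span_bp / 2
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    p <- pos[i]
    if (is.unsorted(p)) stop("positions must be sorted within chromosome")
    cm <- cumsum(as.numeric(meth[i]))
    ct <- cumsum(as.numeric(total[i]))
    lo <- findInterval(p - h - 0.5, p) + 1L
    hi <- findInterval(p + h + 0.5, p)
    wm <- cm[hi] - c(0, cm)[lo]
    wt <- ct[hi] - c(0, ct)[lo]
    out[i] <- ifelse(wt > 0, wm / wt, NA_real_)
  }
  out
}

#' Per-CpG differential methylation between two sample groups
#'
#' Replicate counts are pooled within each group, smoothed with
#' [smooth_methylation()], and compared with a two-proportion z-test with
#' continuity correction on the pooled totals. A CpG is a candidate iff
#' `|diff| >= delta_site` and `p <= p_site`. CpGs with zero pooled coverage
#' in either group are excluded (count reported in the `n_excluded`
#' attribute).
#'
#' @param cpg a `cpg_table`.
#' @param samples_a,samples_b sample names of the two groups.
#' @param cfg a [dmr_call_config()].
#' @return Data frame (chrom, pos, meth_a, meth_b, diff, z, p, candidate),
#'   `diff = meth_a - meth_b` on smoothed fractions.
#' @export
test_cpg_differential <- function(cpg, samples_a, samples_b,
                                  cfg = dmr_call_config()) {
  a <- pool_counts(cpg, samples_a)
  b <- pool_counts(cpg, samples_b)
  keep <- a$total > 0 & b$total > 0
  n_excluded <- sum(!keep)
  chrom <- cpg$chrom[keep]; pos <- cpg$pos[keep]
  pa <- smooth_methylation(chrom, pos, a$meth[keep], a$total[keep],
                           cfg$smoothing_span)
  pb <- smooth_methylation(chrom, pos, b$meth[keep], b$total[keep],
                           cfg$smoothing_span)
  na <- a$total[keep]; nb <- b$total[keep]
  d <- pa - pb
  pbar <- (pa * na + pb * nb) / (na + nb)
  se <- sqrt(pbar * (1 - pbar) * (1 / na + 1 / nb))
  cc <- 0.5 * (1 / na + 1 / nb)
  z <- ifelse(se > 0, sign(d) * pmax(abs(d) - cc, 0) / se, 0)
  p <- 2 * pnorm(-abs(z))
  res <- data.frame(chrom = chrom, pos = pos, meth_a = pa, meth_b = pb,
                    diff = d, z = z, p = p,
                    candidate = abs(d) >= cfg$delta_site & p <= cfg$p_site,
                    stringsAsFactors = FALSE)
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Segment candidate CpGs into differentially methylated regions
#'
#' Candidate CpGs are grouped into maximal same-sign runs whose consecutive
#' gaps are at most `dis_merge` bp (within one chromosome). A run becomes a
#' DMR iff it has at least `min_cg` CpGs, its mean CpG difference satisfies
#' `|mean diff| >= delta_region`, and its Stouffer-combined p-value satisfies
#' `p <= p_region`. Intervals are 0-based half-open, spanning the first to
#' last member CpG.
#'
#' @param cpg_stats output of [test_cpg_differential()].
#' @param cfg a [dmr_call_config()].
#' @return Data frame (chrom, start, end, n_cpg, mean_diff, stat, p,
#'   direction) with `direction` `"hyper"` when group A exceeds group B.
#' @export
segment_dmrs <- function(cpg_stats, cfg = dmr_call_config()) {
  cand <- cpg_stats[cpg_stats$candidate, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(),
                      mean_diff = numeric(), stat = numeric(), p = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  if (nrow(cand) == 0) return(empty)
  o <- order(cand$chrom, cand$pos)
  cand <- cand[o, ]
  new_run <- c(TRUE,
               cand$chrom[-1] != cand$chrom[-nrow(cand)] |
                 diff(cand$pos) > cfg$dis_merge |
                 sign(cand$diff[-1]) != sign(cand$diff[-nrow(cand)]))
  run <- cumsum(new_run)
  agg <- function(f, x) as.vector(tapply(x, run, f))
  res <- data.frame(
    chrom = as.vector(tapply(cand$chrom, run, `[`, 1)),
    start = agg(min, cand$pos),
    end = agg(max, cand$pos) + 1L,
    n_cpg = as.vector(table(run)),
    mean_diff = agg(mean, cand$diff),
    stat = agg(function(z) sum(z) / sqrt(length(z)), cand$z),
    stringsAsFactors = FALSE)
  res$p <- 2 * pnorm(-abs(res$stat))
  res$direction <- ifelse(res$mean_diff > 0, "hyper", "hypo")
  keep <- res$n_cpg >= cfg$min_cg &
    abs(res$mean_diff) >= cfg$delta_region & res$p <= cfg$p_region
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call DMRs between two sample groups
#'
#' Convenience wrapper: per-CpG differential test then segmentation.
#'
#' @inheritParams test_cpg_differential
#' @param comparison label recorded in the `source_comparisons` column.
#' @return DMR data frame as from [segment_dmrs()] plus `source_comparisons`.
#' @export
call_dmrs <- function(cpg, samples_a, samples_b, cfg = dmr_call_config(),
                      comparison = "A_vs_B") {
  dmrs <- segment_dmrs(test_cpg_differential(cpg, samples_a, samples_b, cfg),
                       cfg)
  if (nrow(dmrs)) dmrs$source_comparisons <- comparison
  else dmrs$source_comparisons <- character(0)
  dmrs
}

#' Combine DMR sets, collapsing overlapping regions
#'
#' Takes the interval union of several DMR lists: regions sharing at least
#' one bp (half-open coordinates) are replaced by their span, and the
#' `source_comparisons` labels of merged members are unioned. Idempotent and
#' order-independent.
#'
#' @param dmr_lists a list of DMR data frames (each with chrom/start/end and
#'   optionally `source_comparisons`).
#' @return Combined DMR data frame (chrom, start, end, n_sources,
#'   source_comparisons).
#' @export
combine_dmr_sets <- function(dmr_lists) {
  if (is.data.frame(dmr_lists)) dmr_lists <- list(dmr_lists)
  dmr_lists <- Filter(function(d) nrow(d) > 0, dmr_lists)
  if (length(dmr_lists) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sources = integer(),
                      source_comparisons = character(),
                      stringsAsFactors = FALSE))
  all <- do.call(rbind, lapply(dmr_lists, function(d) {
    data.frame(chrom = d$chrom, start = d$start, end = d$end,
               source_comparisons =
                 if ("source_comparisons" %in% names(d)) d$source_comparisons
                 else NA_character_,
               stringsAsFactors = FALSE)
  }))
  gr <- as_gr(all)
  ## min.gapwidth = 0: only intervals sharing >= 1 bp collapse; abutting
  ## intervals stay distinct
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  src <- tapply(all$source_comparisons[S4Vectors::queryHits(hit)],
                S4Vectors::subjectHits(hit), function(s)
                  paste(sort(unique(s[!is.na(s)])), collapse = ","))
  out <- gr_to_df(red)
  out$n_sources <- as.vector(table(factor(S4Vectors::subjectHits(hit),
                                          levels = seq_along(red))))
  out$source_comparisons <- as.vector(src[as.character(seq_along(red))])
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

## eligible CpGs: coverage >= cpg_min_cov in every sample of interest
eligible_cpgs <- function(cpg, cfg, samples = colnames(cpg$total)) {
  j <- match(samples, colnames(cpg$total))
  rowSums(cpg$total[, j, drop = FALSE] >= cfg$cpg_min_cov) == length(j)
}

#' Coverage-filter a DMR set
#'
#' Drops CpGs with coverage below `cpg_min_cov` in any sample before region
#' averaging, then removes DMRs whose mean coverage over the remaining CpGs
#' is below `dmr_min_cov` in any sample. DMRs left with no eligible CpGs are
#' removed (count in the `n_empty` attribute).
#'
#' @param dmrs DMR data frame.
#' @param cpg a `cpg_table` covering all samples to be enforced.
#' @param cfg a [dmr_call_config()].
#' @param samples samples whose coverage is enforced (default all).
#' @return Filtered DMR data frame with an `n_cpg_eligible` column.
#' @export
filter_by_coverage <- function(dmrs, cpg, cfg = dmr_call_config(),
                               samples = colnames(cpg$total)) {
  if (nrow(dmrs) == 0) return(dmrs)
  ok <- eligible_cpgs(cpg, cfg, samples)
  cg <- GenomicRanges::GRanges(cpg$chrom,
                               IRanges::IRanges(cpg$pos + 1L, cpg$pos + 1L))
  hit <- GenomicRanges::findOverlaps(cg, as_gr(dmrs))
  qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
  use <- ok[qh]
  qh <- qh[use]; sh <- sh[use]
  n_elig <- as.vector(table(factor(sh, levels = seq_len(nrow(dmrs)))))
  j <- match(samples, colnames(cpg$total))
  mean_cov <- sapply(j, function(col)
    as.vector(tapply(cpg$total[qh, col], factor(sh, levels = seq_len(nrow(dmrs))),
                     mean)))
  if (is.null(dim(mean_cov))) mean_cov <- matrix(mean_cov, nrow = nrow(dmrs))
  covered <- n_elig > 0 &
    apply(mean_cov >= cfg$dmr_min_cov, 1, function(r) all(r %in% TRUE))
  out <- dmrs[covered, , drop = FALSE]
  out$n_cpg_eligible <- n_elig[covered]
  attr(out, "n_empty") <- sum(n_elig == 0)
  rownames(out) <- NULL
  out
}

#' Per-DMR mean methylation by sample group
#'
#' Pools eligible-CpG counts within each group over the region:
#' `100 * sum(meth) / sum(total)`.
#'
#' @param dmrs DMR data frame.
#' @param cpg a `cpg_table`.
#' @param groups named list mapping group label to sample names.
#' @param cfg a [dmr_call_config()] (for the CpG coverage filter).
#' @return Matrix (DMR x group) of methylation percentages.
#' @export
dmr_methylation <- function(dmrs, cpg, groups, cfg = dmr_call_config()) {
  ok <- eligible_cpgs(cpg, cfg, unique(unlist(groups)))
  cg <- GenomicRanges::GRanges(cpg$chrom,
                               IRanges::IRanges(cpg$pos + 1L, cpg$pos + 1L))
  hit <- GenomicRanges::findOverlaps(cg, as_gr(dmrs))
  qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
  use <- ok[qh]; qh <- qh[use]; sh <- sh[use]
  f <- factor(sh, levels = seq_len(nrow(dmrs)))
  out <- sapply(groups, function(smp) {
    j <- match(smp, colnames(cpg$meth))
    m <- rowSums(cpg$meth[qh, j, drop = FALSE])
    t <- rowSums(cpg$total[qh, j, drop = FALSE])
    100 * as.vector(tapply(m, f, sum)) / as.vector(tapply(t, f, sum))
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(dmrs),
                                       dimnames = list(NULL, names(groups)))
  rownames(out) <- NULL
  out
}

#' K-means clustering of DMR methylation trajectories
#'
#' Stage columns are standardised (R's `scale`, i.e. per-stage across
#' regions) before clustering; k-means runs with 100 restarts under a fixed
#' seed. Clusters are reported with their unscaled mean trajectories and
#' relabelled by post-ESC methylation gain so that, at k = 3, cluster I is
#' the medium-gain, cluster II the high-gain and cluster III the
#' demethylated dynamic: clusters gaining methylation are ordered by
#' ascending gain first, then losing clusters by descending gain.
#'
#' @param traj matrix (regions x stages) of methylation levels.
#' @param k number of clusters.
#' @param seed RNG seed for the restarts.
#' @param nstart,iter_max k-means control.
#' @return List with `labels` (cluster per region, `"clusterI"`... in gain
#'   order), `centers` (unscaled mean trajectories), `withinss`, and `order`.
#' @export
cluster_dmr_trajectories <- function(traj, k, seed = 1L, nstart = 100,
                                     iter_max = 100) {
  traj <- as.matrix(traj)
  if (k > nrow(traj)) stop("k exceeds the number of regions")
  sds <- apply(traj, 2, sd)
  scaled <- scale(traj, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  km <- with_seed(seed, kmeans(scaled, centers = k, nstart = nstart,
                               iter.max = iter_max))
  centers <- do.call(rbind, lapply(seq_len(k), function(i)
    colMeans(traj[km$cluster == i, , drop = FALSE])))
  gain <- centers[, 2L] - centers[, 1L]
  if (ncol(traj) < 2) gain <- rep(0, k)
  ord <- c(which(gain >= 0)[order(gain[gain >= 0])],
           which(gain < 0)[order(-gain[gain < 0])])
  lab <- paste0("cluster", as.character(utils::as.roman(seq_len(k))))
  labels <- lab[match(km$cluster, ord)]
  list(labels = labels, centers = centers[ord, , drop = FALSE],
       withinss = sum(km$withinss), order = ord)
}

#' Classify KO-vs-WT DMRs against the WT differentiation dynamics
#'
#' Each KO-vs-WT DMR is labelled with the dynamics cluster of the WT
#' time-course DMR it overlaps (largest bp overlap when several), or
#' `"stable_in_WT"` when it overlaps none; direction is `"hypo"` iff the KO
#' mean methylation over the region is below the WT mean.
#'
#' @param ko_dmrs KO-vs-WT DMR data frame.
#' @param wt_dmrs WT time-course DMR data frame with a `cluster` column.
#' @param ko_mean,wt_mean per-DMR mean methylation (%) of `ko_dmrs` in KO and
#'   WT samples.
#' @return `ko_dmrs` with `wt_cluster` and `direction` columns.
#' @export
classify_ko_dmrs <- function(ko_dmrs, wt_dmrs, ko_mean, wt_mean) {
  stopifnot(length(ko_mean) == nrow(ko_dmrs),
            length(wt_mean) == nrow(ko_dmrs))
  out <- ko_dmrs
  out$wt_cluster <- "stable_in_WT"
  if (nrow(wt_dmrs) > 0 && nrow(ko_dmrs) > 0) {
    hit <- GenomicRanges::findOverlaps(as_gr(ko_dmrs), as_gr(wt_dmrs))
    if (length(hit)) {
      qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
      w <- GenomicRanges::width(IRanges::pintersect(
        as_gr(ko_dmrs)[qh], as_gr(wt_dmrs)[sh]))
      best <- tapply(seq_along(qh), qh, function(i) i[which.max(w[i])])
      out$wt_cluster[as.integer(names(best))] <-
        wt_dmrs$cluster[sh[unlist(best)]]
    }
  }
  out$direction <- ifelse(ko_mean < wt_mean, "hypo", "hyper")
  out
}

#' Overlap fraction between two interval sets
#'
#' @param set_a,set_b data frames with chrom/start/end (0-based half-open).
#' @return List with `fraction` (share of `set_a` intervals overlapping at
#'   least 1 bp of `set_b`) and `shared` (the overlapping subset of `set_a`).
#' @export
compare_dmr_sets <- function(set_a, set_b) {
  if (nrow(set_a) == 0) return(list(fraction = NaN, shared = set_a))
  if (nrow(set_b) == 0)
    return(list(fraction = 0, shared = set_a[0, , drop = FALSE]))
  n <- GenomicRanges::countOverlaps(as_gr(set_a), as_gr(set_b))
  list(fraction = mean(n > 0), shared = set_a[n > 0, , drop = FALSE])
}

#' Tile a genome into fixed-width windows
#'
#' Produces an exact partition of each chromosome: non-overlapping, gap-free
#' tiles of `tile_bp` (the last tile is truncated at the chromosome end).
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param tile_bp tile width.
#' @return Data frame (chrom, start, end), 0-based half-open.
#' @export
tile_genome <- function(chrom_lengths, tile_bp = 400L) {
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0L, L - 1L, by = tile_bp)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + tile_bp, L), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
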