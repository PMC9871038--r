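## Regulatory-region annotation: enhancer stitching and rank-elbow
## super-enhancer calling, promoter definition, DMR overlap flags,
## randomisation-based annotation enrichment, and region-to-gene
## association rules.

#' Stitch peaks and call typical/super enhancers by rank-curve elbow
#'
#' Peaks within `stitch_bp` of each other are merged (signal summed);
#' optionally peaks lying wholly within `tss_exclusion` bp of a TSS are
#' removed first. Stitched regions are ranked by signal; with both axes
#' scaled to the unit square, the cutoff sits where the tangent to the
#' signal-vs-rank curve has slope 1 (the point of largest vertical gap below
#' the diagonal). Regions above the cutoff are super enhancers.
#'
#' @param peaks data frame (chrom, start, end, signal), 0-based half-open.
#' @param stitch_bp stitching distance (default 12500).
#' @param tss optional vector/list of data frame with `chrom` and `tss` for
#'   promoter-proximal exclusion.
#' @param tss_exclusion half-window around each TSS (default 2500).
#' @return Data frame (chrom, start, end, signal, rank, class) sorted by
#'   rank; `class` is `"super_enhancer"` or `"typical_enhancer"`. With fewer
#'   than 3 regions, or a flat signal curve, all regions are typical (a
#'   warning is raised in the former case).
#' @export
stitch_and_rank_enhancers <- function(peaks, stitch_bp = 12500,
                                      tss = NULL, tss_exclusion = 2500) {
  stopifnot(all(peaks$signal >= 0))
  if (!is.null(tss) && nrow(peaks) > 0) {
    tss_gr <- GenomicRanges::GRanges(
      tss$chrom, IRanges::IRanges(pmax(1, tss$tss - tss_exclusion + 1L),
                                  tss$tss + tss_exclusion))
    inside <- IRanges::overlapsAny(as_gr(peaks), tss_gr, type = "within")
    peaks <- peaks[!inside, , drop = FALSE]
  }
  if (nrow(peaks) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), signal = numeric(), rank = integer(),
                      class = character(), stringsAsFactors = FALSE))
  gr <- as_gr(peaks)
  red <- GenomicRanges::reduce(gr, min.gapwidth = stitch_bp)
  hit <- GenomicRanges::findOverlaps(gr, red)
  sig <- as.vector(tapply(peaks$signal[S4Vectors::queryHits(hit)],
                          factor(S4Vectors::subjectHits(hit),
                                 levels = seq_along(red)), sum))
  out <- gr_to_df(red)
  out$signal <- sig
  out <- out[order(out$signal, out$chrom, out$start), ]
  out$rank <- seq_len(nrow(out))
  n <- nrow(out)
  cut_rank <- n + 1L                      # default: nothing super
  if (n < 3) {
    warning("fewer than 3 stitched regions; all classed typical")
  } else if (diff(range(out$signal)) > 0) {
    x <- out$rank / n
    y <- (out$signal - min(out$signal)) / diff(range(out$signal))
    cut_rank <- which.max(x - y) + 1L     # first rank above the slope-1 point
  }
  out$class <- ifelse(out$rank >= cut_rank, "super_enhancer",
                      "typical_enhancer")
  rownames(out) <- NULL
  out
}

#' Define promoter windows around TSSs
#'
#' @param gene_model data frame with gene, chrom, tss.
#' @param window half-window (bp) around the TSS (default 2000).
#' @param active_peaks optional peak data frame; when given, only promoters
#'   overlapping at least one peak (active mark) are returned.
#' @return Data frame (gene, chrom, start, end, class = "promoter").
#' @export
define_promoters <- function(gene_model, window = 2000,
                             active_peaks = NULL) {
  pr <- data.frame(gene = gene_model$gene, chrom = gene_model$chrom,
                   start = pmax(0, gene_model$tss - window),
                   end = gene_model$tss + window,
                   class = "promoter", stringsAsFactors = FALSE)
  if (!is.null(active_peaks) && nrow(active_peaks) > 0) {
    act <- GenomicRanges::countOverlaps(as_gr(pr), as_gr(active_peaks)) > 0
    pr <- pr[act, , drop = FALSE]
    rownames(pr) <- NULL
  }
  pr
}

#' Flag DMRs overlapping regulatory regions
#'
#' A DMR is flagged if it shares at least 1 bp with a region active at any
#' stage; the flag records the overlapping region classes (super enhancers
#' take precedence over typical enhancers over promoters when summarising).
#'
#' @param dmrs DMR data frame.
#' @param regions data frame with chrom/start/end/class (enhancers; may
#'   carry a `stage` column).
#' @param promoters optional promoter data frame from [define_promoters()].
#' @return `dmrs` with `regulatory` (logical) and `regulatory_class`.
#' @export
overlap_dmrs_with_regions <- function(dmrs, regions, promoters = NULL) {
  all_reg <- rbind(
    if (nrow(regions)) regions[, c("chrom", "start", "end", "class")],
    if (!is.null(promoters) && nrow(promoters))
      promoters[, c("chrom", "start", "end", "class")]
  )
  out <- dmrs
  out$regulatory <- FALSE
  out$regulatory_class <- NA_character_
  if (is.null(all_reg) || nrow(all_reg) == 0 || nrow(dmrs) == 0) return(out)
  hit <- GenomicRanges::findOverlaps(as_gr(dmrs), as_gr(all_reg))
  if (length(hit)) {
    prec <- c(super_enhancer = 1, typical_enhancer = 2, promoter = 3)
    cls <- tapply(all_reg$class[S4Vectors::subjectHits(hit)],
                  S4Vectors::queryHits(hit), function(cl)
                    cl[which.min(prec[cl])])
    idx <- as.integer(names(cls))
    out$regulatory[idx] <- TRUE
    out$regulatory_class[idx] <- as.vector(cls)
  }
  out
}

#' Randomisation-based genomic annotation enrichment
#'
#' Observed overlap (bp) between the query intervals and each annotation set
#' is compared to a null distribution obtained by re-placing every query
#' interval uniformly at random on its own chromosome (lengths preserved),
#' `n_samplings` times. Empirical two-sided p-values (add-one corrected) are
#' BH-adjusted across annotation sets into q-values.
#'
#' @param query data frame (chrom, start, end).
#' @param annotations named list of annotation data frames.
#' @param workspace named vector of chromosome lengths.
#' @param n_samplings number of randomisations (default 1000).
#' @param seed RNG seed.
#' @return Data frame (feature, observed_bp, expected_bp, log2_ratio, p, q,
#'   status) with status in enriched/depleted/ns (q <= 0.05).
#' @export
randomized_annotation_enrichment <- function(query, annotations, workspace,
                                             n_samplings = 1000, seed = 1L) {
  stopifnot(is.list(annotations), !is.null(names(annotations)))
  bad <- !query$chrom %in% names(workspace) |
    query$end > workspace[query$chrom]
  if (any(bad)) stop("query intervals outside the workspace")
  ## per-feature, per-chromosome cumulative-coverage lookup: C(p) = covered
  ## bp in [0, p), so the overlap of [a, b) is C(b) - C(a). Query intervals
  ## are treated independently (they are disjoint in the intended use).
  cov_fun <- function(ann, ch) {
    a <- ann[ann$chrom == ch, , drop = FALSE]
    if (nrow(a) == 0) return(function(p) numeric(length(p)))
    ir <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
    s <- IRanges::start(ir) - 1L; e <- IRanges::end(ir)
    cumw <- cumsum(e - s)
    function(p) {
      i <- findInterval(p, s)
      ifelse(i == 0, 0, cumw[pmax(i, 1)] - pmax(0, e[pmax(i, 1)] - p))
    }
  }
  chroms <- unique(query$chrom)
  covs <- lapply(annotations, function(a)
    setNames(lapply(chroms, function(ch) cov_fun(a, ch)), chroms))
  widths <- query$end - query$start
  obs <- vapply(covs, function(cf) {
    sum(vapply(seq_len(nrow(query)), function(i) {
      f <- cf[[query$chrom[i]]]
      f(query$end[i]) - f(query$start[i])
    }, numeric(1)))
  }, numeric(1))
  ## all samplings at once: one random start matrix per query interval
  null <- with_seed(seed, {
    starts <- matrix(
      floor(runif(nrow(query) * n_samplings, 0,
                  rep(workspace[query$chrom] - widths + 1, n_samplings))),
      nrow = nrow(query))
    vapply(covs, function(cf) {
      tot <- numeric(n_samplings)
      for (i in seq_len(nrow(query))) {
        f <- cf[[query$chrom[i]]]
        tot <- tot + f(starts[i, ] + widths[i]) - f(starts[i, ])
      }
      tot
    }, numeric(n_samplings))
  })
  null <- t(matrix(null, ncol = length(covs),
                   dimnames = list(NULL, names(covs))))
  expd <- rowMeans(null)
  p <- vapply(seq_along(covs), function(i) {
    hi <- (1 + sum(null[i, ] >= obs[i])) / (n_samplings + 1)
    lo <- (1 + sum(null[i, ] <= obs[i])) / (n_samplings + 1)
    min(1, 2 * min(hi, lo))
  }, numeric(1))
  l2 <- ifelse(expd > 0 & obs > 0, log2(obs / expd),
               ifelse(expd == 0 & obs == 0, NA_real_,
                      ifelse(obs > expd, Inf, -Inf)))
  l2[vapply(annotations, nrow, integer(1)) == 0] <- NA_real_
  q <- p.adjust(p, method = "BH")
  status <- ifelse(q <= 0.05 & !is.na(l2) & l2 > 0, "enriched",
                   ifelse(q <= 0.05 & !is.na(l2) & l2 < 0, "depleted", "ns"))
  data.frame(feature = names(annotations), observed_bp = obs,
             expected_bp = expd, log2_ratio = l2, p = p, q = q,
             status = status, stringsAsFactors = FALSE, row.names = NULL)
}

#' Associate genomic regions to genes
#'
#' Two rules: (a) `"window"` - a region is associated to every gene whose
#' TSS lies within `window_kb` kb (inclusive) of the region; (b)
#' `"basalPlusExt"` - each gene gets a basal domain (TSS -5 kb/+1 kb,
#' strand-aware) extended on both sides up to `ext_kb` kb but stopping at
#' the nearest neighbouring basal domain; a region maps to all genes whose
#' extended domain it intersects.
#'
#' @param regions data frame (chrom, start, end) with optional `region_id`.
#' @param gene_model data frame (gene, chrom, tss, strand).
#' @param rule `"window"` or `"basalPlusExt"`.
#' @param window_kb association window for the window rule (default 100).
#' @param basal_up,basal_down basal domain extents upstream/downstream of
#'   the TSS (bp).
#' @param ext_kb maximum extension (default 100).
#' @return Data frame (region_id, gene) with one row per association.
#' @export
associate_regions_to_genes <- function(regions, gene_model,
                                       rule = c("window", "basalPlusExt"),
                                       window_kb = 100,
                                       basal_up = 5000, basal_down = 1000,
                                       ext_kb = 100) {
  rule <- match.arg(rule)
  if (is.null(regions$region_id))
    regions$region_id <- sprintf("region%05d", seq_len(nrow(regions)))
  if (nrow(regions) == 0 || nrow(gene_model) == 0)
    return(data.frame(region_id = character(), gene = character(),
                      stringsAsFactors = FALSE))
  rgr <- as_gr(regions)
  if (rule == "window") {
    tss_gr <- GenomicRanges::GRanges(
      gene_model$chrom,
      IRanges::IRanges(gene_model$tss + 1L, gene_model$tss + 1L))
    ## gap counts bases strictly between ranges, so distance d bp <=> gap
    ## d - 1: the window boundary itself (d = window) is inclusive
    hit <- GenomicRanges::findOverlaps(
      rgr, tss_gr, maxgap = window_kb * 1000 - 1)
  } else {
    strand <- gene_model$strand %||% rep("+", nrow(gene_model))
    b_start <- ifelse(strand == "-", gene_model$tss - basal_down,
                      gene_model$tss - basal_up)
    b_end <- ifelse(strand == "-", gene_model$tss + basal_up,
                    gene_model$tss + basal_down)
    dom <- data.frame(chrom = gene_model$chrom,
                      start = pmax(0, b_start), end = b_end)
    ext <- ext_kb * 1000
    for (ch in unique(dom$chrom)) {
      i <- which(dom$chrom == ch)
      i <- i[order(dom$start[i])]
      bs <- dom$start[i]; be <- dom$end[i]
      left_lim <- c(-Inf, cummax(be[-length(be)]))
      right_lim <- rev(cummin(rev(c(bs[-1], Inf))))
      dom$start[i] <- pmax(pmax(bs - ext, left_lim), 0)
      dom$end[i] <- pmin(be + ext, right_lim)
      ## neighbouring basal domains may already overlap: never shrink below
      ## the basal domain itself
      dom$start[i] <- pmin(dom$start[i], bs)
      dom$end[i] <- pmax(dom$end[i], be)
    }
    hit <- GenomicRanges::findOverlaps(rgr, as_gr(dom))
  }
  data.frame(region_id = regions$region_id[S4Vectors::queryHits(hit)],
             gene = gene_model$gene[S4Vectors::subjectHits(hit)],
             stringsAsFactors = FALSE)
}
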