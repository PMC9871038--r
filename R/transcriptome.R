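## Expression normalisation, time-course and pairwise differential
## expression, profile clustering and the rescue-overlap test.
##
## Tests are log-scale stand-ins (one-way F across groups; Welch t for
## pairwise contrasts, pseudo-count 1) behind the published threshold
## scheme: time-course |log2FC| >= 1.5 at FDR <= 0.001, pairwise >= 1 at
## 0.05, rescue >= 0.5 at 0.05, all inclusive, BH-adjusted.

#' Normalise counts to length- and depth-corrected abundance (RPKM)
#'
#' Effective library size is the raw depth times a median-ratio composition
#' factor (ratios to per-gene geometric means, factors normalised to
#' geometric mean 1); with fewer than 50 usable genes the factor falls back
#' to 1. Genes with at least 1 RPKM in at least 2 samples are flagged
#' `expressed`; the remainder are the low-expression filter set.
#'
#' @param counts genes x samples count matrix.
#' @param gene_lengths per-gene lengths in bp (> 0).
#' @return List with `rpkm`, `expressed` (logical per gene),
#'   `effective_lib`, and `factors`.
#' @export
normalize_expression <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(gene_lengths) == nrow(counts), all(gene_lengths > 0))
  depth <- colSums(counts)
  if (any(depth == 0)) stop("zero library size in sample(s): ",
                            paste(colnames(counts)[depth == 0], collapse = ", "))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (sum(pos) >= 50) {
    lg <- rowMeans(log(counts[pos, , drop = FALSE]))
    r <- apply(log(counts[pos, , drop = FALSE]) - lg, 2, median)
    f <- exp(r - mean(r))
  } else f <- rep(1, ncol(counts))
  eff <- depth * f
  rpkm <- sweep(sweep(counts, 2, eff / 1e6, "/"), 1, gene_lengths / 1e3, "/")
  expressed <- rowSums(rpkm >= 1) >= 2
  list(rpkm = rpkm, expressed = expressed, effective_lib = eff, factors = f)
}

## vectorised per-row group stats on a matrix
row_group_stats <- function(x, groups) {
  gs <- split(seq_len(ncol(x)), groups)
  means <- sapply(gs, function(j) rowMeans(x[, j, drop = FALSE]))
  vars <- sapply(gs, function(j)
    if (length(j) > 1) apply(x[, j, drop = FALSE], 1, var) else rep(NA_real_,
                                                                    nrow(x)))
  ns <- vapply(gs, length, integer(1))
  list(means = means, vars = vars, ns = ns)
}

deg_pass <- function(logfc, fdr, class,
                     thresholds = DEG_THRESHOLDS) {
  th <- thresholds[[class]]
  if (is.null(th)) stop("unknown threshold class: ", class)
  abs(logfc) >= th[["lfc"]] & fdr <= th[["fdr"]]
}

#' ANOVA-like time-course differential expression
#'
#' One-way F-test per gene on `log2(rpkm + 1)` across all condition-stage
#' groups. The reported log2 fold change is the largest absolute group
#' difference to the baseline group, computed on group means of
#' `abundance + 1`. Genes with zero variance everywhere get p = 1.
#'
#' @param rpkm abundance matrix (genes x samples).
#' @param groups factor/character of condition-stage group per sample.
#' @param baseline the baseline group label (e.g. `"WT_ESC"`).
#' @param class threshold class (default `"timecourse"`).
#' @return Data frame (gene, logfc, f, p, fdr, pass).
#' @export
timecourse_anova <- function(rpkm, groups, baseline,
                             class = "timecourse") {
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(rpkm), baseline %in% groups)
  if (length(unique(groups)) < 2) stop("need at least two groups")
  x <- log2(rpkm + 1)
  st <- row_group_stats(x, groups)
  n <- ncol(x); g <- length(st$ns)
  grand <- rowMeans(x)
  ssb <- rowSums(sweep(sweep(st$means, 1, grand)^2, 2, st$ns, "*"))
  sst <- rowSums((x - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  p <- pf(f, g - 1, n - g, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1
  p[ssw == 0 & ssb > 0] <- 0
  ## max |log2FC| vs baseline on group means of abundance + 1
  ab <- row_group_stats(rpkm, groups)$means
  lfc_all <- log2(ab + 1) - log2(ab[, baseline] + 1)
  lfc_all <- lfc_all[, colnames(lfc_all) != baseline, drop = FALSE]
  imax <- max.col(abs(lfc_all), ties.method = "first")
  logfc <- lfc_all[cbind(seq_len(nrow(lfc_all)), imax)]
  fdr <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(rpkm) %||% seq_len(nrow(rpkm)),
             logfc = logfc, f = f, p = p, fdr = fdr,
             pass = deg_pass(logfc, fdr, class),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise differential expression (two-sample t on log abundance)
#'
#' By default a pooled-variance Student t-test: with two replicates per
#' group the Welch-Satterthwaite approximation collapses to about one
#' degree of freedom and loses essentially all power, whereas the pooled
#' test keeps `na + nb - 2` df (the two groups share the count noise model
#' here, so equal variances are the natural assumption). Set
#' `var_equal = FALSE` for Welch.
#'
#' @param rpkm abundance matrix.
#' @param samples_a,samples_b column names of the two groups.
#' @param class threshold class: `"pairwise"` (KO vs WT at a stage) or
#'   `"rescue"` (re-expression vs empty vector).
#' @param var_equal pool the group variances (default TRUE).
#' @return Data frame (gene, logfc, t, df, p, fdr, pass); `logfc > 0` means
#'   higher in group A.
#' @export
pairwise_contrast <- function(rpkm, samples_a, samples_b,
                              class = "pairwise", var_equal = TRUE) {
  ja <- match(samples_a, colnames(rpkm)); jb <- match(samples_b, colnames(rpkm))
  if (anyNA(ja) || anyNA(jb)) stop("unknown sample names")
  xa <- log2(rpkm[, ja, drop = FALSE] + 1)
  xb <- log2(rpkm[, jb, drop = FALSE] + 1)
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, var); vb <- apply(xb, 1, var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(se2))
  } else {
    se2 <- va / na + vb / nb
    df <- ifelse(se2 > 0,
                 se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
                 NA_real_)
  }
  t <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  p <- ifelse(se2 > 0, 2 * pt(-abs(t), df),
              ifelse(ma == mb, 1, 0))
  logfc <- log2(rowMeans(rpkm[, ja, drop = FALSE]) + 1) -
    log2(rowMeans(rpkm[, jb, drop = FALSE]) + 1)
  fdr <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(rpkm) %||% seq_len(nrow(rpkm)),
             logfc = logfc, t = t, df = df, p = p, fdr = fdr,
             pass = deg_pass(logfc, fdr, class),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' K-means clustering of expression profiles
#'
#' Rows (genes) are z-scored across samples before distances are computed;
#' k-means uses `centers = k`, `iter.max = 25`, `nstart = 100` under a fixed
#' seed. A within-cluster sum-of-squares sweep over `k_grid` is returned as
#' the elbow diagnostic for the choice of k.
#'
#' @param x genes x samples abundance matrix (DEGs).
#' @param k number of clusters (default 4).
#' @param seed RNG seed.
#' @param k_grid k values for the within-SS diagnostic.
#' @return List with `cluster` (per gene), `centers`, `withinss`, and
#'   `wss_by_k`.
#' @export
cluster_expression_profiles <- function(x, k = 4, seed = 1L,
                                        k_grid = 1:8) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of genes")
  z <- t(scale(t(x)))
  z[!is.finite(z)] <- 0
  km <- with_seed(seed, kmeans(z, centers = k, iter.max = 25, nstart = 100))
  wss <- vapply(k_grid[k_grid <= nrow(z)], function(kk)
    with_seed(seed, sum(kmeans(z, centers = kk, iter.max = 25,
                               nstart = 25)$withinss)), numeric(1))
  list(cluster = setNames(km$cluster, rownames(x)), centers = km$centers,
       withinss = sum(km$withinss),
       wss_by_k = setNames(wss, k_grid[k_grid <= nrow(z)]))
}

#' Rescue-overlap test
#'
#' What fraction of genes upregulated in the KO is repressed again when the
#' methyltransferase is re-expressed, and is that overlap larger than chance?
#' One-sided Fisher's exact test (greater) on the 2x2 membership table over
#' the gene universe.
#'
#' @param up_in_ko,down_in_rescue gene sets (subsets of `universe`).
#' @param universe all analysed genes.
#' @return List with `fraction`, `odds_ratio`, `p`, and the `table`.
#' @export
rescue_overlap_test <- function(up_in_ko, down_in_rescue, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  if (!all(up_in_ko %in% universe) || !all(down_in_rescue %in% universe))
    stop("gene sets must be subsets of the universe")
  a <- length(intersect(up_in_ko, down_in_rescue))
  b <- length(setdiff(up_in_ko, down_in_rescue))
  c <- length(setdiff(down_in_rescue, up_in_ko))
  d <- length(universe) - a - b - c
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE,
                dimnames = list(up_in_ko = c("yes", "no"),
                                down_in_rescue = c("yes", "no")))
  ft <- fisher.test(tab, alternative = "greater")
  list(fraction = if (length(up_in_ko)) a / length(up_in_ko) else NaN,
       odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}
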