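## Independent oracles and fixture builders shared across the suite.
## Oracles are deliberately naive (enumeration / O(n^2)) and never call the
## code paths they check.

## O(n^2) interval merge: repeatedly fuse any overlapping pair to fixed point
oracle_merge <- function(df) {
  chrom <- as.character(df$chrom)
  start <- as.numeric(df$start); end <- as.numeric(df$end)
  alive <- rep(TRUE, length(start))
  repeat {
    changed <- FALSE
    for (i in which(alive)) {
      for (j in which(alive)) {
        if (i == j || !alive[i] || !alive[j]) next
        if (chrom[i] == chrom[j] && start[i] < end[j] && start[j] < end[i]) {
          start[i] <- min(start[i], start[j])
          end[i] <- max(end[i], end[j])
          alive[j] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- data.frame(chrom = chrom[alive], start = start[alive],
                    end = end[alive], stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

## one-sided (greater) Fisher p by hypergeometric enumeration on
## table [[a, b], [c, d]] (rows: in set 1 yes/no; cols: in set 2 yes/no)
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  kk <- max(0, k - n):min(k, m)
  sum(stats::dhyper(kk[kk >= a], m, n, k))
}

oracle_fisher_less <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  kk <- max(0, k - n):min(k, m)
  sum(stats::dhyper(kk[kk <= a], m, n, k))
}

## BH step-up by direct definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

## brute-force overlap flags of set a against set b
oracle_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end)
  }, logical(1))
}

## minimal cpg_table fixture
make_cpg_table <- function(chrom, pos, meth, total,
                           conditions = NULL, stages = NULL) {
  meth <- as.matrix(meth); total <- as.matrix(total)
  samples <- data.frame(
    condition = conditions %||% rep("WT", ncol(meth)),
    stage = stages %||% rep("ESC", ncol(meth)),
    replicate = seq_len(ncol(meth)),
    sample = colnames(meth) %||% paste0("s", seq_len(ncol(meth))),
    stringsAsFactors = FALSE)
  colnames(meth) <- colnames(total) <- samples$sample
  structure(list(chrom = chrom, pos = pos, region_id = NULL,
                 meth = meth, total = total, samples = samples),
            class = "cpg_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## adjusted Rand index between two labelings
ari <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(n) n * (n - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

## random candidate-CpG stats row builder for segmentation fixtures
cand_stats <- function(chrom, pos, diff, candidate = TRUE,
                       z = sign(diff) * 6) {
  data.frame(chrom = chrom, pos = pos, meth_a = NA, meth_b = NA,
             diff = diff, z = z, p = 2 * pnorm(-abs(z)),
             candidate = candidate, stringsAsFactors = FALSE)
}

## small, fast simulation configuration for end-to-end tests
tiny_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_chromosomes = 2L, chrom_length_bp = 3e6,
             n_cpg = 4000L, n_regions = 120L, n_genes = 800L,
             n_deg_per_cluster = 50L, n_tfs = 25L, n_direct_tfs = 3L,
             edges_per_tf = 40L, ...)
}
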