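test_that("boxcar smoother handles single CpGs, constants and hand-computed windows", {
  ## isolated CpG: window of one
  expect_equal(smooth_methylation("chr1", 100L, 8, 10, 500), 0.8)
  ## constant signal is preserved
  n <- 20
  out <- smooth_methylation(rep("chr1", n), seq(0, by = 60, length.out = n),
                            rep(5, n), rep(10, n), 500)
  expect_equal(out, rep(0.5, n))
  ## three CpGs within 100 bp, equal coverage: centre is the plain mean
  out <- smooth_methylation(rep("chr1", 3), c(0L, 50L, 100L),
                            c(2, 4, 6), c(10, 10, 10), 500)
  expect_equal(out[2], 0.4)
  ## coverage weighting: unequal totals shift the mean
  out <- smooth_methylation(rep("chr1", 2), c(0L, 10L),
                            c(0, 30), c(10, 30), 500)
  expect_equal(out[1], 30 / 40)
  ## chromosomes are independent
  out <- smooth_methylation(c("chr1", "chr2"), c(0L, 0L),
                            c(0, 10), c(10, 10), 500)
  expect_equal(out, c(0, 1))
})

test_that("per-CpG differential test matches exact enumeration and edge cases", {
  tbl <- function(ma, ta, mb, tb, pos = 0L) {
    make_cpg_table("chr1", pos, cbind(a = ma, b = mb), cbind(a = ta, b = tb))
  }
  ## identical pooled counts: no difference, p = 1
  cp <- make_cpg_table("chr1", 0L, cbind(x = 30, y = 30), cbind(x = 100, y = 100))
  r <- test_cpg_differential(cp, "x", "y")
  expect_equal(r$diff, 0)
  expect_equal(r$p, 1)
  ## maximal separation is a candidate with diff 1
  cp <- make_cpg_table("chr1", 0L, cbind(x = 100, y = 0), cbind(x = 100, y = 100))
  r <- test_cpg_differential(cp, "x", "y")
  expect_equal(r$diff, 1)
  expect_true(r$candidate)
  ## 30/100 vs 60/100: the z-test tracks an exact unconditional
  ## binomial-enumeration oracle (agreement on the log-p scale)
  cp <- make_cpg_table("chr1", 0L, cbind(x = 30, y = 60), cbind(x = 100, y = 100))
  r <- test_cpg_differential(cp, "x", "y")
  p0 <- 90 / 200
  pr <- outer(dbinom(0:100, 100, p0), dbinom(0:100, 100, p0))
  zs <- function(x, y) {
    ph <- (x + y) / 200; s <- sqrt(ph * (1 - ph) * 0.02)
    ifelse(s > 0, abs(x / 100 - y / 100) / s, 0)
  }
  zobs <- abs(0.3 - 0.6) / sqrt(p0 * (1 - p0) * 0.02)
  p_exact <- sum(pr[outer(0:100, 0:100, zs) >= zobs - 1e-12])
  expect_lt(abs(log10(r$p) - log10(p_exact)) / abs(log10(p_exact)), 0.1)
  ## zero coverage in one group: CpG excluded and logged
  cp <- make_cpg_table("chr1", c(0L, 500L), cbind(x = c(5, 5), y = c(5, 0)),
                       cbind(x = c(10, 10), y = c(10, 0)))
  r <- test_cpg_differential(cp, "x", "y")
  expect_equal(nrow(r), 1)
  expect_equal(attr(r, "n_excluded"), 1)
})

test_that("segmentation honours minCG, dis.merge and delta boundaries", {
  cfg <- dmr_call_config()
  ## 6 same-sign candidates spaced 20 bp, diff 0.4: one DMR with 6 CpGs
  st <- cand_stats("chr1", seq(0L, by = 20L, length.out = 6), rep(0.4, 6))
  d <- segment_dmrs(st, cfg)
  expect_equal(nrow(d), 1)
  expect_equal(d$n_cpg, 6)
  expect_equal(d$direction, "hyper")
  expect_equal(d$start, 0)
  expect_equal(d$end, 101)
  ## minCG = 5: four candidates are not enough, five are
  expect_equal(nrow(segment_dmrs(st[1:4, ], cfg)), 0)
  expect_equal(nrow(segment_dmrs(st[1:5, ], cfg)), 1)
  ## dis.merge = 100: gap of exactly 100 bp stays one run, 101 splits;
  ## the split second run has < minCG CpGs and is dropped
  pos <- c(0L, 20L, 40L, 60L, 160L, 180L)
  d <- segment_dmrs(cand_stats("chr1", pos, rep(0.4, 6)), cfg)
  expect_equal(nrow(d), 1)
  expect_equal(d$n_cpg, 6)
  pos2 <- c(0L, 20L, 40L, 60L, 80L, 181L, 201L, 221L, 241L, 261L)
  d <- segment_dmrs(cand_stats("chr1", pos2, rep(0.4, 10)), cfg)
  expect_equal(nrow(d), 2)
  ## runs 150 bp apart are distinct DMRs when both pass minCG
  pos3 <- c(seq(0L, 80L, 20L), seq(230L, 310L, 20L))
  d <- segment_dmrs(cand_stats("chr1", pos3, rep(0.4, 10)), cfg)
  expect_equal(nrow(d), 2)
  ## delta = 0.2 region boundary is inclusive
  expect_equal(nrow(segment_dmrs(
    cand_stats("chr1", seq(0L, 80L, 20L), rep(0.20, 5)), cfg)), 1)
  expect_equal(nrow(segment_dmrs(
    cand_stats("chr1", seq(0L, 80L, 20L), rep(0.19, 5)), cfg)), 0)
  ## opposite signs never share a run
  st <- cand_stats("chr1", seq(0L, by = 20L, length.out = 10),
                   rep(c(0.4, -0.4), each = 5))
  expect_equal(nrow(segment_dmrs(st, cfg)), 2)
})

test_that("combining DMR sets equals the naive all-pairs merge oracle", {
  ## hand examples
  a <- data.frame(chrom = "chr1", start = 100, end = 200,
                  source_comparisons = "a")
  b <- data.frame(chrom = "chr1", start = 150, end = 300,
                  source_comparisons = "b")
  cmb <- combine_dmr_sets(list(a, b))
  expect_equal(cmb[, c("start", "end")], data.frame(start = 100, end = 300))
  expect_equal(cmb$source_comparisons, "a,b")
  ## disjoint inputs unchanged
  d <- data.frame(chrom = "chr1", start = c(0, 500), end = c(100, 600))
  expect_equal(combine_dmr_sets(list(d))[, c("start", "end")],
               d[, c("start", "end")])
  ## 500 random intervals vs the O(n^2) oracle; idempotence; bp conservation
  set.seed(41)
  for (rep in 1:5) {
    r <- data.frame(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                    start = sample.int(2000, 100))
    r$end <- r$start + sample.int(150, 100)
    got <- combine_dmr_sets(list(r))
    exp <- oracle_merge(r)
    expect_equal(got[, c("chrom", "start", "end")], exp)
    again <- combine_dmr_sets(list(got))
    expect_equal(again[, c("chrom", "start", "end")], exp)
    ## order independence
    perm <- r[sample.int(nrow(r)), ]
    expect_equal(combine_dmr_sets(list(perm))[, c("chrom", "start", "end")],
                 exp)
    ## union bp conserved
    expect_equal(sum(got$end - got$start), sum(exp$end - exp$start))
  }
})

test_that("coverage filters honour the 5x CpG and 10x DMR boundaries", {
  pos <- seq(0L, by = 40L, length.out = 10)
  dmr <- data.frame(chrom = "chr1", start = 0, end = 400)
  ## one sample at mean 9x: DMR removed; at 10x: retained
  cp9 <- make_cpg_table(rep("chr1", 10), pos,
                        cbind(a = rep(5, 10), b = rep(5, 10)),
                        cbind(a = rep(30, 10), b = rep(9, 10)))
  expect_equal(nrow(filter_by_coverage(dmr, cp9)), 0)
  cp10 <- make_cpg_table(rep("chr1", 10), pos,
                         cbind(a = rep(5, 10), b = rep(5, 10)),
                         cbind(a = rep(30, 10), b = rep(10, 10)))
  expect_equal(nrow(filter_by_coverage(dmr, cp10)), 1)
  ## CpGs under 5x in any sample are dropped before averaging
  tot <- cbind(a = c(rep(30, 5), rep(4, 5)), b = rep(30, 10))
  cp <- make_cpg_table(rep("chr1", 10), pos, tot * 0 + 3, tot)
  f <- filter_by_coverage(dmr, cp)
  expect_equal(f$n_cpg_eligible, 5)
  ## a DMR left with zero eligible CpGs is removed and counted
  tot0 <- cbind(a = rep(4, 10), b = rep(30, 10))
  cp0 <- make_cpg_table(rep("chr1", 10), pos, tot0 * 0, tot0)
  f0 <- filter_by_coverage(dmr, cp0)
  expect_equal(nrow(f0), 0)
  expect_equal(attr(f0, "n_empty"), 1)
  ## generous coverage everywhere: set unchanged
  cp30 <- make_cpg_table(rep("chr1", 10), pos,
                         cbind(a = rep(10, 10), b = rep(10, 10)),
                         cbind(a = rep(30, 10), b = rep(30, 10)))
  expect_equal(nrow(filter_by_coverage(dmr, cp30)), 1)
})

test_that("trajectory clustering recovers planted dynamics and labels by gain", {
  ## three well-separated dynamics
  set.seed(11)
  mk <- function(profile, n) t(replicate(n, profile + rnorm(4, 0, 0.02)))
  traj <- rbind(mk(c(0.1, 0.7, 0.7, 0.7), 40),   # medium gain
                mk(c(0.1, 0.9, 0.9, 0.9), 40),   # high gain
                mk(c(0.8, 0.2, 0.2, 0.2), 20))   # demethylated
  truth <- rep(c("gainMedium", "gainHigh", "demethylated"), c(40, 40, 20))
  cl <- cluster_dmr_trajectories(traj, k = 3, seed = 7)
  expect_gte(ari(cl$labels, truth), 0.9)
  ## semantic ordering: I = medium gain, II = high gain, III = demethylated
  expect_equal(unique(cl$labels[truth == "gainMedium"]), "clusterI")
  expect_equal(unique(cl$labels[truth == "gainHigh"]), "clusterII")
  expect_equal(unique(cl$labels[truth == "demethylated"]), "clusterIII")
  ## identical trajectories, k = 1: zero within-SS
  flat <- matrix(rep(c(0.2, 0.4, 0.6, 0.8), each = 10), nrow = 10)
  c1 <- cluster_dmr_trajectories(flat, k = 1, seed = 1)
  expect_equal(c1$withinss, 0)
  ## within-SS non-increasing in k on fixed data
  wss <- vapply(1:4, function(k)
    cluster_dmr_trajectories(traj, k, seed = 3)$withinss, numeric(1))
  expect_true(all(diff(wss) <= 1e-8))
  ## k larger than the data errors
  expect_error(cluster_dmr_trajectories(flat, k = 99), "k exceeds")
})

test_that("KO DMRs are classified by largest WT-cluster overlap with direction", {
  wt <- data.frame(chrom = "chr1", start = c(0, 1000, 3000),
                   end = c(500, 2000, 3500),
                   cluster = c("clusterI", "clusterII", "clusterIII"))
  ko <- data.frame(chrom = "chr1",
                   start = c(100, 450, 5000, 1500),
                   end = c(300, 1800, 5200, 3200))
  out <- classify_ko_dmrs(ko, wt, ko_mean = c(10, 20, 80, 90),
                          wt_mean = c(70, 80, 20, 30))
  ## inside cluster I
  expect_equal(out$wt_cluster[1], "clusterI")
  ## straddles I (50 bp) and II (800 bp): largest overlap wins
  expect_equal(out$wt_cluster[2], "clusterII")
  ## no WT overlap
  expect_equal(out$wt_cluster[3], "stable_in_WT")
  ## straddles II (500 bp) and III (200 bp)
  expect_equal(out$wt_cluster[4], "clusterII")
  expect_equal(out$direction, c("hypo", "hypo", "hyper", "hyper"))
})

test_that("interval-set comparison equals the brute-force overlap oracle", {
  expect_equal(compare_dmr_sets(
    data.frame(chrom = "chr1", start = 0, end = 10),
    data.frame(chrom = "chr1", start = 0, end = 10))$fraction, 1)
  expect_equal(compare_dmr_sets(
    data.frame(chrom = "chr1", start = 0, end = 10),
    data.frame(chrom = "chr1", start = 50, end = 60))$fraction, 0)
  set.seed(8)
  a <- data.frame(chrom = sample(c("chr1", "chr2"), 60, TRUE),
                  start = sample.int(1000, 60))
  a$end <- a$start + sample.int(80, 60)
  b <- data.frame(chrom = sample(c("chr1", "chr2"), 60, TRUE),
                  start = sample.int(1000, 60))
  b$end <- b$start + sample.int(80, 60)
  got <- compare_dmr_sets(a, b)
  expect_equal(got$fraction, mean(oracle_overlaps_any(a, b)))
})

test_that("fixed-width tiling partitions each chromosome exactly", {
  tiles <- tile_genome(c(chr1 = 2000L, chr2 = 1100L), 400L)
  for (ch in c("chr1", "chr2")) {
    t <- tiles[tiles$chrom == ch, ]
    expect_equal(t$start[1], 0)
    expect_equal(t$end[nrow(t)], c(chr1 = 2000L, chr2 = 1100L)[[ch]])
    expect_true(all(t$start[-1] == t$end[-nrow(t)])) # no gaps, no overlap
  }
  expect_equal(tiles$end - tiles$start,
               c(rep(400, 5), rep(400, 2), 300))
})
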