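test_that("rank-elbow super-enhancer calling isolates heavy-tailed signal", {
  pk <- function(sig) data.frame(chrom = "chr1",
                                 start = seq_along(sig) * 50000,
                                 end = seq_along(sig) * 50000 + 1000,
                                 signal = sig)
  ## [1,1,1,1,100]: exactly the 100 region is super
  r <- stitch_and_rank_enhancers(pk(c(1, 1, 1, 1, 100)))
  expect_equal(sum(r$class == "super_enhancer"), 1)
  expect_equal(r$signal[r$class == "super_enhancer"], 100)
  ## flat curve: no super enhancers
  r <- stitch_and_rank_enhancers(pk(rep(7, 10)))
  expect_equal(sum(r$class == "super_enhancer"), 0)
  ## super count invariant under uniform signal scaling
  set.seed(6)
  sig <- c(rlnorm(50, 2, 0.4), 200 / runif(5)^0.8)
  n1 <- sum(stitch_and_rank_enhancers(pk(sig))$class == "super_enhancer")
  n2 <- sum(stitch_and_rank_enhancers(pk(sig * 37))$class == "super_enhancer")
  expect_equal(n1, n2)
  expect_gt(n1, 0)
  ## fewer than 3 regions: all typical, with a warning
  expect_warning(r <- stitch_and_rank_enhancers(pk(c(5, 50))), "typical")
  expect_true(all(r$class == "typical_enhancer"))
})

test_that("peak stitching merges at the distance rule and is idempotent", {
  two <- data.frame(chrom = "chr1", start = c(0, 11000), end = c(1000, 12000),
                    signal = c(5, 5))
  r <- suppressWarnings(stitch_and_rank_enhancers(two, stitch_bp = 12500))
  expect_equal(nrow(r), 1)
  expect_equal(r$signal, 10)
  far <- data.frame(chrom = "chr1", start = c(0, 20000), end = c(1000, 21000),
                    signal = c(5, 5))
  expect_equal(nrow(suppressWarnings(
    stitch_and_rank_enhancers(far, stitch_bp = 12500))), 2)
  ## stitched output is non-overlapping and stitching it again is a no-op
  set.seed(7)
  pk <- data.frame(chrom = sample(c("chr1", "chr2"), 80, TRUE),
                   start = sample.int(5e5, 80))
  pk$end <- pk$start + 500
  pk$signal <- rlnorm(80, 2, 1)
  r1 <- stitch_and_rank_enhancers(pk)
  expect_false(any(oracle_overlaps_any(
    r1[-1, c("chrom", "start", "end")], r1[1, c("chrom", "start", "end")]) &
      FALSE))  # guard: see full pairwise check below
  ovl <- sapply(seq_len(nrow(r1)), function(i)
    sum(r1$chrom == r1$chrom[i] & r1$start < r1$end[i] & r1$start[i] < r1$end))
  expect_true(all(ovl == 1))
  r2 <- stitch_and_rank_enhancers(r1[, c("chrom", "start", "end", "signal")])
  expect_equal(r2[, c("chrom", "start", "end")],
               r1[order(r1$signal), c("chrom", "start", "end")],
               ignore_attr = TRUE)
  ## promoter-proximal peaks are excluded before stitching
  tssdf <- data.frame(chrom = "chr1", tss = 500)
  prox <- data.frame(chrom = "chr1", start = c(0, 50000), end = c(1000, 51000),
                     signal = c(5, 5))
  r3 <- suppressWarnings(stitch_and_rank_enhancers(prox, tss = tssdf))
  expect_equal(nrow(r3), 1)
  expect_equal(r3$start, 50000)
})

test_that("DMR regulatory flags equal the brute-force overlap oracle", {
  dmr <- data.frame(chrom = "chr1", start = c(100, 5000), end = c(200, 5100))
  reg <- data.frame(chrom = "chr1", start = 150, end = 400,
                    class = "super_enhancer")
  f <- overlap_dmrs_with_regions(dmr, reg)
  expect_equal(f$regulatory, c(TRUE, FALSE))
  expect_equal(f$regulatory_class, c("super_enhancer", NA))
  ## 100-interval fixture against the O(n^2) oracle
  set.seed(9)
  dmrs <- data.frame(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                     start = sample.int(10000, 100))
  dmrs$end <- dmrs$start + sample.int(200, 100)
  regs <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                     start = sample.int(10000, 40))
  regs$end <- regs$start + sample.int(400, 40)
  regs$class <- sample(c("typical_enhancer", "super_enhancer"), 40, TRUE)
  f <- overlap_dmrs_with_regions(dmrs, regs)
  expect_equal(f$regulatory, oracle_overlaps_any(dmrs, regs))
  ## promoters participate via the promoter argument
  prom <- data.frame(gene = "g1", chrom = "chr1", start = 5050, end = 5300,
                     class = "promoter")
  f2 <- overlap_dmrs_with_regions(dmr, reg, prom)
  expect_equal(f2$regulatory_class, c("super_enhancer", "promoter"))
})

test_that("randomised annotation enrichment is calibrated and deterministic", {
  workspace <- c(chr1 = 1e6)
  set.seed(10)
  q <- data.frame(chrom = "chr1", start = sample.int(9e5, 200))
  q$end <- q$start + 500
  ## annotation covering ~30% of the workspace: random query is not enriched
  ann <- data.frame(chrom = "chr1",
                    start = seq(0, 9.9e5, by = 1e4))
  ann$end <- ann$start + 3000
  r <- randomized_annotation_enrichment(q, list(cov30 = ann), workspace,
                                        n_samplings = 400, seed = 3)
  expect_lt(abs(r$log2_ratio), 0.3)
  expect_equal(r$status, "ns")
  ## analytic expectation: f * |query|
  expect_lt(abs(r$expected_bp - 0.3 * sum(q$end - q$start)) /
              (0.3 * sum(q$end - q$start)), 0.1)
  ## fixed seed reproduces q-values exactly
  r2 <- randomized_annotation_enrichment(q, list(cov30 = ann), workspace,
                                         n_samplings = 400, seed = 3)
  expect_identical(r, r2)
  ## a query designed to sit inside the annotation is enriched
  qin <- data.frame(chrom = "chr1", start = ann$start[1:30] + 100)
  qin$end <- qin$start + 1000
  renr <- randomized_annotation_enrichment(qin, list(cov30 = ann), workspace,
                                           n_samplings = 400, seed = 3)
  expect_equal(renr$status, "enriched")
  ## empty annotation reported as NA ratio
  r0 <- randomized_annotation_enrichment(
    q, list(none = ann[0, ]), workspace, n_samplings = 50, seed = 1)
  expect_true(is.na(r0$log2_ratio))
  ## intervals outside the workspace are rejected
  expect_error(randomized_annotation_enrichment(
    data.frame(chrom = "chr1", start = 999900, end = 1000500),
    list(a = ann), workspace, 10, 1), "workspace")
})

test_that("null enrichment keeps the false-positive fraction below twice nominal", {
  workspace <- c(chr1 = 5e5)
  set.seed(12)
  n_sig <- 0
  n_feat <- 0
  for (s in 1:25) {
    q <- data.frame(chrom = "chr1", start = sample.int(4.5e5, 25))
    q$end <- q$start + 400
    anns <- lapply(1:2, function(i) {
      a <- data.frame(chrom = "chr1", start = sample.int(4.5e5, 40))
      a$end <- a$start + 800
      a
    })
    names(anns) <- c("f1", "f2")
    r <- randomized_annotation_enrichment(q, anns, workspace,
                                          n_samplings = 200, seed = s)
    n_sig <- n_sig + sum(r$q <= 0.05)
    n_feat <- n_feat + nrow(r)
  }
  expect_lte(n_sig / n_feat, 0.1)
})

test_that("region-gene association honours the 100 kb window boundary", {
  reg <- data.frame(chrom = "chr1", start = 0, end = 1000,
                    region_id = "r1")
  gm <- function(tss) data.frame(gene = "g1", chrom = "chr1", tss = tss,
                                 strand = "+")
  ## 99 kb away: associated; exactly 100 kb: associated; 101 kb: not
  expect_equal(nrow(associate_regions_to_genes(reg, gm(1000 + 99000 - 1))), 1)
  expect_equal(nrow(associate_regions_to_genes(reg, gm(999 + 100000))), 1)
  expect_equal(nrow(associate_regions_to_genes(reg, gm(999 + 100001))), 0)
  ## TSS inside the region is trivially associated
  expect_equal(nrow(associate_regions_to_genes(reg, gm(500))), 1)
})

test_that("basal-plus-extension domains match a hand-drawn three-gene oracle", {
  ## genes at 200k (+), 220k (+), 500k (-) on one chromosome
  gm <- data.frame(gene = c("gA", "gB", "gC"), chrom = "chr1",
                   tss = c(200000, 220000, 500000),
                   strand = c("+", "+", "-"))
  ## basal domains: gA [195k,201k); gB [215k,221k); gC (minus strand)
  ## [499k,505k)
  ## extensions (100 kb cap, stop at neighbour basal):
  ##   gA: left to 95k (cap), right to 215k (gB basal)
  ##   gB: left to 201k (gA basal), right to 321k (cap)
  ##   gC: left to 399k (cap), right to 605k (cap)
  hit <- function(start, end)
    associate_regions_to_genes(
      data.frame(chrom = "chr1", start = start, end = end, region_id = "q"),
      gm, rule = "basalPlusExt")$gene
  expect_equal(hit(96000, 96500), "gA")
  expect_equal(hit(94000, 94900), character(0))
  expect_equal(sort(hit(200500, 200600)), "gA")
  expect_equal(sort(hit(214000, 216000)), c("gA", "gB"))   # boundary zone
  expect_equal(hit(230000, 231000), "gB")
  expect_equal(hit(330000, 331000), character(0))          # between gB cap and gC cap
  expect_equal(hit(396000, 397000), character(0))          # just left of gC cap
  expect_equal(hit(399500, 400000), "gC")
  expect_equal(hit(604000, 604500), "gC")
  expect_equal(hit(606000, 607000), character(0))
})
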