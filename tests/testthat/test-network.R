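mk_edges <- function(...) {
  d <- data.frame(...)
  d$tf <- as.character(d$tf); d$target <- as.character(d$target)
  d
}

test_that("backbone keeps source-A edges and the source-B class intersection", {
  a <- mk_edges(tf = "t1", target = "g1")
  b <- rbind(
    mk_edges(tf = "t2", target = "g2", evidence_class = "coexpression"),
    mk_edges(tf = "t2", target = "g2", evidence_class = "chipseq"),
    mk_edges(tf = "t3", target = "g3", evidence_class = "coexpression"))
  bb <- build_backbone(a, b)
  expect_setequal(paste(bb$tf, bb$target), c("t1 g1", "t2 g2"))
  expect_equal(bb$sources[bb$tf == "t1"], "A")
  expect_equal(bb$sources[bb$tf == "t2"], "B")
  ## duplicates collapse with provenance
  bb2 <- build_backbone(mk_edges(tf = "t2", target = "g2"), b)
  expect_equal(bb2$sources[bb2$tf == "t2"], "A,B")
  ## random labelled lists vs a brute-force set-algebra oracle
  set.seed(16)
  for (i in 1:10) {
    tfs <- paste0("t", 1:6); gs <- paste0("g", 1:15)
    ra <- mk_edges(tf = sample(tfs, 30, TRUE), target = sample(gs, 30, TRUE))
    rb <- mk_edges(tf = sample(tfs, 60, TRUE), target = sample(gs, 60, TRUE),
                   evidence_class = sample(c("coexpression", "chipseq"),
                                           60, TRUE))
    got <- sort(paste(build_backbone(ra, rb)$tf, build_backbone(ra, rb)$target))
    kb <- paste(rb$tf, rb$target)
    want <- sort(unique(c(
      paste(ra$tf, ra$target),
      intersect(kb[rb$evidence_class == "coexpression"],
                kb[rb$evidence_class == "chipseq"]))))
    expect_equal(got, want)
  }
})

test_that("DEG filtering keeps only all-DEG edges and drops isolated nodes", {
  e <- mk_edges(tf = c("t1", "t1", "t2"), target = c("g1", "g2", "g3"))
  all_deg <- filter_to_degs(e, c("t1", "t2", "g1", "g2", "g3"), c("t1", "t2"))
  expect_equal(nrow(all_deg$edges), 3)
  part <- filter_to_degs(e, c("t1", "g1"), c("t1", "t2"))
  expect_equal(nrow(part$edges), 1)
  expect_setequal(part$nodes$node, c("t1", "g1"))
  expect_warning(none <- filter_to_degs(e, "g9", c("t1")), "no edges")
  expect_equal(nrow(none$edges), 0)
})

test_that("node classification is a conjunction and monotone in evidence", {
  e <- mk_edges(tf = c("t1", "t2"), target = c("g1", "g2"))
  net <- filter_to_degs(e, c("t1", "t2", "g1", "g2"), c("t1", "t2"))
  ev <- data.frame(gene = c("t1", "t2", "g1"),
                   up_in_ko = c(TRUE, TRUE, TRUE),
                   down_in_rescue = c(TRUE, FALSE, TRUE),
                   has_hypo_regulatory_dmr = c(TRUE, TRUE, TRUE))
  cl <- classify_nodes(net, ev)
  expect_equal(cl$nodes$class[cl$nodes$node == "t1"], "direct")
  expect_equal(cl$nodes$class[cl$nodes$node == "t2"], "indirect")
  expect_equal(cl$nodes$class[cl$nodes$node == "g1"], "target")
  ## truth table over random flags, plus monotonicity under flag removal
  set.seed(17)
  for (i in 1:20) {
    ev2 <- data.frame(gene = c("t1", "t2", "g1", "g2"),
                      up_in_ko = sample(c(TRUE, FALSE), 4, TRUE),
                      down_in_rescue = sample(c(TRUE, FALSE), 4, TRUE),
                      has_hypo_regulatory_dmr = sample(c(TRUE, FALSE), 4, TRUE))
    cl2 <- classify_nodes(net, ev2)
    for (n in c("t1", "t2")) {
      want <- if (all(unlist(ev2[ev2$gene == n, 2:4]))) "direct" else "indirect"
      expect_equal(cl2$nodes$class[cl2$nodes$node == n], want)
    }
    ## removing one TRUE flag never promotes indirect -> direct
    ev3 <- ev2
    f <- sample(2:4, 1)
    ev3[[f]] <- FALSE
    cl3 <- classify_nodes(net, ev3)
    promoted <- cl2$nodes$class == "indirect" & cl3$nodes$class == "direct"
    expect_false(any(promoted))
  }
})

test_that("out-degree ranking uses descending degree with lexicographic ties", {
  ## star graph: the hub is rank 1 and top-percentile
  star <- mk_edges(tf = rep("hub", 10), target = paste0("g", 1:10))
  net <- filter_to_degs(star, c("hub", paste0("g", 1:10)), "hub")
  net <- rank_by_out_degree(net, percentile = 1)
  expect_equal(net$ranking$tf[1], "hub")
  expect_equal(net$ranking$out_degree[1], 10)
  expect_true(net$nodes$top_percentile[net$nodes$node == "hub"])
  expect_equal(sum(net$nodes$top_percentile), ceiling(0.01 * nrow(net$nodes)))
  ## equal degrees: ties resolved lexicographically, flag set has size
  ## ceiling(p% x N)
  e <- mk_edges(tf = rep(c("tb", "ta"), each = 2),
                target = c("g1", "g2", "g3", "g4"))
  net2 <- filter_to_degs(e, unique(c(e$tf, e$target)), c("ta", "tb"))
  net2 <- rank_by_out_degree(net2, percentile = 40)
  expect_equal(net2$ranking$tf, c("ta", "tb"))
  expect_equal(sum(net2$nodes$top_percentile), ceiling(0.4 * 6))
  ## random graphs: ranking equals an order() oracle
  set.seed(18)
  for (i in 1:10) {
    tfs <- paste0("t", 1:8)
    re <- unique(mk_edges(tf = sample(tfs, 60, TRUE),
                          target = sample(paste0("g", 1:30), 60, TRUE)))
    nr <- rank_by_out_degree(filter_to_degs(
      re, unique(c(re$tf, re$target)), tfs))
    deg <- vapply(tfs, function(t) sum(re$tf == t), integer(1))
    present <- tfs[tfs %in% nr$nodes$node]
    want <- present[order(-deg[present], present)]
    expect_equal(nr$ranking$tf, want)
  }
})

test_that("TF activity scoring matches hypergeometric enumeration", {
  universe <- sprintf("g%03d", 1:10)
  e <- mk_edges(tf = rep("t1", 5), target = universe[1:5])
  net <- list(edges = e,
              nodes = data.frame(node = c("t1", universe[1:5]),
                                 is_tf = c(TRUE, rep(FALSE, 5))))
  class(net) <- "regnet"
  ## targets == DEGs, 5 of 10: single extreme arrangement
  r <- tf_activity_enrichment(net, universe[1:5], c("t1", universe)[2:11])
  expect_equal(r$p, 1 / choose(10, 5))
  ## random tables vs enumeration to 1e-12
  set.seed(19)
  for (i in 1:40) {
    uni <- sprintf("u%03d", 1:sample(50:200, 1))
    tgt <- sample(uni, sample(5:30, 1))
    deg <- sample(uni, sample(5:min(80, length(uni)), 1))
    e2 <- mk_edges(tf = "tf", target = tgt)
    n2 <- structure(list(edges = e2,
                         nodes = data.frame(node = c("tf", tgt),
                                            is_tf = c(TRUE, rep(FALSE,
                                                                length(tgt))))),
                    class = "regnet")
    r2 <- tf_activity_enrichment(n2, deg, uni)
    a <- length(intersect(tgt, deg))
    expect_equal(r2$p, oracle_fisher_greater(
      a, length(tgt) - a, length(deg) - a,
      length(uni) - length(tgt) - length(deg) + a), tolerance = 1e-12)
  }
  ## independence null: p roughly uniform
  set.seed(20)
  ps <- replicate(300, {
    uni <- sprintf("u%03d", 1:100)
    n3 <- structure(list(edges = mk_edges(tf = "tf",
                                          target = sample(uni, 20)),
                         nodes = data.frame(node = "tf", is_tf = TRUE)),
                    class = "regnet")
    tf_activity_enrichment(n3, sample(uni, 30), uni)$p
  })
  expect_gt(mean(ps), 0.35)  # discrete one-sided p: mean >= 0.5 - granularity
  expect_lt(mean(ps <= 0.05), 0.1)
})

test_that("network serialisation round-trips edges, nodes and flags", {
  e <- mk_edges(tf = c("t1", "t1", "t2"), target = c("g1", "g2", "g1"))
  net <- filter_to_degs(e, c("t1", "t2", "g1", "g2"), c("t1", "t2"))
  net <- classify_nodes(net, data.frame(
    gene = "t1", up_in_ko = TRUE, down_in_rescue = TRUE,
    has_hypo_regulatory_dmr = TRUE))
  net <- rank_by_out_degree(net)
  dir <- withr::local_tempdir()
  write_network(net, file.path(dir, "net"))
  back <- read_network(file.path(dir, "net"))
  expect_equal(back$edges[, c("tf", "target")], net$edges[, c("tf", "target")])
  expect_equal(back$nodes$node, net$nodes$node)
  expect_equal(back$nodes$class, net$nodes$class)
  expect_equal(back$nodes$out_degree, net$nodes$out_degree)
  expect_true(file.exists(file.path(dir, "net.graphml")))
})
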